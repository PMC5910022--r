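test_that("generators are pure functions of spec and seed", {
  a <- make_hinge_model(opening_angle = 12, seed = 9)
  b <- make_hinge_model(opening_angle = 12, seed = 9)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- make_hinge_model(opening_angle = 12, seed = 10)
  expect_false(identical(a$b_factor, c$b_factor))
  expect_identical(a$x, c$x) # coordinates are analytic, seed only jitters B

  t1 <- hdx_ground_truth(seed = 3)
  t2 <- hdx_ground_truth(seed = 3)
  expect_identical(t1, t2)
  d1 <- make_hdx_dataset(t1, seed = 4)$measurements
  d2 <- make_hdx_dataset(t1, seed = 4)$measurements
  expect_identical(d1, d2)

  s1 <- make_saxs_data(rg = 38, seed = 6)
  s2 <- make_saxs_data(rg = 38, seed = 6)
  expect_identical(s1$intensity, s2$intensity)
  k1 <- make_kinetic_series(seed = 8)
  expect_identical(k1, make_kinetic_series(seed = 8))

  # generators do not disturb the caller's RNG stream
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  invisible(make_hinge_model(seed = 2))
  expect_identical(rnorm(1), before)
})

test_that("hinge opening drives every conformational observable monotonically", {
  dom <- hinge_domains()
  angles <- c(0, 5, 10, 15, 20, 30)
  met <- purrr::map_dfr(angles, function(ang) {
    s <- make_hinge_model(opening_angle = ang)
    coms <- lapply(c("D1", "D2", "D3", "D4"), function(nm) {
      center_of_mass(select_domain(s, dom[dom$name == nm, ]))
    })
    tibble::tibble(
      angle = ang,
      d14 = com_distance(coms[[1]], coms[[4]]),
      dih = com_dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]]),
      rg = model_rg(s)
    )
  })
  expect_true(all(diff(met$d14) > 0))
  expect_true(all(diff(abs(met$dih - met$dih[1])) > 0))
  expect_true(all(diff(met$rg) > 0))
})

test_that("state classification on generator output recovers generated labels", {
  dom <- hinge_domains()
  ref_row <- conformation_report(
    make_hinge_model(opening_angle = 0), domains = dom, compute_bsa = FALSE
  )
  reference <- list(
    d1d4_distance = ref_row$d1d4_distance[1],
    com_dihedral_abs = ref_row$com_dihedral_abs[1]
  )
  # noise-free generated states must classify correctly in every case
  cases <- tibble::tribble(
    ~angle, ~label,
    0, "C", 1, "C", 4, "pO", 8, "pO", 25, "O", 40, "O"
  )
  got <- vapply(cases$angle, function(ang) {
    r <- conformation_report(
      make_hinge_model(opening_angle = ang), domains = dom,
      reference = reference, compute_bsa = FALSE
    )
    r$state[1]
  }, "")
  expect_equal(got, cases$label)
})

test_that("synthetic HDX maps satisfy the coverage contract", {
  truth <- hdx_ground_truth(n_residues = 96)
  covered <- rep(0, 96)
  for (i in seq_len(nrow(truth$map))) {
    idx <- truth$map$start[i]:truth$map$end[i]
    covered[idx] <- covered[idx] + 1
  }
  expect_gte(mean(covered >= 1), 0.90)
  expect_gte(mean(covered >= 2), 0.30)
  expect_true(all(nchar(truth$map$sequence) ==
                    truth$map$end - truth$map$start + 1))
})

test_that("HDX simulation honours rate limits", {
  interval <- tibble::tibble(condition = "bound", start = 5L, end = 12L, factor = 3)
  base <- hdx_ground_truth(
    n_residues = 20, peptide_length = 8, protected_intervals = interval
  )
  zero <- base
  for (cond in zero$conditions) zero$rates[[cond]] <- rep(0, 20)
  ds0 <- make_hdx_dataset(zero, noise_sd_pct = 0)
  up0 <- hdx_uptake(ds0$measurements, ds0$controls)
  expect_true(all(up0$percent_d == 0))

  sat <- base
  for (cond in sat$conditions) sat$rates[[cond]] <- rep(Inf, 20)
  ds1 <- make_hdx_dataset(sat, timepoints = 10, noise_sd_pct = 0)
  up1 <- hdx_uptake(ds1$measurements, ds1$controls)
  expect_true(all(abs(up1$percent_d - 100) < 1e-9))

  # replicate SD below 2% of the mean, as generated
  truth <- hdx_ground_truth()
  ds <- make_hdx_dataset(truth, seed = 2)
  agg <- hdx_aggregate(hdx_uptake(ds$measurements, ds$controls))
  busy <- agg[agg$percent_d_mean > 20, ]
  expect_lt(
    median(busy$percent_d_sd / busy$percent_d_mean), 0.02
  )
})

test_that("zero-noise SAXS data equal their generating curves", {
  h <- make_hinge_model()
  q <- seq(0.01, 0.2, by = 0.005)
  exact <- make_saxs_data(structure = h, q_grid = q, noise_pct = 0)
  expect_equal(exact$intensity, debye_curve(h, q_grid = q)$intensity)

  ideal <- make_saxs_data(rg = 38, noise_pct = 0)
  expect_equal(guinier_fit(ideal)$rg, 38, tolerance = 1e-6)

  ks <- make_kinetic_series(noise_pct = 0, tau = 0.25)
  expect_equal(
    ks$rg, 35 + 5 * exp(-ks$time_s / 0.25),
    tolerance = 1e-12
  )
})
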