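gaussian_curve <- function(rg, q = seq(0.005, 0.04, by = 0.001), i0 = 1) {
  scattering_curve(q, i0 * exp(-q^2 * rg^2 / 3))
}

test_that("Guinier fit is exact on ideal curves and robust to noise", {
  fit <- guinier_fit(gaussian_curve(30))
  expect_equal(fit$rg, 30, tolerance = 1e-6)
  expect_equal(fit$i0, 1, tolerance = 1e-6)
  expect_lte(fit$q_range_used[2] * fit$rg, 1.3 + 1e-9)

  noisy <- make_saxs_data(rg = 38, noise_pct = 1, seed = 12,
                          q_grid = seq(0.003, 0.05, by = 5e-4))
  expect_equal(guinier_fit(noisy)$rg, 38, tolerance = 0.5)

  flat <- scattering_curve(seq(0.005, 0.04, by = 0.001), rep(2, 36))
  expect_error(guinier_fit(flat), "Guinier")
})

test_that("model Rg matches closed forms", {
  two <- as_structure(tibble::tibble(
    name = c("CA", "CA"), element = "C", chain_id = "A", res_seq = 1:2,
    x = c(0, 10), y = 0, z = 0
  ))
  expect_equal(model_rg(two), 5)
  one <- as_structure(tibble::tibble(
    name = "CA", element = "C", chain_id = "A", res_seq = 1, x = 3, y = 2, z = 1
  ))
  expect_equal(model_rg(one), 0)

  # uniform ball of radius R has Rg = sqrt(3/5) R
  set.seed(41)
  n <- 1e4
  R <- 25
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2)) * R * runif(n)^(1 / 3)
  ball <- as_structure(tibble::tibble(
    name = "CA", element = "C", chain_id = "A", res_seq = seq_len(n),
    x = u[, 1], y = u[, 2], z = u[, 3]
  ))
  expect_equal(model_rg(ball), sqrt(3 / 5) * R, tolerance = 0.01 * sqrt(3 / 5) * R)

  h <- make_hinge_model()
  moved <- as_structure(rigid_transform(h, c(2, 1, 1), 49, c(7, -3, 11)))
  expect_equal(model_rg(moved), model_rg(h), tolerance = 1e-9)
})

test_that("p(r) reproduces pair distances, Rg and dmax ordering", {
  two <- as_structure(tibble::tibble(
    name = c("CA", "CA"), element = "C", chain_id = "A", res_seq = 1:2,
    x = c(0, 10), y = 0, z = 0
  ))
  pd <- pddf_from_model(two, bin_width = 1, weighting = "uniform")
  expect_equal(sum(pd$p > 0), 1)
  expect_equal(pd$r[pd$p > 0], 10) # bin centred on the 10 A pair distance
  expect_equal(attr(pd, "rg"), 5, tolerance = 1e-9) # two points: Rg = d/2
  expect_equal(attr(pd, "dmax"), 10)

  h <- make_hinge_model()
  pd_h <- pddf_from_model(h, bin_width = 1, weighting = "mass")
  expect_equal(attr(pd_h, "rg"), model_rg(h), tolerance = 1)

  open <- make_hinge_model(opening_angle = 30)
  expect_gt(
    attr(pddf_from_model(open), "dmax"),
    attr(pddf_from_model(h), "dmax")
  )
})

test_that("Debye curves honour limits and are Guinier-consistent", {
  two <- as_structure(tibble::tibble(
    name = c("CA", "CA"), element = "C", chain_id = "A", res_seq = 1:2,
    res_name = "GLY", x = c(0, 10), y = 0, z = 0
  ))
  cv <- debye_curve(two, q_grid = c(1e-6, 0.01), weighting = "uniform")
  expect_equal(cv$intensity[1], 4, tolerance = 1e-6) # (sum w)^2 at q -> 0

  one <- debye_curve(two[1, ], q_grid = seq(0.01, 0.3, 0.01), weighting = "uniform")
  expect_true(all(one$intensity == 1)) # single scatterer is flat w^2

  h <- make_hinge_model()
  cv_h <- debye_curve(h, q_grid = seq(0.002, 0.08, by = 0.001))
  rg_guinier <- guinier_fit(cv_h)$rg
  rg_model <- model_rg(h, weighting = "electron")
  expect_equal(rg_guinier, rg_model, tolerance = 0.02 * rg_model)
})

test_that("chi comparison discriminates models and ignores overall scale", {
  h_open <- make_hinge_model(opening_angle = 30)
  h_closed <- make_hinge_model(opening_angle = 0)
  q <- seq(0.01, 0.2, by = 0.002)
  exp_open <- make_saxs_data(structure = h_open, q_grid = q, noise_pct = 1, seed = 3)

  mod_open <- debye_curve(h_open, q_grid = seq(0.005, 0.25, by = 0.002))
  mod_closed <- debye_curve(h_closed, q_grid = seq(0.005, 0.25, by = 0.002))
  chi_o <- chi_compare(exp_open, mod_open)$chi
  chi_c <- chi_compare(exp_open, mod_closed)$chi
  expect_lt(chi_o, chi_c)
  expect_lt(chi_o, 2) # correct model fits within noise

  self <- chi_compare(
    dplyr::mutate(mod_open, sigma = 1),
    mod_open
  )
  expect_equal(self$chi, 0, tolerance = 1e-9)

  scaled <- dplyr::mutate(exp_open, intensity = intensity * 7, sigma = sigma * 7)
  expect_equal(chi_compare(scaled, mod_open)$chi, chi_o, tolerance = 1e-6)

  short <- debye_curve(h_open, q_grid = seq(0.05, 0.1, by = 0.002))
  expect_error(chi_compare(exp_open, short), "beyond")
})

test_that("exponential relaxation fit recovers tau and endpoints", {
  clean <- make_kinetic_series(noise_pct = 0)
  f <- fit_exp_decay(clean$time_s, clean$rg)
  expect_equal(f$tau, 0.1, tolerance = 1e-6)
  expect_equal(f$rg_initial, 40, tolerance = 1e-6)
  expect_equal(f$rg_final, 35, tolerance = 1e-6)

  taus <- vapply(1:50, function(sd) {
    ks <- make_kinetic_series(noise_pct = 2, seed = sd)
    fit_exp_decay(ks$time_s, ks$rg, ks$sigma)$tau
  }, 1)
  expect_lt(abs(median(taus) - 0.1) / 0.1, 0.05)

  expect_error(fit_exp_decay(c(0, 0.1, 0.2, 0.3), rep(40, 4)), "constant")
  expect_error(fit_exp_decay(c(0, 0.1), c(40, 39)), "4 time points")
})

test_that("the 3-column curve reader accepts comments and comma dialects", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "# q I sigma", "0.01 100.0 1.0", "0.02 80.0 0.9", "0.03, 55.0, 0.8"
  ), path)
  cv <- read_saxs_curve(path)
  expect_equal(nrow(cv), 3)
  expect_equal(cv$q, c(0.01, 0.02, 0.03))
  expect_equal(cv$sigma, c(1.0, 0.9, 0.8))
  expect_error(
    scattering_curve(c(0.02, 0.01), c(1, 2)),
    "increasing"
  )
})
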