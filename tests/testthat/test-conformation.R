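test_that("center of mass matches hand arithmetic for all weightings", {
  two <- as_structure(tibble::tibble(
    name = c("CA", "CA"), element = "C", chain_id = "A", res_seq = 1:2,
    x = c(0, 2), y = 0, z = 0
  ))
  expect_equal(unname(center_of_mass(two, "uniform")), c(1, 0, 0))

  one <- as_structure(tibble::tibble(
    name = "CA", element = "C", chain_id = "A", res_seq = 1,
    x = 5, y = 5, z = 5
  ))
  expect_equal(unname(center_of_mass(one)), c(5, 5, 5))

  co <- as_structure(tibble::tibble(
    name = c("C1", "O1"), element = c("C", "O"), chain_id = "A", res_seq = 1:2,
    x = c(0, 1.6), y = 0, z = 0
  ))
  # mass-weighted x = m_O * 1.6 / (m_C + m_O), recomputed by hand
  expect_equal(
    center_of_mass(co)[["x"]],
    15.999 * 1.6 / (12.011 + 15.999),
    tolerance = 1e-10
  )
  expect_equal(center_of_mass(co)[["x"]], 0.9139, tolerance = 1e-3)

  expect_error(center_of_mass(two[0, ]), "empty")
})

test_that("com_distance is the Euclidean norm", {
  expect_equal(com_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(com_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(21)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(com_distance(a, b), sqrt(sum((a - b)^2)), tolerance = 1e-9)
  }
})

test_that("dihedral reproduces closed forms and the normal-vector oracle", {
  expect_equal(
    com_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0,
    tolerance = 1e-10
  )
  expect_equal(
    com_dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)), 180,
    tolerance = 1e-10
  )
  set.seed(7)
  for (i in 1:25) {
    pts <- lapply(1:4, function(k) rnorm(3, sd = 3))
    expect_equal(
      com_dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      dihedral_oracle(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
      tolerance = 1e-6
    )
  }
  expect_error(
    com_dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
    "collinear"
  )
})

test_that("dihedral is invariant to rigid motion, scaling and reversal", {
  set.seed(8)
  for (i in 1:10) {
    pts <- matrix(rnorm(12, sd = 4), 4, 3)
    ref <- com_dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    R <- conformeter:::rotation_matrix_axis_angle(rnorm(3), runif(1, 0, 360))
    shift <- rnorm(3, sd = 10)
    moved <- t(R %*% t(pts)) + matrix(shift, 4, 3, byrow = TRUE)
    expect_equal(
      com_dihedral(moved[1, ], moved[2, ], moved[3, ], moved[4, ]), ref,
      tolerance = 1e-8
    )
    sc <- pts * 3.7
    expect_equal(
      com_dihedral(sc[1, ], sc[2, ], sc[3, ], sc[4, ]), ref,
      tolerance = 1e-8
    )
    expect_equal(
      com_dihedral(pts[4, ], pts[3, ], pts[2, ], pts[1, ]), ref,
      tolerance = 1e-8
    )
  }
})

test_that("region B factors: mean/population-SD and planted-offset recovery", {
  s <- ca_chain(2, b = c(20, 30))
  d <- domain_definition("r", "A", list(c(1, 2)))
  bf <- region_bfactor(s, d)
  expect_equal(bf$b_mean, 25)
  expect_equal(bf$b_sd, 5)

  one <- region_bfactor(ca_chain(1, b = 40), domain_definition("r", "A", list(c(1, 1))))
  expect_equal(one$b_mean, 40)
  expect_equal(one$b_sd, 0)

  dom <- hinge_domains()
  hb <- make_hinge_model(door_b_offset = 30, seed = 11)
  base <- make_hinge_model(door_b_offset = 0, seed = 11)
  offset <- region_bfactor(hb, dom[dom$name == "door", ])$b_mean -
    region_bfactor(base, dom[dom$name == "door", ])$b_mean
  expect_equal(offset, 30, tolerance = 1)
})

test_that("state classification follows the distance/dihedral cut-offs", {
  ref <- list(d1d4_distance = 30, com_dihedral_abs = 20)
  expect_equal(classify_state(30, 20, ref), "C")
  expect_equal(classify_state(30.5, 18, ref), "pC") # ~2 deg dihedral decrease
  expect_equal(classify_state(35, 25, ref), "pO")
  expect_equal(classify_state(50, 30, ref), "O")
  expect_equal(classify_state(44, 20, ref, thresholds = list(open_dist = 15)), "pO")
  expect_error(classify_state(30, 20, list()), "reference")
})

test_that("conformation report labels synthetic dimers by generated state", {
  dom <- hinge_domains()
  closed <- make_hinge_model(opening_angle = 0)
  ref_row <- conformation_report(closed, domains = dom, compute_bsa = FALSE)
  reference <- list(
    d1d4_distance = ref_row$d1d4_distance[1],
    com_dihedral_abs = ref_row$com_dihedral_abs[1]
  )

  dimer <- make_hinge_model(opening_angle = 0, dimerize = TRUE)
  rep_c <- conformation_report(dimer, domains = dom, reference = reference)
  expect_equal(nrow(rep_c), 2)
  expect_equal(rep_c$chain, c("A", "B"))
  expect_equal(rep_c$state, c("C", "C"))
  expect_true(all(rep_c$buried_area > 0))

  # mixed-state dimer: open subunit + partially open subunit
  open_a <- tibble::as_tibble(make_hinge_model(opening_angle = 30))
  po_b <- tibble::as_tibble(make_hinge_model(opening_angle = 6))
  po_b$chain_id <- "B"
  po_b$x <- po_b$x + 500
  po_b$serial <- po_b$serial + nrow(open_a)
  mixed <- as_structure(dplyr::bind_rows(open_a, po_b))
  rep_m <- conformation_report(mixed,
    domains = dom, reference = reference, compute_bsa = FALSE
  )
  expect_equal(rep_m$state, c("O", "pO"))

  # monomer input: single record, no error
  rep_1 <- conformation_report(closed,
    domains = dom, reference = reference, compute_bsa = FALSE
  )
  expect_equal(nrow(rep_1), 1)

  # missing domain errors name the chain and domain
  trunc <- closed[closed$res_seq <= 60, ]
  expect_error(
    conformation_report(as_structure(trunc), domains = dom, compute_bsa = FALSE),
    "D3"
  )
})
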