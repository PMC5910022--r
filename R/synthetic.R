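# All generators are pure functions of (spec, seed): RNG state is scoped
# and restored, so identical calls give identical output.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rotation_matrix_axis_angle <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Calpha trace of one ideal alpha helix along +x
helix_trace <- function(n, origin_y, origin_z, x0 = 0) {
  i <- seq_len(n) - 1
  cbind(
    x0 + 1.5 * i,
    origin_y + 2.3 * cos(i * 100 * pi / 180),
    origin_z + 2.3 * sin(i * 100 * pi / 180)
  )
}

#' Synthetic two-lobe hinge model
#'
#' Builds a pseudo-atomic clamshell: two Calpha-trace four-helix lobes
#' stacked face to face (lobe 1 below the interface plane, lobe 2 above),
#' joined by a 3-residue linker at the hinge. Lobe 2 is rotated by
#' `opening_angle` about `hinge_axis` through the hinge point, so the free
#' ends separate like a book opening — the geometry that drives the
#' domain-COM distance/dihedral, buried-area and Rg analyses. B factors
#' are 30 A^2 baseline with seeded jitter (sd 0.5) and `door_b_offset`
#' added to the designated door region. The default hinge axis is tilted
#' off the interface normal plane so that opening changes the four-domain
#' COM dihedral as well as the D1-D4 distance.
#'
#' @param n_residues_per_lobe Residues per lobe (multiple of 4).
#' @param opening_angle Degrees in \[0, 60\].
#' @param hinge_axis Rotation axis (normalized internally).
#' @param door_b_offset B-factor offset (A^2) applied to the door region.
#' @param seed RNG seed (B-factor jitter only; coordinates are analytic).
#' @param dimerize Add a second subunit (chain B) related by a 2-fold?
#' @return A `conf_structure` of CA pseudo-atoms, chain "A" (and "B").
#' @export
make_hinge_model <- function(n_residues_per_lobe = 60, opening_angle = 0,
                             hinge_axis = c(-0.20, -0.95, -0.24),
                             door_b_offset = 0, seed = 1, dimerize = FALSE) {
  if (opening_angle < 0 || opening_angle > 60) {
    abort_config("opening_angle must be in [0, 60] degrees")
  }
  n_hel <- n_residues_per_lobe %/% 4
  x_far <- 1.5 * n_hel + 3 # far subdomain starts past the near one
  # lobe 1 (below z = 0): far-from-hinge subdomain first (residues of D1),
  # then the near-hinge subdomain (D2); two helices per subdomain
  lobe1 <- rbind(
    helix_trace(n_hel, -1.5, -4, x0 = x_far),
    helix_trace(n_hel, 4.5, -8, x0 = x_far),
    helix_trace(n_hel, -1.5, -8, x0 = 0),
    helix_trace(n_hel, 4.5, -4, x0 = 0)
  )
  lobe2 <- lobe1
  lobe2[, 3] <- -lobe2[, 3] # mirror above the interface plane
  # lobe 2 runs hinge-outwards: near subdomain (D3) first, far (D4) last
  lobe2 <- lobe2[c((2 * n_hel + 1):(4 * n_hel), 1:(2 * n_hel)), , drop = FALSE]
  hinge_point <- c(0, 1.5, 0)
  if (opening_angle > 0) {
    R <- rotation_matrix_axis_angle(hinge_axis, opening_angle)
    lobe2 <- t(R %*% t(sweep(lobe2, 2, hinge_point))) +
      matrix(hinge_point, nrow(lobe2), 3, byrow = TRUE)
  }
  linker <- cbind(c(-2.5, -3.5, -2.5), c(1.5, 1.5, 1.5), c(-2.0, 0, 2.0))
  xyz <- rbind(lobe1, linker, lobe2)
  n_total <- nrow(xyz)
  dom <- hinge_domains(n_residues_per_lobe)
  door <- dom[dom$name == "door", ]
  res_seq <- seq_len(n_total)
  b <- with_seed(seed, 30 + rnorm(n_total, sd = 0.5))
  b[res_seq >= door$start & res_seq <= door$end] <-
    b[res_seq >= door$start & res_seq <= door$end] + door_b_offset
  b <- pmax(b, 0)
  atoms <- tibble::tibble(
    serial = res_seq, name = "CA", element = "C", res_name = "ALA",
    chain_id = "A", res_seq = res_seq,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = b
  )
  if (dimerize) {
    two_fold <- atoms
    two_fold$chain_id <- "B"
    two_fold$x <- -20 - atoms$x
    two_fold$y <- -atoms$y
    two_fold$serial <- atoms$serial + n_total
    atoms <- dplyr::bind_rows(atoms, two_fold)
  }
  as_structure(atoms, source_id = sprintf(
    "synthetic-hinge(angle=%g,seed=%d)", opening_angle, seed
  ))
}

#' Domain partition of the synthetic hinge model
#'
#' Mirrors the four-domain layout of a clamshell protease on the hinge
#' model's numbering: D1/D2 split lobe 1 (far-from-hinge half first, as
#' the helices run away from the hinge), D3/D4 split lobe 2, the N and C
#' halves are the two lobes, and "door" is a quarter-lobe stretch inside
#' D1 used for B-factor planting.
#'
#' @param n_residues_per_lobe Must match [make_hinge_model()].
#' @param chain_id Chain to attach the partition to.
#' @return A domain-definition tibble with names D1-D4, IDE-N, IDE-C, door.
#' @export
hinge_domains <- function(n_residues_per_lobe = 60, chain_id = "A") {
  n <- n_residues_per_lobe
  half <- n %/% 2
  l2 <- n + 3L # lobe 2 starts after the 3-residue linker
  dplyr::bind_rows(
    domain_definition("D1", chain_id, list(c(1L, half))),
    domain_definition("D2", chain_id, list(c(half + 1L, n))),
    domain_definition("D3", chain_id, list(c(l2 + 1L, l2 + half))),
    domain_definition("D4", chain_id, list(c(l2 + half + 1L, l2 + n))),
    domain_definition("IDE-N", chain_id, list(c(1L, n))),
    domain_definition("IDE-C", chain_id, list(c(l2 + 1L, l2 + n))),
    domain_definition("door", chain_id, list(c(half %/% 2L, half %/% 2L + n %/% 8L)))
  )
}

#' Ground truth for a synthetic HDX experiment
#'
#' Draws a protein sequence and per-residue intrinsic exchange rates
#' (log-uniform over 10^-5..1 s^-1, spanning the 10-100,000 s schedule),
#' and a peptic peptide map of overlapping peptides (tiling stride =
#' half the peptide length, so interior residues are covered twice;
#' coverage >= 90% with >= 30% multi-coverage). Conditions slow selected
#' residue ranges by a protection factor.
#'
#' @param n_residues Protein length.
#' @param protected_intervals Tibble/data frame with `condition`, `start`,
#'   `end`, `factor` (rate division factor > 1). Residues outside keep
#'   apo rates.
#' @param conditions Condition labels; the first is the unperturbed
#'   reference.
#' @param peptide_length Peptide length (tiling uses stride length/2).
#' @param seed RNG seed.
#' @return List: `sequence`, `rates` (tibble residue x condition), `map`
#'   (peptide tibble), `protected_intervals`.
#' @export
hdx_ground_truth <- function(n_residues = 96,
                             protected_intervals = NULL,
                             conditions = c("apo", "bound"),
                             peptide_length = 12, seed = 1) {
  if (is.null(protected_intervals)) {
    protected_intervals <- tibble::tibble(
      condition = conditions[2], start = 25L, end = 48L, factor = 3
    )
  }
  if (any(protected_intervals$start < 1) ||
      any(protected_intervals$end > n_residues)) {
    abort_config("protected interval outside 1..n_residues")
  }
  with_seed(seed, {
    aa_pool <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]] # no prolines by default
    sequence <- paste(sample(aa_pool, n_residues, replace = TRUE), collapse = "")
    k_base <- 10^runif(n_residues, -5, 0)
    rates <- tibble::tibble(res_seq = seq_len(n_residues))
    for (cond in conditions) {
      k <- k_base
      pi_c <- protected_intervals[protected_intervals$condition == cond, , drop = FALSE]
      for (i in seq_len(nrow(pi_c))) {
        idx <- pi_c$start[i]:pi_c$end[i]
        k[idx] <- k[idx] / pi_c$factor[i]
      }
      rates[[cond]] <- k
    }
    stride <- max(1L, peptide_length %/% 2L)
    starts <- unique(c(seq(1L, n_residues - peptide_length + 1L, by = stride),
                       n_residues - peptide_length + 1L))
    map <- tibble::tibble(
      start = as.integer(starts),
      end = as.integer(starts + peptide_length - 1L)
    )
    # variable-length digestion: short anchor peptides at regular spots pin
    # the half-overlap tiling chain to full rank
    anchor_starts <- seq(1L, n_residues - stride + 1L, by = 4L * stride)
    map <- dplyr::bind_rows(map, tibble::tibble(
      start = as.integer(anchor_starts),
      end = as.integer(anchor_starts + stride - 1L)
    ))
    map <- dplyr::distinct(dplyr::arrange(map, .data$start, .data$end))
    map$sequence <- substring(sequence, map$start, map$end)
    list(
      sequence = sequence, rates = rates, map = map,
      protected_intervals = tibble::as_tibble(protected_intervals),
      conditions = conditions, seed = seed
    )
  })
}

#' Simulate an HDX peptide measurement table
#'
#' Per-peptide uptake is the sum over its exchangeable residues of
#' `1 - exp(-k t)`, converted to a centroid mass with a back-exchange
#' retention factor (the equilibrium-deuterated control sits at
#' `m_nondeut + retention * 1.00628 * n_exch`), then perturbed by Gaussian
#' noise of `noise_sd_pct` percent of the true deuteron count —
#' emulating triplicate determinations with SD below 2% of the mean.
#'
#' @param truth Output of [hdx_ground_truth()].
#' @param timepoints Exchange times, seconds.
#' @param n_replicates Replicates per peptide/time/condition.
#' @param noise_sd_pct Relative noise, percent of the true deuteron count.
#' @param retention Deuterium retention after workup (back-exchange = 1 -
#'   retention).
#' @param seed RNG seed.
#' @return List: `measurements` (condition, sequence, start, end, time_s,
#'   replicate, centroid_mass), `controls` (m_nondeut, m_equil per
#'   peptide), `truth` (echoed).
#' @export
make_hdx_dataset <- function(truth,
                             timepoints = c(10, 100, 1000, 1e4, 1e5),
                             n_replicates = 3, noise_sd_pct = 1,
                             retention = 0.7, seed = 1) {
  map <- truth$map
  n_pep <- nrow(map)
  n_exch <- vapply(map$sequence, exchangeable_amides, 1L, USE.NAMES = FALSE)
  # crude average residue mass is enough: controls bracket the scale
  m_nd <- 110 * nchar(map$sequence) + 18
  m_eq <- m_nd + retention * 1.00628 * n_exch
  controls <- tibble::tibble(
    sequence = map$sequence, start = map$start, end = map$end,
    m_nondeut = m_nd, m_equil = m_eq
  )
  grid <- tidyr::expand_grid(
    condition = truth$conditions, pep = seq_len(n_pep),
    time_s = timepoints, replicate = seq_len(n_replicates)
  )
  d_true <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    i <- grid$pep[r]
    k <- truth$rates[[grid$condition[r]]][map$start[i]:map$end[i]]
    aa <- strsplit(map$sequence[i], "")[[1]]
    exch <- seq_along(aa) > 1 & aa != "P"
    d_true[r] <- sum((1 - exp(-k[exch] * grid$time_s[r])))
  }
  noise <- with_seed(seed, rnorm(nrow(grid), sd = 1))
  d_obs <- d_true + noise * (noise_sd_pct / 100) * d_true
  i <- grid$pep
  centroid <- m_nd[i] + pmin(1, pmax(0, ifelse(n_exch[i] > 0, d_obs / n_exch[i], 0))) *
    (m_eq[i] - m_nd[i])
  measurements <- tibble::tibble(
    condition = grid$condition,
    sequence = map$sequence[i], start = map$start[i], end = map$end[i],
    time_s = grid$time_s, replicate = grid$replicate,
    centroid_mass = centroid
  )
  list(measurements = measurements, controls = controls, truth = truth)
}

#' Exact segment-level truth for a synthetic HDX dataset
#'
#' Computes, from the generating rates, the true percent deuteration of
#' each residue segment per condition and time point (mean of
#' `1 - exp(-k t)` over the segment's residues) and the true differential
#' between two conditions — the ground truth against which significance
#' calls are judged.
#'
#' @param truth Output of [hdx_ground_truth()].
#' @param segments Tibble with `start`, `end`.
#' @param timepoints Times, seconds.
#' @param condition,reference Condition labels.
#' @return Tibble: segment bounds, `time_s`, `true_delta_percent_d`,
#'   `true_max_abs_delta`.
#' @export
hdx_truth_delta <- function(truth, segments,
                            timepoints = c(10, 100, 1000, 1e4, 1e5),
                            condition = "bound", reference = "apo") {
  out <- tidyr::expand_grid(
    segments[, c("start", "end")], time_s = timepoints
  )
  out$true_delta_percent_d <- vapply(seq_len(nrow(out)), function(r) {
    idx <- out$start[r]:out$end[r]
    kc <- truth$rates[[condition]][idx]
    kr <- truth$rates[[reference]][idx]
    100 * mean((1 - exp(-kc * out$time_s[r])) - (1 - exp(-kr * out$time_s[r])))
  }, 1)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(out, .data$start, .data$end),
    true_max_abs_delta = max(abs(.data$true_delta_percent_d))
  ))
}

#' Simulated SAXS curve
#'
#' From a structure: the coarse Debye curve plus seeded Gaussian noise of
#' `noise_pct` percent of each intensity (sigma column records the noise
#' scale). From an Rg value: the ideal Guinier form
#' `I = i0 exp(-q^2 Rg^2 / 3)`.
#'
#' @param structure Optional `conf_structure` (wins over `rg`).
#' @param rg Optional Rg for the Gaussian ideal curve.
#' @param q_grid Momentum-transfer grid.
#' @param noise_pct Relative noise, percent (0 = exact curve).
#' @param i0 Forward intensity for the ideal curve.
#' @param seed RNG seed.
#' @return A scattering-curve tibble with `sigma`.
#' @export
make_saxs_data <- function(structure = NULL, rg = NULL,
                           q_grid = seq(0.005, 0.25, by = 0.0025),
                           noise_pct = 1, i0 = 1, seed = 1) {
  base <- if (!is.null(structure)) {
    debye_curve(structure, q_grid)
  } else if (!is.null(rg)) {
    scattering_curve(q_grid, i0 * exp(-q_grid^2 * rg^2 / 3))
  } else {
    abort_input("need a structure or an rg value")
  }
  sigma <- pmax(noise_pct / 100 * base$intensity, 1e-12 * max(base$intensity))
  I <- if (noise_pct > 0) {
    base$intensity + with_seed(seed, rnorm(length(sigma), sd = sigma))
  } else {
    base$intensity
  }
  out <- scattering_curve(q_grid, I, sigma)
  attr(out, "coarse") <- attr(base, "coarse")
  out
}

#' Simulated time-resolved Rg relaxation series
#'
#' Single-exponential law `Rg(t) = rg_final + (rg_initial - rg_final)
#' exp(-t / tau)` with seeded Gaussian noise — the substrate-induced
#' open-to-closed collapse with its ~0.1 s time constant, observed over a
#' 2 s mixing window.
#'
#' @param rg_initial,rg_final Endpoint Rg values, Angstrom.
#' @param tau Relaxation time, seconds.
#' @param times Observation times, seconds.
#' @param noise_pct Gaussian noise, percent of each true Rg.
#' @param seed RNG seed.
#' @return Tibble: `time_s`, `rg`, `sigma`.
#' @export
make_kinetic_series <- function(rg_initial = 40, rg_final = 35, tau = 0.1,
                                times = seq(0.005, 2, length.out = 30),
                                noise_pct = 1, seed = 1) {
  if (tau <= 0) abort_config("tau must be positive")
  rg_true <- rg_final + (rg_initial - rg_final) * exp(-times / tau)
  sigma <- noise_pct / 100 * rg_true
  rg <- if (noise_pct > 0) {
    rg_true + with_seed(seed, rnorm(length(times), sd = sigma))
  } else {
    rg_true
  }
  tibble::tibble(time_s = times, rg = rg, sigma = sigma)
}
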