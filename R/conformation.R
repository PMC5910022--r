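#' Centre of mass of a structure
#'
#' @param structure A `conf_structure` (already selected to the region of
#'   interest).
#' @param weighting `"mass"` (atomic masses, default), `"uniform"` (all
#'   weights 1), or `"ca_only"` (mass weighting over the Calpha subset).
#' @return Named numeric `c(x, y, z)` in Angstrom.
#' @export
center_of_mass <- function(structure, weighting = c("mass", "uniform", "ca_only")) {
  weighting <- match.arg(weighting)
  s <- structure
  if (weighting == "ca_only") {
    s <- s[s$name == "CA" & toupper(s$element) == "C", , drop = FALSE]
  }
  if (nrow(s) == 0) abort_input("centre of mass of an empty selection")
  w <- if (weighting == "uniform") rep(1, nrow(s)) else s$mass
  c(
    x = sum(w * s$x) / sum(w),
    y = sum(w * s$y) / sum(w),
    z = sum(w * s$z) / sum(w)
  )
}

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
com_distance <- function(a, b) {
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Torsion angle of a four-point chain
#'
#' Standard dihedral of the chain p1 -> p2 -> p3 -> p4, computed with the
#' atan2 formulation. The conformational-state descriptor is the absolute
#' value in \[0, 180\] degrees; the signed angle is available for
#' diagnostics via `signed = TRUE`.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @param signed Return the signed angle in (-180, 180\]?
#' @return Angle in degrees.
#' @export
com_dihedral <- function(p1, p2, p3, p4, signed = FALSE) {
  b1 <- as.numeric(p2) - as.numeric(p1)
  b2 <- as.numeric(p3) - as.numeric(p2)
  b3 <- as.numeric(p4) - as.numeric(p3)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10 || nb2 < 1e-12) {
    abort_numeric("degenerate dihedral: three consecutive points are collinear")
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
  if (signed) ang else abs(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Mean and SD of B factors over a region
#'
#' Unweighted mean and population standard deviation of the isotropic
#' B factor over the heavy atoms selected by `region`.
#'
#' @param structure A `conf_structure`.
#' @param region A domain definition tibble.
#' @return A one-row tibble: `region`, `n_atoms`, `b_mean`, `b_sd`.
#' @export
region_bfactor <- function(structure, region) {
  sel <- select_domain(structure, region, heavy_only = TRUE)
  b <- sel$b_factor
  n <- length(b)
  tibble::tibble(
    region = region$name[1], n_atoms = n,
    b_mean = mean(b),
    b_sd = sqrt(sum((b - mean(b))^2) / n)
  )
}

#' Classify a subunit conformational state
#'
#' Labels a subunit open (O), partially open (pO), partially closed (pC) or
#' closed (C) from the change in D1-D4 centre-of-mass distance and COM
#' dihedral relative to a closed-state reference. Default cut-offs follow
#' the observed spreads — open-family states sit 5-24 A further apart and
#' 7-17 degrees more twisted than closed-family states, while pC differs
#' from C by an approximately 2 degree dihedral decrease at essentially
#' unchanged distance: C if ddist < 2 and |ddih| < 2; pC if ddist < 2 and
#' ddih <= -2; pO if 2 <= ddist < 12; O if ddist >= 12 (midpoint split of
#' the 5-24 A span).
#'
#' @param d1d4_distance,com_dihedral_abs Metrics of the subunit under test.
#' @param reference A list or one-row data frame with `d1d4_distance` and
#'   `com_dihedral_abs` of the closed-state reference, computed with
#'   identical domain bounds and weighting.
#' @param thresholds Named list overriding `closed_dist` (2), `open_dist`
#'   (12), `dihedral_tol` (2).
#' @return One of `"O"`, `"pO"`, `"pC"`, `"C"`.
#' @export
classify_state <- function(d1d4_distance, com_dihedral_abs, reference,
                           thresholds = list()) {
  th <- list(closed_dist = 2, open_dist = 12, dihedral_tol = 2)
  th[names(thresholds)] <- thresholds
  d_ref <- reference$d1d4_distance
  phi_ref <- reference$com_dihedral_abs
  if (is.null(d_ref) || is.null(phi_ref) || !is.finite(d_ref) || !is.finite(phi_ref)) {
    abort_config("reference metrics missing d1d4_distance / com_dihedral_abs")
  }
  dd <- d1d4_distance - d_ref
  dphi <- com_dihedral_abs - phi_ref
  if (dd >= th$open_dist) return("O")
  if (dd >= th$closed_dist) return("pO")
  if (dphi <= -th$dihedral_tol) return("pC")
  "C"
}

#' Per-subunit conformational report
#'
#' Assembles, for every chain of a (possibly dimeric) model, the D1-D4
#' centre-of-mass distance, the absolute COM dihedral of the D1-D2-D3-D4
#' chain, the buried surface between the N and C halves, region-averaged
#' B factors, and the O/pO/pC/C state label relative to a closed reference.
#'
#' @param structure A `conf_structure` covering one or more subunit chains.
#' @param domains Template domain partition for a single chain (the
#'   `chain_id` column is re-targeted to each chain found); defaults to
#'   [ide_domains()].
#' @param reference Optional closed-state reference metrics for
#'   [classify_state()] (list or one-row data frame with `d1d4_distance`,
#'   `com_dihedral_abs`). Without it, `state` is `NA`.
#' @param weighting Centre-of-mass weighting, see [center_of_mass()].
#' @param bfactor_regions Character vector of domain names whose B-factor
#'   means are appended as `b_<name>` columns (default `door`, `D3`).
#' @param compute_bsa Compute the buried N/C interface area (slowest step)?
#' @param thresholds Passed to [classify_state()].
#' @param probe_radius,n_points SASA parameters for the buried area.
#' @return A tibble, one row per chain, ordered by chain id: `source_id`,
#'   `chain`, `d1d4_distance`, `com_dihedral_abs`, `buried_area`, `state`,
#'   plus B-factor columns.
#' @export
conformation_report <- function(structure, domains = ide_domains(),
                                reference = NULL,
                                weighting = c("mass", "uniform", "ca_only"),
                                bfactor_regions = c("door", "D3"),
                                compute_bsa = TRUE, thresholds = list(),
                                probe_radius = 1.4, n_points = 960) {
  weighting <- match.arg(weighting)
  chains <- sort(unique(structure$chain_id))
  needed <- c("D1", "D2", "D3", "D4")
  purrr::map_dfr(chains, function(ch) {
    dom <- domains
    dom$chain_id <- ch
    for (nm in needed) {
      d <- dom[dom$name == nm, , drop = FALSE]
      if (nrow(d) == 0) abort_config(paste0("domain '", nm, "' missing from partition"))
      hit <- structure$chain_id == ch &
        structure$res_seq >= min(d$start) & structure$res_seq <= max(d$end)
      if (!any(hit)) {
        abort_input(sprintf("chain %s has no atoms in domain %s", ch, nm))
      }
    }
    coms <- lapply(needed, function(nm) {
      center_of_mass(select_domain(structure, domain_by_name(dom, nm)), weighting)
    })
    bsa <- NA_real_
    if (compute_bsa) {
      part_n <- select_domain(structure, domain_by_name(dom, "IDE-N"))
      part_c <- select_domain(structure, domain_by_name(dom, "IDE-C"))
      bsa <- buried_interface_area(part_n, part_c,
        probe_radius = probe_radius, n_points = n_points
      )
    }
    dist14 <- com_distance(coms[[1]], coms[[4]])
    dih <- com_dihedral(coms[[1]], coms[[2]], coms[[3]], coms[[4]])
    state <- NA_character_
    if (!is.null(reference)) {
      state <- classify_state(dist14, dih, reference, thresholds)
    }
    row <- tibble::tibble(
      source_id = structure_source(structure), chain = ch,
      d1d4_distance = dist14, com_dihedral_abs = dih,
      buried_area = bsa, state = state
    )
    for (rn in intersect(bfactor_regions, unique(dom$name))) {
      bf <- region_bfactor(structure, domain_by_name(dom, rn))
      row[[paste0("b_", rn)]] <- bf$b_mean
    }
    row
  })
}
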