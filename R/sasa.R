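#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling SASA: each atom's sphere of radius r_vdw + probe carries
#' `n_points` quasi-uniform test points (golden-section spiral, fully
#' deterministic); the accessible fraction is the fraction of points lying
#' outside every neighbouring expanded sphere, scaled by the sphere area
#' 4 pi (r_vdw + probe)^2. Radii are Bondi van der Waals radii.
#'
#' @param structure A `conf_structure`; all elements must have a tabulated
#'   van der Waals radius.
#' @param probe_radius Solvent probe radius in Angstrom (water: 1.4).
#' @param n_points Test points per atom sphere.
#' @return A `sasa_result`: list with `atoms` (per-atom tibble including
#'   `area`), `total_area`, `probe_radius`, `n_points`.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960) {
  if (nrow(structure) == 0) abort_input("SASA of an empty structure")
  r <- element_vdw_radius(structure$element) + probe_radius
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  areas <- shrake_rupley_areas(xyz, r, n_points)
  out <- list(
    atoms = dplyr::mutate(tibble::as_tibble(structure), area = areas),
    total_area = sum(areas),
    probe_radius = probe_radius,
    n_points = as.integer(n_points)
  )
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(
    "Shrake-Rupley SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points/atom)\n",
    x$total_area, nrow(x$atoms), x$probe_radius, x$n_points
  ))
  invisible(x)
}

#' @rdname sasa
#' @param x A `sasa_result`.
#' @param ... Unused.
#' @export
tidy.sasa_result <- function(x, ...) {
  dplyr::select(
    x$atoms, "serial", "name", "element", "chain_id", "res_seq", "area"
  )
}

#' @rdname sasa
#' @export
glance.sasa_result <- function(x, ...) {
  tibble::tibble(
    total_area = x$total_area, n_atoms = nrow(x$atoms),
    probe_radius = x$probe_radius, n_points = x$n_points
  )
}

# deterministic quasi-uniform unit sphere points (golden-section spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

shrake_rupley_areas <- function(xyz, r, n_points) {
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (r[i] + rmax)^2 & d2 > 1e-12)
    nb <- nb[d2[nb] < (r[i] + r[nb])^2]
    if (length(nb) == 0) {
      areas[i] <- 4 * pi * r[i]^2
      next
    }
    test <- pts * r[i]
    test[, 1] <- test[, 1] + xyz[i, 1]
    test[, 2] <- test[, 2] + xyz[i, 2]
    test[, 3] <- test[, 3] + xyz[i, 3]
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dx <- test[exposed, 1] - xyz[j, 1]
      dy <- test[exposed, 2] - xyz[j, 2]
      dz <- test[exposed, 3] - xyz[j, 3]
      exposed[exposed] <- dx * dx + dy * dy + dz * dz >= r[j]^2
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(exposed) / n_points
  }
  areas
}

#' Buried surface area between two structure parts
#'
#' BSA = SASA(A) + SASA(B) - SASA(A union B): the total solvent-accessible
#' area lost by both sides on association (both-sides convention; pass
#' `halved = TRUE` for the PISA-style "interface area"). Negative sampling
#' noise is clamped at zero.
#'
#' @param part_a,part_b Disjoint `conf_structure` parts.
#' @param probe_radius,n_points As in [sasa()].
#' @param halved Report BSA/2 (one-sided interface area)?
#' @return Buried area in Angstrom^2.
#' @export
buried_interface_area <- function(part_a, part_b, probe_radius = 1.4,
                                  n_points = 960, halved = FALSE) {
  key <- function(s) paste(s$chain_id, s$res_seq, s$i_code, s$name, s$alt_loc)
  if (length(intersect(key(part_a), key(part_b))) > 0) {
    abort_input("part_a and part_b share atom keys; parts must be disjoint")
  }
  both <- as_structure(
    dplyr::bind_rows(tibble::as_tibble(part_a), tibble::as_tibble(part_b)),
    source_id = structure_source(part_a)
  )
  bsa <- sasa(part_a, probe_radius, n_points)$total_area +
    sasa(part_b, probe_radius, n_points)$total_area -
    sasa(both, probe_radius, n_points)$total_area
  bsa <- max(0, bsa)
  if (halved) bsa / 2 else bsa
}
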