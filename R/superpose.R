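#' Pair atoms between two structures by identity
#'
#' Builds ordered coordinate pairs over the intersection of
#' `(chain, res_seq, i_code, name)` keys, optionally restricted to Calpha
#' or backbone atoms. An explicit `chain_map` (named character vector,
#' names = chains of `a`, values = chains of `b`) allows pairing across
#' renamed chains.
#'
#' @param a,b `conf_structure` tibbles.
#' @param mode `"ca"`, `"backbone"` (N, CA, C, O) or `"all"`.
#' @param chain_map Optional chain renaming applied to `b` before matching.
#' @return List with `fixed` and `mobile` (n x 3 matrices) and `n_pairs`.
#' @export
pair_atoms <- function(a, b, mode = c("ca", "backbone", "all"),
                       chain_map = NULL) {
  mode <- match.arg(mode)
  filt <- function(s) {
    s <- s[!toupper(s$element) %in% c("H", "D"), , drop = FALSE]
    switch(mode,
      ca = s[s$name == "CA" & toupper(s$element) == "C", , drop = FALSE],
      backbone = s[s$name %in% c("N", "CA", "C", "O"), , drop = FALSE],
      all = s
    )
  }
  a <- filt(a)
  b <- filt(b)
  bc <- b$chain_id
  if (!is.null(chain_map)) {
    inv <- setNames(names(chain_map), unname(chain_map))
    bc <- ifelse(bc %in% names(inv), inv[bc], bc)
  }
  ka <- paste(a$chain_id, a$res_seq, a$i_code, a$name)
  kb <- paste(bc, b$res_seq, b$i_code, b$name)
  shared <- intersect(ka, kb)
  if (length(shared) == 0) abort_input("no shared atoms to pair")
  ia <- match(shared, ka)
  ib <- match(shared, kb)
  ord <- order(ia)
  list(
    fixed = as.matrix(a[ia[ord], c("x", "y", "z")]),
    mobile = as.matrix(b[ib[ord], c("x", "y", "z")]),
    n_pairs = length(shared)
  )
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' `R %*% mobile + t` onto `fixed`, via SVD of the covariance matrix with
#' the reflection branch corrected to determinant +1.
#'
#' @param fixed,mobile n x 3 coordinate matrices in matched row order
#'   (e.g. from [pair_atoms()]), n >= 3 and not collinear.
#' @return A `superposition` object: `rotation` (3 x 3), `translation`
#'   (length 3), `rmsd`, `n_pairs`.
#' @export
superpose <- function(fixed, mobile) {
  fixed <- as.matrix(fixed)
  mobile <- as.matrix(mobile)
  n <- nrow(fixed)
  if (n != nrow(mobile)) abort_input("fixed and mobile have different sizes")
  if (n < 3) abort_numeric("superposition needs at least 3 atom pairs")
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(fixed, 2, cf)
  if (sum(svd(Q)$d > 1e-9 * max(svd(Q)$d, 1e-300)) < 2) {
    abort_numeric("degenerate superposition: points are collinear")
  }
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- as.numeric(cf - R %*% cm)
  moved <- t(R %*% t(mobile)) + matrix(t_vec, n, 3, byrow = TRUE)
  out <- list(
    rotation = R, translation = t_vec,
    rmsd = sqrt(mean(rowSums((moved - fixed)^2))),
    n_pairs = n
  )
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf(
    "Kabsch superposition: RMSD %.4f A over %d pairs (rotation %.2f deg)\n",
    x$rmsd, x$n_pairs, rotation_angle(x$rotation)
  ))
  invisible(x)
}

#' @rdname superpose
#' @param x A `superposition`.
#' @param ... Unused.
#' @export
glance.superposition <- function(x, ...) {
  tibble::tibble(
    rmsd = x$rmsd, n_pairs = x$n_pairs,
    rotation_angle = rotation_angle(x$rotation),
    translation_norm = sqrt(sum(x$translation^2))
  )
}

#' @rdname superpose
#' @export
tidy.superposition <- function(x, ...) {
  tibble::tibble(
    term = c("r11", "r12", "r13", "r21", "r22", "r23", "r31", "r32", "r33",
             "t1", "t2", "t3"),
    estimate = c(t(x$rotation), x$translation)
  )
}

rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

apply_superposition <- function(structure, sp) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  moved <- t(sp$rotation %*% t(xyz)) +
    matrix(sp$translation, nrow(xyz), 3, byrow = TRUE)
  structure$x <- moved[, 1]
  structure$y <- moved[, 2]
  structure$z <- moved[, 3]
  structure
}

#' RMSD between two structures
#'
#' Convenience wrapper: pair atoms, superpose, report. With `fit = FALSE`
#' returns the raw (unfitted) RMSD over paired atoms.
#'
#' @inheritParams pair_atoms
#' @param fit Superpose before measuring?
#' @return A one-row tibble: `rmsd`, `n_pairs`, `mode`, `fitted`.
#' @export
rmsd_compare <- function(a, b, mode = c("ca", "backbone", "all"),
                         chain_map = NULL, fit = TRUE) {
  mode <- match.arg(mode)
  pr <- pair_atoms(a, b, mode, chain_map)
  val <- if (fit) {
    superpose(pr$fixed, pr$mobile)$rmsd
  } else {
    sqrt(mean(rowSums((pr$fixed - pr$mobile)^2)))
  }
  tibble::tibble(rmsd = val, n_pairs = pr$n_pairs, mode = mode, fitted = fit)
}

#' Domain-anchored rigid-body displacement
#'
#' Exposes inter-domain motion: superposes `model_b` onto `model_a` using
#' only the `anchor` domain, then reports how far the `probe_region` moved —
#' its centre-of-mass displacement and the angle of its residual best-fit
#' rotation. Anchoring on one lobe of a hinge shows the rigid-body swing of
#' the other.
#'
#' @param model_a,model_b `conf_structure` models sharing numbering.
#' @param anchor,probe_region Domain definition tibbles present in both.
#' @param mode Atom pairing mode, see [pair_atoms()].
#' @return A one-row tibble: `com_displacement` (Angstrom),
#'   `rotation_angle` (degrees), `anchor_rmsd`, `n_anchor`, `n_probe`.
#' @export
domain_anchored_displacement <- function(model_a, model_b, anchor,
                                         probe_region, mode = "ca") {
  anc_a <- select_domain(model_a, anchor)
  anc_b <- select_domain(model_b, anchor)
  pr_anchor <- pair_atoms(anc_a, anc_b, mode)
  sp <- superpose(pr_anchor$fixed, pr_anchor$mobile)
  b_fit <- apply_superposition(model_b, sp)
  probe_a <- select_domain(model_a, probe_region)
  probe_b <- select_domain(b_fit, probe_region)
  pr_probe <- pair_atoms(probe_a, probe_b, mode)
  disp <- com_distance(colMeans(pr_probe$fixed), colMeans(pr_probe$mobile))
  sp_probe <- superpose(pr_probe$fixed, pr_probe$mobile)
  tibble::tibble(
    com_displacement = disp,
    rotation_angle = rotation_angle(sp_probe$rotation),
    anchor_rmsd = sp$rmsd,
    n_anchor = pr_anchor$n_pairs, n_probe = pr_probe$n_pairs
  )
}
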