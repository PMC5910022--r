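#' Read a 3-column SAXS curve
#'
#' Whitespace- or comma-separated `q, I, sigma` text with `#` comments;
#' sigma optional.
#'
#' @param path File path.
#' @return A tibble `q`, `intensity`, `sigma` validated as a scattering
#'   curve (q strictly increasing and positive, finite intensities).
#' @export
read_saxs_curve <- function(path) {
  if (!file.exists(path)) abort_input(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "[,[:space:]]+")
  nums <- suppressWarnings(lapply(fields, as.numeric))
  ok <- vapply(nums, function(v) length(v) >= 2 && !anyNA(v[1:2]), TRUE)
  nums <- nums[ok]
  if (length(nums) == 0) abort_input(paste0("no numeric rows in ", path))
  q <- vapply(nums, `[`, 1, 1)
  i <- vapply(nums, `[`, 1, 2)
  s <- vapply(nums, function(v) if (length(v) >= 3) v[3] else NA_real_, 1)
  scattering_curve(q, i, s)
}

#' Construct/validate a scattering curve
#'
#' @param q Momentum transfer grid, 1/Angstrom, strictly increasing, > 0.
#' @param intensity Intensities (arbitrary units), finite.
#' @param sigma Optional uncertainties.
#' @return A tibble with columns `q`, `intensity`, `sigma`.
#' @export
scattering_curve <- function(q, intensity, sigma = NA_real_) {
  if (any(q <= 0) || any(diff(q) <= 0)) {
    abort_input("q grid must be positive and strictly increasing")
  }
  if (!all(is.finite(intensity))) abort_input("non-finite intensities")
  tibble::tibble(q = q, intensity = intensity, sigma = sigma)
}

#' Guinier fit of a scattering curve
#'
#' Weighted linear fit of ln I against q^2 over the low-q window, iterated
#' to self-consistency: starting from the first `min_points` points, the
#' window is re-chosen as all q with `q * Rg <= q_rg_limit` until the
#' window stabilizes (at most 20 rounds). The slope is -Rg^2/3.
#'
#' @param curve A scattering-curve tibble.
#' @param q_rg_limit Guinier validity limit (1.3 for globular particles).
#' @param min_points Minimum points required in the window.
#' @return A `guinier_fit`: `rg`, `i0`, `q_range_used`, `n_points`,
#'   `fit_residual` (RMS of ln-I residuals).
#' @export
guinier_fit <- function(curve, q_rg_limit = 1.3, min_points = 5) {
  q <- curve$q
  I <- curve$intensity
  sig <- curve$sigma
  usable <- I > 0
  if (sum(usable) < min_points) abort_numeric("too few positive intensities for Guinier fit")
  w_all <- if (all(is.finite(sig))) (I / sig)^2 else rep(1, length(q))
  fit_window <- function(idx) {
    x <- q[idx]^2
    y <- log(I[idx])
    w <- w_all[idx]
    f <- lm(y ~ x, weights = w)
    slope <- coef(f)[["x"]]
    if (slope >= 0) abort_numeric("no Guinier region: ln I does not decrease with q^2")
    list(
      rg = sqrt(-3 * slope), i0 = exp(coef(f)[["(Intercept)"]]),
      resid = sqrt(mean(f$residuals^2))
    )
  }
  idx <- which(usable)[seq_len(min_points)]
  last <- NULL
  for (iter in 1:20) {
    f <- fit_window(idx)
    new_idx <- which(usable & q * f$rg <= q_rg_limit)
    if (length(new_idx) < min_points) {
      new_idx <- which(usable)[seq_len(min_points)]
    }
    if (identical(new_idx, idx)) { last <- f; break }
    idx <- new_idx
    if (iter == 20) abort_numeric("Guinier window did not converge in 20 iterations")
  }
  if (is.null(last)) last <- fit_window(idx)
  out <- list(
    rg = last$rg, i0 = last$i0,
    q_range_used = range(q[idx]), n_points = length(idx),
    fit_residual = last$resid, q_rg_limit = q_rg_limit
  )
  class(out) <- "guinier_fit"
  out
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "Guinier fit: Rg %.2f A, I(0) %.4g, %d points, q in [%.4g, %.4g] (q*Rg <= %.2f)\n",
    x$rg, x$i0, x$n_points, x$q_range_used[1], x$q_range_used[2], x$q_rg_limit
  ))
  invisible(x)
}

#' @rdname guinier_fit
#' @param x A `guinier_fit`.
#' @param ... Unused.
#' @export
tidy.guinier_fit <- function(x, ...) {
  tibble::tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0))
}

#' @rdname guinier_fit
#' @export
glance.guinier_fit <- function(x, ...) {
  tibble::tibble(
    rg = x$rg, i0 = x$i0, n_points = x$n_points,
    q_min = x$q_range_used[1], q_max = x$q_range_used[2],
    fit_residual = x$fit_residual
  )
}

saxs_weights <- function(structure, weighting) {
  switch(weighting,
    mass = structure$mass,
    uniform = rep(1, nrow(structure)),
    electron = residue_electron_count(structure$res_name)
  )
}

#' Radius of gyration from coordinates
#'
#' `Rg = sqrt( sum w_i |r_i - COM|^2 / sum w_i )`.
#'
#' @param structure A `conf_structure` with >= 1 atom.
#' @param weighting `"mass"`, `"uniform"`, or `"electron"` (per-residue
#'   electron counts, the scattering-relevant weight for Calpha-level
#'   models).
#' @return Rg in Angstrom.
#' @export
model_rg <- function(structure, weighting = c("mass", "uniform", "electron")) {
  weighting <- match.arg(weighting)
  if (nrow(structure) == 0) abort_input("Rg of an empty structure")
  w <- saxs_weights(structure, weighting)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  com <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, com)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Pair-distance distribution function from coordinates
#'
#' Weighted histogram of all intramolecular pairwise distances. Rg is
#' recoverable as `sqrt( sum r^2 p / (2 sum p) )` and dmax is the largest
#' pair distance.
#'
#' @param structure A `conf_structure` with >= 2 atoms.
#' @param bin_width Histogram bin width, Angstrom.
#' @param weighting As in [model_rg()].
#' @return A `pddf`: tibble `r` (bin centres), `p` plus attributes; fields
#'   `dmax` and `rg`.
#' @export
pddf_from_model <- function(structure, bin_width = 1,
                            weighting = c("mass", "uniform", "electron")) {
  weighting <- match.arg(weighting)
  if (nrow(structure) < 2) abort_input("p(r) needs at least two atoms")
  w <- saxs_weights(structure, weighting)
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  d <- as.numeric(stats::dist(xyz))
  # pair weights w_i * w_j in dist order
  n <- nrow(xyz)
  iw <- rep(seq_len(n - 1), times = (n - 1):1)
  jw <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  ww <- w[iw] * w[jw]
  dmax <- max(d)
  # bins centred on multiples of bin_width, so a lone pair at 10 A sits in
  # the bin labelled 10
  breaks <- seq(-bin_width / 2, dmax + bin_width, by = bin_width)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  p <- vapply(seq_len(length(breaks) - 1), function(k) sum(ww[bin == k]), 1)
  r_mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  # exact second-moment identity: sum_{i!=j} w_i w_j r_ij^2 = 2 W^2 Rg^2,
  # so the self-term sum(w^2) joins the denominator (negligible at large N)
  rg <- sqrt(sum(r_mid^2 * p) / (2 * sum(p) + sum(w^2)))
  out <- tibble::tibble(r = r_mid, p = p)
  attr(out, "dmax") <- dmax
  attr(out, "rg") <- rg
  class(out) <- c("pddf", class(out))
  out
}

#' @export
print.pddf <- function(x, ...) {
  cat(sprintf(
    "p(r): dmax %.2f A, Rg(p(r)) %.2f A, %d bins\n",
    attr(x, "dmax"), attr(x, "rg"), nrow(x)
  ))
  NextMethod()
}

#' Coarse Debye scattering curve from a model
#'
#' Exact scattering of discrete point scatterers,
#' `I(q) = sum_ij w_i w_j sin(q r_ij) / (q r_ij)`, evaluated at
#' residue-level centroids with electron-count weights by default. This is
#' a coarse substitute for full atomic predictors: no hydration shell and
#' no excluded-volume term, so curves are comparable between models, not
#' to absolute experimental scale beyond an overall factor.
#'
#' @param structure A `conf_structure`.
#' @param q_grid Momentum-transfer grid (1/Angstrom).
#' @param level `"residue"` (one centroid per residue) or `"atom"`.
#' @param weighting Scatterer weights (default `"electron"`).
#' @return A scattering-curve tibble with attribute `coarse = TRUE`.
#' @export
debye_curve <- function(structure, q_grid = seq(0.005, 0.3, by = 0.005),
                        level = c("residue", "atom"),
                        weighting = c("electron", "mass", "uniform")) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  s <- tibble::as_tibble(structure)
  if (level == "residue") {
    s <- dplyr::summarise(
      dplyr::group_by(s, .data$chain_id, .data$res_seq, .data$res_name),
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      mass = sum(.data$mass), .groups = "drop"
    )
  }
  if (nrow(s) < 1) abort_input("no scatterers after coarse-graining")
  w <- switch(weighting,
    electron = residue_electron_count(s$res_name),
    mass = s$mass,
    uniform = rep(1, nrow(s))
  )
  xyz <- as.matrix(s[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n == 1) {
    return(scattering_curve(q_grid, rep(w^2, length(q_grid))))
  }
  d <- as.numeric(stats::dist(xyz))
  iw <- rep(seq_len(n - 1), times = (n - 1):1)
  jw <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  ww <- w[iw] * w[jw]
  self_term <- sum(w^2)
  I <- vapply(q_grid, function(q) {
    x <- q * d
    sinc <- ifelse(x < 1e-8, 1, sin(x) / x)
    self_term + 2 * sum(ww * sinc)
  }, 1)
  out <- scattering_curve(q_grid, I)
  attr(out, "coarse") <- TRUE
  out
}

#' Chi goodness-of-fit between experimental and model curves
#'
#' Interpolates the model curve onto the experimental q grid, finds the
#' optimal linear scale factor `c` analytically, and reports
#' `chi = sqrt( sum((I_exp - c I_mod) / sigma)^2 / (N - 1) )`. Invariant
#' to rescaling of either curve.
#'
#' @param experimental Scattering-curve tibble with finite `sigma`.
#' @param model Scattering-curve tibble (model prediction).
#' @return A one-row tibble: `chi`, `scale`, `n_points`.
#' @export
chi_compare <- function(experimental, model) {
  q <- experimental$q
  if (min(q) < min(model$q) - 1e-9 || max(q) > max(model$q) + 1e-9) {
    abort_input("experimental q grid extends beyond the model curve")
  }
  if (!all(is.finite(experimental$sigma))) {
    abort_input("chi requires experimental sigmas")
  }
  Imod <- approx(model$q, model$intensity, xout = q)$y
  Ie <- experimental$intensity
  s2 <- experimental$sigma^2
  scale <- sum(Ie * Imod / s2) / sum(Imod^2 / s2)
  chi <- sqrt(sum(((Ie - scale * Imod) / experimental$sigma)^2) / (length(q) - 1))
  tibble::tibble(chi = chi, scale = scale, n_points = length(q))
}

#' Single-exponential relaxation fit of a time-resolved Rg series
#'
#' Fits `Rg(t) = rg_final + (rg_initial - rg_final) exp(-t / tau)` by
#' least squares. For fixed tau the model is linear in the two amplitudes,
#' so tau is profiled: decade-spaced tau seeds spanning the observation
#' window locate the best basin and a 1-D golden-section refinement
#' polishes it. Deterministic.
#'
#' @param times Time points, seconds, >= 0, at least 4.
#' @param rg_values Observed Rg, Angstrom.
#' @param sigmas Optional weights (1/sigma^2).
#' @return An `exp_decay_fit`: `rg_initial`, `rg_final`, `tau`,
#'   `residual` (RMS), `n_points`.
#' @export
fit_exp_decay <- function(times, rg_values, sigmas = NULL) {
  if (length(times) < 4) abort_input("need at least 4 time points")
  if (any(times < 0)) abort_input("negative times")
  if (max(rg_values) - min(rg_values) < 1e-9 * max(abs(rg_values), 1)) {
    abort_numeric("constant Rg series: no decay to fit")
  }
  w <- if (is.null(sigmas)) rep(1, length(times)) else 1 / sigmas^2
  # profile: at fixed tau solve the linear system for (rg_final, amplitude)
  rss_at <- function(log_tau) {
    tau <- exp(log_tau)
    e <- exp(-times / tau)
    X <- cbind(1, e)
    f <- lm.wfit(X, rg_values, w)
    sum(w * f$residuals^2)
  }
  span <- range(times[times > 0])
  grid <- log(10^seq(log10(span[1] / 100), log10(span[2] * 10), by = 1))
  rss <- vapply(grid, rss_at, 1)
  k <- which.min(rss)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- optimize(rss_at, c(lo, hi), tol = 1e-10)
  tau <- exp(opt$minimum)
  e <- exp(-times / tau)
  f <- lm.wfit(cbind(1, e), rg_values, w)
  rg_final <- f$coefficients[1]
  amp <- f$coefficients[2]
  if (!all(is.finite(c(rg_final, amp, tau)))) {
    abort_numeric("exponential fit failed to converge")
  }
  out <- list(
    rg_initial = unname(rg_final + amp), rg_final = unname(rg_final),
    tau = tau, residual = sqrt(mean(f$residuals^2)),
    n_points = length(times), times = times, rg_values = rg_values
  )
  class(out) <- "exp_decay_fit"
  out
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "Single-exponential relaxation: tau %.4g s, Rg %.2f -> %.2f A (RMS %.3g, n=%d)\n",
    x$tau, x$rg_initial, x$rg_final, x$residual, x$n_points
  ))
  invisible(x)
}

#' @rdname fit_exp_decay
#' @param x An `exp_decay_fit`.
#' @param ... Unused.
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble::tibble(
    term = c("rg_initial", "rg_final", "tau"),
    estimate = c(x$rg_initial, x$rg_final, x$tau)
  )
}

#' @rdname fit_exp_decay
#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble::tibble(
    rg_initial = x$rg_initial, rg_final = x$rg_final, tau = x$tau,
    residual = x$residual, n_points = x$n_points
  )
}
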