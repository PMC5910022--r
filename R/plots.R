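# ggplot2 views of the main result types. Each returns a ggplot object.

#' @rdname guinier_fit
#' @param object A `guinier_fit` (autoplot) — plotted as ln I vs q^2 with
#'   the fitted line over the window actually used.
#' @param curve The scattering curve the fit was made from.
#' @export
autoplot.guinier_fit <- function(object, curve, ...) {
  df <- tibble::tibble(
    q2 = curve$q^2, ln_i = log(pmax(curve$intensity, .Machine$double.xmin)),
    used = curve$q >= object$q_range_used[1] & curve$q <= object$q_range_used[2]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$q2, .data$ln_i)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$used), size = 0.8) +
    ggplot2::geom_abline(
      intercept = log(object$i0), slope = -object$rg^2 / 3, linetype = 2
    ) +
    ggplot2::labs(
      x = expression(q^2 ~ (ring(A)^-2)), y = "ln I(q)",
      title = sprintf("Guinier fit: Rg = %.1f Å", object$rg),
      colour = "in window"
    )
}

#' @rdname fit_exp_decay
#' @param object An `exp_decay_fit` (autoplot) — data with the fitted
#'   relaxation curve.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  df <- tibble::tibble(time_s = object$times, rg = object$rg_values)
  tt <- seq(min(df$time_s), max(df$time_s), length.out = 200)
  fitline <- tibble::tibble(
    time_s = tt,
    rg = object$rg_final + (object$rg_initial - object$rg_final) *
      exp(-tt / object$tau)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$rg)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = fitline, colour = "red") +
    ggplot2::labs(
      x = "time (s)", y = expression(R[g] ~ (ring(A))),
      title = sprintf("Single-exponential relaxation, tau = %.3g s", object$tau)
    )
}

#' Heat-map view of residue-level differential uptake
#'
#' @param residue_map Output of [hdx_residue_map()].
#' @return A ggplot tile map, residues on x, time points on y, fill =
#'   delta percent D.
#' @export
plot_residue_map <- function(residue_map) {
  long <- tidyr::pivot_longer(residue_map, -"res_seq",
    names_to = "time", values_to = "delta_percent_d"
  )
  long$time <- factor(long$time, levels = unique(long$time))
  ggplot2::ggplot(long, ggplot2::aes(.data$res_seq, .data$time,
    fill = .data$delta_percent_d
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(
      x = "residue", y = "exchange time",
      fill = expression(Delta * "%D")
    )
}

#' Distance/dihedral scatter of a conformational report
#'
#' @param report Output of [conformation_report()].
#' @return A ggplot of COM dihedral vs D1-D4 distance, coloured by state.
#' @export
plot_conformation_report <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(
    .data$d1d4_distance, .data$com_dihedral_abs,
    colour = .data$state, label = .data$chain
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "D1-D4 COM distance (Å)", y = "|COM dihedral| (deg)",
      colour = "state"
    )
}

#' Pair-distance distribution plot
#'
#' @param pddf Output of [pddf_from_model()].
#' @return A ggplot of p(r) against r with dmax marked.
#' @export
plot_pddf <- function(pddf) {
  ggplot2::ggplot(tibble::as_tibble(pddf), ggplot2::aes(.data$r, .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(pddf, "dmax"), linetype = 3) +
    ggplot2::labs(x = "r (Å)", y = "p(r)")
}
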