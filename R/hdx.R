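#' Number of exchangeable backbone amides in a peptide
#'
#' The N-terminal residue back-exchanges too fast to retain label and
#' prolines have no amide hydrogen, so the count is
#' `length - 1 - (number of prolines at positions >= 2)`. The alternative
#' convention that also discards position 2 is available via
#' `skip_first = 2`.
#'
#' @param sequence One-letter amino-acid string (standard 20 codes).
#' @param skip_first How many N-terminal residues are considered fully
#'   back-exchanged (1, the default, or 2).
#' @return Integer count >= 0.
#' @export
exchangeable_amides <- function(sequence, skip_first = 1) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% valid)) {
    abort_input(paste0(
      "unknown residue code(s): ",
      paste(unique(aa[!aa %in% valid]), collapse = ", ")
    ))
  }
  if (length(aa) <= skip_first) return(0L)
  rest <- aa[(skip_first + 1):length(aa)]
  as.integer(length(rest) - sum(rest == "P"))
}

#' Back-exchange-corrected deuterium uptake
#'
#' Converts centroid masses to deuteron counts with the two-control
#' (Zhang-Smith) correction:
#' `D = n_exch * (m_t - m_nondeut) / (m_equil - m_nondeut)`, where the
#' non-deuterated and equilibrium-deuterated controls bracket the scale and
#' absorb back-exchange during workup. `percent_d = 100 * D / n_exch`.
#' Centroids outside the control bracket are clamped with a warning.
#'
#' @param measurements Tibble of peptide measurements with columns
#'   `condition`, `sequence`, `start`, `end`, `time_s`, `replicate`,
#'   `centroid_mass` (or a pre-computed `deuterons` column, used as-is).
#' @param controls Tibble with per-peptide control masses: `sequence`,
#'   `start`, `end`, `m_nondeut`, `m_equil`. Ignored when `measurements`
#'   carries `deuterons`.
#' @param skip_first Passed to [exchangeable_amides()].
#' @return The measurements tibble with `n_exch`, `deuterons` and
#'   `percent_d` columns added.
#' @export
hdx_uptake <- function(measurements, controls = NULL, skip_first = 1) {
  m <- tibble::as_tibble(measurements)
  if (any(m$end - m$start + 1 != nchar(m$sequence))) {
    abort_input("peptide bounds inconsistent with sequence length")
  }
  m$n_exch <- vapply(m$sequence, exchangeable_amides, 1L,
    skip_first = skip_first, USE.NAMES = FALSE
  )
  if (!"deuterons" %in% names(m)) {
    if (is.null(controls)) abort_input("centroid masses need a controls table")
    key <- function(d) paste(d$sequence, d$start, d$end)
    idx <- match(key(m), key(controls))
    if (any(is.na(idx))) abort_input("measurement peptide missing from controls")
    m_nd <- controls$m_nondeut[idx]
    m_eq <- controls$m_equil[idx]
    if (any(m_eq <= m_nd)) {
      abort_input("equilibrium-deuterated control mass must exceed non-deuterated")
    }
    eps <- 1e-9 + 0.02 * (m_eq - m_nd)
    out_of_range <- m$centroid_mass < m_nd - eps | m$centroid_mass > m_eq + eps
    if (any(out_of_range)) {
      warn(sprintf(
        "%d centroid mass(es) outside the control bracket; clamped",
        sum(out_of_range)
      ))
    }
    frac <- pmin(1, pmax(0, (m$centroid_mass - m_nd) / (m_eq - m_nd)))
    m$deuterons <- m$n_exch * frac
  }
  m$percent_d <- ifelse(m$n_exch > 0, 100 * m$deuterons / m$n_exch, 0)
  clamped <- m$percent_d < 0 | m$percent_d > 100
  if (any(clamped)) {
    warn(sprintf("%d percent_d value(s) clamped to [0, 100]", sum(clamped)))
    m$percent_d <- pmin(100, pmax(0, m$percent_d))
    m$deuterons <- m$percent_d / 100 * m$n_exch
  }
  m
}

#' Replicate statistics per peptide, time point and condition
#'
#' @param uptake Output of [hdx_uptake()].
#' @return Tibble with one row per `condition x sequence x start x end x
#'   time_s`: `n_rep`, mean and population SD of `percent_d` and
#'   `deuterons`. A single replicate yields `sd = 0` with a warning.
#' @export
hdx_aggregate <- function(uptake) {
  singles <- dplyr::count(
    uptake, .data$condition, .data$sequence, .data$start, .data$end, .data$time_s
  )
  if (any(singles$n == 1)) {
    warn(sprintf(
      "%d peptide/time cell(s) have a single replicate; sd reported as 0",
      sum(singles$n == 1)
    ))
  }
  pop_sd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))
  dplyr::summarise(
    dplyr::group_by(
      uptake, .data$condition, .data$sequence, .data$start, .data$end,
      .data$time_s
    ),
    n_exch = .data$n_exch[1], n_rep = dplyr::n(),
    deuterons_mean = mean(.data$deuterons), deuterons_sd = pop_sd(.data$deuterons),
    percent_d_mean = mean(.data$percent_d), percent_d_sd = pop_sd(.data$percent_d),
    .groups = "drop"
  )
}

#' Differential HDX between two conditions
#'
#' Computes the per-time-point change in mean percent deuteration
#' (condition minus reference) for every shared peptide, and flags a
#' peptide significant when the maximal absolute change across time points
#' exceeds `threshold_pct` — the single-threshold rule under which only
#' deuteration changes greater than 10% count as significant. Negative
#' significant changes are protection.
#'
#' @param aggregated Output of [hdx_aggregate()] containing both conditions.
#' @param condition,reference Condition labels to compare.
#' @param threshold_pct Significance threshold on |delta percent D|.
#' @return Tibble, one row per peptide x time point: `delta_percent_d`,
#'   `max_abs_delta` (per peptide), `significant`, `direction`.
#' @export
hdx_differential <- function(aggregated, condition, reference,
                             threshold_pct = 10) {
  a <- aggregated[aggregated$condition == condition, , drop = FALSE]
  r <- aggregated[aggregated$condition == reference, , drop = FALSE]
  if (nrow(a) == 0 || nrow(r) == 0) {
    abort_input("condition or reference absent from aggregated uptake")
  }
  key <- function(d) paste(d$sequence, d$start, d$end, d$time_s)
  idx <- match(key(a), key(r))
  if (all(is.na(idx))) abort_input("no shared peptide/time keys between conditions")
  a <- a[!is.na(idx), , drop = FALSE]
  r <- r[idx[!is.na(idx)], , drop = FALSE]
  out <- tibble::tibble(
    sequence = a$sequence, start = a$start, end = a$end, time_s = a$time_s,
    n_exch = a$n_exch,
    percent_d_condition = a$percent_d_mean,
    percent_d_reference = r$percent_d_mean,
    delta_percent_d = a$percent_d_mean - r$percent_d_mean
  )
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$sequence, .data$start, .data$end),
    max_abs_delta = max(abs(.data$delta_percent_d))
  )
  out <- dplyr::ungroup(out)
  out$significant <- out$max_abs_delta > threshold_pct
  out$direction <- dplyr::case_when(
    !out$significant ~ "none",
    out$delta_percent_d < 0 ~ "protection",
    TRUE ~ "deprotection"
  )
  out
}
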