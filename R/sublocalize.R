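#' Sub-localize peptide-level HDX to minimal residue segments
#'
#' Overlapping peptic peptides carry residue-level information at their
#' shared boundaries. The covered residues are partitioned into minimal
#' segments at the union of all peptide start/end boundaries, and the
#' per-amide fractional uptake `f_j` of each segment is solved from the
#' bounded least-squares system `A f = b`: `A[i, j]` counts the amides of
#' segment j that are exchangeable inside peptide i (the peptide's
#' N-terminal residue and all prolines carry no retained label),
#' `b[i]` is the peptide's deuteron count, and `0 <= f_j <= 1`.
#'
#' Segments whose uptake the peptide set cannot pin down (rank-deficient
#' columns) are never silently averaged: they are flagged
#' `"underdetermined"` and reported at the value of their shortest
#' supporting peptide. A segment covered by a single peptide spanning
#' exactly that segment is flagged `"no_sublocalization"`.
#'
#' @param peptides Tibble with one row per peptide at a single condition
#'   and time point: `sequence`, `start`, `end`, `deuterons` (mean over
#'   replicates). Typically a filtered slice of [hdx_aggregate()] output
#'   (column `deuterons_mean` is accepted too).
#' @param skip_first Passed to the exchangeability rule (see
#'   [exchangeable_amides()]).
#' @return A list of class `hdx_sublocalization`: `segments` tibble
#'   (`start`, `end`, `n_exchangeable`, `fraction_d`, `deuterons`,
#'   `percent_d`, `n_supporting`, `flag`), `peptide_residuals` tibble,
#'   `rank`, `n_segments`.
#' @export
hdx_sublocalize <- function(peptides, skip_first = 1) {
  p <- tibble::as_tibble(peptides)
  if (!"deuterons" %in% names(p) && "deuterons_mean" %in% names(p)) {
    p$deuterons <- p$deuterons_mean
  }
  stopifnot(all(c("sequence", "start", "end", "deuterons") %in% names(p)))
  if (nrow(p) == 0) abort_input("no peptides to sub-localize")
  if (any(p$end - p$start + 1 != nchar(p$sequence))) {
    abort_input("peptide bounds inconsistent with sequence length")
  }

  # residue-level bookkeeping over the covered region
  res_range <- min(p$start):max(p$end)
  covered <- rep(FALSE, length(res_range))
  res_aa <- rep(NA_character_, length(res_range))
  for (i in seq_len(nrow(p))) {
    pos <- p$start[i]:p$end[i]
    covered[pos - res_range[1] + 1] <- TRUE
    res_aa[pos - res_range[1] + 1] <- strsplit(toupper(p$sequence[i]), "")[[1]]
  }

  # minimal segments: cut at every peptide start and every end + 1,
  # and at coverage gaps
  cuts <- sort(unique(c(p$start, p$end + 1L)))
  seg_start <- integer()
  seg_end <- integer()
  for (k in seq_len(length(cuts) - 1)) {
    a <- cuts[k]
    b <- cuts[k + 1] - 1L
    pos <- a:b
    cov <- covered[pos - res_range[1] + 1]
    if (!any(cov)) next
    seg_start <- c(seg_start, a)
    seg_end <- c(seg_end, b)
  }
  n_seg <- length(seg_start)

  # A[i, j]: exchangeable amides of segment j inside peptide i
  A <- matrix(0, nrow(p), n_seg)
  for (i in seq_len(nrow(p))) {
    aa <- strsplit(toupper(p$sequence[i]), "")[[1]]
    pos <- p$start[i]:p$end[i]
    exch <- seq_along(pos) > skip_first & aa != "P"
    for (j in seq_len(n_seg)) {
      inside <- pos >= seg_start[j] & pos <= seg_end[j]
      A[i, j] <- sum(exch & inside)
    }
  }
  b <- p$deuterons

  # segment exchangeable count: positions exchangeable in >= 1 peptide
  n_exch_seg <- integer(n_seg)
  for (j in seq_len(n_seg)) {
    pos <- seg_start[j]:seg_end[j]
    any_exch <- vapply(pos, function(q) {
      any(vapply(seq_len(nrow(p)), function(i) {
        q >= p$start[i] && q <= p$end[i] &&
          (q - p$start[i] + 1) > skip_first &&
          substr(toupper(p$sequence[i]), q - p$start[i] + 1, q - p$start[i] + 1) != "P"
      }, TRUE))
    }, TRUE)
    n_exch_seg[j] <- sum(any_exch)
  }

  keep <- n_exch_seg > 0
  rank_A <- qr(A)$rank
  identifiable <- vapply(seq_len(n_seg), function(j) {
    if (!keep[j]) return(FALSE)
    ej <- rep(0, n_seg)
    ej[j] <- 1
    qr(rbind(A, ej))$rank == rank_A
  }, TRUE)

  # bounded least squares on fractional uptake
  obj <- function(f) sum((A %*% f - b)^2)
  grad <- function(f) as.numeric(2 * t(A) %*% (A %*% f - b))
  fit <- optim(rep(0.5, n_seg), obj, grad,
    method = "L-BFGS-B", lower = 0, upper = 1,
    control = list(factr = 10, maxit = 500)
  )
  f <- fit$par
  # polish: exact least-squares on the variables away from their bounds
  # (active-set refinement; keeps full-rank systems exact to solver tol)
  free <- which(f > 1e-8 & f < 1 - 1e-8 & identifiable)
  if (length(free) > 0) {
    b_adj <- b - A[, -free, drop = FALSE] %*% f[-free]
    ls <- tryCatch(qr.solve(A[, free, drop = FALSE], b_adj), error = function(e) NULL)
    if (!is.null(ls) && all(ls >= 0 & ls <= 1)) {
      cand <- f
      cand[free] <- as.numeric(ls)
      if (obj(cand) <= obj(f) + 1e-12) f <- cand
    }
  }

  n_support <- colSums(A > 0)
  flag <- rep("ok", n_seg)
  flag[!identifiable] <- "underdetermined"
  for (j in which(n_support == 1)) {
    i <- which(A[, j] > 0)
    if (p$start[i] == seg_start[j] && p$end[i] == seg_end[j]) {
      flag[j] <- "no_sublocalization"
    }
  }

  # fallback value for non-identifiable segments: shortest supporting peptide
  for (j in which(!identifiable & keep)) {
    supp <- which(A[, j] > 0)
    if (length(supp) == 0) next
    i <- supp[which.min(p$end[supp] - p$start[supp])]
    n_i <- exchangeable_amides(p$sequence[i], skip_first)
    f[j] <- if (n_i > 0) min(1, max(0, b[i] / n_i)) else 0
  }

  segments <- tibble::tibble(
    start = seg_start, end = seg_end,
    n_exchangeable = n_exch_seg,
    fraction_d = f,
    deuterons = f * n_exch_seg,
    percent_d = 100 * f,
    n_supporting = n_support,
    flag = flag
  )[keep, , drop = FALSE]

  residuals <- tibble::tibble(
    sequence = p$sequence, start = p$start, end = p$end,
    deuterons = b,
    fitted = as.numeric(A %*% f),
    residual = as.numeric(A %*% f) - b
  )
  out <- list(
    segments = segments, peptide_residuals = residuals,
    rank = rank_A, n_segments = sum(keep)
  )
  class(out) <- "hdx_sublocalization"
  out
}

#' @export
print.hdx_sublocalization <- function(x, ...) {
  cat(sprintf(
    "HDX sub-localization: %d segments (rank %d), max |peptide residual| %.3g D\n",
    x$n_segments, x$rank, max(abs(x$peptide_residuals$residual))
  ))
  print(x$segments)
  invisible(x)
}

#' @rdname hdx_sublocalize
#' @param x An `hdx_sublocalization`.
#' @param ... Unused.
#' @export
tidy.hdx_sublocalization <- function(x, ...) x$segments

#' @rdname hdx_sublocalize
#' @export
glance.hdx_sublocalization <- function(x, ...) {
  tibble::tibble(
    n_segments = x$n_segments, rank = x$rank,
    n_flagged = sum(x$segments$flag != "ok"),
    rss = sum(x$peptide_residuals$residual^2)
  )
}

#' Segment-level differential HDX across conditions
#'
#' Runs [hdx_sublocalize()] per condition and time point on aggregated
#' uptake, then differences segment percent deuteration (condition minus
#' reference) and applies the max-|delta| significance rule.
#'
#' @param aggregated Output of [hdx_aggregate()].
#' @param condition,reference Condition labels.
#' @param threshold_pct Significance threshold on |delta percent D|.
#' @param skip_first Exchangeability convention.
#' @return Tibble, one row per segment x time point, with
#'   `delta_percent_d`, `max_abs_delta`, `significant`, `direction`, `flag`.
#' @export
hdx_segment_differential <- function(aggregated, condition, reference,
                                     threshold_pct = 10, skip_first = 1) {
  run_one <- function(cond) {
    slice_all <- aggregated[aggregated$condition == cond, , drop = FALSE]
    if (nrow(slice_all) == 0) abort_input(paste0("condition absent: ", cond))
    purrr::map_dfr(sort(unique(slice_all$time_s)), function(tp) {
      sl <- slice_all[slice_all$time_s == tp, , drop = FALSE]
      sub <- hdx_sublocalize(
        dplyr::rename(sl, deuterons = "deuterons_mean"), skip_first
      )
      dplyr::mutate(sub$segments, time_s = tp, condition = cond)
    })
  }
  a <- run_one(condition)
  r <- run_one(reference)
  key <- function(d) paste(d$start, d$end, d$time_s)
  idx <- match(key(a), key(r))
  if (all(is.na(idx))) abort_input("segmentations do not overlap between conditions")
  a <- a[!is.na(idx), , drop = FALSE]
  r <- r[idx[!is.na(idx)], , drop = FALSE]
  out <- tibble::tibble(
    start = a$start, end = a$end, time_s = a$time_s,
    percent_d_condition = a$percent_d, percent_d_reference = r$percent_d,
    delta_percent_d = a$percent_d - r$percent_d,
    flag = ifelse(a$flag == "ok" & r$flag == "ok", "ok", "flagged")
  )
  out <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(out, .data$start, .data$end),
    max_abs_delta = max(abs(.data$delta_percent_d))
  ))
  out$significant <- out$max_abs_delta > threshold_pct
  out$direction <- dplyr::case_when(
    !out$significant ~ "none",
    out$delta_percent_d < 0 ~ "protection",
    TRUE ~ "deprotection"
  )
  out
}

#' Residue-level heat map of differential uptake
#'
#' Broadcasts segment-level (or peptide-level) delta percent-D values to
#' the residues they cover, one column per time point — the tabular form
#' of a structure-painted HDX heat map. Residues in flagged
#' (rank-deficient) segments take the finest flag-free cover when one
#' exists, otherwise the flagged value.
#'
#' @param differential Output of [hdx_segment_differential()] (or
#'   [hdx_differential()]; peptide bounds are then used as segments).
#' @param only_significant Zero out non-significant segments?
#' @return Tibble: `res_seq` and one `t_<time>` column per time point.
#' @export
hdx_residue_map <- function(differential, only_significant = FALSE) {
  d <- tibble::as_tibble(differential)
  if (only_significant) {
    d$delta_percent_d[!d$significant] <- 0
  }
  if (!"flag" %in% names(d)) d$flag <- "ok"
  res_range <- min(d$start):max(d$end)
  times <- sort(unique(d$time_s))
  out <- tibble::tibble(res_seq = res_range)
  for (tp in times) {
    slice <- d[d$time_s == tp, , drop = FALSE]
    # prefer flag-free, then shorter (finer) segments
    slice <- slice[order(slice$flag != "ok", slice$end - slice$start), , drop = FALSE]
    vals <- rep(0, length(res_range))
    filled <- rep(FALSE, length(res_range))
    for (i in seq_len(nrow(slice))) {
      pos <- slice$start[i]:slice$end[i] - res_range[1] + 1
      take <- !filled[pos]
      vals[pos[take]] <- slice$delta_percent_d[i]
      filled[pos[take]] <- TRUE
    }
    out[[paste0("t_", format(tp, scientific = FALSE))]] <- vals
  }
  out
}

#' Write a structure coloured by differential uptake
#'
#' Places per-residue delta percent-D values into the B-factor column of a
#' PDB file so molecular-graphics software can paint them on the model.
#' Residues absent from the map get 0.
#'
#' @param structure A `conf_structure`.
#' @param residue_values Tibble with `res_seq` and a value column.
#' @param path Output PDB path.
#' @param value_col Name of the value column (default: the first `t_`
#'   column).
#' @return `path`, invisibly.
#' @export
write_uptake_pdb <- function(structure, residue_values, path,
                             value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- grep("^t_", names(residue_values), value = TRUE)[1]
    if (is.na(value_col)) abort_input("no value column found in residue map")
  }
  idx <- match(structure$res_seq, residue_values$res_seq)
  vals <- residue_values[[value_col]][idx]
  vals[is.na(vals)] <- 0
  s <- tibble::as_tibble(structure)
  s$b_factor <- vals
  writeLines(format_pdb(s), path)
  invisible(path)
}
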