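#' Run configuration
#'
#' A plain named list, serialized as JSON so that a run's resolved
#' parameters are always written beside its outputs (round-trip stable).
#' `conformeter_config()` fills defaults; unknown fields are rejected.
#'
#' @param ... Overrides for any default field: `structures` (paths),
#'   `reference` (path of the closed-state reference model), `domains`
#'   (data frame or path of a domain-definition CSV), `thresholds` (state
#'   cut-offs), `probe_radius`, `n_points`, `hdx_timepoints`,
#'   `hdx_threshold_pct`, `hdx_skip_first`, `q_rg_limit`, `out_dir`,
#'   `seed`.
#' @return A `conformeter_config` list.
#' @export
conformeter_config <- function(...) {
  cfg <- list(
    structures = character(), reference = NULL, domains = NULL,
    thresholds = list(closed_dist = 2, open_dist = 12, dihedral_tol = 2),
    probe_radius = 1.4, n_points = 960,
    hdx_timepoints = c(10, 100, 1000, 1e4, 1e5),
    hdx_threshold_pct = 10, hdx_skip_first = 1,
    q_rg_limit = 1.3, out_dir = ".", seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort_config(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "conformeter_config"
  cfg
}

#' @rdname conformeter_config
#' @param config A `conformeter_config`.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname conformeter_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("config not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(conformeter_config, raw)
}

resolve_domains <- function(config, fallback = ide_domains()) {
  d <- config$domains
  if (is.null(d)) return(fallback)
  if (is.character(d)) d <- readr::read_csv(d, show_col_types = FALSE)
  tibble::as_tibble(d)
}

write_atomic <- function(write_fn, path) {
  # partial results never overwrite complete ones
  tmp <- paste0(path, ".tmp")
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the conformational-state report stage
#'
#' Reads every structure in the config, computes per-subunit metrics
#' against the reference model (when given), and writes
#' `conformation_report.csv` plus the resolved config to the output
#' directory. Deterministic for a given config.
#'
#' @param config A `conformeter_config`.
#' @return The report tibble, invisibly.
#' @export
run_conformation <- function(config) {
  if (length(config$structures) == 0) abort_config("no structures in config")
  dom <- resolve_domains(config)
  reference <- NULL
  if (!is.null(config$reference)) {
    ref_s <- read_structure(config$reference)
    ref_report <- conformation_report(ref_s,
      domains = dom, compute_bsa = FALSE
    )
    reference <- list(
      d1d4_distance = ref_report$d1d4_distance[1],
      com_dihedral_abs = ref_report$com_dihedral_abs[1]
    )
  }
  report <- purrr::map_dfr(config$structures, function(p) {
    conformation_report(read_structure(p),
      domains = dom, reference = reference,
      thresholds = config$thresholds,
      probe_radius = config$probe_radius, n_points = config$n_points
    )
  })
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_atomic(
    function(p) readr::write_csv(report, p),
    file.path(config$out_dir, "conformation_report.csv")
  )
  write_config(config, file.path(config$out_dir, "run_config.json"))
  invisible(report)
}

#' Run the HDX differential stage
#'
#' Uptake with back-exchange correction, replicate aggregation,
#' peptide-level and segment-level differentials with the configured
#' significance threshold, and a residue heat map. Writes `hdx_uptake.csv`,
#' `hdx_differential.csv`, `hdx_segments.csv`, `hdx_residue_map.csv`.
#'
#' @param config A `conformeter_config`.
#' @param measurements,controls HDX tables (see [hdx_uptake()]); paths to
#'   CSV files are accepted.
#' @param condition,reference Condition labels to compare.
#' @return List of the four result tibbles, invisibly.
#' @export
run_hdx <- function(config, measurements, controls = NULL,
                    condition, reference) {
  if (is.character(measurements)) {
    measurements <- readr::read_csv(measurements, show_col_types = FALSE)
  }
  if (is.character(controls)) {
    controls <- readr::read_csv(controls, show_col_types = FALSE)
  }
  up <- hdx_uptake(measurements, controls, skip_first = config$hdx_skip_first)
  agg <- hdx_aggregate(up)
  diff_pep <- hdx_differential(agg, condition, reference,
    threshold_pct = config$hdx_threshold_pct
  )
  diff_seg <- hdx_segment_differential(agg, condition, reference,
    threshold_pct = config$hdx_threshold_pct,
    skip_first = config$hdx_skip_first
  )
  rmap <- hdx_residue_map(diff_seg)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- list(
    hdx_uptake = agg, hdx_differential = diff_pep,
    hdx_segments = diff_seg, hdx_residue_map = rmap
  )
  for (nm in names(outs)) {
    write_atomic(
      function(p) readr::write_csv(outs[[nm]], p),
      file.path(config$out_dir, paste0(nm, ".csv"))
    )
  }
  write_config(config, file.path(config$out_dir, "run_config.json"))
  invisible(outs)
}

#' Run the SAXS stage
#'
#' Guinier fit of each experimental curve, model Rg / p(r) / coarse Debye
#' prediction and chi for each structure, and an optional
#' single-exponential fit of a kinetic Rg series. Writes
#' `saxs_guinier.csv`, `saxs_models.csv`, `saxs_chi.csv`,
#' `saxs_kinetics.csv` as applicable.
#'
#' @param config A `conformeter_config`.
#' @param curves Named list of scattering-curve tibbles or .dat paths.
#' @param structures Named list of `conf_structure` models or paths.
#' @param kinetic_series Optional tibble (`time_s`, `rg`, optional
#'   `sigma`) or CSV path.
#' @return List of result tibbles, invisibly.
#' @export
run_saxs <- function(config, curves = list(), structures = list(),
                     kinetic_series = NULL) {
  load_curve <- function(x) if (is.character(x)) read_saxs_curve(x) else x
  load_struct <- function(x) if (is.character(x)) read_structure(x) else x
  curves <- lapply(curves, load_curve)
  structures <- lapply(structures, load_struct)
  outs <- list()
  if (length(curves) > 0) {
    outs$saxs_guinier <- purrr::imap_dfr(curves, function(cv, nm) {
      dplyr::mutate(glance(guinier_fit(cv, config$q_rg_limit)), curve = nm,
        .before = 1
      )
    })
  }
  if (length(structures) > 0) {
    outs$saxs_models <- purrr::imap_dfr(structures, function(s, nm) {
      pd <- pddf_from_model(s, weighting = "electron")
      tibble::tibble(
        model = nm, rg_model = model_rg(s, "electron"),
        rg_pddf = attr(pd, "rg"), dmax = attr(pd, "dmax")
      )
    })
    if (length(curves) > 0) {
      outs$saxs_chi <- purrr::imap_dfr(structures, function(s, nm) {
        q_max <- max(purrr::map_dbl(curves, ~ max(.x$q)))
        q_min <- min(purrr::map_dbl(curves, ~ min(.x$q)))
        mod <- debye_curve(s, q_grid = seq(
          max(1e-4, q_min * 0.9), q_max * 1.05, length.out = 120
        ))
        purrr::imap_dfr(curves, function(cv, cnm) {
          dplyr::mutate(chi_compare(cv, mod), model = nm, curve = cnm,
            .before = 1
          )
        })
      })
    }
  }
  if (!is.null(kinetic_series)) {
    if (is.character(kinetic_series)) {
      kinetic_series <- readr::read_csv(kinetic_series, show_col_types = FALSE)
    }
    sig <- if ("sigma" %in% names(kinetic_series)) kinetic_series$sigma else NULL
    outs$saxs_kinetics <- glance(
      fit_exp_decay(kinetic_series$time_s, kinetic_series$rg, sig)
    )
  }
  if (length(outs) == 0) abort_input("nothing to do: no curves, models or kinetics")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(outs)) {
    write_atomic(
      function(p) readr::write_csv(outs[[nm]], p),
      file.path(config$out_dir, paste0(nm, ".csv"))
    )
  }
  write_config(config, file.path(config$out_dir, "run_config.json"))
  invisible(outs)
}
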