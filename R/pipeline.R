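#' Pipeline run configuration
#'
#' Exactly one of `synthetic` (a [synth_config()]) or `inputs` (a
#' directory written by [write_dataset()], or an in-memory
#' `furascope_dataset`) must be supplied.
#'
#' @param synthetic Optional [synth_config()] describing a synthetic run.
#' @param inputs Optional path to a dataset directory or a
#'   `furascope_dataset`.
#' @param out_dir Optional output directory for the run report and
#'   per-cell tables.
#' @param seed Optional integer overriding the synthetic config's seed.
#' @param registration `"landmarks"` (use landmark pairs when present,
#'   the analog of manual alignment), `"intensity"` (automated NCC
#'   estimation from the transmission images), or `"identity"`.
#' @param intensity_transform Intensity scale for the correlation, see
#'   [run_correlation()].
#' @param min_delta KCl gate threshold, ratio units.
#' @param auc_window_s AUC integration window, seconds.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL, out_dir = NULL,
                       seed = NULL,
                       registration = c("landmarks", "intensity",
                                        "identity"),
                       intensity_transform = "asinh",
                       min_delta = 0.1, auc_window_s = 60) {
  registration <- match.arg(registration)
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of 'synthetic' or 'inputs' must be supplied")
  if (!is.null(synthetic)) {
    stopifnot(inherits(synthetic, "synth_config"))
    if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  }
  structure(
    list(synthetic = synthetic, inputs = inputs, out_dir = out_dir,
         registration = registration,
         intensity_transform = intensity_transform,
         min_delta = min_delta, auc_window_s = auc_window_s),
    class = "run_config")
}

#' Analyze a dataset end to end
#'
#' Runs the full analysis chain on a `furascope_dataset` (synthetic or
#' loaded from disk): ratio traces and AUC scoring with the KCl gate,
#' confocal-to-widefield registration with ROI propagation, per-cell
#' RNAscope quantification, mean + 2*SD thresholds for both modalities,
#' four-way classification, and the union-set Pearson correlation for
#' each probe/agonist pairing (TRPA1 x AITC, TRPV1 x capsaicin).
#'
#' @param ds A `furascope_dataset`.
#' @param registration,intensity_transform,min_delta,auc_window_s See
#'   [run_config()].
#' @return A run report list: thresholds, category counts, union sizes,
#'   correlation results, the estimated transform, dropped ROIs, and
#'   per-cell records (as `cells`).
#' @export
analyze_dataset <- function(ds, registration = "landmarks",
                            intensity_transform = "asinh",
                            min_delta = 0.1, auc_window_s = 60) {
  stopifnot(inherits(ds, "furascope_dataset"))
  sched <- ds$config$schedule

  # --- functional scoring -------------------------------------------
  traces <- if (!is.null(ds$widefield)) {
    extract_traces(ds$widefield$ch340, ds$widefield$ch385, ds$roi_labels)
  } else ds$traces
  scores <- score_cells(traces, sched, min_delta = min_delta,
                        auc_window_s = auc_window_s)

  # --- registration + RNAscope quantification -----------------------
  dropped <- integer(0)
  if (!is.null(ds$confocal)) {
    tf <- if (registration == "identity") {
      similarity_transform()
    } else if (registration == "landmarks" && !is.null(ds$landmarks)) {
      estimate_transform(NULL, NULL, landmarks = ds$landmarks)
    } else {
      estimate_transform(ds$widefield$transmission,
                         ds$confocal$transmission)
    }
    conf_dim <- dim(ds$confocal$TRPA1)[1:2]
    mapped <- map_rois(ds$roi_labels, tf, conf_dim)
    dropped <- mapped$dropped
    intens <- rbind(
      cell_signals(project_stack(ds$confocal$TRPA1, "average"),
                   mapped$labels, "TRPA1"),
      cell_signals(project_stack(ds$confocal$TRPV1, "average"),
                   mapped$labels, "TRPV1"))
  } else {
    tf <- similarity_transform()
    intens <- ds$measurements
    if (is.null(intens))
      stop("dataset has neither confocal images nor a measurements table")
  }

  nc_model <- fit_negative_control(ds$negative_controls)

  # --- per-pairing classification + correlation ---------------------
  pairings <- list(list(channel = "TRPA1", agonist = "AITC"),
                   list(channel = "TRPV1", agonist = "capsaicin"))
  out <- list()
  cells <- list()
  for (p in pairings) {
    sc <- scores[scores$agonist == p$agonist, ]
    it <- intens[intens$channel == p$channel, ]
    rec <- merge(sc[, c("cell_id", "auc", "kcl_pass")],
                 it[, c("cell_id", "mean_intensity")], by = "cell_id")
    names(rec)[names(rec) == "mean_intensity"] <- "rnascope_intensity"
    gated_auc <- rec$auc[rec$kcl_pass]
    fm <- fit_nonresponder_threshold(gated_auc)
    cl <- classify_cells(rec, fm, nc_model)
    corr <- run_correlation(cl$records, channel = p$channel,
                            agonist = p$agonist,
                            intensity_transform = intensity_transform)
    key <- p$channel
    cl$records$channel <- p$channel
    cl$records$agonist <- p$agonist
    cells[[key]] <- cl$records
    out[[key]] <- list(
      agonist = p$agonist,
      functional_threshold = fm$threshold,
      functional_fit = list(mean = fm$mean, sd = fm$sd,
                            iterations = fm$fit_iterations,
                            converged = fm$converged),
      counts = cl$counts,
      union_n = corr$n,
      correlation = list(r = corr$r, p_value = corr$p_value, n = corr$n,
                         intensity_transform = corr$intensity_transform))
  }

  list(
    n_cells = length(unique(scores$cell_id)),
    n_gated = sum(scores$kcl_pass[scores$agonist == scores$agonist[1]]),
    rnascope_threshold = nc_model$threshold,
    negative_control = list(mean = nc_model$mean, sd = nc_model$sd,
                            n_cells = nc_model$n_cells),
    transform = list(rotation_deg = tf$rotation_deg, dx_px = tf$dx,
                     dy_px = tf$dy, scale = tf$scale,
                     mode = attr(tf, "mode") %||% "identity"),
    dropped_rois = dropped,
    channels = out,
    input_hashes = list(traces = rlang::hash(traces),
                        intensities = rlang::hash(intens),
                        negative_controls = rlang::hash(ds$negative_controls)),
    cells = cells)
}

#' Run the pipeline from a run configuration
#'
#' Generates (or loads) the dataset and analyzes it; identical
#' configuration and seed produce an identical report. If `out_dir` is
#' set, writes `report.json`, `cells_<channel>.csv` and `transform.json`.
#'
#' @param config A [run_config()].
#' @return The run report (invisibly contains per-cell tables in
#'   `$cells`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- if (!is.null(config$synthetic)) {
    generate_dataset(config$synthetic)
  } else if (inherits(config$inputs, "furascope_dataset")) {
    config$inputs
  } else {
    read_dataset(config$inputs)
  }
  report <- analyze_dataset(ds, registration = config$registration,
                            intensity_transform = config$intensity_transform,
                            min_delta = config$min_delta,
                            auc_window_s = config$auc_window_s)
  report$seed <- if (!is.null(config$synthetic)) config$synthetic$seed else NA
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
    for (ch in names(report$cells))
      utils::write.csv(report$cells[[ch]],
                       file.path(config$out_dir,
                                 sprintf("cells_%s.csv", tolower(ch))),
                       row.names = FALSE)
    write_transform(similarity_transform(report$transform$rotation_deg,
                                         report$transform$dx_px,
                                         report$transform$dy_px,
                                         report$transform$scale),
                    file.path(config$out_dir, "transform.json"))
  }
  report
}

#' Serialize a run report to JSON
#'
#' The per-cell tables (`$cells`) are not embedded; the JSON holds
#' thresholds, counts, union sizes, correlations, the transform and the
#' input hashes. Serialization is value-deterministic: identical reports
#' produce byte-identical files.
#'
#' @param report A report from [analyze_dataset()] / [run_pipeline()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  slim <- report[setdiff(names(report), "cells")]
  json <- jsonlite::toJSON(slim, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}
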