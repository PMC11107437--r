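#' Agonist application schedule
#'
#' An application schedule is a data.frame with one row per agonist
#' application and columns `agonist` (name), `concentration` (molar),
#' `start_s` and `duration_s` (seconds). The default reproduces the
#' standard stimulation protocol for cultured DRG neurons: AITC 100 uM for
#' 60 s, capsaicin 1 uM for 30 s, and the KCl 60 mM viability control for
#' 15 s, applied sequentially with recovery gaps.
#'
#' @param aitc_start,caps_start,kcl_start Application start times in
#'   seconds.
#' @return A validated schedule data.frame.
#' @export
default_schedule <- function(aitc_start = 60, caps_start = 240,
                             kcl_start = 420) {
  validate_schedule(data.frame(
    agonist = c("AITC", "capsaicin", "KCl"),
    concentration = c(100e-6, 1e-6, 60e-3),
    start_s = c(aitc_start, caps_start, kcl_start),
    duration_s = c(60, 30, 15),
    stringsAsFactors = FALSE
  ))
}

#' @rdname default_schedule
#' @param schedule A candidate schedule data.frame.
#' @export
validate_schedule <- function(schedule) {
  need <- c("agonist", "concentration", "start_s", "duration_s")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)))
    stop("schedule must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (any(schedule$duration_s <= 0)) stop("application 'duration_s' must be > 0")
  if (any(schedule$start_s < 0)) stop("application 'start_s' must be >= 0")
  o <- order(schedule$start_s)
  schedule <- schedule[o, , drop = FALSE]
  ends <- schedule$start_s + schedule$duration_s
  if (nrow(schedule) > 1 &&
      any(schedule$start_s[-1] < ends[-nrow(schedule)]))
    stop("applications overlap: each application must start after the ",
         "previous one has ended")
  rownames(schedule) <- NULL
  schedule
}

#' Background-subtracted F340/F385 ratio image
#'
#' Computes the per-pixel Fura-2 excitation ratio
#' `(F340 - bg340) / (F385 - bg385)`. The background intensity is
#' subtracted from each channel before the ratio is formed. Pixels whose
#' background-subtracted denominator is <= 0 are flagged invalid (`NA`)
#' and are excluded from ROI means downstream.
#'
#' @param frame_340,frame_385 Numeric matrices of identical dimensions
#'   (single frames of the 340 nm / 385 nm excitation channels).
#' @param background_340,background_385 Scalar background intensities
#'   (>= 0), e.g. from [estimate_background()].
#' @return Numeric matrix of ratios, `NA` where invalid.
#' @export
compute_ratio <- function(frame_340, frame_385,
                          background_340 = 0, background_385 = 0) {
  if (!is.matrix(frame_340) || !is.matrix(frame_385) ||
      !all(dim(frame_340) == dim(frame_385)))
    stop("frame_340 and frame_385 must be matrices of identical dimensions")
  if (background_340 < 0 || background_385 < 0)
    stop("background intensities must be >= 0")
  num <- frame_340 - background_340
  den <- frame_385 - background_385
  bad <- den <= 0
  den[bad] <- NA_real_
  out <- num / den
  out[bad] <- NA_real_
  out
}

#' Estimate the per-channel background intensity
#'
#' The default estimator is the mode of the pixel intensities outside all
#' ROIs (intensities are binned to the nearest integer count; for
#' non-integer data the mode of a kernel density estimate is used).
#'
#' @param frame Numeric image matrix.
#' @param labels Integer ROI label matrix (0 = background) of the same
#'   dimensions, or `NULL` to use the whole frame.
#' @return Scalar background estimate.
#' @export
estimate_background <- function(frame, labels = NULL) {
  stopifnot(is.matrix(frame))
  px <- if (is.null(labels)) as.numeric(frame) else frame[labels == 0]
  px <- px[is.finite(px)]
  if (length(px) == 0) stop("no background pixels available")
  r <- round(px)
  if (max(abs(px - r)) < 1e-9) {
    tab <- table(r)
    return(as.numeric(names(tab)[which.max(tab)]))
  }
  d <- stats::density(px, n = 1024)
  d$x[which.max(d$y)]
}

#' Extract a per-cell ratio trace from a ratio movie
#'
#' For each frame, takes the mean of the valid (non-`NA`) ratio pixels in
#' the cell's ROI, on the acquisition time grid.
#'
#' @param ratio_movie 3-D numeric array `[rows, cols, frames]` of ratio
#'   images, or a list of ratio matrices.
#' @param labels Integer ROI label matrix.
#' @param cell_id Integer label of the cell to extract.
#' @param times Frame times in seconds; default a 1 Hz grid starting at 0.
#' @param min_area Minimum ROI pixel count; smaller ROIs are an error.
#' @return A data.frame with columns `time_s` and `ratio`; attributes
#'   `cell_id` and `roi_area`.
#' @export
extract_trace <- function(ratio_movie, labels, cell_id, times = NULL,
                          min_area = 4) {
  if (is.list(ratio_movie))
    ratio_movie <- array(unlist(ratio_movie),
                         dim = c(dim(ratio_movie[[1]]), length(ratio_movie)))
  stopifnot(length(dim(ratio_movie)) == 3L, is.matrix(labels))
  idx <- which(labels == cell_id)
  if (length(idx) == 0)
    stop(sprintf("cell_id %s not present in label image", cell_id))
  if (length(idx) < min_area)
    stop(sprintf("ROI of cell %s has %d pixels, below the minimum of %d",
                 cell_id, length(idx), min_area))
  nt <- dim(ratio_movie)[3]
  npix <- prod(dim(ratio_movie)[1:2])
  vals <- matrix(ratio_movie[rep(idx, nt) + rep((0:(nt - 1)) * npix,
                                                each = length(idx))],
                 nrow = length(idx))
  tr <- colMeans(vals, na.rm = TRUE)
  if (all(is.nan(tr)))
    stop(sprintf("all ratio pixels invalid for cell %s", cell_id))
  if (is.null(times)) times <- seq_len(nt) - 1
  stopifnot(length(times) == nt)
  out <- data.frame(time_s = times, ratio = tr)
  attr(out, "cell_id") <- cell_id
  attr(out, "roi_area") <- length(idx)
  out
}

#' Baseline of a ratio trace before an application
#'
#' The baseline is the average of the trace over a period of 5 s ending
#' 3 s before the beginning of the application, i.e. the samples with
#' time in `[start - 8, start - 3)` seconds (5 samples at 1 Hz).
#'
#' @param trace Trace data.frame with `time_s` and `ratio` (see
#'   [extract_trace()]).
#' @param window One-row schedule data.frame (or list) with `start_s`.
#' @return Scalar baseline in ratio units.
#' @export
compute_baseline <- function(trace, window) {
  start <- window$start_s
  sel <- trace$time_s >= (start - 8) & trace$time_s < (start - 3)
  if (sum(sel) < 5)
    stop(sprintf(
      "insufficient baseline: need 5 samples in [%g, %g) s, found %d",
      start - 8, start - 3, sum(sel)))
  mean(trace$ratio[sel])
}

#' Baseline-corrected area under the curve for one application
#'
#' Trapezoidal integral of `(ratio - baseline)` over the 60 s following
#' the start of the agonist application (configurable), in ratio-seconds.
#' Negative areas are retained.
#'
#' @inheritParams compute_baseline
#' @param baseline Baseline in ratio units (see [compute_baseline()]).
#' @param auc_window_s Integration window length after application start.
#' @return Scalar AUC in ratio * seconds.
#' @export
compute_auc <- function(trace, window, baseline, auc_window_s = 60) {
  start <- window$start_s
  sel <- trace$time_s >= start & trace$time_s <= start + auc_window_s
  tt <- trace$time_s[sel]
  if (length(tt) < 2 || max(tt) < start + auc_window_s)
    stop(sprintf("recording ends before %g s; cannot integrate window",
                 start + auc_window_s))
  yy <- trace$ratio[sel] - baseline
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' KCl viability gate
#'
#' A cell passes the gate if its peak baseline-corrected ratio within the
#' KCl application window (extended by 10 s to catch slow depolarization
#' peaks) reaches at least `min_delta`. Only cells passing the gate are
#' treated as viable neurons downstream.
#'
#' @inheritParams compute_baseline
#' @param kcl_window One-row schedule data.frame with `start_s` and
#'   `duration_s` for the KCl application.
#' @param min_delta Minimum peak delta-ratio (default 0.1).
#' @return Logical.
#' @export
kcl_gate <- function(trace, kcl_window, min_delta = 0.1) {
  start <- kcl_window$start_s
  stop_t <- start + kcl_window$duration_s + 10
  if (max(trace$time_s) < start)
    stop("KCl window lies outside the recording")
  base <- compute_baseline(trace, kcl_window)
  sel <- trace$time_s >= start & trace$time_s <= stop_t
  max(trace$ratio[sel] - base) >= min_delta
}

#' Score every cell of a recording against a schedule
#'
#' Computes, for each cell and each non-KCl agonist, the baseline and the
#' baseline-corrected AUC, plus the KCl gate result.
#'
#' @param traces Long data.frame with columns `cell_id`, `time_s`, `ratio`
#'   (e.g. from [extract_traces()]).
#' @param schedule Application schedule (see [default_schedule()]); must
#'   contain a `"KCl"` row for the gate.
#' @param min_delta KCl gate threshold, see [kcl_gate()].
#' @param auc_window_s AUC integration window, see [compute_auc()].
#' @return Data.frame with columns `cell_id`, `agonist`, `baseline`,
#'   `auc`, `kcl_pass`.
#' @export
score_cells <- function(traces, schedule, min_delta = 0.1,
                        auc_window_s = 60) {
  schedule <- validate_schedule(schedule)
  kcl_row <- schedule[schedule$agonist == "KCl", , drop = FALSE]
  ago <- schedule[schedule$agonist != "KCl", , drop = FALSE]
  if (nrow(kcl_row) != 1)
    stop("schedule must contain exactly one 'KCl' application for the gate")
  by_cell <- split(traces[, c("time_s", "ratio")], traces$cell_id)
  ids <- as.numeric(names(by_cell))
  o <- order(ids)
  by_cell <- by_cell[o]; ids <- ids[o]
  res <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tr <- by_cell[[i]]
    tr <- tr[order(tr$time_s), ]
    pass <- kcl_gate(tr, kcl_row, min_delta)
    rows <- lapply(seq_len(nrow(ago)), function(j) {
      w <- ago[j, ]
      b <- compute_baseline(tr, w)
      data.frame(cell_id = ids[i], agonist = w$agonist, baseline = b,
                 auc = compute_auc(tr, w, b, auc_window_s),
                 kcl_pass = pass, stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extract traces for all cells of a two-channel movie
#'
#' Streams over frame pairs: computes the background-subtracted ratio with
#' [compute_ratio()] and averages valid ratio pixels per ROI.
#'
#' @param movie_340,movie_385 3-D arrays `[rows, cols, frames]`.
#' @param labels Integer ROI label matrix.
#' @param background_340,background_385 Scalar backgrounds; if `NULL`,
#'   estimated from the first frame of each channel with
#'   [estimate_background()].
#' @param times Frame times (seconds); default 1 Hz from 0.
#' @return Long data.frame `cell_id`, `time_s`, `ratio`.
#' @export
extract_traces <- function(movie_340, movie_385, labels,
                           background_340 = NULL, background_385 = NULL,
                           times = NULL) {
  stopifnot(length(dim(movie_340)) == 3L,
            all(dim(movie_340) == dim(movie_385)))
  if (is.null(background_340))
    background_340 <- estimate_background(movie_340[, , 1], labels)
  if (is.null(background_385))
    background_385 <- estimate_background(movie_385[, , 1], labels)
  nt <- dim(movie_340)[3]
  if (is.null(times)) times <- seq_len(nt) - 1
  idx <- which(labels > 0)
  cell_of <- labels[idx]
  ids <- sort(unique(cell_of))
  fac <- factor(cell_of, levels = ids)
  traces <- matrix(NA_real_, nrow = length(ids), ncol = nt)
  for (t in seq_len(nt)) {
    r <- compute_ratio(movie_340[, , t], movie_385[, , t],
                       background_340, background_385)
    rv <- r[idx]
    sums <- rowsum(ifelse(is.na(rv), 0, rv), fac)
    ns <- rowsum(as.numeric(!is.na(rv)), fac)
    traces[, t] <- ifelse(ns > 0, sums / ns, NA_real_)
  }
  data.frame(
    cell_id = rep(ids, each = nt),
    time_s = rep(times, times = length(ids)),
    ratio = as.numeric(t(traces))
  )
}
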