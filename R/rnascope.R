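#' Project a confocal Z-stack to a single plane
#'
#' Average-intensity projection is used for correlation to functional
#' measurements (it reflects multiple signals in the path of light);
#' maximum-intensity projection is used for detection of single mRNA
#' puncta in neurites.
#'
#' @param zstack 3-D numeric array `[rows, cols, planes]` with at least one
#'   plane (a matrix is treated as a single-plane stack).
#' @param mode `"average"` or `"maximum"`.
#' @return 2-D numeric matrix.
#' @export
project_stack <- function(zstack, mode = c("average", "maximum")) {
  mode <- match.arg(mode)
  if (is.matrix(zstack)) zstack <- array(zstack, dim = c(dim(zstack), 1L))
  if (length(dim(zstack)) != 3L || dim(zstack)[3] < 1L)
    stop("zstack must be a 3-D array with at least one plane")
  nz <- dim(zstack)[3]
  if (mode == "average") {
    out <- zstack[, , 1]
    if (nz > 1) for (k in 2:nz) out <- out + zstack[, , k]
    out / nz
  } else {
    out <- zstack[, , 1]
    if (nz > 1) for (k in 2:nz) out <- pmax(out, zstack[, , k])
    out
  }
}

#' Per-cell RNAscope signal from a projection
#'
#' The per-cell statistic is the mean projected intensity over the cell's
#' ROI after subtracting the projection's off-ROI background (mode
#' estimator, see [estimate_background()]). Setting `statistic =
#' "integrated"` returns the background-subtracted sum over the ROI
#' instead.
#'
#' @param projection 2-D numeric matrix (see [project_stack()]).
#' @param labels Integer ROI label matrix (in the projection's frame).
#' @param cell_id Integer cell label.
#' @param background Scalar background; if `NULL`, estimated from off-ROI
#'   pixels.
#' @param statistic `"mean"` (default) or `"integrated"`.
#' @return Scalar signal in arbitrary intensity units.
#' @export
cell_signal <- function(projection, labels, cell_id, background = NULL,
                        statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(projection), is.matrix(labels),
            all(dim(projection) == dim(labels)))
  idx <- which(labels == cell_id)
  if (length(idx) == 0)
    stop(sprintf("cell_id %s not present in label image", cell_id))
  if (is.null(background)) background <- estimate_background(projection, labels)
  vals <- projection[idx] - background
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0)
    stop(sprintf("all projection pixels invalid for cell %s", cell_id))
  if (statistic == "mean") mean(vals) else sum(vals)
}

#' Per-cell RNAscope signal for all cells
#'
#' @inheritParams cell_signal
#' @param channel Probe name recorded in the output (e.g. `"TRPA1"`).
#' @return Data.frame `cell_id`, `channel`, `mean_intensity`.
#' @export
cell_signals <- function(projection, labels, channel = "TRPA1",
                         background = NULL,
                         statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  if (is.null(background)) background <- estimate_background(projection, labels)
  ids <- sort(unique(labels[labels > 0]))
  data.frame(
    cell_id = ids,
    channel = channel,
    mean_intensity = vapply(ids, function(id)
      cell_signal(projection, labels, id, background, statistic), 0.0),
    stringsAsFactors = FALSE
  )
}

#' Fit the intra-day negative-control model
#'
#' The RNAscope positivity threshold is `mean + 2 * SD` of the per-cell
#' intensities measured with the negative-control (bacterial DapB) probe on
#' the same day. The SD uses the n-1 denominator.
#'
#' @param control_intensities Numeric vector of per-cell control
#'   intensities; at least 3 values.
#' @return A list of class `negative_control_model` with `mean`, `sd`,
#'   `threshold` (= mean + 2*sd) and `n_cells`.
#' @export
fit_negative_control <- function(control_intensities) {
  x <- control_intensities[is.finite(control_intensities)]
  if (length(x) < 3)
    stop("at least 3 negative-control cells are required")
  m <- mean(x); s <- stats::sd(x)
  structure(
    list(modality = "rnascope", mean = m, sd = s, threshold = m + 2 * s,
         n_cells = length(x)),
    class = "negative_control_model"
  )
}

#' @export
print.negative_control_model <- function(x, ...) {
  cat(sprintf(
    "negative-control model (n = %d): mean %.4g, sd %.4g, threshold %.4g\n",
    x$n_cells, x$mean, x$sd, x$threshold))
  invisible(x)
}

# Discrete Laplacian-of-Gaussian kernel, sign-flipped so bright blobs give
# positive responses, normalized so a matched Gaussian spot of unit peak
# amplitude yields a response of 1: the detector floor is then in image
# amplitude units.
log_kernel <- function(sigma) {
  h <- max(2L, ceiling(3 * sigma))
  g <- seq(-h, h)
  xx <- matrix(g, 2 * h + 1, 2 * h + 1)
  yy <- t(xx)
  r2 <- xx^2 + yy^2
  k <- -(r2 - 2 * sigma^2) / (sigma^4) * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)            # zero response to constant background
  k / sum(k * exp(-r2 / (2 * sigma^2)))
}

#' Detect diffraction-limited puncta in a maximum projection
#'
#' Laplacian-of-Gaussian blob detection over a range of scales, with
#' non-maximum suppression. Intended for single mRNA molecules in
#' neurites; perikaryal signal is typically too dense for individual
#' molecules to be discernible, which is why the headline per-cell
#' statistic is the projected intensity rather than a puncta count.
#'
#' @param projection 2-D numeric matrix (maximum-intensity projection).
#' @param sigma_range Range of blob scales in pixels, default `c(1, 3)`.
#' @param n_scales Number of scales across `sigma_range`.
#' @param intensity_floor Minimum scale-normalized LoG response for a
#'   candidate.
#' @return Data.frame `x`, `y` (0-based pixel coordinates), `sigma`,
#'   `intensity` (raw image value at the peak), `response`. Empty if no
#'   puncta are found.
#' @export
detect_puncta <- function(projection, sigma_range = c(1, 3), n_scales = 5,
                          intensity_floor = 1) {
  stopifnot(is.matrix(projection))
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_scales)
  nr <- nrow(projection); nc <- ncol(projection)
  resp <- array(0, dim = c(nr, nc, n_scales))
  for (k in seq_along(sigmas))
    resp[, , k] <- EBImage::filter2(projection, log_kernel(sigmas[k]),
                                    boundary = "replicate")
  # local maxima in 3x3 spatial neighborhood and across adjacent scales
  cand <- NULL
  for (k in seq_along(sigmas)) {
    r <- resp[, , k]
    m <- r >= intensity_floor
    if (!any(m)) next
    sh <- function(dr, dc) {
      out <- matrix(-Inf, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      out[rs, cs] <- r[rs - dr, cs - dc]
      out
    }
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- m & (r >= sh(dr, dc))
    }
    if (k > 1) m <- m & (r >= resp[, , k - 1])
    if (k < n_scales) m <- m & (r >= resp[, , k + 1])
    if (any(m)) {
      w <- which(m, arr.ind = TRUE)
      cand <- rbind(cand, data.frame(
        x = w[, 2] - 1, y = w[, 1] - 1, sigma = sigmas[k],
        intensity = projection[w], response = r[w]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      intensity = numeric(0), response = numeric(0)))
  # greedy non-maximum suppression by response
  cand <- cand[order(-cand$response), ]
  keep <- logical(nrow(cand))
  kx <- ky <- kr <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    min_d <- pmax(2, 1.5 * pmax(cand$sigma[i], kr))
    if (length(kx) == 0 ||
        all((kx - cand$x[i])^2 + (ky - cand$y[i])^2 >= min_d^2)) {
      keep[i] <- TRUE
      kx <- c(kx, cand$x[i]); ky <- c(ky, cand$y[i]); kr <- c(kr, cand$sigma[i])
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}
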