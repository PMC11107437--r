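# Solve for the untruncated Gaussian (mu, sigma) given the mean m and sd s
# of the sample kept below a known cut t. Uses the truncated-normal moment
# equations; alpha = (t - mu) / sigma.
truncated_gaussian_fit <- function(m, s, t) {
  if (s <= 0) return(list(mean = m, sd = 0))
  q <- (t - m) / s
  if (q > 6) return(list(mean = m, sd = s))  # truncation negligible
  g <- function(alpha) {
    d <- stats::dnorm(alpha) / stats::pnorm(alpha)
    v <- 1 - alpha * d - d^2
    if (v <= 1e-12) return(Inf)
    (alpha + d) / sqrt(v) - q
  }
  root <- tryCatch(
    stats::uniroot(g, lower = -3, upper = 12, extendInt = "upX",
                   tol = 1e-10)$root,
    error = function(e) NA_real_)
  if (!is.finite(root)) return(list(mean = m, sd = s))
  d <- stats::dnorm(root) / stats::pnorm(root)
  v <- 1 - root * d - d^2
  sigma <- s / sqrt(v)
  list(mean = m + sigma * d, sd = sigma)
}

#' Functional response threshold from the non-responder distribution
#'
#' Fits a Gaussian to the AUC values of cells without a response and
#' returns `mean + 2 * SD` as the response threshold. Because
#' non-responders are themselves defined by the threshold, the fit is
#' iterative: values above the current threshold are excluded and the
#' Gaussian is refit to the remainder until the excluded set is stable (or
#' 50 iterations). Each refit corrects the sample moments for the known
#' upper truncation at the current threshold (truncated-normal maximum
#' likelihood), so on purely Gaussian input the procedure is a consistent
#' estimator of `mu + 2 * sigma` rather than converging to the biased
#' trim-and-refit fixed point near `mu + 1.7 * sigma`.
#'
#' @param aucs Numeric vector of per-cell AUC values (ratio-seconds); at
#'   least 10 values.
#' @param max_iter Maximum number of trim/refit iterations.
#' @return A list of class `threshold_model` with `modality`, `mean`,
#'   `sd`, `threshold` (= mean + 2*sd), `fit_iterations`, `converged`,
#'   `n_used` (cells in the final non-responder set).
#' @export
fit_nonresponder_threshold <- function(aucs, max_iter = 50) {
  x <- aucs[is.finite(aucs)]
  if (length(x) < 10)
    stop("at least 10 cells are required to fit the non-responder threshold")
  mk <- function(m, s, it, conv, n) structure(
    list(modality = "functional", mean = m, sd = s, threshold = m + 2 * s,
         fit_iterations = it, converged = conv, n_used = n),
    class = "threshold_model")
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) return(mk(m, 0, 0L, TRUE, length(x)))
  keep <- x <= m + 2 * s
  thr <- m + 2 * s
  for (it in seq_len(max_iter)) {
    xi <- x[keep]
    if (length(xi) < 3) {
      warning("non-responder set collapsed below 3 cells; returning last fit")
      return(mk(m, s, it, FALSE, length(xi)))
    }
    ms <- mean(xi); ss <- stats::sd(xi)
    if (!any(!keep)) {            # nothing trimmed: no truncation to correct
      fit <- list(mean = ms, sd = ss)
    } else {
      fit <- truncated_gaussian_fit(ms, ss, thr)
    }
    m <- fit$mean; s <- fit$sd
    thr <- m + 2 * s
    new_keep <- x <= thr
    if (identical(new_keep, keep))
      return(mk(m, s, it, TRUE, sum(keep)))
    keep <- new_keep
  }
  warning(sprintf(
    "threshold fit did not converge after %d iterations (threshold %.4g, %d cells kept)",
    max_iter, thr, sum(keep)))
  mk(m, s, max_iter, FALSE, sum(keep))
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "%s threshold model: mean %.4g, sd %.4g, threshold %.4g (%d iterations%s, n = %d)\n",
    x$modality, x$mean, x$sd, x$threshold, x$fit_iterations,
    if (isTRUE(x$converged)) "" else ", NOT converged", x$n_used))
  invisible(x)
}

#' Classify KCl-gated cells into the four concordance categories
#'
#' A cell is functional-positive iff its AUC is strictly greater than the
#' functional threshold, and RNAscope-positive iff its intensity is
#' strictly greater than the negative-control threshold ("above-threshold"
#' is a strict inequality; a value exactly at the threshold is negative).
#' Only cells passing the KCl gate enter classification.
#'
#' @param records Data.frame with columns `cell_id`, `auc`,
#'   `rnascope_intensity` and `kcl_pass`.
#' @param functional_model `threshold_model` from
#'   [fit_nonresponder_threshold()] (any list with a `threshold` field
#'   works).
#' @param rnascope_model `negative_control_model` from
#'   [fit_negative_control()].
#' @return A list with `records` (classified gated cells, with
#'   `functional_positive`, `rnascope_positive`, `category`) and `counts`
#'   (named list `both`, `rnascope_only`, `functional_only`, `neither`,
#'   `total`).
#' @export
classify_cells <- function(records, functional_model, rnascope_model) {
  need <- c("cell_id", "auc", "rnascope_intensity", "kcl_pass")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (anyNA(records$auc) || anyNA(records$rnascope_intensity))
    stop("missing measurement: every record needs both 'auc' and ",
         "'rnascope_intensity'")
  gated <- records[records$kcl_pass, , drop = FALSE]
  fp <- gated$auc > functional_model$threshold
  rp <- gated$rnascope_intensity > rnascope_model$threshold
  cat4 <- ifelse(fp & rp, "both",
          ifelse(rp, "rnascope_only",
          ifelse(fp, "functional_only", "neither")))
  gated$functional_positive <- fp
  gated$rnascope_positive <- rp
  gated$category <- factor(cat4, levels = c("both", "rnascope_only",
                                            "functional_only", "neither"))
  counts <- as.list(table(gated$category))
  counts$total <- nrow(gated)
  list(records = gated, counts = counts)
}

#' Union set of cells positive on either modality
#'
#' All cells with an above-threshold signal on either RNAscope or the
#' functional response; the population on which the Pearson correlation is
#' computed. Its size equals `both + rnascope_only + functional_only`.
#'
#' @param records Classified records (see [classify_cells()]).
#' @return Subset of `records` with at least one positivity flag.
#' @export
select_union <- function(records) {
  if (!all(c("functional_positive", "rnascope_positive") %in% names(records)))
    stop("records must be classified first (see classify_cells)")
  records[records$functional_positive | records$rnascope_positive, ,
          drop = FALSE]
}

#' Summary percentages for a category-count table
#'
#' @param counts Named list or vector with `both`, `rnascope_only`,
#'   `functional_only`, `neither` counts.
#' @param denominator `"total"` (all gated cells), `"union"` (cells
#'   positive on either modality), or `"functional"` (cells positive on
#'   the functional/reporter modality, as used for co-transfection
#'   summaries where the reporter defines the transfected population).
#' @return Named numeric vector of percentages.
#' @export
category_summary <- function(counts,
                             denominator = c("total", "union", "functional")) {
  denominator <- match.arg(denominator)
  b <- as.numeric(counts[["both"]])
  r <- as.numeric(counts[["rnascope_only"]])
  f <- as.numeric(counts[["functional_only"]])
  n <- as.numeric(counts[["neither"]] %||% 0)
  den <- switch(denominator,
                total = b + r + f + n,
                union = b + r + f,
                functional = b + f)
  c(both = 100 * b / den, rnascope_only = 100 * r / den,
    functional_only = 100 * f / den, neither = 100 * n / den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
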