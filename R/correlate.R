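#' Pearson product-moment correlation with t-based p-value
#'
#' Standard product-moment r; the two-sided p-value comes from the exact
#' t-transform `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 degrees of
#' freedom. A seeded permutation p-value is available as a robustness
#' check.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with non-zero
#'   variance.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations for `method = "permutation"`.
#' @param perm_seed Seed for the permutation draw.
#' @return List with `r`, `p_value`, `n`, `df`, `t`.
#' @export
pearson_cor <- function(x, y, method = c("t", "permutation"),
                        n_perm = 10000, perm_seed = 1) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("zero variance in x or y; correlation undefined")
  r <- sum(xc * yc) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  tt <- if (abs(r) < 1) r * sqrt((n - 2) / (1 - r^2)) else sign(r) * Inf
  p <- if (method == "t") {
    2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(perm_seed)
    rp <- replicate(n_perm, {
      ys <- sample(yc)
      sum(xc * ys) / sqrt(sxx * syy)
    })
    (1 + sum(abs(rp) >= abs(r))) / (n_perm + 1)
  }
  list(r = r, p_value = p, n = n, df = n - 2, t = tt)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Correlation between RNAscope signal and functional response
#'
#' Applies [pearson_cor()] to `(rnascope_intensity, auc)` over the union
#' set (cells positive on either modality) of classified records.
#'
#' By default the RNAscope intensity is asinh-transformed before the
#' correlation: per-cell mRNA signal is approximately lognormal over the
#' expressing population, and asinh behaves like a logarithm for clearly
#' positive signal while remaining defined at and below zero, so union
#' sets containing functional-only cells (no mRNA signal) are handled
#' without dropping cells. Use `intensity_transform = "identity"` for the
#' raw-scale correlation.
#'
#' @param records Classified records (see [classify_cells()]).
#' @param channel,agonist Names recorded in the result.
#' @param intensity_transform `"asinh"` (default), `"log"`, or
#'   `"identity"`.
#' @param auc_transform `"identity"` (default) or `"asinh"`.
#' @param ... Passed to [pearson_cor()].
#' @return List of class `correlation_result`: `channel`, `agonist`, `r`,
#'   `p_value`, `n`, `intensity_transform`, `auc_transform`.
#' @export
run_correlation <- function(records, channel = "TRPA1", agonist = "AITC",
                            intensity_transform = c("asinh", "log",
                                                    "identity"),
                            auc_transform = c("identity", "asinh"), ...) {
  intensity_transform <- match.arg(intensity_transform)
  auc_transform <- match.arg(auc_transform)
  u <- select_union(records)
  if (nrow(u) < 3)
    stop(sprintf("degenerate union set (n = %d): need at least 3 cells",
                 nrow(u)))
  tr <- function(v, how) switch(how, asinh = asinh(v), log = log(v),
                                identity = v)
  x <- tr(u$rnascope_intensity, intensity_transform)
  y <- tr(u$auc, auc_transform)
  if (intensity_transform == "log" && any(!is.finite(x)))
    stop("log intensity transform produced non-finite values; ",
         "use 'asinh' for union sets containing non-positive intensities")
  pc <- pearson_cor(x, y, ...)
  structure(
    list(channel = channel, agonist = agonist, r = pc$r,
         p_value = pc$p_value, n = pc$n,
         intensity_transform = intensity_transform,
         auc_transform = auc_transform),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s RNAscope vs %s response: R = %.3f, p = %.3g, n = %d\n",
              x$channel, x$agonist, x$r, x$p_value, x$n))
  invisible(x)
}

#' Fisher z-transform confidence interval for a correlation
#'
#' @param rho Correlation coefficient.
#' @param n Sample size (> 3).
#' @param level Confidence level.
#' @return Length-2 vector `c(lower, upper)` on the correlation scale.
#' @export
fisher_ci <- function(rho, n, level = 0.95) {
  stopifnot(n > 3, abs(rho) < 1)
  z <- atanh(rho)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

#' Scatter plot of the union-set correlation
#'
#' Requires ggplot2 (Suggests). Shows the union-set cells on the analysis
#' scale with both thresholds as reference lines.
#'
#' @param records Classified records.
#' @param functional_model,rnascope_model Threshold models.
#' @param result Optional `correlation_result` used for the subtitle.
#' @return A ggplot object.
#' @export
plot_correlation <- function(records, functional_model, rnascope_model,
                             result = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_correlation requires the 'ggplot2' package")
  u <- select_union(records)
  p <- ggplot2::ggplot(u, ggplot2::aes(
        x = asinh(.data$rnascope_intensity), y = .data$auc)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = asinh(rnascope_model$threshold),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = functional_model$threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "asinh RNAscope intensity (a.u.)",
                  y = "AUC (ratio · s)")
  if (!is.null(result))
    p <- p + ggplot2::labs(subtitle = sprintf("R = %.2f, p = %.2g, n = %d",
                                              result$r, result$p_value,
                                              result$n))
  p
}
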