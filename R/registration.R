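#' Similarity transform between imaging coordinate frames
#'
#' Constructs a similarity transform (rotation + translation + isotropic
#' scale) mapping moving-frame coordinates (typically the confocal image)
#' into fixed-frame coordinates (typically the wide-field functional image).
#' A point `p = (x, y)` maps to `q = scale * R(rotation) %*% p + (dx, dy)`.
#'
#' Coordinates are 0-based with pixel centers at integer positions, origin
#' at the top-left corner, x increasing rightwards (columns) and y
#' increasing downwards (rows).
#'
#' @param rotation_deg Rotation angle in degrees (counter-clockwise in the
#'   x-right / y-down convention).
#' @param dx,dy Translation in pixels.
#' @param scale Isotropic scale factor; must be positive.
#' @return An object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation_deg = 0, dx = 0, dy = 0, scale = 1) {
  stopifnot(is.numeric(rotation_deg), is.numeric(dx), is.numeric(dy),
            is.numeric(scale), length(scale) == 1L)
  if (!is.finite(scale) || scale <= 0)
    stop("'scale' must be a positive finite number")
  structure(
    list(rotation_deg = as.numeric(rotation_deg),
         dx = as.numeric(dx), dy = as.numeric(dy),
         scale = as.numeric(scale)),
    class = "similarity_transform"
  )
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "similarity_transform: rotation %.4f deg, translation (%.4f, %.4f) px, scale %.6f\n",
    x$rotation_deg, x$dx, x$dy, x$scale))
  invisible(x)
}

rotation_matrix <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Invert a similarity transform
#'
#' @param tf A `similarity_transform`.
#' @return The inverse transform, such that composing the two is the
#'   identity.
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  R <- rotation_matrix(-tf$rotation_deg)
  t_inv <- -(R %*% c(tf$dx, tf$dy)) / tf$scale
  similarity_transform(-tf$rotation_deg, t_inv[1], t_inv[2], 1 / tf$scale)
}

#' Compose two similarity transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first and then `a`.
#'
#' @param a,b `similarity_transform` objects.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"),
            inherits(b, "similarity_transform"))
  Ra <- rotation_matrix(a$rotation_deg)
  t_new <- a$scale * (Ra %*% c(b$dx, b$dy)) + c(a$dx, a$dy)
  similarity_transform(a$rotation_deg + b$rotation_deg,
                       t_new[1], t_new[2], a$scale * b$scale)
}

#' Apply a similarity transform to points or an image
#'
#' Points are mapped exactly. Images are resampled into the fixed frame by
#' inverse mapping with bilinear interpolation; output pixels whose source
#' location falls outside the input image are `NA` (invalid) and are
#' excluded from downstream ROI statistics.
#'
#' @param x Either a two-column matrix / data.frame of `(x, y)` point
#'   coordinates, or a numeric matrix interpreted as an image (rows = y,
#'   columns = x). Matrices with exactly two columns are treated as points;
#'   use [transform_image()] directly for two-column images.
#' @param tf A `similarity_transform` mapping moving to fixed coordinates.
#' @param out_dim For images, the `c(nrow, ncol)` of the output (fixed)
#'   frame; defaults to the input dimensions.
#' @return Transformed points (matrix with columns x, y) or the resampled
#'   image.
#' @export
apply_transform <- function(x, tf, out_dim = NULL) {
  stopifnot(inherits(tf, "similarity_transform"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x) && ncol(x) == 2L && is.null(out_dim))
    return(transform_points(x, tf))
  transform_image(x, tf, out_dim)
}

#' @rdname apply_transform
#' @export
transform_points <- function(x, tf) {
  stopifnot(inherits(tf, "similarity_transform"))
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.numeric(x), ncol(x) == 2L)
  R <- rotation_matrix(tf$rotation_deg)
  out <- tf$scale * (x %*% t(R))
  out[, 1] <- out[, 1] + tf$dx
  out[, 2] <- out[, 2] + tf$dy
  colnames(out) <- c("x", "y")
  out
}

# Bilinear sampling of img at 0-based (x, y) coordinates; NA outside.
bilinear_sample <- function(img, xs, ys) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0;   fy <- ys - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1 &
        (x0 + ceiling(fx)) <= nc - 1 & (y0 + ceiling(fy)) <= nr - 1
  out <- rep(NA_real_, length(xs))
  if (!any(ok)) return(out)
  x0k <- x0[ok]; y0k <- y0[ok]; fxk <- fx[ok]; fyk <- fy[ok]
  x1k <- pmin(x0k + 1, nc - 1); y1k <- pmin(y0k + 1, nr - 1)
  i00 <- img[cbind(y0k + 1, x0k + 1)]
  i01 <- img[cbind(y0k + 1, x1k + 1)]
  i10 <- img[cbind(y1k + 1, x0k + 1)]
  i11 <- img[cbind(y1k + 1, x1k + 1)]
  out[ok] <- (1 - fyk) * ((1 - fxk) * i00 + fxk * i01) +
             fyk       * ((1 - fxk) * i10 + fxk * i11)
  out
}

#' @rdname apply_transform
#' @export
transform_image <- function(img, tf, out_dim = NULL) {
  stopifnot(is.matrix(img), is.numeric(img),
            inherits(tf, "similarity_transform"))
  if (is.null(out_dim)) out_dim <- dim(img)
  inv <- invert_transform(tf)
  xs <- rep(seq_len(out_dim[2]) - 1, each = out_dim[1])
  ys <- rep(seq_len(out_dim[1]) - 1, times = out_dim[2])
  src <- transform_points(cbind(xs, ys), inv)
  matrix(bilinear_sample(img, src[, 1], src[, 2]),
         nrow = out_dim[1], ncol = out_dim[2])
}

#' Least-squares similarity fit to paired landmarks
#'
#' Closed-form fit of the similarity transform mapping `moving` landmark
#' coordinates onto `fixed` landmark coordinates, by complex linear
#' regression (equivalent to the 2-D Procrustes / Umeyama solution without
#' reflection).
#'
#' @param fixed,moving Two-column matrices or data.frames of paired `(x, y)`
#'   coordinates; at least 2 pairs.
#' @return A `similarity_transform` with attribute `"rmse"` (root mean
#'   squared landmark residual in pixels).
#' @export
fit_transform_landmarks <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  stopifnot(ncol(fixed) == 2L, ncol(moving) == 2L)
  if (nrow(fixed) != nrow(moving))
    stop("landmark sets must be paired (equal number of rows)")
  if (nrow(fixed) < 2L)
    stop("at least 2 landmark pairs are required")
  w <- complex(real = fixed[, 1], imaginary = fixed[, 2])
  z <- complex(real = moving[, 1], imaginary = moving[, 2])
  zc <- z - mean(z); wc <- w - mean(w)
  denom <- sum(Mod(zc)^2)
  if (denom == 0) stop("degenerate landmarks: moving points are coincident")
  a <- sum(wc * Conj(zc)) / denom
  b <- mean(w) - a * mean(z)
  tf <- similarity_transform(Arg(a) * 180 / pi, Re(b), Im(b), Mod(a))
  res <- transform_points(moving, tf) - fixed
  attr(tf, "rmse") <- sqrt(mean(res^2) * 2)
  tf
}

# Normalized cross-correlation over jointly valid pixels.
ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 16) return(-Inf)
  a <- a[ok]; b <- b[ok]
  a <- a - mean(a); b <- b - mean(b)
  d <- sqrt(sum(a^2) * sum(b^2))
  if (d == 0) return(-Inf)
  sum(a * b) / d
}

# Integer-pixel translation maximizing the (zero-padded) cross-correlation
# of mean-subtracted images, via FFT.
fft_translation <- function(fixed, moving) {
  f <- fixed; m <- moving
  f[!is.finite(f)] <- 0; m[!is.finite(m)] <- 0
  f <- f - mean(f); m <- m - mean(m)
  nr <- nrow(f) + nrow(m); nc <- ncol(f) + ncol(m)
  fp <- matrix(0, nr, nc); mp <- matrix(0, nr, nc)
  fp[seq_len(nrow(f)), seq_len(ncol(f))] <- f
  mp[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  cc <- Re(stats::fft(stats::fft(fp) * Conj(stats::fft(mp)), inverse = TRUE))
  idx <- which.max(cc)
  r <- (idx - 1) %% nr; c <- (idx - 1) %/% nr
  if (r > nr / 2) r <- r - nr
  if (c > nc / 2) c <- c - nc
  c(dx = c, dy = r)
}

#' Estimate the confocal-to-widefield similarity transform
#'
#' Landmark mode (when `landmarks` is supplied) uses the closed-form
#' least-squares similarity fit. Intensity mode searches a grid of rotation
#' and scale candidates, recovering the translation for each candidate by
#' FFT cross-correlation, then refines all four parameters by Nelder-Mead
#' maximization of the normalized cross-correlation (NCC) between the
#' warped moving image and the fixed image.
#'
#' @param fixed Fixed-frame (wide-field) transmission image, numeric matrix.
#' @param moving Moving-frame (confocal) transmission image, numeric matrix.
#' @param landmarks Optional data.frame/matrix with columns
#'   `x_fixed, y_fixed, x_moving, y_moving` of paired points (at least 2).
#' @param rot_range,scale_range Search intervals for intensity mode,
#'   degrees and scale factor.
#' @param rot_step,scale_step Grid steps for the coarse search.
#' @param ncc_floor Final NCC below this value flags the result as
#'   low-confidence (with a warning).
#' @return A `similarity_transform` mapping moving to fixed coordinates,
#'   with attributes `"ncc"`, `"low_confidence"` and `"mode"`.
#' @export
estimate_transform <- function(fixed, moving, landmarks = NULL,
                               rot_range = c(-15, 15), rot_step = 3,
                               scale_range = c(0.9, 1.1), scale_step = 0.05,
                               ncc_floor = 0.4) {
  if (!is.null(landmarks)) {
    lm <- as.data.frame(landmarks)
    need <- c("x_fixed", "y_fixed", "x_moving", "y_moving")
    if (!all(need %in% names(lm))) {
      if (ncol(lm) == 4L) names(lm) <- need
      else stop("landmarks must have columns x_fixed, y_fixed, x_moving, y_moving")
    }
    if (nrow(lm) < 2L) stop("at least 2 landmark pairs are required")
    tf <- fit_transform_landmarks(lm[, c("x_fixed", "y_fixed")],
                                  lm[, c("x_moving", "y_moving")])
    attr(tf, "mode") <- "landmark"
    attr(tf, "low_confidence") <- FALSE
    return(tf)
  }
  stopifnot(is.matrix(fixed), is.matrix(moving))
  cm <- c((ncol(moving) - 1) / 2, (nrow(moving) - 1) / 2)  # moving center

  # Candidate transform: rotation/scale about the moving-image center plus
  # translation tau. Canonical (about-origin) form for the constructor:
  canonical <- function(theta, s, tau) {
    R <- rotation_matrix(theta)
    t0 <- cm + tau - s * (R %*% cm)
    similarity_transform(theta, t0[1], t0[2], s)
  }

  rots <- seq(rot_range[1], rot_range[2], by = rot_step)
  scales <- seq(scale_range[1], scale_range[2], by = scale_step)
  best <- list(score = -Inf)
  for (s in scales) for (th in rots) {
    warped <- transform_image(moving, canonical(th, s, c(0, 0)), dim(fixed))
    tau <- fft_translation(fixed, warped)
    shifted <- transform_image(moving, canonical(th, s, tau), dim(fixed))
    sc <- ncc(shifted, fixed)
    if (sc > best$score) best <- list(score = sc, theta = th, s = s, tau = tau)
  }
  obj <- function(par) {
    s <- exp(par[4])
    if (s < 0.5 || s > 2) return(1e6)
    w <- transform_image(moving, canonical(par[1], s, par[2:3]), dim(fixed))
    -ncc(w, fixed)
  }
  fit <- stats::optim(c(best$theta, best$tau, log(best$s)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-10))
  tf <- canonical(fit$par[1], exp(fit$par[4]), fit$par[2:3])
  final_ncc <- -fit$value
  attr(tf, "ncc") <- final_ncc
  attr(tf, "mode") <- "intensity"
  low <- final_ncc < ncc_floor
  attr(tf, "low_confidence") <- low
  if (low)
    warning(sprintf("registration NCC %.3f below confidence floor %.3f",
                    final_ncc, ncc_floor))
  tf
}

#' Map ROI labels from the wide-field into the confocal frame
#'
#' Each confocal output pixel is assigned the label of its nearest
#' wide-field pixel under the forward transform (nearest-neighbor label
#' propagation). ROIs that end up with no pixel inside the confocal field
#' of view are dropped and reported.
#'
#' @param labels Integer label matrix in the wide-field (fixed) frame;
#'   0 = background.
#' @param tf `similarity_transform` mapping confocal (moving) to wide-field
#'   (fixed) coordinates.
#' @param out_dim `c(nrow, ncol)` of the confocal frame.
#' @return A list with `labels` (label matrix in the confocal frame) and
#'   `dropped` (integer vector of labels absent from the output).
#' @export
map_rois <- function(labels, tf, out_dim = dim(labels)) {
  stopifnot(is.matrix(labels), inherits(tf, "similarity_transform"))
  xs <- rep(seq_len(out_dim[2]) - 1, each = out_dim[1])
  ys <- rep(seq_len(out_dim[1]) - 1, times = out_dim[2])
  src <- transform_points(cbind(xs, ys), tf)
  cx <- round(src[, 1]); cy <- round(src[, 2])
  ok <- cx >= 0 & cy >= 0 & cx < ncol(labels) & cy < nrow(labels)
  out <- integer(length(xs))
  out[ok] <- labels[cbind(cy[ok] + 1, cx[ok] + 1)]
  out <- matrix(out, nrow = out_dim[1], ncol = out_dim[2])
  present_in <- sort(unique(labels[labels > 0]))
  present_out <- sort(unique(out[out > 0]))
  list(labels = out, dropped = setdiff(present_in, present_out))
}

#' Read/write a similarity transform as JSON
#'
#' @param tf A `similarity_transform`.
#' @param path File path.
#' @export
write_transform <- function(tf, path) {
  stopifnot(inherits(tf, "similarity_transform"))
  jsonlite::write_json(
    list(rotation_deg = tf$rotation_deg, dx_px = tf$dx, dy_px = tf$dy,
         scale = tf$scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity_transform(x$rotation_deg, x$dx_px, x$dy_px, x$scale)
}
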