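#' Configuration for the synthetic imaging-study generator
#'
#' Describes a seeded synthetic experiment: a population of cultured cells
#' imaged with ratiometric Fura-2 at 1 Hz under a sequential agonist
#' schedule, then fixed and imaged as confocal RNAscope Z-stacks in a
#' displaced coordinate frame.
#'
#' Under the defaults every KCl-viable neuron is drawn from one continuous
#' bivariate population in which log mRNA expression and agonist-response
#' AUC are correlated at `true_correlation`; the correlation is enforced
#' as the realized sample correlation of the latent pair, so
#' pipeline-recovery error reflects the measurement chain only. Bimodal
#' expressing/non-expressing populations and discordant cells
#' (RNAscope-positive without a functional response and vice versa) are
#' configured with `fraction_expressing`, `rate_rnascope_only` and
#' `rate_functional_only`; with discordance configured, `true_correlation`
#' applies to the doubly-positive population.
#'
#' @param n_cells Number of cells in the field.
#' @param fraction_neurons Fraction of cells that are KCl-responsive
#'   neurons; the rest emulate non-neuronal cells that fail the KCl gate.
#' @param fraction_expressing Fraction of neurons expressing each probe's
#'   transcript (applied independently per channel).
#' @param true_correlation Target Pearson correlation between
#'   log-expression and AUC (see Details), in `[-1, 1]`.
#' @param noise_sd Gaussian noise SD added to the ratio traces (ratio
#'   units).
#' @param frame_rate Acquisition rate in Hz (frame pairs per second).
#' @param schedule Application schedule; default [default_schedule()]:
#'   AITC 100 uM / 60 s, capsaicin 1 uM / 30 s, KCl 60 mM / 15 s.
#' @param transform Named list `rotation_deg`, `dx_px`, `dy_px`, `scale`:
#'   the true similarity misalignment between the confocal and wide-field
#'   frames (rotation and scale about the image center plus translation).
#' @param rate_rnascope_only,rate_functional_only Fractions of neurons
#'   that are mRNA-positive without a functional response, and vice versa.
#' @param seed Integer seed; identical configs (including seed) generate
#'   bit-identical outputs.
#' @param expression_meanlog,expression_sdlog Lognormal parameters of
#'   per-cell expression among expressing neurons (arbitrary units).
#' @param auc_mean,auc_sd Gaussian parameters of the true response AUC
#'   among responders (ratio-seconds).
#' @param n_controls Number of intra-day negative-control cells.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_cells = 500,
                         fraction_neurons = 0.85,
                         fraction_expressing = 1.0,
                         true_correlation = 0.43,
                         noise_sd = 0.02,
                         frame_rate = 1,
                         schedule = default_schedule(),
                         transform = list(rotation_deg = 2, dx_px = 6,
                                          dy_px = -4, scale = 1.02),
                         rate_rnascope_only = 0,
                         rate_functional_only = 0,
                         seed = 1,
                         expression_meanlog = log(40),
                         expression_sdlog = 0.8,
                         auc_mean = 25,
                         auc_sd = 10,
                         n_controls = 30) {
  chk01 <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single number in [0, 1]", nm))
  }
  if (!is.numeric(n_cells) || length(n_cells) != 1 || n_cells < 1 ||
      n_cells != round(n_cells))
    stop("'n_cells' must be a positive integer")
  chk01(fraction_neurons, "fraction_neurons")
  chk01(fraction_expressing, "fraction_expressing")
  chk01(rate_rnascope_only, "rate_rnascope_only")
  chk01(rate_functional_only, "rate_functional_only")
  if (!is.numeric(true_correlation) || abs(true_correlation) > 1)
    stop("'true_correlation' must lie in [-1, 1]")
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("'frame_rate' must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  if (fraction_expressing < rate_rnascope_only)
    stop("'rate_rnascope_only' cannot exceed 'fraction_expressing'")
  if (fraction_expressing - rate_rnascope_only + rate_functional_only > 1)
    stop("'fraction_expressing' + 'rate_functional_only' exceed the population")
  need_tf <- c("rotation_deg", "dx_px", "dy_px", "scale")
  if (!is.list(transform) || !all(need_tf %in% names(transform)))
    stop("'transform' must be a list with fields ",
         paste(need_tf, collapse = ", "))
  if (transform$scale <= 0) stop("'transform$scale' must be > 0")
  schedule <- validate_schedule(schedule)
  structure(
    list(n_cells = as.integer(n_cells),
         fraction_neurons = fraction_neurons,
         fraction_expressing = fraction_expressing,
         true_correlation = true_correlation,
         noise_sd = noise_sd,
         frame_rate = frame_rate,
         schedule = schedule,
         transform = transform,
         rate_rnascope_only = rate_rnascope_only,
         rate_functional_only = rate_functional_only,
         seed = as.integer(seed),
         expression_meanlog = expression_meanlog,
         expression_sdlog = expression_sdlog,
         auc_mean = auc_mean,
         auc_sd = auc_sd,
         n_controls = as.integer(n_controls)),
    class = "synth_config")
}

# Internal imaging constants of the synthetic microscope. Chosen once to
# emulate a 16-bit CCD at 10x: see the methods vignette.
synth_camera <- list(
  bg340 = 150, bg385 = 300, read_sd_wf = 3,
  f385_mean = 2500, f385_sd = 300, f385_min = 800,
  cell_radius = 4.5, roi_radius = 4, spacing = 14, margin = 12,
  conf_bg = 20, conf_read_sd = 2, n_planes = 21,
  autofluor_mean = 5, autofluor_sd = 1.5,
  baseline_mean = 0.8, baseline_sd = 0.05,
  tau_rise = 3, tau_decay = 20,
  kcl_meanlog = 0, kcl_sdlog = 0.3,
  landmark_jitter = 0.3, n_landmarks = 8
)

# Standardize to exact sample mean 0 / sd 1.
standardize <- function(z) (z - mean(z)) / stats::sd(z)

# Pair of latent vectors with EXACT sample correlation rho.
exact_corr_pair <- function(n, rho) {
  z1 <- standardize(stats::rnorm(n))
  z2 <- stats::rnorm(n)
  e <- stats::residuals(stats::lm.fit(cbind(1, z1), z2))
  e <- standardize(e)
  list(z1 = z1, z2 = rho * z1 + sqrt(1 - rho^2) * e)
}

# Response kernel: exponential rise during the application, exponential
# decay afterwards. Unit amplitude.
response_kernel <- function(times, start, duration,
                            tau_rise = synth_camera$tau_rise,
                            tau_decay = synth_camera$tau_decay) {
  k <- numeric(length(times))
  up <- times >= start & times <= start + duration
  k[up] <- 1 - exp(-(times[up] - start) / tau_rise)
  peak <- 1 - exp(-duration / tau_rise)
  down <- times > start + duration
  k[down] <- peak * exp(-(times[down] - start - duration) / tau_decay)
  k
}

# Discrete trapezoid of a sampled series over [t0, t0 + window].
trapz_window <- function(times, values, t0, window) {
  sel <- times >= t0 & times <= t0 + window
  tt <- times[sel]; yy <- values[sel]
  sum(diff(tt) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Render a single-cell ratio trace
#'
#' Builds a Fura-2 ratio time course as a baseline plateau plus one
#' response kernel per scheduled application. The kernel is a
#' single-exponential rise (tau 3 s) with plateau followed by an
#' exponential decay (tau 20 s); its amplitude is scaled so that the
#' trapezoidal AUC of the noiseless kernel over the 60 s analysis window
#' on the acquisition grid equals the cell's true AUC. The KCl kernel is
#' present iff the cell is KCl-responsive.
#'
#' @param cell One-row data.frame or list with fields `true_auc_aitc`,
#'   `true_auc_caps`, `kcl_responsive`, and optionally `kcl_amplitude`
#'   (peak delta-ratio, default 1) and `baseline_ratio` (default 0.8).
#' @param schedule Application schedule (validated, non-overlapping).
#' @param noise_sd Gaussian noise SD in ratio units.
#' @param seed Optional seed for the noise draw.
#' @param frame_rate Sampling rate, Hz.
#' @param t_end Recording length in seconds; default extends 90 s past the
#'   last application.
#' @param auc_window_s AUC analysis window used for amplitude calibration.
#' @return Trace data.frame `time_s`, `ratio`.
#' @export
render_trace <- function(cell, schedule, noise_sd = 0, seed = NULL,
                         frame_rate = 1, t_end = NULL, auc_window_s = 60) {
  schedule <- validate_schedule(schedule)
  if (is.null(t_end))
    t_end <- max(schedule$start_s + pmax(schedule$duration_s, auc_window_s)) + 30
  times <- seq(0, t_end, by = 1 / frame_rate)
  base <- cell$baseline_ratio %||% 0.8
  ratio <- rep(base, length(times))
  for (j in seq_len(nrow(schedule))) {
    w <- schedule[j, ]
    k <- response_kernel(times, w$start_s, w$duration_s)
    if (w$agonist == "KCl") {
      if (!isTRUE(cell$kcl_responsive)) next
      amp <- cell$kcl_amplitude %||% 1
    } else {
      target <- switch(tolower(w$agonist),
                       aitc = cell$true_auc_aitc,
                       capsaicin = cell$true_auc_caps,
                       0)
      if (is.null(target) || target == 0) next
      unit_auc <- trapz_window(times, k, w$start_s, auc_window_s)
      amp <- target / unit_auc
    }
    ratio <- ratio + amp * k
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    ratio <- ratio + stats::rnorm(length(times), 0, noise_sd)
  }
  data.frame(time_s = times, ratio = ratio)
}

# Category assignment per neuron per channel given config rates.
draw_categories <- function(n, cfg) {
  p_rna <- cfg$rate_rnascope_only
  p_func <- cfg$rate_functional_only
  p_both <- cfg$fraction_expressing - p_rna
  p_neither <- 1 - p_both - p_rna - p_func
  sample(c("both", "rnascope_only", "functional_only", "neither"), n,
         replace = TRUE, prob = c(p_both, p_rna, p_func, p_neither))
}

# Per-channel latent expression / AUC draws honoring true_correlation.
draw_channel <- function(cat4, cfg) {
  n <- length(cat4)
  expr <- numeric(n)
  auc <- numeric(n)
  ib <- cat4 == "both"
  if (sum(ib) >= 3) {
    z <- exact_corr_pair(sum(ib), cfg$true_correlation)
    expr[ib] <- exp(cfg$expression_meanlog + cfg$expression_sdlog * z$z1)
    auc[ib] <- cfg$auc_mean + cfg$auc_sd * z$z2
  } else if (any(ib)) {
    expr[ib] <- stats::rlnorm(sum(ib), cfg$expression_meanlog,
                              cfg$expression_sdlog)
    auc[ib] <- stats::rnorm(sum(ib), cfg$auc_mean, cfg$auc_sd)
  }
  ir <- cat4 == "rnascope_only"
  expr[ir] <- stats::rlnorm(sum(ir), cfg$expression_meanlog,
                            cfg$expression_sdlog)
  io <- cat4 == "functional_only"
  auc[io] <- cfg$auc_mean + cfg$auc_sd * stats::rnorm(sum(io))
  list(expression = expr, auc = auc)
}

disk_pixels <- function(cx, cy, radius, nrow_, ncol_) {
  r <- ceiling(radius)
  xs <- (round(cx) - r):(round(cx) + r)
  ys <- (round(cy) - r):(round(cy) + r)
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2 &
    g$x >= 0 & g$y >= 0 & g$x < ncol_ & g$y < nrow_
  g <- g[keep, ]
  g$y + 1 + g$x * nrow_   # linear index into a [nrow, ncol] matrix
}

#' Generate a complete synthetic dataset
#'
#' Produces, under one seed, the wide-field 340/385 movie pair, the
#' confocal RNAscope Z-stacks (TRPA1, TRPV1, DAPI, transmitted light) in a
#' frame displaced by the configured similarity transform, the ROI label
#' image, operator-style landmark pairs, intra-day negative-control
#' intensities, and the ground-truth table. Identical configs (including
#' seed) produce bit-identical outputs.
#'
#' @param config A [synth_config()].
#' @param render_images If `FALSE`, skip pixel-level rendering: the
#'   dataset then carries the ratio traces and a per-cell `measurements`
#'   table (intensity with measurement noise) instead of image arrays.
#'   Used for statistically oriented simulations where the imaging chain
#'   itself is not under test.
#' @return A list of class `furascope_dataset`; see Details.
#' @details Fields: `config`, `truth` (ground-truth table), `traces`
#'   (long per-cell ratio traces), `roi_labels`, `widefield` (`ch340`,
#'   `ch385` arrays and `transmission`), `confocal` (`TRPA1`, `TRPV1`,
#'   `DAPI` stacks and `transmission`), `negative_controls`, `landmarks`,
#'   `transform` (true confocal-to-widefield `similarity_transform`), and
#'   `measurements` (lightweight mode only).
#' @export
generate_dataset <- function(config, render_images = TRUE) {
  stopifnot(inherits(config, "synth_config"))
  cam <- synth_camera
  set.seed(config$seed)
  n <- config$n_cells

  # --- geometry ------------------------------------------------------
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  W <- ncol_g * cam$spacing + 2 * cam$margin
  H <- nrow_g * cam$spacing + 2 * cam$margin
  gx <- (seq_len(ncol_g) - 0.5) * cam$spacing + cam$margin
  gy <- (seq_len(nrow_g) - 0.5) * cam$spacing + cam$margin
  pos <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  pos$x <- pos$x + pmax(pmin(stats::rnorm(n, 0, 1.2), 3), -3)
  pos$y <- pos$y + pmax(pmin(stats::rnorm(n, 0, 1.2), 3), -3)

  # true transform: rotation/scale about the image center + translation
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  R <- rotation_matrix(config$transform$rotation_deg)
  t0 <- ctr + c(config$transform$dx_px, config$transform$dy_px) -
    config$transform$scale * (R %*% ctr)
  true_tf <- similarity_transform(config$transform$rotation_deg,
                                  t0[1], t0[2], config$transform$scale)
  conf_pos <- transform_points(as.matrix(pos), invert_transform(true_tf))

  # --- population ----------------------------------------------------
  is_neuron <- seq_len(n) %in% sample.int(n, round(config$fraction_neurons * n))
  nn <- sum(is_neuron)
  cat_a <- cat_v <- rep("non_neuron", n)
  cat_a[is_neuron] <- draw_categories(nn, config)
  cat_v[is_neuron] <- draw_categories(nn, config)
  cha <- draw_channel(cat_a[is_neuron], config)
  chv <- draw_channel(cat_v[is_neuron], config)
  expr_a <- expr_v <- auc_a <- auc_v <- numeric(n)
  expr_a[is_neuron] <- cha$expression
  auc_a[is_neuron] <- cha$auc
  expr_v[is_neuron] <- chv$expression
  auc_v[is_neuron] <- chv$auc
  kcl_resp <- is_neuron
  kcl_amp <- numeric(n)
  kcl_amp[is_neuron] <- stats::rlnorm(nn, cam$kcl_meanlog, cam$kcl_sdlog)
  baseline <- stats::rnorm(n, cam$baseline_mean, cam$baseline_sd)
  autofluor <- stats::rnorm(n, cam$autofluor_mean, cam$autofluor_sd)
  f385 <- pmax(stats::rnorm(n, cam$f385_mean, cam$f385_sd), cam$f385_min)

  truth <- data.frame(
    cell_id = seq_len(n), is_neuron = is_neuron,
    expression_trpa1 = expr_a, expression_trpv1 = expr_v,
    true_auc_aitc = auc_a, true_auc_caps = auc_v,
    category_trpa1 = cat_a, category_trpv1 = cat_v,
    kcl_responsive = kcl_resp, kcl_amplitude = kcl_amp,
    baseline_ratio = baseline, autofluorescence = autofluor,
    x = pos$x, y = pos$y,
    x_confocal = conf_pos[, 1], y_confocal = conf_pos[, 2],
    stringsAsFactors = FALSE)

  # --- traces --------------------------------------------------------
  sched <- config$schedule
  t_end <- max(sched$start_s + pmax(sched$duration_s, 60)) + 30
  times <- seq(0, t_end, by = 1 / config$frame_rate)
  nt <- length(times)
  # vectorized equivalent of render_trace() over all cells: one kernel per
  # application, amplitudes calibrated per cell exactly as in render_trace
  tr_mat <- matrix(baseline, nrow = n, ncol = nt)
  for (j in seq_len(nrow(sched))) {
    w <- sched[j, ]
    k <- response_kernel(times, w$start_s, w$duration_s)
    amp <- if (w$agonist == "KCl") {
      kcl_amp * as.numeric(kcl_resp)
    } else {
      target <- switch(tolower(w$agonist), aitc = auc_a, capsaicin = auc_v,
                       numeric(n))
      target / trapz_window(times, k, w$start_s, 60)
    }
    tr_mat <- tr_mat + amp %o% k
  }
  if (config$noise_sd > 0)
    tr_mat <- tr_mat + matrix(stats::rnorm(n * nt, 0, config$noise_sd), n, nt)
  traces <- data.frame(
    cell_id = rep(seq_len(n), each = nt),
    time_s = rep(times, times = n),
    ratio = as.numeric(t(tr_mat)))

  # --- ROI labels ----------------------------------------------------
  labels <- matrix(0L, H, W)
  cell_px <- vector("list", n)
  for (i in seq_len(n)) {
    px <- disk_pixels(pos$x[i], pos$y[i], cam$roi_radius, H, W)
    labels[px] <- i
    cell_px[[i]] <- disk_pixels(pos$x[i], pos$y[i], cam$cell_radius, H, W)
  }

  # --- negative controls & landmarks ---------------------------------
  negative_controls <- stats::rnorm(config$n_controls, cam$autofluor_mean,
                                    cam$autofluor_sd) +
    stats::rnorm(config$n_controls, 0, 0.1)
  anchors <- rbind(
    c(0.2, 0.2), c(0.8, 0.2), c(0.2, 0.8), c(0.8, 0.8),
    c(0.5, 0.2), c(0.5, 0.8), c(0.2, 0.5), c(0.8, 0.5))
  lm_idx <- unique(vapply(seq_len(min(cam$n_landmarks, nrow(anchors))),
    function(k) which.min((pos$x - anchors[k, 1] * W)^2 +
                          (pos$y - anchors[k, 2] * H)^2), 0L))
  jit <- function(m) m + stats::rnorm(length(m), 0, cam$landmark_jitter)
  landmarks <- data.frame(
    x_fixed = jit(pos$x[lm_idx]), y_fixed = jit(pos$y[lm_idx]),
    x_moving = jit(conf_pos[lm_idx, 1]), y_moving = jit(conf_pos[lm_idx, 2]))

  ds <- structure(
    list(config = config, truth = truth, traces = traces,
         roi_labels = labels, negative_controls = negative_controls,
         landmarks = landmarks, transform = true_tf,
         widefield = NULL, confocal = NULL, measurements = NULL),
    class = "furascope_dataset")

  if (!render_images) {
    meas <- function(expr) autofluor + expr + stats::rnorm(n, 0, 0.08)
    ds$measurements <- rbind(
      data.frame(cell_id = seq_len(n), channel = "TRPA1",
                 mean_intensity = meas(expr_a), stringsAsFactors = FALSE),
      data.frame(cell_id = seq_len(n), channel = "TRPV1",
                 mean_intensity = meas(expr_v), stringsAsFactors = FALSE))
    return(ds)
  }

  # --- wide-field movie ----------------------------------------------
  npix <- H * W
  all_px <- unlist(cell_px)
  cell_of_px <- rep(seq_len(n), vapply(cell_px, length, 0L))
  lam385 <- f385[cell_of_px]
  sig385 <- lam385 - cam$bg385
  ch340 <- array(0L, dim = c(H, W, nt))   # integer counts: half the memory
  ch385 <- array(0L, dim = c(H, W, nt))
  for (t in seq_len(nt)) {
    f385_t <- cam$bg385 + stats::rnorm(npix, 0, cam$read_sd_wf)
    f340_t <- cam$bg340 + stats::rnorm(npix, 0, cam$read_sd_wf)
    f385_t[all_px] <- stats::rpois(length(all_px), lam385) +
      stats::rnorm(length(all_px), 0, cam$read_sd_wf)
    lam340 <- cam$bg340 + tr_mat[cell_of_px, t] * sig385
    f340_t[all_px] <- stats::rpois(length(all_px), pmax(lam340, 0)) +
      stats::rnorm(length(all_px), 0, cam$read_sd_wf)
    ch385[, , t] <- as.integer(round(f385_t))  # counts stay inside [0, 65535]
    ch340[, , t] <- as.integer(round(f340_t))
  }
  wf_trans <- matrix(100 + stats::rnorm(npix, 0, 2), H, W)
  wf_trans[all_px] <- wf_trans[all_px] + f385[cell_of_px] / 20
  wf_trans <- pmax(round(wf_trans), 0)

  # --- confocal stacks ------------------------------------------------
  conf_px <- vector("list", n)
  for (i in seq_len(n))
    conf_px[[i]] <- disk_pixels(conf_pos[i, 1], conf_pos[i, 2],
                                cam$cell_radius, H, W)
  c_all <- unlist(conf_px)
  c_cell <- rep(seq_len(n), vapply(conf_px, length, 0L))
  zw <- stats::dnorm(seq_len(cam$n_planes),
                     mean = (cam$n_planes + 1) / 2, sd = cam$n_planes / 4)
  zw <- zw / mean(zw)   # average projection recovers the per-cell signal
  render_channel <- function(per_cell) {
    stack <- array(0, dim = c(H, W, cam$n_planes))
    lev <- per_cell[c_cell]
    for (k in seq_len(cam$n_planes)) {
      pl <- cam$conf_bg + stats::rnorm(npix, 0, cam$conf_read_sd)
      lam <- pmax(lev * zw[k], 0)
      pl[c_all] <- pl[c_all] + stats::rpois(length(c_all), lam)
      stack[, , k] <- pmax(round(pl), 0)
    }
    stack
  }
  conf_trpa1 <- render_channel(autofluor + expr_a)
  conf_trpv1 <- render_channel(autofluor + expr_v)
  dapi <- render_channel(rep(80, n))
  conf_trans <- matrix(100 + stats::rnorm(npix, 0, 2), H, W)
  conf_trans[c_all] <- conf_trans[c_all] + f385[c_cell] / 20
  conf_trans <- pmax(round(conf_trans), 0)

  ds$widefield <- list(ch340 = ch340, ch385 = ch385, transmission = wf_trans)
  ds$confocal <- list(TRPA1 = conf_trpa1, TRPV1 = conf_trpv1, DAPI = dapi,
                      transmission = conf_trans)
  ds
}

#' Render a sparse field of diffraction-limited puncta
#'
#' Synthesizes a neurite-style maximum-projection image containing
#' isolated Gaussian spots (single mRNA molecules) on a noisy background,
#' with known ground-truth positions; used to validate the puncta
#' detector.
#'
#' @param n_spots Number of spots.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param sigma Spot Gaussian SD in pixels.
#' @param amplitude Peak amplitude above background.
#' @param noise_sd Gaussian background noise SD.
#' @param min_separation Minimum center-to-center spacing.
#' @param seed Seed.
#' @return List with `image` and `spots` (data.frame `x`, `y`, 0-based).
#' @export
render_puncta_field <- function(n_spots = 20, dim = c(128, 128), sigma = 1.5,
                                amplitude = 50, noise_sd = 5,
                                min_separation = 8, seed = 1) {
  set.seed(seed)
  H <- dim[1]; W <- dim[2]
  xs <- ys <- numeric(0)
  guard <- 0
  while (length(xs) < n_spots && guard < 10000) {
    guard <- guard + 1
    x <- stats::runif(1, 6, W - 7); y <- stats::runif(1, 6, H - 7)
    if (length(xs) == 0 ||
        min((xs - x)^2 + (ys - y)^2) >= min_separation^2) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  img <- matrix(stats::rnorm(H * W, 0, noise_sd), H, W)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  for (i in seq_along(xs)) {
    img <- img + matrix(
      amplitude * exp(-((gx - xs[i])^2 + (gy - ys[i])^2) / (2 * sigma^2)),
      H, W)
  }
  list(image = img, spots = data.frame(x = xs, y = ys))
}
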