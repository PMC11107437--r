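test_that("invalid configurations are rejected with the field name", {
  expect_error(synth_config(fraction_neurons = 1.2), "fraction_neurons")
  expect_error(synth_config(fraction_expressing = -0.1),
               "fraction_expressing")
  expect_error(synth_config(true_correlation = 1.5), "true_correlation")
  expect_error(synth_config(n_cells = 0), "n_cells")
  expect_error(synth_config(frame_rate = 0), "frame_rate")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(synth_config(transform = list(rotation_deg = 0)),
               "transform")
  expect_error(synth_config(fraction_expressing = 0.2,
                            rate_rnascope_only = 0.5),
               "rate_rnascope_only")
})

test_that("identical configs generate bit-identical datasets", {
  cfg <- synth_config(n_cells = 12, seed = 77)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$widefield$ch340, b$widefield$ch340)
  expect_identical(a$widefield$ch385, b$widefield$ch385)
  expect_identical(a$confocal$TRPA1, b$confocal$TRPA1)
  expect_identical(a$roi_labels, b$roi_labels)
  expect_identical(a$truth, b$truth)
  expect_identical(a$negative_controls, b$negative_controls)
  # a different seed changes the pixels
  c <- generate_dataset(synth_config(n_cells = 12, seed = 78))
  expect_false(identical(a$widefield$ch340, c$widefield$ch340))
})

test_that("noiseless perfect correlation is realized exactly", {
  cfg <- synth_config(n_cells = 200, true_correlation = 1, noise_sd = 0,
                      seed = 81)
  ds <- generate_dataset(cfg, render_images = FALSE)
  tr <- ds$truth
  b <- tr$category_trpa1 == "both"   # expressing responders
  r <- cor(log(tr$expression_trpa1[b]), tr$true_auc_aitc[b])
  expect_lt(abs(r - 1), 1e-9)
})

test_that("the sample correlation of the latent pair is enforced exactly", {
  for (rho in c(-0.5, 0, 0.43, 0.9)) {
    cfg <- synth_config(n_cells = 300, true_correlation = rho, seed = 82)
    ds <- generate_dataset(cfg, render_images = FALSE)
    tr <- ds$truth
    b <- tr$category_trpa1 == "both"
    expect_lt(abs(cor(log(tr$expression_trpa1[b]), tr$true_auc_aitc[b]) -
                    rho), 1e-9)
  }
})

test_that("fraction_expressing = 0 yields zero expression everywhere", {
  cfg <- synth_config(n_cells = 50, fraction_expressing = 0, seed = 83)
  ds <- generate_dataset(cfg, render_images = FALSE)
  expect_true(all(ds$truth$expression_trpa1 == 0))
  expect_true(all(ds$truth$expression_trpv1 == 0))
  expect_equal(sum(ds$truth$expression_trpa1 > 0), 0)
})

test_that("rendered traces integrate back to the true AUC", {
  sched <- default_schedule()
  cell <- list(true_auc_aitc = 30, true_auc_caps = 0,
               kcl_responsive = TRUE, kcl_amplitude = 1,
               baseline_ratio = 0.8)
  tr <- render_trace(cell, sched, noise_sd = 0)
  w <- sched[sched$agonist == "AITC", ]
  b <- compute_baseline(tr, w)
  expect_lt(abs(compute_auc(tr, w, b) - 30), 0.5)
  # zero target: AUC stays within the noise-induced band
  cell0 <- cell; cell0$true_auc_aitc <- 0
  tr0 <- render_trace(cell0, sched, noise_sd = 0.02, seed = 4)
  b0 <- compute_baseline(tr0, w)
  expect_lt(abs(compute_auc(tr0, w, b0)), 2 * 0.6)  # ~2x AUC noise SD
  # overlapping applications are rejected
  bad <- sched; bad$start_s <- c(60, 100, 420)
  expect_error(render_trace(cell, bad), "overlap")
})

test_that("non-responsive cells show no KCl response above the noise", {
  sched <- default_schedule()
  kw <- sched[sched$agonist == "KCl", ]
  viol <- 0
  for (s in 1:100) {
    cell <- list(true_auc_aitc = 25, true_auc_caps = 25,
                 kcl_responsive = FALSE, baseline_ratio = 0.8)
    tr <- render_trace(cell, sched, noise_sd = 0.02, seed = 200 + s)
    b <- compute_baseline(tr, kw)
    sel <- tr$time_s >= kw$start_s & tr$time_s <= kw$start_s + kw$duration_s + 10
    if (max(tr$ratio[sel] - b) > 3 * 0.02) viol <- viol + 1
  }
  # peak of ~26 Gaussian samples exceeds 3 SD only rarely
  expect_lte(viol, 10)
})

test_that("noiseless pipeline AUC is calibrated to the ground truth", {
  # 200 replicate cells, noise_sd = 0: mean recovered AUC within 1%
  sched <- default_schedule()
  set.seed(85)
  ratio_err <- numeric(0)
  for (agonist in c("AITC", "capsaicin")) {
    w <- sched[sched$agonist == agonist, ]
    for (rep in 1:100) {
      auc_true <- runif(1, 5, 60)
      cell <- list(true_auc_aitc = if (agonist == "AITC") auc_true else 20,
                   true_auc_caps = if (agonist == "AITC") 20 else auc_true,
                   kcl_responsive = TRUE, kcl_amplitude = 1,
                   baseline_ratio = 0.8)
      tr <- render_trace(cell, sched, noise_sd = 0)
      b <- compute_baseline(tr, w)
      ratio_err <- c(ratio_err, compute_auc(tr, w, b) / auc_true)
    }
  }
  expect_lt(abs(mean(ratio_err) - 1), 0.01)
  expect_lt(max(abs(ratio_err - 1)), 0.02)
})

test_that("confocal signal encodes expression and the frame displacement", {
  cfg <- synth_config(n_cells = 40, seed = 86)
  ds <- generate_dataset(cfg)
  # average projection of the TRPA1 stack at the mapped ROIs recovers a
  # signal proportional to expression
  m <- map_rois(ds$roi_labels, ds$transform, dim(ds$confocal$TRPA1)[1:2])
  proj <- project_stack(ds$confocal$TRPA1, "average")
  sig <- cell_signals(proj, m$labels, "TRPA1")
  mm <- merge(sig, ds$truth, by = "cell_id")
  expect_gt(cor(mm$mean_intensity, mm$expression_trpa1 + mm$autofluorescence),
            0.99)
  # the confocal frame really is displaced: identity mapping misplaces ROIs
  m_id <- map_rois(ds$roi_labels, similarity_transform(),
                   dim(ds$confocal$TRPA1)[1:2])
  sig_id <- cell_signals(proj, m_id$labels, "TRPA1")
  mm_id <- merge(sig_id, ds$truth, by = "cell_id")
  expect_lt(cor(mm_id$mean_intensity,
                mm_id$expression_trpa1 + mm_id$autofluorescence),
            cor(mm$mean_intensity, mm$expression_trpa1 + mm$autofluorescence))
})

test_that("datasets round-trip through the on-disk TIFF/CSV layout", {
  cfg <- synth_config(n_cells = 8, seed = 87)
  ds <- generate_dataset(cfg)
  dir <- tempfile("ds")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$widefield$ch340, ds$widefield$ch340 + 0)
  expect_identical(back$confocal$TRPA1, ds$confocal$TRPA1)
  expect_equal(back$roi_labels, ds$roi_labels, ignore_attr = TRUE)
  expect_equal(back$negative_controls, ds$negative_controls,
               tolerance = 1e-6)
  expect_equal(back$transform, ds$transform, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(back$config$schedule, ds$config$schedule)
  unlink(dir, recursive = TRUE)
})
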