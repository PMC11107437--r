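test_that("compute_ratio subtracts background and flags invalid pixels", {
  f340 <- matrix(200, 2, 2); f385 <- matrix(100, 2, 2)
  expect_equal(compute_ratio(f340, f385)[1, 1], 2.0)
  expect_equal(compute_ratio(f340, f385, 50, 50)[1, 1], 3.0)
  # denominator <= 0 is invalid
  f385[1, 2] <- 40
  r <- compute_ratio(f340, f385, 50, 50)
  expect_true(is.na(r[1, 2]))
  expect_error(compute_ratio(f340, matrix(1, 3, 3)), "identical dimensions")
  expect_error(compute_ratio(f340, f385, -1, 0), ">= 0")
})

test_that("compute_ratio matches the scalar loop oracle on random frames", {
  set.seed(11)
  for (rep in 1:20) {
    f340 <- matrix(runif(64, 0, 400), 8, 8)
    f385 <- matrix(runif(64, 0, 400), 8, 8)
    r <- compute_ratio(f340, f385, 30, 60)
    expect_equal(r, oracle_ratio(f340, f385, 30, 60), tolerance = 1e-12)
  }
})

test_that("extract_trace averages valid ROI pixels per frame", {
  labels <- matrix(0L, 4, 4); labels[2:3, 2:3] <- 1L
  mov <- array(1.5, dim = c(4, 4, 6))
  tr <- extract_trace(mov, labels, 1)
  expect_equal(tr$ratio, rep(1.5, 6))
  expect_equal(attr(tr, "roi_area"), 4L)
  # two-pixel ROI mean
  labels2 <- matrix(0L, 4, 4); labels2[1, 1:2] <- 2L
  mov2 <- array(0, dim = c(4, 4, 2))
  mov2[1, 1, ] <- 1.0; mov2[1, 2, ] <- 3.0
  expect_equal(extract_trace(mov2, labels2, 2, min_area = 2)$ratio,
               c(2.0, 2.0))
  expect_error(extract_trace(mov, labels, 99), "not present")
  expect_error(extract_trace(mov2, labels2, 2, min_area = 5), "below the minimum")
})

test_that("baseline is the mean over [start-8, start-3) with 5 samples", {
  tr <- make_trace(rep(1.2, 200))
  w <- list(start_s = 100)
  expect_equal(compute_baseline(tr, w), 1.2)
  tr2 <- make_trace(rep(0, 200))
  tr2$ratio[tr2$time_s %in% 92:96] <- c(1, 1, 1, 2, 2)
  expect_equal(compute_baseline(tr2, w), 1.4)
  # sample at start-3 is excluded from the window
  tr3 <- tr2; tr3$ratio[tr3$time_s == 97] <- 100
  expect_equal(compute_baseline(tr3, w), 1.4)
  expect_error(compute_baseline(make_trace(rep(1, 50)), list(start_s = 4)),
               "insufficient baseline")
})

test_that("AUC is the baseline-corrected trapezoid over 60 s", {
  w <- list(start_s = 20)
  tr <- make_trace(rep(0.8, 120))
  expect_equal(compute_auc(tr, w, 0.8), 0.0)
  tr2 <- tr; tr2$ratio[tr2$time_s >= 20 & tr2$time_s <= 80] <- 1.8
  expect_equal(compute_auc(tr2, w, 0.8), 60.0)
  expect_error(compute_auc(make_trace(rep(1, 50)), w, 1), "recording ends")
  # negative responses are retained, not clipped
  tr3 <- tr; tr3$ratio[tr3$time_s >= 20 & tr3$time_s <= 80] <- 0.3
  expect_equal(compute_auc(tr3, w, 0.8), -30.0)
})

test_that("AUC matches an independent per-sample trapezoid oracle", {
  skip_if_not_installed("pracma")
  set.seed(7)
  w <- list(start_s = 5)
  for (rep in 1:100) {
    y <- runif(71, 0.5, 3)
    tr <- make_trace(y)
    b <- runif(1, 0.5, 1.5)
    got <- compute_auc(tr, w, b)
    sel <- tr$time_s >= 5 & tr$time_s <= 65
    expect_lt(abs(got - oracle_trapz(tr$time_s[sel], y[sel] - b)), 1e-10)
    expect_lt(abs(got - pracma::trapz(tr$time_s[sel], y[sel] - b)), 1e-10)
  }
})

test_that("AUC linearity and baseline shift invariance hold", {
  set.seed(8)
  w <- list(start_s = 10)
  for (rep in 1:20) {
    y <- runif(80, 0.5, 3)
    tr <- make_trace(y)
    b <- compute_baseline(tr, w)
    a0 <- compute_auc(tr, w, b)
    alpha <- runif(1, 0.2, 4)
    tr_scaled <- make_trace(alpha * (y - b) + b)
    expect_equal(compute_auc(tr_scaled, w, b), alpha * a0,
                 tolerance = 1e-9)
    cshift <- runif(1, -0.3, 0.9)
    tr_shift <- make_trace(y + cshift)
    b2 <- compute_baseline(tr_shift, w)
    expect_equal(b2, b + cshift, tolerance = 1e-12)
    expect_lt(abs(compute_auc(tr_shift, w, b2) - a0), 1e-9)
  }
})

test_that("KCl gate requires a peak delta-ratio above min_delta", {
  kw <- list(start_s = 60, duration_s = 15)
  flat <- make_trace(rep(0.8, 120))
  expect_false(kcl_gate(flat, kw))
  resp <- flat
  resp$ratio[resp$time_s >= 60 & resp$time_s <= 70] <- 1.6
  expect_true(kcl_gate(resp, kw))
  # degenerate threshold: everything passes
  expect_true(kcl_gate(flat, kw, min_delta = 0))
  expect_error(kcl_gate(flat, list(start_s = 500, duration_s = 15)),
               "outside the recording")
})

test_that("KCl gate recovers ground-truth viability on synthetic data", {
  cfg <- synth_config(n_cells = 400, seed = 21)
  ds <- generate_dataset(cfg, render_images = FALSE)
  sc <- score_cells(ds$traces, cfg$schedule)
  one <- sc[sc$agonist == "AITC", ]
  m <- merge(one, ds$truth[, c("cell_id", "kcl_responsive")], by = "cell_id")
  # responsive neurons essentially always pass at default noise
  expect_gte(mean(m$kcl_pass[m$kcl_responsive]), 0.99)
  # non-neurons never pass (no depolarization response)
  expect_lte(mean(m$kcl_pass[!m$kcl_responsive]), 0.01)
})

test_that("traces extracted from a rendered movie match the generator traces", {
  cfg <- synth_config(n_cells = 5, seed = 31)
  ds <- generate_dataset(cfg)
  tr <- extract_traces(ds$widefield$ch340, ds$widefield$ch385,
                       ds$roi_labels)
  m <- merge(tr, ds$traces, by = c("cell_id", "time_s"),
             suffixes = c("_movie", "_truth"))
  expect_equal(nrow(m), nrow(ds$traces))
  # residual photon/read noise after ROI averaging is small
  expect_lt(max(abs(m$ratio_movie - m$ratio_truth)), 0.06)
  expect_lt(sd(m$ratio_movie - m$ratio_truth), 0.01)
})

test_that("schedules are validated", {
  s <- default_schedule()
  expect_equal(s$agonist, c("AITC", "capsaicin", "KCl"))
  expect_equal(s$duration_s, c(60, 30, 15))
  bad <- s; bad$start_s <- c(60, 100, 420)  # capsaicin starts during AITC
  expect_error(validate_schedule(bad), "overlap")
  bad2 <- s; bad2$duration_s[1] <- 0
  expect_error(validate_schedule(bad2), "duration")
})
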