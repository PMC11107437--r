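test_that("non-responder threshold fit is consistent for mu + 2*sigma", {
  # pure Gaussian, no responders
  set.seed(17)
  x <- rnorm(10000)
  m <- fit_nonresponder_threshold(x)
  expect_lt(abs(m$threshold - 2.0), 0.1)
  expect_true(m$converged)
  # planted responder population is trimmed out
  set.seed(18)
  x2 <- c(rnorm(9000), rnorm(1000) + 20)
  m2 <- fit_nonresponder_threshold(x2)
  expect_lt(abs(m2$threshold - 2.0), 0.3)
  # identical values: sd 0, threshold = value
  m3 <- fit_nonresponder_threshold(rep(5, 20))
  expect_equal(m3$mean, 5); expect_equal(m3$sd, 0)
  expect_equal(m3$threshold, 5)
  expect_error(fit_nonresponder_threshold(rnorm(5)), "at least 10")
})

test_that("threshold fit is location/scale equivariant and tail-calibrated", {
  set.seed(19)
  base <- rnorm(10000)
  for (p in list(c(3, 2), c(-10, 0.5), c(100, 25))) {
    x <- p[1] + p[2] * base
    m <- fit_nonresponder_threshold(x)
    expect_lt(abs(m$threshold - (p[1] + 2 * p[2])), 0.1 * p[2])
    fpr <- mean(x > m$threshold)          # one-sided 2 SD tail
    expect_lt(abs(fpr - 0.023), 0.01)
  }
})

test_that("classification applies strict thresholds and the KCl gate", {
  th <- fixed_thresholds()
  # boundary: exactly at threshold is negative
  rec <- data.frame(cell_id = 1:2, auc = c(10, 10.0001),
                    rnascope_intensity = c(5, 5), kcl_pass = TRUE)
  cl <- classify_cells(rec, th$functional, th$rnascope)
  expect_equal(cl$records$functional_positive, c(FALSE, TRUE))
  expect_equal(cl$records$rnascope_positive, c(FALSE, FALSE))
  # toy table spanning all four quadrants
  toy <- rbind(
    data.frame(cell_id = 1, auc = 20, rnascope_intensity = 8, kcl_pass = TRUE),
    data.frame(cell_id = 2:3, auc = 3, rnascope_intensity = 8, kcl_pass = TRUE),
    data.frame(cell_id = 4, auc = 15, rnascope_intensity = 2, kcl_pass = TRUE),
    data.frame(cell_id = 5:6, auc = 1, rnascope_intensity = 1, kcl_pass = TRUE))
  cl2 <- classify_cells(toy, th$functional, th$rnascope)
  expect_equal(unlist(cl2$counts[c("both", "rnascope_only",
                                   "functional_only", "neither")]),
               c(both = 1L, rnascope_only = 2L, functional_only = 1L,
                 neither = 2L))
  expect_equal(cl2$counts$total, 6L)
  # gated-only: cells failing KCl are excluded and counts still sum
  toy$kcl_pass[5] <- FALSE
  cl3 <- classify_cells(toy, th$functional, th$rnascope)
  expect_equal(cl3$counts$total, 5L)
  expect_equal(sum(unlist(cl3$counts[c("both", "rnascope_only",
                                       "functional_only", "neither")])),
               cl3$counts$total)
  expect_error(classify_cells(transform(toy, auc = NA), th$functional,
                              th$rnascope), "missing measurement")
})

test_that("union selection implements either-positive with known sizes", {
  th <- fixed_thresholds()
  all_neg <- records_from_counts(0, 0, 0, 10)
  cl <- classify_cells(all_neg, th$functional, th$rnascope)
  expect_equal(nrow(select_union(cl$records)), 0)
  for (counts in list(c(98, 309, 95, 388), c(323, 488, 22, 57))) {
    rec <- records_from_counts(counts[1], counts[2], counts[3], counts[4])
    cl <- classify_cells(rec, th$functional, th$rnascope)
    expect_equal(nrow(select_union(cl$records)),
                 counts[1] + counts[2] + counts[3])
  }
  expect_error(select_union(data.frame(cell_id = 1)), "classified first")
})

test_that("raising either threshold never grows the union", {
  set.seed(20)
  rec <- data.frame(cell_id = 1:500, auc = rnorm(500, 5, 5),
                    rnascope_intensity = rlnorm(500, 1, 1), kcl_pass = TRUE)
  sizes <- sapply(seq(0, 15, by = 1), function(thr) {
    cl <- classify_cells(rec, list(threshold = thr), list(threshold = 2))
    nrow(select_union(cl$records))
  })
  expect_true(all(diff(sizes) <= 0))
  sizes2 <- sapply(seq(0, 15, by = 1), function(thr) {
    cl <- classify_cells(rec, list(threshold = 5), list(threshold = thr))
    nrow(select_union(cl$records))
  })
  expect_true(all(diff(sizes2) <= 0))
})

test_that("configured discordance rates are reproduced by the pipeline", {
  # rates mimicking the reported TRPA1 category proportions
  target <- c(both = 98, rnascope_only = 309, functional_only = 95,
              neither = 388) / 890
  fr <- matrix(0, 20, 4)
  for (s in 1:20) {
    cfg <- synth_config(
      n_cells = 300, fraction_expressing = unname(target[1] + target[2]),
      rate_rnascope_only = unname(target[2]),
      rate_functional_only = unname(target[3]),
      true_correlation = 0.43, seed = 600 + s)
    ds <- generate_dataset(cfg, render_images = FALSE)
    rep <- analyze_dataset(ds)
    cts <- rep$channels$TRPA1$counts
    fr[s, ] <- unlist(cts[c("both", "rnascope_only", "functional_only",
                            "neither")]) / cts$total
  }
  expect_true(all(abs(colMeans(fr) - target) <= 0.03))
})
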