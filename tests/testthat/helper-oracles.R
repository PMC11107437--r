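# Independent scalar-loop oracles used to cross-check the vectorized
# implementations, plus small fixture builders.

# per-pixel ratio oracle
oracle_ratio <- function(f340, f385, bg340, bg385) {
  out <- matrix(NA_real_, nrow(f340), ncol(f340))
  for (i in seq_len(nrow(f340))) for (j in seq_len(ncol(f340))) {
    den <- f385[i, j] - bg385
    if (den > 0) out[i, j] <- (f340[i, j] - bg340) / den
  }
  out
}

# per-sample trapezoid oracle
oracle_trapz <- function(t, y) {
  s <- 0
  for (k in seq_len(length(t) - 1))
    s <- s + (t[k + 1] - t[k]) * (y[k] + y[k + 1]) / 2
  s
}

# per-pixel projection oracle
oracle_project <- function(stack, mode) {
  d <- dim(stack)
  out <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    v <- stack[i, j, ]
    out[i, j] <- if (mode == "average") mean(v) else max(v)
  }
  out
}

# covariance / SD Pearson oracle
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sd(x) * sd(y))
}

# flat synthetic trace fixture
make_trace <- function(values, times = seq_along(values) - 1) {
  data.frame(time_s = times, ratio = values)
}

# classified record builder: n rows at fixed (auc, intensity)
make_records <- function(n, auc, intensity, id_start = 1) {
  if (n == 0) return(NULL)
  data.frame(cell_id = seq_len(n) + id_start - 1, auc = auc,
             rnascope_intensity = intensity, kcl_pass = TRUE)
}

# records table realizing given category counts under thresholds (10, 5)
records_from_counts <- function(both, rnascope_only, functional_only,
                                neither) {
  rec <- rbind(make_records(both, 20, 20),
               make_records(rnascope_only, 1, 20, id_start = both + 1),
               make_records(functional_only, 20, 1,
                            id_start = both + rnascope_only + 1),
               make_records(neither, 1, 1,
                            id_start = both + rnascope_only +
                              functional_only + 1))
  rec
}

fixed_thresholds <- function() {
  list(functional = list(threshold = 10),
       rnascope = list(threshold = 5))
}

# textured cell-field image for registration tests
make_cell_field <- function(H = 160, W = 160, n_blobs = 60, seed = 42) {
  set.seed(seed)
  img <- matrix(rnorm(H * W, 0, 2), H, W)
  nx <- rep(0:(W - 1), each = H); ny <- rep(0:(H - 1), times = W)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 15, W - 16); cy <- runif(1, 15, H - 16)
    a <- runif(1, 10, 40)
    img <- img + matrix(a * exp(-((nx - cx)^2 + (ny - cy)^2) / 18), H, W)
  }
  img
}
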