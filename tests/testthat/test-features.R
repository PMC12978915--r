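# Welch PSD and the 10-metric feature bank.

test_that("welch_psd matches the reference implementation and Parseval", {
  # frozen from scipy.signal.welch(x, fs=1000, window='blackman',
  # nperseg=128, noverlap=64, detrend='constant', scaling='density')
  fs <- 1000
  n <- 4096L
  t <- (seq_len(n) - 1L) / fs
  x <- sin(2 * pi * 50 * t) + 0.5 * sin(2 * pi * 120 * t) +
    0.25 * cos(2 * pi * 211.3 * t)
  p <- welch_psd(x, fs, psd_params())
  idx <- c(0L, 5L, 6L, 7L, 15L, 16L, 27L, 40L, 64L) + 1L
  f_ref <- c(0, 39.0625, 46.875, 54.6875, 117.1875, 125, 210.9375,
             312.5, 500)
  p_ref <- c(8.752269368976068e-05, 0.004512093064820802,
             0.0315370315955894, 0.025712905116107115,
             0.008130984185991692, 0.006108278607731673,
             0.0023114796567452454, 1.2505326217637142e-12,
             1.0346535355243546e-14)
  expect_equal(p$freqs_hz[idx], f_ref, tolerance = 1e-12)
  expect_equal(p$power[idx], p_ref, tolerance = 1e-8)

  # all-zero signal -> all-zero power
  expect_equal(welch_psd(rep(0, 1000L), fs, psd_params())$power,
               rep(0, 65L))

  # unit-variance white noise, 60 s: integrated PSD = 1 within 10%
  set.seed(31)
  w <- rnorm(60 * fs)
  pw <- welch_psd(w, fs, psd_params())
  df <- pw$freqs_hz[2L] - pw$freqs_hz[1L]
  expect_equal(sum(pw$power) * df, 1, tolerance = 0.10)

  # sinusoid at an exact bin: >= 90% of power within that bin +/- 1
  f0 <- 10 * fs / 128                     # an exact Welch bin
  ps <- welch_psd(sin(2 * pi * f0 * t), fs, psd_params())
  k <- which.min(abs(ps$freqs_hz - f0))
  expect_gte(sum(ps$power[(k - 1):(k + 1)]) / sum(ps$power), 0.90)

  expect_error(welch_psd(rnorm(100L), fs, psd_params()), "nperseg")
})

test_that("time-domain metrics match closed forms and a naive loop oracle", {
  fs <- 512
  pre <- preprocess_params(env_window_s = 16 / 512)  # small window
  # alternating +1/-1, length N
  N <- 1000L
  alt <- rep(c(1, -1), length.out = N)
  dur <- N / fs
  td <- time_domain_features(alt, fs, pre)
  expect_equal(unname(td["ZC"]), (N - 1) / dur)
  expect_equal(unname(td["SSC"]), (N - 2) / dur)
  expect_equal(unname(td["WFL"]), 2 * (N - 1))
  expect_equal(unname(td["meanRMS"]), 1)      # |x| = 1 everywhere
  expect_equal(unname(td["stdRMS"]), 0)
  # monotone ramp 0 -> 1
  ramp <- seq(0, 1, length.out = N)
  td2 <- time_domain_features(ramp, fs, pre)
  expect_equal(unname(td2["ZC"]), 0)
  expect_equal(unname(td2["SSC"]), 0)
  expect_equal(unname(td2["WFL"]), 1)
  # random integer-valued signal vs naive one-pass loop oracle, bit-exact
  set.seed(32)
  x <- as.numeric(sample(-5:5, 1000L, replace = TRUE))
  td3 <- time_domain_features(x, fs, pre)
  zc <- 0L; ssc <- 0L; wfl <- 0
  for (i in seq_len(999L)) {
    if (x[i] * x[i + 1L] < 0) zc <- zc + 1L
    wfl <- wfl + abs(x[i + 1L] - x[i])
  }
  for (i in 2:999) {
    if ((x[i] - x[i - 1L]) * (x[i] - x[i + 1L]) > 0) ssc <- ssc + 1L
  }
  w <- 16L; hop <- 8L
  nwin <- floor((1000L - w) / hop) + 1L
  env <- vapply(seq_len(nwin), function(i) {
    sqrt(mean(x[seq.int((i - 1L) * hop + 1L, (i - 1L) * hop + w)]^2))
  }, numeric(1))
  expect_identical(unname(td3["ZC"]), zc / (1000 / fs))
  expect_identical(unname(td3["SSC"]), ssc / (1000 / fs))
  expect_identical(unname(td3["WFL"]), wfl)
  expect_equal(unname(td3["meanRMS"]), mean(env), tolerance = 1e-14)
  expect_equal(unname(td3["stdRMS"]), sd(env), tolerance = 1e-14)
  expect_error(time_domain_features(c(1, 2), fs, pre), "3 samples")
})

make_psd <- function(freqs, power, params = psd_params()) {
  structure(list(freqs_hz = freqs, power = power, params = params),
            class = "emg_psd")
}

test_that("frequency-domain metrics match degenerate-spectrum oracles", {
  par <- psd_params()
  # single-bin spectrum at f0
  f <- seq(0, 500, by = 25)
  p <- numeric(length(f)); p[f == 150] <- 3
  fd <- freq_domain_features(make_psd(f, p), par)
  expect_equal(unname(fd["meanFreq"]), 150)
  expect_equal(unname(fd["medianFreq"]), 150)
  expect_equal(unname(fd["entropy"]), 0)
  expect_equal(unname(fd["SpecDef"]), 1)
  # flat in-band spectrum -> entropy = 1
  p2 <- as.numeric(f >= 20 & f <= 500)
  fd2 <- freq_domain_features(make_psd(f, p2), par)
  expect_equal(unname(fd2["entropy"]), 1)
  # two equal bins at f and 2f: SpecDef = sqrt(2.5)/1.5 (moment oracle)
  f3 <- c(100, 200)
  fd3 <- freq_domain_features(make_psd(f3, c(1, 1)), par)
  expect_equal(unname(fd3["meanFreq"]), 150)
  expect_equal(unname(fd3["SpecDef"]), sqrt(2.5) / 1.5, tolerance = 1e-12)
  expect_equal(unname(fd3["DP"]), 0.5)     # one of two bins >= 150 Hz
  # zero in-band power -> error
  expect_error(freq_domain_features(make_psd(f, numeric(length(f))), par),
               "silent segment")
})

test_that("frequency metrics are scale invariant; SpecDef >= 1 with equality only for lines", {
  par <- psd_params()
  set.seed(33)
  f <- seq(0, 500, by = 500 / 64)
  for (i in 1:200) {
    p <- rexp(length(f))
    fd1 <- freq_domain_features(make_psd(f, p), par)
    c0 <- runif(1, 1e-6, 1e6)
    fd2 <- freq_domain_features(make_psd(f, c0 * p), par)
    expect_equal(fd1, fd2, tolerance = 1e-12)
    expect_gte(unname(fd1["SpecDef"]), 1)
  }
  # equality only for single-bin spectra: random lines give exactly 1
  for (i in 1:20) {
    p <- numeric(length(f))
    p[sample(which(f >= 20), 1L)] <- rexp(1)
    expect_equal(unname(freq_domain_features(make_psd(f, p), par)["SpecDef"]),
                 1, tolerance = 1e-12)
  }
  # time-domain amplitude scaling: frequency metrics of a real signal
  set.seed(34)
  x <- rnorm(4096)
  a <- freq_domain_features(welch_psd(x, 1000, par), par)
  b <- freq_domain_features(welch_psd(7.3 * x, 1000, par), par)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("downward spectral shift decreases meanFreq, medianFreq and DP", {
  par <- psd_params()
  f <- seq(0, 500, by = 500 / 64)
  base <- exp(-(f - 120)^2 / (2 * 60^2))
  for (shift in c(20, 50, 100)) {
    lower <- exp(-(f - 120 + shift)^2 / (2 * 60^2))
    a <- freq_domain_features(make_psd(f, base), par)
    b <- freq_domain_features(make_psd(f, lower), par)
    expect_lt(b[["meanFreq"]], a[["meanFreq"]])
    expect_lt(b[["medianFreq"]], a[["medianFreq"]])
    expect_lt(b[["DP"]], a[["DP"]])
  }
  # medianFreq and meanFreq stay inside the in-band frequency range
  set.seed(35)
  for (i in 1:100) {
    p <- rexp(length(f))
    fd <- freq_domain_features(make_psd(f, p), par)
    inband <- f[f >= 20 & f <= 500]
    expect_gte(fd[["medianFreq"]], min(inband))
    expect_lte(fd[["medianFreq"]], max(inband))
    expect_gte(fd[["meanFreq"]], min(inband))
    expect_lte(fd[["meanFreq"]], max(inband))
  }
})

test_that("extract_features yields one row per (channel, segment) and agrees with single-signal calls", {
  pipe <- scaled_pipeline(41, null_map())
  feat <- pipe$features
  expect_equal(nrow(feat), 14L * 11L)
  expect_false(anyNA(feat[, metric_names <- c("meanRMS", "stdRMS", "SSC",
                                              "ZC", "WFL", "meanFreq",
                                              "medianFreq", "entropy",
                                              "DP", "SpecDef")]))
  # control stdRMS column = 1 for C2 and C3
  for (ref in c("C2", "C3")) {
    expect_equal(feat$stdRMS[feat$segment == ref], rep(1, 14L),
                 tolerance = 1e-12)
  }
  # batched implementation equals the public single-signal functions
  ses <- pipe$session
  for (pick in list(c("C2", 1L), c("F_LMLO", 7L), c("C_RCC", 14L))) {
    lab <- pick[[1]]; ci <- as.integer(pick[[2]])
    x <- ses$segments[[lab]]$samples[ci, ]
    td <- time_domain_features(x, ses$fs, scaled_pre())
    fd <- freq_domain_features(welch_psd(x, ses$fs, scaled_psd()),
                               scaled_psd())
    row <- feat[feat$segment == lab & feat$channel == ses$channel_order[ci], ]
    expect_equal(unlist(row[names(td)]), td, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unlist(row[names(fd)]), fd, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("doubling a muscle's gain strictly increases its compression meanRMS", {
  g <- stats::setNames(rep(1, 7), emg_muscles())
  g["deltoid"] <- 2
  f1 <- scaled_pipeline(42, activation_map(gain = g,
                                           spectral_mix = 0))$features
  g["deltoid"] <- 4
  f2 <- scaled_pipeline(42, activation_map(gain = g,
                                           spectral_mix = 0))$features
  pick <- function(f) f$meanRMS[f$channel == "deltoid_left" &
                                  f$segment == "F_LCC"]
  expect_gt(pick(f2), pick(f1))
})

test_that("sub-windowed mode averages per-window metrics", {
  pipe <- scaled_pipeline(43, null_map())
  ses <- pipe$session
  featw <- extract_features(ses, scaled_pre(), scaled_psd(),
                            subwindow_s = 1)
  expect_equal(nrow(featw), 14L * 11L)
  # oracle for one cell: mean of per-window metrics
  x <- ses$segments$C2$samples[1L, ]
  w <- as.integer(round(1 * ses$fs))
  vals <- sapply(seq_len(floor(length(x) / w)), function(i) {
    xi <- x[seq.int((i - 1L) * w + 1L, i * w)]
    c(time_domain_features(xi, ses$fs, scaled_pre()),
      freq_domain_features(welch_psd(xi, ses$fs, scaled_psd()),
                           scaled_psd()))
  })
  row <- featw[featw$segment == "C2" &
                 featw$channel == "sternocleidomastoid_left", ]
  expect_equal(unlist(row[rownames(vals)]), rowMeans(vals),
               tolerance = 1e-12, ignore_attr = TRUE)
})
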