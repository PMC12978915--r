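# Feature bank: Welch power spectral density and the ten time- and
# frequency-domain metrics computed per (channel, segment).

#' Welch PSD parameters
#'
#' @param nperseg Samples per Welch segment (default 128).
#' @param overlap Segment overlap fraction (default 0.5).
#' @param window Taper name; `"blackman"` (default) or `"hann"` or
#'   `"rectangular"`.
#' @param band_low_hz,band_high_hz Analysis band for the frequency-domain
#'   metrics (default 20-500 Hz, matching the filter band).
#' @param f_split_hz Split frequency for the high-frequency power
#'   fraction metric DP (default 150 Hz).
#' @return A list of class `psd_params`.
#' @export
psd_params <- function(nperseg = 128L, overlap = 0.5, window = "blackman",
                       band_low_hz = 20, band_high_hz = 500,
                       f_split_hz = 150) {
  stopifnot(nperseg >= 8, overlap >= 0, overlap < 1,
            band_low_hz < band_high_hz)
  window <- match.arg(window, c("blackman", "hann", "rectangular"))
  structure(list(nperseg = as.integer(nperseg), overlap = overlap,
                 window = window, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz, f_split_hz = f_split_hz),
            class = "psd_params")
}

# periodic (DFT-even) tapers, matching the usual spectral convention
taper_window <- function(name, m) {
  k <- seq_len(m) - 1L
  switch(name,
         blackman = 0.42 - 0.5 * cos(2 * pi * k / m) +
           0.08 * cos(4 * pi * k / m),
         hann = 0.5 - 0.5 * cos(2 * pi * k / m),
         rectangular = rep(1, m))
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over overlapping, tapered, mean-removed
#' segments; one-sided density scaling, so the integral of `power` over
#' frequency approximates the signal variance.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param params A [psd_params()].
#' @return A list of class `emg_psd` with `freqs_hz` (uniform grid
#'   `fs/nperseg`), `power` (non-negative), and `params`.
#' @export
welch_psd <- function(x, fs, params = psd_params()) {
  m <- params$nperseg
  if (length(x) < m) {
    stop("signal (", length(x), " samples) shorter than nperseg (", m, ")",
         call. = FALSE)
  }
  w <- taper_window(params$window, m)
  step <- m - as.integer(floor(m * params$overlap))
  starts <- seq.int(1L, length(x) - m + 1L, by = step)
  seg <- matrix(x[outer(seq_len(m) - 1L, starts, "+")], nrow = m)
  seg <- seg - matrix(colMeans(seg), m, ncol(seg), byrow = TRUE)
  Y <- stats::mvfft(seg * w)
  nf <- m %/% 2L + 1L
  p <- rowMeans(abs(Y[seq_len(nf), , drop = FALSE])^2)
  p <- p / (fs * sum(w^2))
  if (m %% 2L == 0L) p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
  else p[2:nf] <- 2 * p[2:nf]
  structure(list(freqs_hz = (seq_len(nf) - 1L) * fs / m, power = p,
                 params = params),
            class = "emg_psd")
}

#' Time-domain metrics
#'
#' Computes, over one normalised, filtered segment:
#' * `meanRMS` - mean of the windowed RMS envelope;
#' * `stdRMS` - sample standard deviation of the envelope;
#' * `SSC` - slope sign changes per second: interior samples where the
#'   slope changes sign, i.e. `(x_i - x_{i-1})(x_i - x_{i+1}) > 0`, with
#'   both-side excursion at least `delta`;
#' * `ZC` - zero crossings per second: indices with `x_i * x_{i+1} < 0`
#'   and `|x_i - x_{i+1}| >= eps`;
#' * `WFL` - waveform length, the total variation `sum |x_{i+1} - x_i|`
#'   over the whole segment.
#'
#' @param x Numeric vector (at least 3 samples).
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()] (envelope settings).
#' @param eps,delta Amplitude thresholds for ZC and SSC (default 0).
#' @return Named numeric vector `meanRMS, stdRMS, SSC, ZC, WFL`.
#' @export
time_domain_features <- function(x, fs, params = preprocess_params(),
                                 eps = 0, delta = 0) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  env <- rms_envelope(x, fs, params)
  dur <- n / fs
  d <- diff(x)
  zc <- sum(x[-n] * x[-1L] < 0 & abs(d) >= eps)
  dl <- d[-(n - 1L)]                      # x_i - x_{i-1} for interior i
  dr <- -d[-1L]                           # x_i - x_{i+1}
  ssc <- sum(dl * dr > 0 & pmax(abs(dl), abs(dr)) >= delta)
  c(meanRMS = mean(env$values),
    stdRMS = stats::sd(env$values),
    SSC = ssc / dur,
    ZC = zc / dur,
    WFL = sum(abs(d)))
}

#' Frequency-domain metrics
#'
#' Restricts the PSD to the analysis band and computes, with
#' `p_k = P_k / sum(P)`:
#' * `meanFreq` - spectral centroid `sum f_k p_k` (Hz);
#' * `medianFreq` - frequency where cumulative power reaches one half,
#'   linearly interpolated (Hz);
#' * `entropy` - normalised Shannon spectral entropy
#'   `-sum p_k log p_k / log K` in `[0, 1]`;
#' * `DP` - fraction of in-band power at or above `f_split_hz`;
#' * `SpecDef` - spectral deformation, the moment ratio `Omega2/Omega1`
#'   with `Omega_r = (M_r / M_0)^(1/r)`, `M_r = sum f_k^r P_k`; equals 1
#'   for a single-line spectrum and grows with spectral spread.
#'
#' @param psd An [welch_psd()] result.
#' @param params A [psd_params()]; defaults to the PSD's own.
#' @return Named numeric vector
#'   `meanFreq, medianFreq, entropy, DP, SpecDef`.
#' @export
freq_domain_features <- function(psd, params = psd$params) {
  keep <- psd$freqs_hz >= params$band_low_hz &
    psd$freqs_hz <= params$band_high_hz
  freq_metrics(psd$freqs_hz[keep], psd$power[keep], params$f_split_hz)
}

# core of the frequency-domain metrics on an already band-restricted
# (freqs, power) pair
freq_metrics <- function(f, p, f_split_hz) {
  tot <- sum(p)
  if (length(f) < 1L || tot <= 0) {
    stop("silent segment: no in-band spectral power", call. = FALSE)
  }
  pk <- p / tot
  mean_f <- sum(f * pk)
  cum <- cumsum(pk)
  K <- length(pk)
  k <- which(cum >= 0.5)[1L]
  if (K == 1L) {
    med_f <- f[1L]
  } else {
    # each bin's power spread over its interval [f_k - df/2, f_k + df/2]:
    # linear interpolation inside the crossing bin; a line spectrum's
    # median is then the line frequency itself
    df <- f[2L] - f[1L]
    c0 <- if (k == 1L) 0 else cum[k - 1L]
    med_f <- f[k] - df / 2 + (0.5 - c0) / pk[k] * df
    med_f <- min(max(med_f, f[1L]), f[K])
  }
  K <- length(pk)
  ent <- if (K == 1L) 0 else {
    nz <- pk > 0
    -sum(pk[nz] * log(pk[nz])) / log(K)
  }
  dp <- sum(pk[f >= f_split_hz])
  om2 <- sqrt(sum(f^2 * pk))
  c(meanFreq = mean_f, medianFreq = med_f, entropy = ent, DP = dp,
    SpecDef = om2 / mean_f)
}

metric_names <- function() {
  c("meanRMS", "stdRMS", "SSC", "ZC", "WFL",
    "meanFreq", "medianFreq", "entropy", "DP", "SpecDef")
}

# Batched Welch PSD: columns of X (time x channels) -> power nf x channels.
welch_psd_mat <- function(X, fs, params) {
  m <- params$nperseg
  n <- nrow(X)
  k <- ncol(X)
  if (n < m) {
    stop("signal (", n, " samples) shorter than nperseg (", m, ")",
         call. = FALSE)
  }
  w <- taper_window(params$window, m)
  step <- m - as.integer(floor(m * params$overlap))
  starts <- seq.int(1L, n - m + 1L, by = step)
  nwin <- length(starts)
  idx <- as.vector(outer(seq_len(m) - 1L, starts, "+"))       # m*nwin
  lin <- rep(idx, k) + rep((seq_len(k) - 1L) * n, each = m * nwin)
  seg <- matrix(X[lin], nrow = m)                              # m x nwin*k
  seg <- seg - rep(colMeans(seg), each = m)
  Y <- stats::mvfft(seg * w)
  nf <- m %/% 2L + 1L
  P <- abs(Y[seq_len(nf), , drop = FALSE])^2
  # per-channel mean over its nwin periodograms as one matrix product
  agg <- matrix(0, nwin * k, k)
  agg[cbind(seq_len(nwin * k), rep(seq_len(k), each = nwin))] <- 1 / nwin
  pm <- P %*% agg
  pm <- pm / (fs * sum(w^2))
  if (m %% 2L == 0L) pm[2:(nf - 1L), ] <- 2 * pm[2:(nf - 1L), ]
  else pm[2:nf, ] <- 2 * pm[2:nf, ]
  list(freqs_hz = (seq_len(nf) - 1L) * fs / m, power = pm)
}

# All 10 metrics for every column of X (time x channels): channels x 10.
segment_features_mat <- function(X, fs, pre_params, psd_par,
                                 eps = 0, delta = 0) {
  n <- nrow(X)
  k <- ncol(X)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  w <- as.integer(round(pre_params$env_window_s * fs))
  if (n < w) {
    stop("signal (", n, " samples) shorter than envelope window (", w,
         " samples)", call. = FALSE)
  }
  env <- rms_windows(X, w, hop_samples(w, pre_params$env_overlap))
  mu <- colMeans(env)
  sdv <- sqrt(colSums((env - rep(mu, each = nrow(env)))^2) /
                max(1L, nrow(env) - 1L))
  dur <- n / fs
  d <- diff(X)
  zc <- colSums(X[-n, , drop = FALSE] * X[-1L, , drop = FALSE] < 0 &
                  abs(d) >= eps) / dur
  dl <- d[-(n - 1L), , drop = FALSE]
  dr <- -d[-1L, , drop = FALSE]
  ssc <- colSums(dl * dr > 0 & pmax(abs(dl), abs(dr)) >= delta) / dur
  wfl <- colSums(abs(d))
  psd <- welch_psd_mat(X, fs, psd_par)
  keep <- psd$freqs_hz >= psd_par$band_low_hz &
    psd$freqs_hz <= psd_par$band_high_hz
  f <- psd$freqs_hz[keep]
  fd <- t(vapply(seq_len(k), function(ci) {
    freq_metrics(f, psd$power[keep, ci], psd_par$f_split_hz)
  }, numeric(5L)))
  out <- cbind(meanRMS = mu, stdRMS = sdv, SSC = ssc, ZC = zc, WFL = wfl,
               fd)
  colnames(out) <- metric_names()
  out
}

feature_row <- function(x, fs, pre_params, psd_par, subwindow_s = NULL) {
  if (is.null(subwindow_s)) {
    td <- time_domain_features(x, fs, pre_params)
    fd <- freq_domain_features(welch_psd(x, fs, psd_par), psd_par)
    return(c(td, fd))
  }
  # sub-windowed mode: metric per window, then averaged
  w <- as.integer(round(subwindow_s * fs))
  nwin <- max(1L, floor(length(x) / w))
  rows <- vapply(seq_len(nwin), function(i) {
    xi <- x[seq.int((i - 1L) * w + 1L, min(i * w, length(x)))]
    c(time_domain_features(xi, fs, pre_params),
      freq_domain_features(welch_psd(xi, fs, psd_par), psd_par))
  }, numeric(10L))
  rowMeans(rows)
}

#' Extract the 10-metric feature table from a session
#'
#' One row per (channel, segment) of a normalised session; columns are
#' the five time-domain and five frequency-domain metrics. By default
#' each metric is computed once over the whole trimmed segment
#' (time-domain metrics from the sample sequence, frequency-domain
#' metrics from the segment-wide Welch PSD). Setting `subwindow_s`
#' instead computes each metric per consecutive sub-window and averages,
#' for within-compression fatigue exploration.
#'
#' @param session A normalised [emg_session()] (see
#'   [preprocess_session()]).
#' @param pre_params A [preprocess_params()].
#' @param psd_par A [psd_params()].
#' @param subwindow_s Optional sub-window length in seconds.
#' @return A data.frame with columns participant_id, channel, muscle,
#'   side, segment and the 10 metrics; one row per (channel, segment).
#' @export
extract_features <- function(session, pre_params = preprocess_params(),
                             psd_par = psd_params(), subwindow_s = NULL) {
  stopifnot(inherits(session, "emg_session"))
  labs <- names(session$segments)
  chans <- session$channel_order
  rows <- vector("list", length(labs))
  for (li in seq_along(labs)) {
    seg <- session$segments[[labs[li]]]
    rows[[li]] <- tryCatch({
      if (is.null(subwindow_s)) {
        segment_features_mat(t(seg$samples), session$fs, pre_params,
                             psd_par)
      } else {
        t(vapply(seq_along(chans), function(ci) {
          feature_row(seg$samples[ci, ], session$fs, pre_params, psd_par,
                      subwindow_s)
        }, numeric(10L)))
      }
    }, error = function(e) {
      stop("feature extraction failed in segment '", labs[li], "': ",
           conditionMessage(e), call. = FALSE)
    })
  }
  m <- do.call(rbind, rows)
  side <- sub(".*_", "", rep(chans, times = length(labs)))
  muscle <- sub("_(left|right)$", "", rep(chans, times = length(labs)))
  out <- data.frame(participant_id = session$participant_id,
                    channel = rep(chans, times = length(labs)),
                    muscle = muscle, side = side,
                    segment = rep(labs, each = length(chans)),
                    row.names = NULL)
  cbind(out, as.data.frame(m))
}

#' Extract features for every session of a cohort
#'
#' @param cohort An [emg_cohort()] of normalised sessions, or raw
#'   sessions with `preprocess = TRUE`.
#' @param pre_params,psd_par,subwindow_s As [extract_features()].
#' @param preprocess If TRUE, run [preprocess_session()] on each session
#'   first.
#' @return Row-bound feature data.frame across participants.
#' @export
extract_cohort_features <- function(cohort,
                                    pre_params = preprocess_params(),
                                    psd_par = psd_params(),
                                    subwindow_s = NULL,
                                    preprocess = FALSE) {
  stopifnot(inherits(cohort, "emg_cohort"))
  do.call(rbind, lapply(cohort$sessions, function(s) {
    if (preprocess) s <- preprocess_session(s, pre_params)$session
    extract_features(s, pre_params, psd_par, subwindow_s)
  })) -> out
  rownames(out) <- NULL
  out
}

#' Write a feature table as tidy CSV
#'
#' Long format: participant_id, muscle, side, segment, metric, value.
#'
#' @param features Data.frame from [extract_features()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features <- function(features, path) {
  dt <- data.table::as.data.table(features)
  long <- data.table::melt(dt,
                           id.vars = c("participant_id", "muscle", "side",
                                       "segment"),
                           measure.vars = metric_names(),
                           variable.name = "metric", value.name = "value")
  data.table::fwrite(long, path)
  invisible(path)
}
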