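# Preprocessing: edge trimming, zero-phase Butterworth bandpass,
# RMS envelope, and control-referenced amplitude normalisation.

#' Preprocessing parameters
#'
#' @param trim_s Seconds removed from each end of every segment
#'   (default 1.5, floor-rounded to whole samples).
#' @param band_low_hz,band_high_hz Bandpass edges in Hz (default 20-500).
#' @param filter_order Designed Butterworth order (default 4). The filter
#'   is applied forward-backward for zero phase, so the effective order
#'   doubles.
#' @param env_window_s RMS envelope window in seconds (default 0.25).
#' @param env_overlap RMS envelope window overlap fraction (default 0.5).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(trim_s = 1.5, band_low_hz = 20,
                              band_high_hz = 500, filter_order = 4L,
                              env_window_s = 0.25, env_overlap = 0.5) {
  stopifnot(trim_s >= 0, band_low_hz > 0, band_high_hz > band_low_hz,
            filter_order >= 1, env_window_s > 0,
            env_overlap >= 0, env_overlap < 1)
  structure(list(trim_s = trim_s, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz,
                 filter_order = as.integer(filter_order),
                 env_window_s = env_window_s, env_overlap = env_overlap),
            class = "preprocess_params")
}

#' Trim segment edges
#'
#' Removes the first and last `trim_s` seconds (floor-rounded to whole
#' samples) from every channel, discarding start/stop alignment artifacts.
#'
#' @param segment An [emg_segment()].
#' @param params A [preprocess_params()].
#' @return The trimmed segment (label and fs preserved).
#' @export
trim_edges <- function(segment, params = preprocess_params()) {
  stopifnot(inherits(segment, "emg_segment"))
  n <- ncol(segment$samples)
  min_dur <- 2 * params$trim_s + 1
  if (n / segment$fs <= min_dur) {
    stop("segment '", segment$label, "': duration ",
         signif(n / segment$fs, 4), " s too short to trim (needs > ",
         min_dur, " s)", call. = FALSE)
  }
  k <- floor(params$trim_s * segment$fs)
  keep <- if (k > 0) seq.int(k + 1L, n - k) else seq_len(n)
  emg_segment(segment$label, segment$samples[, keep, drop = FALSE],
              segment$fs, check_duration = FALSE)
}

# --- Butterworth bandpass design (bilinear transform) -----------------

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0) - c(0, p) * root
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Order-`n` analog Butterworth lowpass prototype, lowpass-to-bandpass
#' transformed and discretised by the bilinear transform with frequency
#' pre-warping. Matches the conventional design (e.g. MATLAB/SciPy
#' `butter(n, c(low, high), "bandpass")`).
#'
#' @param order Prototype order n (polynomial order of b, a is 2n).
#' @param low_hz,high_hz Band edges in Hz.
#' @param fs Sampling rate in Hz; requires `high_hz < fs/2`.
#' @return List with numerator `b` and denominator `a` (length 2n+1).
#' @export
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (high_hz >= fs / 2) {
    stop("band_high_hz (", high_hz, ") must be below the Nyquist ",
         "frequency fs/2 = ", fs / 2, call. = FALSE)
  }
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  }
  n <- as.integer(order)
  # pre-warped analog edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog prototype poles on the unit circle, left half plane
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # lowpass -> bandpass: each pole splits in two
  half <- 0.5 * bw * p_proto
  disc <- sqrt(half^2 - w0^2 + 0i)
  p_s <- c(half + disc, half - disc)
  z_s <- rep(0 + 0i, n)                     # n zeros at s = 0
  gain_s <- bw^n
  # bilinear transform s = 2 fs (z-1)/(z+1)
  fs2 <- 2 * fs
  p_z <- (fs2 + p_s) / (fs2 - p_s)
  z_z <- (fs2 + z_s) / (fs2 - z_s)          # all 1
  z_z <- c(z_z, rep(-1 + 0i, length(p_s) - length(z_s)))
  gain_z <- gain_s * Re(prod(fs2 - z_s) / prod(fs2 - p_s))
  b <- Re(gain_z * poly_from_roots(z_z))
  a <- Re(poly_from_roots(p_z))
  list(b = b, a = a)
}

# zero-phase filtering: odd-extension padding, forward and reverse pass
# (compiled kernel; prehistory is the constant first/last padded sample,
# the steady state for a bandpass whose taps sum to zero)
filtfilt_mat <- function(x, b, a, padlen) {
  filtfilt_cpp(as.matrix(x), b, a, as.integer(padlen))
}

#' Zero-phase bandpass filter a signal
#'
#' Applies the designed Butterworth bandpass forward and backward
#' (zero phase, squared magnitude response). Output length equals input
#' length; the DC component is rejected.
#'
#' @param x Numeric vector, or matrix with one channel per column.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass <- function(x, fs, params = preprocess_params()) {
  vec <- is.null(dim(x))
  xm <- as.matrix(x)
  if (nrow(xm) < 3L * params$filter_order) {
    stop("signal too short to filter (need >= 3 x filter order samples)",
         call. = FALSE)
  }
  d <- butter_bandpass(params$filter_order, params$band_low_hz,
                       params$band_high_hz, fs)
  # pad generously: low-frequency poles ring for ~fs/band_low samples
  padlen <- as.integer(max(3L * length(d$a),
                           ceiling(6 * fs / params$band_low_hz)))
  y <- filtfilt_mat(xm, d$b, d$a, padlen)
  if (vec) as.numeric(y) else y
}

#' Windowed RMS envelope
#'
#' Root-mean-square of the signal over sliding windows of
#' `env_window_s` seconds advancing by `env_window_s * (1 - env_overlap)`
#' (rounded to at least one sample). Trailing samples that do not fill a
#' window are dropped.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param params A [preprocess_params()].
#' @return A list of class `emg_envelope` with fields `values`
#'   (non-negative RMS per window), `window_s`, `overlap`, `fs`.
#' @export
rms_envelope <- function(x, fs, params = preprocess_params()) {
  w <- as.integer(round(params$env_window_s * fs))
  if (w < 1L) stop("envelope window shorter than one sample", call. = FALSE)
  if (length(x) < w) {
    stop("signal (", length(x), " samples) shorter than envelope window (",
         w, " samples)", call. = FALSE)
  }
  vals <- rms_windows(matrix(x, ncol = 1L), w,
                      hop_samples(w, params$env_overlap))[, 1L]
  structure(list(values = vals, window_s = params$env_window_s,
                 overlap = params$env_overlap, fs = fs),
            class = "emg_envelope")
}

hop_samples <- function(w, overlap) max(1L, as.integer(round(w * (1 - overlap))))

# windowed RMS for each column of x; returns n_windows x n_channels
rms_windows <- function(x, w, hop) {
  n <- nrow(x)
  k <- ncol(x)
  nwin <- floor((n - w) / hop) + 1L
  if (w %% hop == 0L) {
    # windows are whole blocks of `hop` samples: block sums then a
    # short rolling sum (covers the default 50% overlap cheaply)
    nblk <- n %/% hop
    bs <- matrix(.colSums(matrix(x[seq_len(nblk * hop), ]^2, nrow = hop),
                          hop, nblk * k), nblk, k)
    r <- w %/% hop
    ws <- bs[seq_len(nwin), , drop = FALSE]
    if (r > 1L) {
      for (j in seq.int(2L, r)) {
        ws <- ws + bs[seq_len(nwin) + (j - 1L), , drop = FALSE]
      }
    }
    return(sqrt(pmax(ws, 0) / w))
  }
  cs <- apply(x * x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = k)
  starts <- (seq_len(nwin) - 1L) * hop          # 0-based window starts
  hi <- cs[starts + w, , drop = FALSE]
  lo <- rbind(0, cs)[starts + 1L, , drop = FALSE]
  sqrt(pmax(hi - lo, 0) / w)
}

#' Normalise a session against its reference controls
#'
#' For every channel, the per-channel scale is the sample standard
#' deviation of the RMS envelope of the reference control: C2 for C2
#' itself, C1 and all flat-paddle compressions; C3 for C3 itself and all
#' curved-paddle compressions. Each segment's samples are divided by the
#' channel's scale. By construction the envelope standard deviation
#' (stdRMS feature) of a normalised reference control is 1.
#'
#' Segments are expected to be trimmed and bandpass filtered already (see
#' [preprocess_session()] for the full chain).
#'
#' @param session An [emg_session()].
#' @param params A [preprocess_params()] (envelope settings).
#' @return List with `session` (normalised) and `scales`, a data.frame
#'   with columns channel, reference, scale for audit.
#' @export
normalize_session <- function(session, params = preprocess_params()) {
  stopifnot(inherits(session, "emg_session"))
  labs <- names(session$segments)
  refs_needed <- unique(reference_control_of(labs))
  refs_needed[refs_needed == "C1"] <- "C2"       # C1 borrows C2's scale
  refs_needed <- unique(refs_needed)
  missing <- setdiff(refs_needed, labs)
  if (length(missing)) {
    stop("missing reference control ", paste(missing, collapse = ", "),
         " required for normalisation", call. = FALSE)
  }
  w <- as.integer(round(params$env_window_s * session$fs))
  hop <- hop_samples(w, params$env_overlap)
  scales <- list()
  for (ref in refs_needed) {
    env <- rms_windows(t(session$segments[[ref]]$samples), w, hop)
    s <- apply(env, 2L, stats::sd)
    bad <- which(!is.finite(s) | s <= 0)
    if (length(bad)) {
      stop("degenerate control channel: zero-variance envelope in '",
           ref, "' channel ",
           paste(session$channel_order[bad], collapse = ", "),
           call. = FALSE)
    }
    scales[[ref]] <- s
  }
  segs <- session$segments
  for (lab in labs) {
    ref <- reference_control_of(lab)
    if (ref == "C1") ref <- "C2"
    segs[[lab]] <- emg_segment(lab, segs[[lab]]$samples / scales[[ref]],
                               session$fs, check_duration = FALSE)
  }
  audit <- do.call(rbind, lapply(names(scales), function(ref) {
    data.frame(channel = session$channel_order, reference = ref,
               scale = scales[[ref]], row.names = NULL)
  }))
  list(session = emg_session(session$participant_id, segs,
                             session$channel_order,
                             check_duration = FALSE),
       scales = audit)
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: edge trimming, zero-phase bandpass
#' filtering, and control-referenced amplitude normalisation.
#'
#' @param session An [emg_session()] of raw segments.
#' @param params A [preprocess_params()].
#' @return As [normalize_session()]: list with `session` and `scales`.
#' @export
preprocess_session <- function(session, params = preprocess_params()) {
  segs <- lapply(session$segments, function(seg) {
    seg <- trim_edges(seg, params)
    y <- bandpass(t(seg$samples), session$fs, params)
    emg_segment(seg$label, t(y), session$fs, check_duration = FALSE)
  })
  ses <- emg_session(session$participant_id, segs, session$channel_order,
                     check_duration = FALSE)
  normalize_session(ses, params)
}
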