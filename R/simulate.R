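# Synthetic protocol-structured sEMG cohorts: spectrally shaped Gaussian
# baseline noise, ipsilateral amplitude gains with a low-frequency
# narrowband admixture during compressions, lognormal between-participant
# variability, and hierarchical seeding.

#' Spectral shape of the baseline sEMG-like noise
#'
#' Target power spectral density of the classical two-parameter analytic
#' surface-EMG shape,
#' `P(f) = fh^4 f^2 / ((f^2 + fl^2) (f^2 + fh^2)^2)`,
#' a broadband hump rising from DC and rolling off above `f_high`.
#'
#' @param f_low,f_high Shape parameters in Hz (defaults 60 and 120).
#' @return A list of class `spectral_shape`.
#' @export
spectral_shape <- function(f_low = 60, f_high = 120) {
  stopifnot(f_low > 0, f_high > f_low)
  structure(list(f_low = f_low, f_high = f_high),
            class = "spectral_shape")
}

shape_psd <- function(f, shape) {
  shape$f_high^4 * f^2 /
    ((f^2 + shape$f_low^2) * (f^2 + shape$f_high^2)^2)
}

# amplitude gain per two-sided FFT bin for frequency-domain shaping
shape_gains <- function(n, fs, psd_fun) {
  j <- seq_len(n) - 1L
  f <- j * fs / n
  f <- ifelse(f > fs / 2, fs - f, f)         # alias to [0, fs/2]
  g <- sqrt(psd_fun(abs(f)))
  g[1L] <- 0                                  # zero-mean output
  g
}

shaped_gaussian <- function(n, fs, psd_fun) {
  # generate at a 2-3-5-smooth length and truncate: same process, but
  # avoids R's slow mixed-radix FFT on lengths with large prime factors
  m <- stats::nextn(n, c(2L, 3L, 5L))
  g <- shape_gains(m, fs, psd_fun)
  w <- stats::rnorm(m)
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / m
  x[seq_len(n)] / sqrt(mean(g^2))             # expected unit variance
}

#' Generate spectrally shaped unit-variance Gaussian noise
#'
#' Filtered white noise via frequency-domain shaping to the
#' [spectral_shape()] target; zero mean, expected unit variance. Uses the
#' current RNG state (seed with [set.seed()] or via [sim_config()]).
#'
#' @param n_samples Number of samples (>= 256).
#' @param fs Sampling rate in Hz.
#' @param shape A [spectral_shape()].
#' @return Numeric vector of length `n_samples`.
#' @export
shaped_noise <- function(n_samples, fs, shape = spectral_shape()) {
  if (!inherits(shape, "spectral_shape")) {
    stop("shape must be a spectral_shape", call. = FALSE)
  }
  if (n_samples < 256L) stop("n_samples must be >= 256", call. = FALSE)
  shaped_gaussian(n_samples, fs, function(f) shape_psd(f, shape))
}

# narrowband Gaussian bump used as the activation admixture
narrowband_noise <- function(n, fs, center_hz = 70, bw_hz = 10) {
  sigma <- bw_hz / 2
  shaped_gaussian(n, fs, function(f) exp(-(f - center_hz)^2 / (2 * sigma^2)))
}

#' Activation map: which muscles respond to which compressions
#'
#' Amplitude gains applied to the ipsilateral channel of each muscle
#' during compressions (contralateral channels always stay at 1), and
#' the fraction of signal power moved into a low-frequency narrowband
#' component (centred 70 Hz, 10 Hz bandwidth) during activation. The
#' default gains make the deltoid dominant, shoulder/neck muscles
#' moderate, and the torso muscles (serratus anterior, external oblique)
#' inactive; the default admixture produces the downward spectral shift
#' activation shows in practice.
#'
#' @param gain Named numeric vector over [emg_muscles()] (a single gain
#'   per muscle, applied in every view), or a muscles x views matrix
#'   (views RCC, LCC, LMLO, RMLO).
#' @param spectral_mix Power fraction in `[0, 1)` moved into the
#'   narrowband component for activated (gain > 1) channels.
#' @param mix_center_hz,mix_bw_hz Centre and bandwidth of the admixture.
#' @return A list of class `activation_map`.
#' @export
activation_map <- function(gain = c(sternocleidomastoid = 1.8,
                                    trapezius_upper = 1.9,
                                    deltoid = 4.0,
                                    infraspinatus = 2.0,
                                    teres_major = 1.6,
                                    serratus_anterior = 1.0,
                                    external_oblique = 1.0),
                           spectral_mix = 0.3,
                           mix_center_hz = 70, mix_bw_hz = 10) {
  views <- c("RCC", "LCC", "LMLO", "RMLO")
  if (is.matrix(gain)) {
    stopifnot(setequal(rownames(gain), emg_muscles()),
              setequal(colnames(gain), views))
    gm <- gain[emg_muscles(), views]
  } else {
    stopifnot(setequal(names(gain), emg_muscles()))
    gm <- matrix(gain[emg_muscles()], length(emg_muscles()), 4L,
                 dimnames = list(emg_muscles(), views))
  }
  if (any(gm < 1)) stop("gains must be >= 1", call. = FALSE)
  stopifnot(spectral_mix >= 0, spectral_mix < 1)
  structure(list(gain = gm, spectral_mix = spectral_mix,
                 mix_center_hz = mix_center_hz, mix_bw_hz = mix_bw_hz),
            class = "activation_map")
}

#' Simulation configuration
#'
#' @param n_participants Cohort size (default 25, >= 3).
#' @param fs Sampling rate in Hz (default 1925.925).
#' @param baseline_sd_mv Baseline noise standard deviation in mV
#'   (default 0.02).
#' @param between_participant_cv Coefficient of variation of the
#'   lognormal participant multipliers applied to the excess gain
#'   (default 0.3; 0 gives identical participants).
#' @param seed Root seed; all randomness derives from it hierarchically
#'   per participant and segment, so cohorts are reproducible and stable
#'   under cohort-size changes.
#' @param control_duration_s,compression_duration_s Protocol durations
#'   (defaults 120 s and 15 s).
#' @param shape Baseline [spectral_shape()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 25L, fs = emg_default_fs(),
                       baseline_sd_mv = 0.02,
                       between_participant_cv = 0.3, seed = 1L,
                       control_duration_s = 120,
                       compression_duration_s = 15,
                       shape = spectral_shape()) {
  stopifnot(n_participants >= 3, fs > 0, baseline_sd_mv > 0,
            between_participant_cv >= 0,
            control_duration_s > 0, compression_duration_s > 0)
  structure(list(n_participants = as.integer(n_participants), fs = fs,
                 baseline_sd_mv = baseline_sd_mv,
                 between_participant_cv = between_participant_cv,
                 seed = as.integer(seed),
                 control_duration_s = control_duration_s,
                 compression_duration_s = compression_duration_s,
                 shape = shape),
            class = "sim_config")
}

# deterministic substream seeds below 2^31 (multiplicative mixing)
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483647
  for (k in idx) {
    s <- (s * 69069 + 104729 * as.double(k) + 12345) %% 2147483647
  }
  as.integer(s)
}

# lognormal multiplier with mean 1 and coefficient of variation cv
lognormal_mult <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one participant session
#'
#' Generates the 11-segment, 14-channel protocol session. Controls are
#' baseline shaped noise at `baseline_sd_mv`. During a compression, each
#' channel ipsilateral to the compressed side whose muscle gain exceeds 1
#' is scaled by the participant-specific gain and has `spectral_mix` of
#' its power replaced by the low-frequency narrowband component;
#' contralateral and inactive channels are plain baseline noise.
#' Participant gains are `1 + (gain - 1) * L` with `L` lognormal
#' (mean 1, cv `between_participant_cv`), so inactive channels (gain 1)
#' remain exactly at baseline for every participant.
#'
#' @param participant_id Participant identifier; also indexes the
#'   participant's random substream together with `config$seed`.
#' @param config A [sim_config()].
#' @param map An [activation_map()].
#' @param participant_index Integer used for seeding (default 1; set by
#'   [simulate_cohort()]).
#' @return An [emg_session()].
#' @export
simulate_session <- function(participant_id, config = sim_config(),
                             map = activation_map(),
                             participant_index = 1L) {
  stopifnot(inherits(config, "sim_config"),
            inherits(map, "activation_map"))
  muscles <- emg_muscles()
  chans <- emg_channels()
  pseed <- derive_seed(config$seed, participant_index)
  set.seed(pseed)
  mult <- lognormal_mult(length(muscles), config$between_participant_cv)
  names(mult) <- muscles
  pgain <- 1 + (map$gain - 1) * mult[rownames(map$gain)]

  ch_muscle <- sub("_(left|right)$", "", chans)
  ch_side <- toupper(substr(sub(".*_", "", chans), 1L, 1L))

  # frequency-shaping gains cached per distinct segment length; noise is
  # generated at a 2-3-5-smooth FFT length and truncated to n
  gain_cache <- list()
  base_block <- function(n, psd_fun, key) {
    m <- stats::nextn(n, c(2L, 3L, 5L))
    g <- gain_cache[[key]]
    if (is.null(g)) {
      g <- shape_gains(m, config$fs, psd_fun)
      gain_cache[[key]] <<- g
    }
    W <- matrix(stats::rnorm(m * length(chans)), m)
    X <- Re(stats::mvfft(stats::mvfft(W) * g, inverse = TRUE)) / m /
      sqrt(mean(g^2))
    X[seq_len(n), , drop = FALSE]
  }

  segs <- list()
  for (si in seq_along(emg_segment_labels())) {
    lab <- emg_segment_labels()[si]
    role <- segment_role(lab)
    dur <- if (role$kind == "control") config$control_duration_s
           else config$compression_duration_s
    n <- as.integer(round(dur * config$fs))
    set.seed(derive_seed(pseed, si))
    # base noise first, one column per channel, so inactive channels draw
    # the same samples whatever the activation map says
    X <- base_block(n, function(f) shape_psd(f, config$shape),
                    paste0("base", n))
    gvec <- rep(1, length(chans))
    mixvec <- rep(0, length(chans))
    if (role$kind == "compression") {
      pos <- paste0(role$side, role$view)       # e.g. "LCC", "RMLO"
      ipsi <- ch_side == role$side
      gvec[ipsi] <- pgain[ch_muscle[ipsi], pos]
      mixvec[ipsi & map$gain[ch_muscle, pos] > 1] <- map$spectral_mix
    }
    act <- which(mixvec > 0)
    if (length(act)) {
      sigma <- map$mix_bw_hz / 2
      m2 <- stats::nextn(n, c(2L, 3L, 5L))
      gnb <- shape_gains(m2, config$fs, function(f) {
        exp(-(f - map$mix_center_hz)^2 / (2 * sigma^2))
      })
      Wn <- matrix(stats::rnorm(m2 * length(act)), m2)
      NB <- (Re(stats::mvfft(stats::mvfft(Wn) * gnb, inverse = TRUE)) / m2 /
               sqrt(mean(gnb^2)))[seq_len(n), , drop = FALSE]
      X[, act] <- sqrt(1 - mixvec[act]) *
        X[, act, drop = FALSE] +
        NB * rep(sqrt(mixvec[act]), each = n)
    }
    m <- t(X * rep(config$baseline_sd_mv * gvec, each = n))
    dimnames(m) <- list(chans, NULL)
    segs[[lab]] <- emg_segment(lab, m, config$fs, check_duration = FALSE)
  }
  emg_session(participant_id, segs, chans, check_duration = FALSE)
}

#' Simulate a cohort
#'
#' @param config A [sim_config()].
#' @param map An [activation_map()].
#' @return An [emg_cohort()] of `config$n_participants` sessions with
#'   independent participant substreams, fully reproducible from
#'   `config$seed`.
#' @export
simulate_cohort <- function(config = sim_config(), map = activation_map()) {
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  emg_cohort(lapply(seq_along(ids), function(i) {
    simulate_session(ids[i], config, map, participant_index = i)
  }))
}
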