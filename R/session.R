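# Session containers: segment, session, cohort, plus validation.

#' Construct a recording segment
#'
#' A segment is one labelled protocol event: a channels-by-time matrix of
#' sEMG samples (millivolts before normalisation) at a fixed sampling
#' rate. Nominal durations are 120 s for controls and 15 s for
#' compressions; durations outside +/-10% of nominal raise a warning, and
#' compressions shorter than 5 s are rejected because edge trimming needs
#' the margin.
#'
#' @param label Segment label, one of [emg_segment_labels()].
#' @param samples Numeric matrix, channels x time. Row names, if present,
#'   must match the owning session's channel order.
#' @param fs Sampling rate in Hz (> 0).
#' @param check_duration Warn/err on off-nominal durations (default TRUE).
#' @return An object of class `emg_segment`.
#' @export
emg_segment <- function(label, samples, fs, check_duration = TRUE) {
  role <- segment_role(label)  # validates label
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("segment '", label, "': samples must be a numeric matrix ",
         "(channels x time)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("segment '", label, "': fs must be a positive number",
         call. = FALSE)
  }
  dur <- ncol(samples) / fs
  if (check_duration) {
    nominal <- if (role$kind == "control") 120 else 15
    if (role$kind == "compression" && dur < 5) {
      stop("segment '", label, "': duration ", signif(dur, 4),
           " s is below the 5 s minimum for compressions", call. = FALSE)
    }
    if (abs(dur - nominal) > 0.10 * nominal) {
      warning("segment '", label, "': duration ", signif(dur, 4),
              " s is outside +/-10% of the nominal ", nominal, " s",
              call. = FALSE)
    }
  }
  structure(list(label = label, samples = samples, fs = fs),
            class = "emg_segment")
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf("<emg_segment %s: %d channels x %d samples @ %.3f Hz (%.2f s)>\n",
              x$label, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

#' Construct a session
#'
#' One participant's set of labelled segments following the protocol. All
#' segments share the sampling rate and channel order. A session that
#' contains any flat-paddle compression must contain its reference
#' control C2; any curved-paddle compression requires C3.
#'
#' @param participant_id Opaque participant identifier (string).
#' @param segments Named list of [emg_segment()] objects; names must equal
#'   the segments' labels. Stored in protocol order.
#' @param channel_order Character vector of channel ids; defaults to the
#'   canonical 14-channel order [emg_channels()].
#' @param check_duration Passed through to duration validation.
#' @return An object of class `emg_session`.
#' @export
emg_session <- function(participant_id, segments,
                        channel_order = emg_channels(),
                        check_duration = TRUE) {
  if (!is.character(participant_id) || length(participant_id) != 1L ||
      !nzchar(participant_id)) {
    stop("participant_id must be a non-empty string", call. = FALSE)
  }
  if (length(segments) == 0L) {
    stop("session has no segments", call. = FALSE)
  }
  labs <- vapply(segments, function(s) s$label, character(1))
  if (!is.null(names(segments)) && !identical(unname(names(segments)), unname(labs))) {
    stop("segment list names must match segment labels", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicated segment labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  }
  names(segments) <- labs
  # protocol order
  segments <- segments[intersect(emg_segment_labels(), labs)]
  labs <- names(segments)

  nch <- length(channel_order)
  fs <- segments[[1L]]$fs
  for (s in segments) {
    if (nrow(s$samples) != nch) {
      stop("segment '", s$label, "' has ", nrow(s$samples),
           " channels; session channel_order has ", nch, call. = FALSE)
    }
    if (!isTRUE(all.equal(s$fs, fs))) {
      stop("segment '", s$label, "' fs differs from session fs",
           call. = FALSE)
    }
  }
  if (any(startsWith(labs, "F_")) && !"C2" %in% labs) {
    stop("missing reference control C2 for flat-paddle compressions",
         call. = FALSE)
  }
  if (any(startsWith(labs, "C_")) && !"C3" %in% labs) {
    stop("missing reference control C3 for curved-paddle compressions",
         call. = FALSE)
  }
  structure(list(participant_id = participant_id, segments = segments,
                 channel_order = channel_order, fs = fs),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf("<emg_session %s: %d segments [%s], %d channels @ %.3f Hz>\n",
              x$participant_id, length(x$segments),
              paste(names(x$segments), collapse = " "),
              length(x$channel_order), x$fs))
  invisible(x)
}

#' Construct a cohort
#'
#' @param sessions List of [emg_session()] objects with unique participant
#'   ids and identical channel order.
#' @return An object of class `emg_cohort`.
#' @export
emg_cohort <- function(sessions) {
  if (length(sessions) == 0L) stop("cohort has no sessions", call. = FALSE)
  ids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicated participant ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  ord <- sessions[[1L]]$channel_order
  for (s in sessions) {
    if (!identical(s$channel_order, ord)) {
      stop("participant '", s$participant_id,
           "' has a different channel order", call. = FALSE)
    }
  }
  names(sessions) <- ids
  structure(list(sessions = sessions), class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort: %d sessions (%s%s)>\n", length(x$sessions),
              paste(utils::head(names(x$sessions), 3), collapse = ", "),
              if (length(x$sessions) > 3) ", ..." else ""))
  invisible(x)
}
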