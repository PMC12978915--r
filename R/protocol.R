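# Protocol vocabulary: muscles, channels, segment labels and their roles.

#' Muscles monitored by the protocol
#'
#' The seven muscles instrumented bilaterally (14 channels total):
#' sternocleidomastoid, upper trapezius, deltoid, infraspinatus,
#' teres major, serratus anterior and external oblique.
#'
#' @return Character vector of the 7 muscle names in canonical order.
#' @export
emg_muscles <- function() {
  c("sternocleidomastoid", "trapezius_upper", "deltoid", "infraspinatus",
    "teres_major", "serratus_anterior", "external_oblique")
}

#' Canonical channel order
#'
#' Channel identifiers are `"<muscle>_<side>"`, left before right within
#' each muscle, muscles in the order of [emg_muscles()]. Exactly 14 exist.
#'
#' @return Character vector of the 14 channel ids.
#' @export
emg_channels <- function() {
  as.vector(t(outer(emg_muscles(), c("left", "right"), paste, sep = "_")))
}

#' Protocol segment labels
#'
#' The 11 events of the study protocol, in acquisition order: a control in
#' the large room (C1), a control in the examination room (C2), the four
#' flat-paddle compressions, a third control (C3) taken at the paddle
#' change, and the four curved-paddle compressions. Compression labels are
#' `<paddle>_<side><view>` with paddle F (flat) or C (curved), side R/L,
#' and view CC (craniocaudal) or MLO (mediolateral oblique).
#'
#' @return Character vector of the 11 segment labels in protocol order.
#' @export
emg_segment_labels <- function() {
  c("C1", "C2", "F_RCC", "F_LCC", "F_LMLO", "F_RMLO",
    "C3", "C_RCC", "C_LCC", "C_LMLO", "C_RMLO")
}

#' Default sampling rate (Hz)
#'
#' Vendor default sampling rate of the wearable sEMG system. Stored
#' per-session; downstream code always reads `fs` from the session.
#'
#' @return Sampling rate in Hz.
#' @export
emg_default_fs <- function() 1925.925

#' Decompose a segment label into its protocol role
#'
#' Controls map to themselves as reference. Compressions decompose into
#' paddle, side and view, and carry the control segment against which they
#' are normalised and tested: flat-paddle compressions reference C2 (the
#' first examination-room control), curved-paddle compressions reference
#' C3 (the control taken at the paddle change). C1 references C1 itself;
#' its normalisation scale is borrowed from C2 (see [normalize_session()]).
#'
#' @param label A segment label, one of [emg_segment_labels()].
#' @return A list with elements `label`, `kind` ("control" or
#'   "compression"), `paddle` ("F"/"C" or NA), `side` ("L"/"R" or NA),
#'   `view` ("CC"/"MLO" or NA) and `reference_control`.
#' @examples
#' segment_role("F_LMLO")
#' segment_role("C3")
#' @export
segment_role <- function(label) {
  label <- as.character(label)
  stopifnot(length(label) == 1L)
  if (!label %in% emg_segment_labels()) {
    stop("unknown segment label: '", label, "'", call. = FALSE)
  }
  if (label %in% c("C1", "C2", "C3")) {
    return(list(label = label, kind = "control", paddle = NA_character_,
                side = NA_character_, view = NA_character_,
                reference_control = label))
  }
  paddle <- substr(label, 1L, 1L)
  side <- substr(label, 3L, 3L)
  view <- substr(label, 4L, nchar(label))
  list(label = label, kind = "compression", paddle = paddle, side = side,
       view = view,
       reference_control = if (paddle == "F") "C2" else "C3")
}

# reference control for each label, vectorised (internal)
reference_control_of <- function(labels) {
  vapply(labels, function(l) segment_role(l)$reference_control, character(1))
}

compression_labels <- function() {
  setdiff(emg_segment_labels(), c("C1", "C2", "C3"))
}
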