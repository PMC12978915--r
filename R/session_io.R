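# CSV interchange for sessions and cohorts.
#
# Canonical layout is a UTF-8 CSV with one metadata line
#   # emgmap participant_id=<id> fs=<Hz> dialect=<long|wide>
# followed by a header row. Long dialect columns:
#   participant_id, segment_label, channel, sample_index, value_mv
# Wide dialect columns:
#   segment_label, sample_index, <one column per channel id>
# Values are millivolt floats written with 17 significant digits so that
# read(write(s)) round-trips bit-exactly.

meta_line <- function(session, dialect) {
  sprintf("# emgmap participant_id=%s fs=%.17g dialect=%s",
          session$participant_id, session$fs, dialect)
}

parse_meta <- function(line) {
  if (!startsWith(line, "# emgmap")) return(NULL)
  kv <- regmatches(line, gregexpr("[a-z_]+=[^ ]+", line))[[1]]
  out <- list()
  for (item in kv) {
    k <- sub("=.*", "", item)
    v <- sub("^[a-z_]+=", "", item)
    out[[k]] <- v
  }
  if (!is.null(out$fs)) out$fs <- as.numeric(out$fs)
  out
}

#' Write a session to CSV
#'
#' @param session An [emg_session()].
#' @param path Output file path.
#' @param dialect `"long"` (default, one row per sample) or `"wide"`
#'   (one column per channel).
#' @return Invisibly, `path`.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!inherits(session, "emg_session")) {
    stop("session must be an emg_session", call. = FALSE)
  }
  if (length(session$segments) == 0L) {
    stop("session has no segments", call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_line(session, dialect), con)
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "long") {
    writeLines("participant_id,segment_label,channel,sample_index,value_mv",
               con)
    for (seg in session$segments) {
      n <- ncol(seg$samples)
      for (ci in seq_along(session$channel_order)) {
        writeLines(paste(session$participant_id, seg$label,
                         session$channel_order[ci], seq_len(n),
                         fmt(seg$samples[ci, ]), sep = ","), con)
      }
    }
  } else {
    writeLines(paste(c("segment_label", "sample_index",
                       session$channel_order), collapse = ","), con)
    for (seg in session$segments) {
      n <- ncol(seg$samples)
      cols <- apply(seg$samples, 1L, fmt)      # n x channels
      if (is.null(dim(cols))) cols <- matrix(cols, nrow = n)
      writeLines(paste(seg$label, seq_len(n),
                       apply(cols, 1L, paste, collapse = ","), sep = ","),
                 con)
    }
  }
  invisible(path)
}

#' Read a session from CSV
#'
#' Accepts the long and wide dialects written by [write_session()]. The
#' sampling rate is taken from the file's metadata line or, failing that,
#' from `schema$fs`. Channels are sorted into the session's canonical
#' order; unknown segment labels are rejected, as are ragged channel
#' lengths within a segment.
#'
#' @param path Input file path.
#' @param schema Optional list; recognised fields: `fs` (Hz, used when the
#'   file has no metadata line), `participant_id` (ditto),
#'   `channel_order` (defaults to [emg_channels()]),
#'   `check_duration` (logical).
#' @return A validated [emg_session()].
#' @export
read_session <- function(path, schema = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  meta <- parse_meta(first)
  skip <- if (is.null(meta)) 0L else 1L
  fs <- if (!is.null(meta$fs)) meta$fs else schema$fs
  if (is.null(fs)) {
    stop("sampling rate not found: no metadata line in '", path,
         "' and no schema$fs supplied", call. = FALSE)
  }
  pid <- if (!is.null(meta$participant_id)) meta$participant_id
         else if (!is.null(schema$participant_id)) schema$participant_id
         else "unknown"
  channel_order <- if (!is.null(schema$channel_order)) schema$channel_order
                   else emg_channels()
  check_duration <- if (!is.null(schema$check_duration)) schema$check_duration
                    else TRUE

  dt <- data.table::fread(path, skip = skip, header = TRUE, sep = ",",
                          encoding = "UTF-8", showProgress = FALSE)
  cols <- names(dt)
  segments <- list()
  if ("value_mv" %in% cols) {                      # long dialect
    need <- c("segment_label", "channel", "sample_index", "value_mv")
    if (!all(need %in% cols)) {
      stop("long-dialect CSV must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if ("participant_id" %in% cols) {
      ids <- unique(dt$participant_id)
      if (length(ids) > 1L) {
        stop("file contains multiple participants: ",
             paste(ids, collapse = ", "), call. = FALSE)
      }
      pid <- as.character(ids)
    }
    bad <- setdiff(unique(dt$channel), channel_order)
    if (length(bad)) {
      stop("unknown channel(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (lab in intersect(emg_segment_labels(), unique(dt$segment_label))) {
      sub <- dt[dt$segment_label == lab]
      lens <- table(sub$channel)
      if (length(unique(as.integer(lens))) > 1L) {
        short <- names(lens)[lens != max(lens)]
        stop("ragged channel lengths in segment '", lab, "' (channel ",
             paste(short, collapse = ", "), ")", call. = FALSE)
      }
      present <- intersect(channel_order, names(lens))
      if (!setequal(present, channel_order)) {
        stop("segment '", lab, "' is missing channel(s): ",
             paste(setdiff(channel_order, present), collapse = ", "),
             call. = FALSE)
      }
      n <- max(sub$sample_index)
      m <- matrix(NA_real_, length(channel_order), n,
                  dimnames = list(channel_order, NULL))
      for (ch in channel_order) {
        rows <- sub[sub$channel == ch]
        m[ch, rows$sample_index] <- rows$value_mv
      }
      if (anyNA(m)) {
        stop("segment '", lab, "': sample indices are not contiguous",
             call. = FALSE)
      }
      segments[[lab]] <- emg_segment(lab, m, fs,
                                     check_duration = check_duration)
    }
    bad_lab <- setdiff(unique(dt$segment_label), emg_segment_labels())
    if (length(bad_lab)) {
      stop("unknown segment label(s): ", paste(bad_lab, collapse = ", "),
           call. = FALSE)
    }
  } else {                                          # wide dialect
    need <- c("segment_label", "sample_index")
    if (!all(need %in% cols)) {
      stop("wide-dialect CSV must have columns segment_label, ",
           "sample_index plus one column per channel", call. = FALSE)
    }
    chans <- setdiff(cols, c(need, "participant_id"))
    bad <- setdiff(chans, channel_order)
    if (length(bad)) {
      stop("unknown channel column(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!setequal(chans, channel_order)) {
      stop("missing channel column(s): ",
           paste(setdiff(channel_order, chans), collapse = ", "),
           call. = FALSE)
    }
    bad_lab <- setdiff(unique(dt$segment_label), emg_segment_labels())
    if (length(bad_lab)) {
      stop("unknown segment label(s): ", paste(bad_lab, collapse = ", "),
           call. = FALSE)
    }
    for (lab in intersect(emg_segment_labels(), unique(dt$segment_label))) {
      sub <- dt[dt$segment_label == lab]
      sub <- sub[order(sub$sample_index)]
      m <- t(as.matrix(sub[, channel_order, with = FALSE]))
      rownames(m) <- channel_order
      segments[[lab]] <- emg_segment(lab, m, fs,
                                     check_duration = check_duration)
    }
  }
  emg_session(pid, segments, channel_order, check_duration = FALSE)
}

#' Write a cohort, one CSV per participant
#'
#' @param cohort An [emg_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Passed to [write_session()].
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir, dialect = "long") {
  if (!inherits(cohort, "emg_cohort")) {
    stop("cohort must be an emg_cohort", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$sessions, function(s) {
    p <- file.path(dir, paste0(s$participant_id, ".csv"))
    write_session(s, p, dialect)
    p
  }, character(1))
  invisible(paths)
}

#' Read a cohort from a directory of session CSVs
#'
#' @param dir Directory containing one CSV per participant.
#' @param schema Passed to [read_session()].
#' @return An [emg_cohort()].
#' @export
read_cohort <- function(dir, schema = list()) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) {
    stop("no session CSVs found in ", dir, call. = FALSE)
  }
  emg_cohort(lapply(files, read_session, schema = schema))
}
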