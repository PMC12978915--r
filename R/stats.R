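# Paired contrasts between protocol stages: Kolmogorov-Smirnov normality
# screening (Lilliefors correction), paired t tests, Bonferroni
# adjustment, and the muscle x metric sensitivity matrix.

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' KS test against a normal distribution with mean and standard deviation
#' estimated from the sample, with the Dallal-Wilkinson / Stephens
#' p-value approximation. Advisory: the contrast pipeline reports this
#' alongside every t test but never gates on it.
#'
#' @param x Numeric vector, n >= 4, positive variance.
#' @return List with `statistic` (D) and `p_value`.
#' @export
lilliefors_test <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 4L) stop("lilliefors_test needs n >= 4", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance sample", call. = FALSE)
  p <- stats::pnorm((x - mean(x)) / s)
  D <- max(seq_len(n) / n - p, p - (seq_len(n) - 1L) / n)
  # Dallal & Wilkinson (1986) approximation, Stephens tail for p > 0.1
  if (n > 100) {
    Kd <- D * (n / 100)^0.49
    nd <- 100
  } else {
    Kd <- D
    nd <- n
  }
  pv <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
              2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
              0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pv > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pv <- if (KK <= 0.302) 1
    else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
      138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
      94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
      12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  list(statistic = D, p_value = min(max(pv, 0), 1))
}

#' Paired t test with normality screening
#'
#' Two-sided paired t test on the per-participant differences `a - b`,
#' plus a Lilliefors KS normality p-value of the differences. Degenerate
#' all-zero-variance differences yield `t = NA`, `p_raw = 1` and
#' `degenerate = TRUE` rather than an error (this occurs by construction
#' for some normalisation-forced metrics).
#'
#' @param a,b Numeric vectors of equal length n >= 3, paired by
#'   participant.
#' @return List with `t`, `df`, `p_raw`, `ks_p`, `n`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) {
    stop("mismatched pairing: length(a) != length(b)", call. = FALSE)
  }
  n <- length(a)
  if (n < 3L) stop("paired_t needs n >= 3", call. = FALSE)
  d <- a - b
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    return(list(t = NA_real_, df = n - 1L, p_raw = 1, ks_p = NA_real_,
                n = n, degenerate = TRUE))
  }
  t <- mean(d) / (sd_d / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  ks <- tryCatch(lilliefors_test(d)$p_value, error = function(e) NA_real_)
  list(t = t, df = n - 1L, p_raw = p, ks_p = ks, n = n, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Family size (>= 1).
#' @return `pmin(1, m * p_values)`, elementwise.
#' @export
bonferroni <- function(p_values, m) {
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("family size m must be >= 1", call. = FALSE)
  }
  pmin(1, m * p_values)
}

# contrast tables per family: data.frame(a, b); m = Bonferroni size
family_contrasts <- function(family) {
  views <- c("RCC", "LCC", "LMLO", "RMLO")
  switch(family,
         compression_vs_control = list(
           pairs = data.frame(a = compression_labels(),
                              b = reference_control_of(compression_labels())),
           m = 8L),
         paddle_vs_paddle = list(
           pairs = data.frame(a = paste0("F_", views),
                              b = paste0("C_", views)),
           m = 4L),
         angle_vs_angle = list(
           pairs = data.frame(a = c("F_RCC", "F_LCC", "C_RCC", "C_LCC"),
                              b = c("F_RMLO", "F_LMLO", "C_RMLO", "C_LMLO")),
           m = 4L),
         control_vs_control = list(
           pairs = data.frame(a = c("C1", "C1"), b = c("C2", "C3")),
           m = 2L),
         stop("unknown contrast family: '", family, "'", call. = FALSE))
}

#' Run one contrast family over a cohort feature table
#'
#' The four families are:
#' * `compression_vs_control`: each of the 8 compressions against its
#'   reference control (flat vs C2, curved vs C3); Bonferroni m = 8 per
#'   (muscle, metric);
#' * `paddle_vs_paddle`: flat vs curved paddle for the same view, m = 4;
#' * `angle_vs_angle`: CC vs MLO view of the same breast within paddle,
#'   m = 4;
#' * `control_vs_control`: C1 vs C2 and C1 vs C3, m = 2.
#'
#' @param features Cohort feature table from [extract_cohort_features()].
#' @param family One of the family names above.
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param m Bonferroni family size; defaults to the family's declared
#'   number of contrasts.
#' @return Data.frame of comparison results: one row per
#'   (channel, metric, contrast) with columns family, channel, muscle,
#'   side, metric, a, b, n, mean_a, sd_a, mean_b, sd_b, t, p_raw, p_adj,
#'   significant, ks_p, degenerate.
#' @export
run_family <- function(features, family, alpha = 0.05, m = NULL) {
  fam <- family_contrasts(family)
  if (is.null(m)) m <- fam$m
  pairs <- fam$pairs
  needed <- unique(c(pairs$a, pairs$b))
  chans <- unique(features$channel)
  metrics <- metric_names()
  parts <- sort(unique(features$participant_id))
  n <- length(parts)

  # dense array [participant, segment, channel, metric] for fast slicing
  missing <- character(0)
  for (lab in needed) {
    have <- unique(features$participant_id[features$segment == lab])
    if (!setequal(have, parts)) {
      missing <- c(missing, paste0(lab, " (",
                                   paste(setdiff(parts, have),
                                         collapse = ", "), ")"))
    }
  }
  if (length(missing)) {
    stop("missing segment(s) for some participants: ",
         paste(missing, collapse = "; "), call. = FALSE)
  }
  sub <- features[features$segment %in% needed, , drop = FALSE]
  arr <- array(NA_real_,
               dim = c(n, length(needed), length(chans), length(metrics)),
               dimnames = list(parts, needed, chans, metrics))
  pi_ <- match(sub$participant_id, parts)
  si <- match(sub$segment, needed)
  ci <- match(sub$channel, chans)
  for (mi in seq_along(metrics)) {
    arr[cbind(pi_, si, ci, mi)] <- sub[[metrics[mi]]]
  }

  npair <- nrow(pairs)
  nrows <- npair * length(chans) * length(metrics)
  col_ch <- character(nrows); col_met <- character(nrows)
  col_a <- character(nrows); col_b <- character(nrows)
  num <- matrix(NA_real_, nrows, 8L,
                dimnames = list(NULL, c("mean_a", "sd_a", "mean_b", "sd_b",
                                        "t", "p_raw", "ks_p", "p_adj")))
  col_deg <- logical(nrows)
  i <- 0L
  for (ch in chans) {
    for (met in metrics) {
      idx <- i + seq_len(npair)
      for (k in seq_len(npair)) {
        va <- arr[, pairs$a[k], ch, met]
        vb <- arr[, pairs$b[k], ch, met]
        tt <- paired_t(va, vb)
        num[idx[k], 1:7] <- c(mean(va), stats::sd(va), mean(vb),
                              stats::sd(vb), tt$t, tt$p_raw, tt$ks_p)
        col_deg[idx[k]] <- tt$degenerate
      }
      num[idx, "p_adj"] <- bonferroni(num[idx, "p_raw"], m)
      col_ch[idx] <- ch
      col_met[idx] <- met
      col_a[idx] <- pairs$a
      col_b[idx] <- pairs$b
      i <- i + npair
    }
  }
  data.frame(family = family, channel = col_ch,
             muscle = sub("_(left|right)$", "", col_ch),
             side = sub(".*_", "", col_ch), metric = col_met,
             a = col_a, b = col_b, n = n,
             mean_a = num[, "mean_a"], sd_a = num[, "sd_a"],
             mean_b = num[, "mean_b"], sd_b = num[, "sd_b"],
             t = num[, "t"], p_raw = num[, "p_raw"],
             p_adj = num[, "p_adj"],
             significant = num[, "p_adj"] < alpha,
             ks_p = num[, "ks_p"], degenerate = col_deg,
             row.names = NULL)
}

#' Sensitivity matrix from compression-vs-control results
#'
#' For each (channel, metric), the fraction of the 8 compression
#' contrasts whose Bonferroni-adjusted test was significant.
#'
#' @param results Data.frame from
#'   `run_family(..., "compression_vs_control")`.
#' @return Numeric matrix channels x metrics with entries in
#'   `{0, 1/8, ..., 1}`, of class `emg_sensitivity`.
#' @export
sensitivity_matrix <- function(results) {
  if (!all(results$family == "compression_vs_control")) {
    stop("sensitivity_matrix requires compression_vs_control results",
         call. = FALSE)
  }
  chans <- unique(results$channel)
  metrics <- intersect(metric_names(), unique(results$metric))
  m <- matrix(0, length(chans), length(metrics),
              dimnames = list(chans, metrics))
  agg <- stats::aggregate(significant ~ channel + metric, data = results,
                          FUN = mean)
  m[cbind(match(agg$channel, chans), match(agg$metric, metrics))] <-
    agg$significant
  structure(m, class = c("emg_sensitivity", "matrix", "array"))
}

#' @export
print.emg_sensitivity <- function(x, ...) {
  cat("<sensitivity matrix: fraction of the 8 compressions significant>\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Write the sensitivity matrix as CSV
#'
#' @param sm Matrix from [sensitivity_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sensitivity <- function(sm, path) {
  df <- data.frame(channel = rownames(sm), unclass(sm),
                   check.names = FALSE, row.names = NULL)
  data.table::fwrite(df, path)
  invisible(path)
}
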