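# Summary products: group tables (mean (SD) with significance marks),
# the per-view percent-change activation map, and the pipeline driver.

#' Group summary table from compression-vs-control results
#'
#' One row per (channel, metric, paddle): the reference control's
#' cross-participant mean (SD) and, for each of the four views, the
#' compression mean (SD) with a significance flag where the
#' Bonferroni-adjusted paired test fell below alpha.
#'
#' @param results Data.frame from
#'   `run_family(features, "compression_vs_control")`.
#' @return Data.frame with columns channel, muscle, side, metric, paddle,
#'   control_mean, control_sd, and `<view>_mean`, `<view>_sd`,
#'   `<view>_sig` for views RCC, LCC, LMLO, RMLO.
#' @export
group_table <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("empty results", call. = FALSE)
  }
  if (!all(results$family == "compression_vs_control")) {
    stop("group_table requires compression_vs_control results",
         call. = FALSE)
  }
  views <- c("RCC", "LCC", "LMLO", "RMLO")
  res <- results
  res$paddle <- substr(res$a, 1L, 1L)
  res$view <- substr(res$a, 3L, nchar(res$a))   # side + angle, e.g. "LMLO"
  keys <- unique(res[, c("channel", "metric", "paddle")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- res[res$channel == k$channel & res$metric == k$metric &
                 res$paddle == k$paddle, ]
    row <- data.frame(channel = k$channel,
                      muscle = sub("_(left|right)$", "", k$channel),
                      side = sub(".*_", "", k$channel),
                      metric = k$metric, paddle = k$paddle,
                      control_mean = sub$mean_b[1L],
                      control_sd = sub$sd_b[1L], row.names = NULL)
    for (v in views) {
      sv <- sub[sub$view == v, ]
      row[[paste0(v, "_mean")]] <- sv$mean_a
      row[[paste0(v, "_sd")]] <- sv$sd_a
      row[[paste0(v, "_sig")]] <- sv$significant
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a group table as text
#'
#' Human-readable `mean (SD)` cells, significant cells marked `*`.
#'
#' @param gt Data.frame from [group_table()].
#' @param digits Significant digits (default 4).
#' @return Character matrix rendering (also printed invisibly usable).
#' @export
format_group_table <- function(gt, digits = 4) {
  views <- c("RCC", "LCC", "LMLO", "RMLO")
  cell <- function(m, s, sig = FALSE) {
    sprintf("%s (%s)%s", signif(m, digits), signif(s, 3),
            ifelse(sig, "*", ""))
  }
  out <- data.frame(channel = gt$channel, metric = gt$metric,
                    paddle = gt$paddle,
                    Control = cell(gt$control_mean, gt$control_sd))
  for (v in views) {
    out[[v]] <- cell(gt[[paste0(v, "_mean")]], gt[[paste0(v, "_sd")]],
                     gt[[paste0(v, "_sig")]])
  }
  out
}

#' Per-view percent-change activation map
#'
#' For each (channel, view, metric): pool the flat- and curved-paddle
#' compression feature values of that view across participants, pool the
#' C2 and C3 control values as the reference population, and report
#' `|mean_compression - mean_control| / |mean_control| * 100`. Also
#' returns, per (muscle, metric), the maximum over both sides and all
#' four views (the number a body-map colour bar would be scaled to).
#'
#' @param features Cohort feature table from [extract_cohort_features()].
#' @return List of class `percent_change_map` with `entries` (data.frame:
#'   channel, muscle, side, view, metric, pct_change) and `max_pct`
#'   (data.frame: muscle, metric, max_pct).
#' @export
percent_change_map <- function(features) {
  views <- c("RCC", "LCC", "LMLO", "RMLO")
  chans <- unique(features$channel)
  metrics <- metric_names()
  ctrl <- features[features$segment %in% c("C2", "C3"), , drop = FALSE]
  entries <- list()
  i <- 0L
  for (ch in chans) {
    csub <- ctrl[ctrl$channel == ch, , drop = FALSE]
    for (met in metrics) {
      mc <- mean(csub[[met]])
      if (!is.finite(mc) || mc == 0) {
        stop("zero control mean for channel '", ch, "', metric '", met,
             "'", call. = FALSE)
      }
      for (v in views) {
        comp <- features[features$channel == ch &
                           features$segment %in% paste0(c("F_", "C_"), v), ,
                         drop = FALSE]
        mcomp <- mean(comp[[met]])
        i <- i + 1L
        entries[[i]] <- data.frame(
          channel = ch, muscle = sub("_(left|right)$", "", ch),
          side = sub(".*_", "", ch), view = v, metric = met,
          pct_change = abs(mcomp - mc) / abs(mc) * 100, row.names = NULL)
      }
    }
  }
  entries <- do.call(rbind, entries)
  rownames(entries) <- NULL
  max_pct <- stats::aggregate(pct_change ~ muscle + metric, data = entries,
                              FUN = max)
  names(max_pct)[3L] <- "max_pct"
  structure(list(entries = entries, max_pct = max_pct),
            class = "percent_change_map")
}

#' @export
print.percent_change_map <- function(x, ...) {
  cat("<percent-change map:", nrow(x$entries), "entries>\n")
  cat("max |%change| per (muscle, metric):\n")
  print(utils::head(x$max_pct[order(-x$max_pct$max_pct), ], 10),
        row.names = FALSE)
  invisible(x)
}

default_pipeline_config <- function() {
  list(
    alpha = 0.05,
    subwindow_s = NULL,
    preprocess = list(trim_s = 1.5, band_low_hz = 20, band_high_hz = 500,
                      filter_order = 4, env_window_s = 0.25,
                      env_overlap = 0.5),
    psd = list(nperseg = 128, overlap = 0.5, window = "blackman",
               band_low_hz = 20, band_high_hz = 500, f_split_hz = 150),
    simulate = list(n_participants = 25, fs = emg_default_fs(),
                    baseline_sd_mv = 0.02, between_participant_cv = 0.3,
                    seed = 1, control_duration_s = 120,
                    compression_duration_s = 15)
  )
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Chains simulation (or cohort loading), preprocessing, feature
#' extraction, the four contrast families, the sensitivity matrix and the
#' percent-change map, writing all artifacts to an output directory:
#' `features.csv`, `comparisons.csv`, `sensitivity_matrix.csv`,
#' `percent_change.csv`, `group_table.csv` and `manifest.json` (config
#' echo, seed, package version). Deterministic given the seed.
#'
#' @param config A configuration list, or a path to a JSON file holding
#'   one. Recognised blocks: `simulate` (used unless `input_dir` is
#'   given), `preprocess`, `psd`, `input_schema` (passed to
#'   [read_cohort()]), plus scalars `alpha`, `subwindow_s`, `input_dir`,
#'   `out_dir`, `seed` (overrides `simulate$seed`).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the in-memory artifacts (`features`,
#'   `comparisons`, `sensitivity`, `percent_change`, `group_table`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- merge_config(default_pipeline_config(), config)
  if (!is.null(config$seed)) cfg$simulate$seed <- config$seed
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pre <- do.call(preprocess_params, cfg$preprocess)
  psd <- do.call(psd_params, cfg$psd)

  stage <- "input"
  result <- tryCatch({
    cohort <- if (!is.null(cfg$input_dir)) {
      schema <- if (is.null(cfg$input_schema)) list() else cfg$input_schema
      read_cohort(cfg$input_dir, schema = schema)
    } else {
      sim_args <- cfg$simulate
      sim_args$shape <- do.call(spectral_shape,
                                if (is.null(sim_args$shape)) list()
                                else sim_args$shape)
      simulate_cohort(do.call(sim_config, sim_args))
    }
    stage <- "preprocess"
    norm <- lapply(cohort$sessions,
                   function(s) preprocess_session(s, pre)$session)
    stage <- "features"
    features <- extract_cohort_features(emg_cohort(norm), pre, psd,
                                        subwindow_s = cfg$subwindow_s)
    stage <- "stats"
    fams <- c("compression_vs_control", "paddle_vs_paddle",
              "angle_vs_angle", "control_vs_control")
    comparisons <- do.call(rbind, lapply(fams, function(f) {
      run_family(features, f, alpha = cfg$alpha)
    }))
    cc <- comparisons[comparisons$family == "compression_vs_control", ]
    sens <- sensitivity_matrix(cc)
    gt <- group_table(cc)
    stage <- "report"
    pcm <- percent_change_map(features)
    list(features = features, comparisons = comparisons,
         sensitivity = sens, group_table = gt, percent_change = pcm)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })

  write_features(result$features, file.path(out_dir, "features.csv"))
  data.table::fwrite(result$comparisons,
                     file.path(out_dir, "comparisons.csv"))
  write_sensitivity(result$sensitivity,
                    file.path(out_dir, "sensitivity_matrix.csv"))
  data.table::fwrite(result$percent_change$entries,
                     file.path(out_dir, "percent_change.csv"))
  data.table::fwrite(result$group_table,
                     file.path(out_dir, "group_table.csv"))
  manifest <- list(package = "emgmap",
                   version = as.character(utils::packageVersion("emgmap")),
                   config = cfg,
                   generated = "run_pipeline")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  result$manifest <- manifest
  invisible(result)
}
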