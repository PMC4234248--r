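# ---------------------------------------------------------------------------
# MUSHRA rating tables and correlation of objective scores with subjective
# ratings.
# ---------------------------------------------------------------------------

#' Validate a MUSHRA rating table
#'
#' Expects columns `subject`, `group`, `condition`, `talker`, `rating`
#' (ratings on the 0-100 MUSHRA scale; each (subject, condition, talker)
#' key at most once).
#'
#' @param df A data frame.
#' @return The validated data frame, class `rating_table`.
#' @export
rating_table <- function(df) {
  need <- c("subject", "group", "condition", "talker", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("rating_table: missing columns: %s",
                 paste(miss, collapse = ", ")))
  bad <- which(!is.finite(df$rating) | df$rating < 0 | df$rating > 100)
  if (length(bad) > 0)
    stop(sprintf("rating_table: rating out of [0, 100] in row(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  key <- paste(df$subject, df$condition, df$talker, sep = "\r")
  if (anyDuplicated(key))
    stop(sprintf("rating_table: duplicated (subject, condition, talker) in row(s) %s",
                 paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
  class(df) <- c("rating_table", "data.frame")
  df
}

#' Load a rating table from delimited text
#'
#' @param path TSV/CSV file with the five named columns `subject`,
#'   `group`, `condition`, `talker`, `rating`.
#' @param sep Field separator (`"\t"` or `","`; guessed from the file
#'   extension by default).
#' @return A `rating_table`.
#' @export
load_ratings <- function(path, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("load_ratings: no such file: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  rating_table(df)
}

#' Aggregate ratings to condition-level means
#'
#' Means are taken over subjects per (condition, talker); with
#' `average_across_talkers = TRUE` a further mean over talkers per
#' condition is returned.
#'
#' @param table A `rating_table`.
#' @param group Optional group filter (value of the `group` column).
#' @param average_across_talkers Logical.
#' @return Data frame with columns `condition` (, `talker`) and
#'   `mean_rating`.
#' @export
aggregate_ratings <- function(table, group = NULL,
                              average_across_talkers = FALSE) {
  df <- as.data.frame(table)
  if (!is.null(group)) df <- df[df$group %in% group, , drop = FALSE]
  if (nrow(df) == 0) stop("aggregate_ratings: no rows for the requested group")
  by_ct <- stats::aggregate(rating ~ condition + talker, data = df, FUN = mean)
  names(by_ct)[names(by_ct) == "rating"] <- "mean_rating"
  if (!average_across_talkers) return(by_ct)
  by_c <- stats::aggregate(mean_rating ~ condition, data = by_ct, FUN = mean)
  by_c
}

#' Pearson and Spearman correlation of paired prediction/rating vectors
#'
#' Values are matched by name; no transformation is applied to the
#' predictions.  Spearman uses average ranks for ties.
#'
#' @param predictions,means Named numeric vectors with matching keys
#'   (>= 3 shared keys required).
#' @return List with `pearson_r`, `spearman_rs`, `n`.
#' @export
correlate_scores <- function(predictions, means) {
  keys <- intersect(names(predictions), names(means))
  if (length(keys) < 3)
    stop("correlate_scores: need at least 3 paired points")
  p <- predictions[keys]; m <- means[keys]
  if (stats::sd(p) == 0 || stats::sd(m) == 0)
    stop("correlate_scores: constant vector")
  list(pearson_r = stats::cor(p, m, method = "pearson"),
       spearman_rs = stats::cor(p, m, method = "spearman"),
       n = length(keys))
}

#' Compute objective scores for a manifest of stimulus pairs
#'
#' The manifest is a data frame with columns `condition`, `talker` and
#' either `ref` / `test` (in-memory [audio_signal()]s in list columns) or
#' `ref_path` / `test_path` (WAV files).  Every configured measure is
#' computed on every pair.  Internal representations are cached per
#' (signal, filterbank, mode, hearing) so option variants reuse them.
#'
#' @param manifest The manifest data frame.
#' @param measures A data frame of measure configurations as produced by
#'   [standard_measure_set()], or a subset of it.
#' @param hearing An [audiogram()] used by the HI variants.
#' @param level_db Presentation level in dB SPL.
#' @param working_rate_hz Internal model rate.
#' @param verbose Print progress.
#' @return Long data frame: `condition`, `talker`, `measure`, `score`.
#' @export
compute_scores <- function(manifest, measures = standard_measure_set(),
                           hearing = example_audiogram(), level_db = 65,
                           working_rate_hz = 22050, verbose = FALSE) {
  get_sig <- function(row, which) {
    if (!is.null(manifest[[which]])) {
      manifest[[which]][[row]]
    } else {
      read_wav(manifest[[paste0(which, "_path")]][row])
    }
  }
  out <- list()
  for (i in seq_len(nrow(manifest))) {
    test <- get_sig(i, "test")
    ref <- get_sig(i, "ref")
    test <- resample_signal(test, working_rate_hz)
    ref <- resample_signal(ref, working_rate_hz)
    al <- align_and_scale(test, ref)
    ref_l <- set_level(al$ref, level_db)
    test_l <- set_level(al$test, level_db)
    ir_cache <- new.env(parent = emptyenv())
    get_ir <- function(sig, tag, family, mode, hi) {
      key <- paste(tag, family, mode, hi, sep = "|")
      if (!exists(key, ir_cache)) {
        fb <- measure_filterbank(family, working_rate_hz)
        ag <- if (hi) hearing else NULL
        assign(key, compute_internal_representation(sig, fb, ag, mode),
               ir_cache)
      }
      get(key, ir_cache)
    }
    for (j in seq_len(nrow(measures))) {
      mj <- measures[j, ]
      if (mj$family %in% c("psm", "qc")) {
        opts <- quality_options(mj$mode, mj$weighting, mj$assimilation,
                                if (mj$hi) hearing else NULL)
        ir_r <- get_ir(ref_l, "ref", mj$family, mj$mode, mj$hi)
        ir_t <- get_ir(test_l, "test", mj$family, mj$mode, mj$hi)
        sc <- qc(ir_t, ir_r, opts)
      } else {
        sc <- lpc_distance(test, ref, mj$family)
      }
      out[[length(out) + 1L]] <- data.frame(
        condition = manifest$condition[i], talker = manifest$talker[i],
        measure = mj$label, score = sc, stringsAsFactors = FALSE)
    }
    if (verbose)
      message(sprintf("scored %s / %s", manifest$condition[i],
                      manifest$talker[i]))
  }
  do.call(rbind, out)
}

#' The standard measure set
#'
#' The sixteen perception-model variants (qc with and without band
#' weighting and assimilation, PSM in lowpass and filterbank modulation
#' modes with and without assimilation, each in normal-hearing and
#' hearing-impaired versions) plus the four LPC-domain distances.
#'
#' @param include_lpc Include the LPC distances.
#' @return Data frame with columns `label`, `family`, `mode`,
#'   `weighting`, `assimilation`, `hi`.
#' @export
standard_measure_set <- function(include_lpc = TRUE) {
  rows <- list()
  for (hi in c(FALSE, TRUE)) {
    suf <- if (hi) " (HI)" else ""
    for (w in c(TRUE, FALSE)) for (b in c(TRUE, FALSE)) {
      lbl <- sprintf("qc%sW%sB%s", if (w) "+" else "-", if (b) "+" else "-",
                     suf)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lbl, family = "qc", mode = "lp", weighting = w,
        assimilation = b, hi = hi, stringsAsFactors = FALSE)
    }
    for (mode in c("fb", "lp")) for (b in c(TRUE, FALSE)) {
      lbl <- sprintf("PSM_%s%sB%s", mode, if (b) "+" else "-", suf)
      rows[[length(rows) + 1L]] <- data.frame(
        label = lbl, family = "psm", mode = mode, weighting = FALSE,
        assimilation = b, hi = hi, stringsAsFactors = FALSE)
    }
  }
  if (include_lpc) {
    for (m in c("isd", "lar", "llr", "wssd")) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = toupper(m), family = m, mode = "lp", weighting = FALSE,
        assimilation = FALSE, hi = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full benchmark: objective scores vs. subjective ratings
#'
#' Computes every configured measure on every stimulus pair of the
#' manifest, aggregates the ratings per (condition, talker) and per
#' condition (averaged across talkers), and correlates predictions with
#' mean ratings at both levels.  (Condition, talker) cells missing from
#' either side are dropped pairwise with a message.
#'
#' @param manifest Stimulus manifest (see [compute_scores()]).
#' @param ratings A `rating_table`.
#' @param group Optional subject-group filter for the ratings.
#' @param measures Measure configuration data frame.
#' @param ... Passed to [compute_scores()].
#' @return List of class `evaluation_result`: `correlations` (data frame
#'   with `measure`, `level` = `ind`/`av`, `pearson_r`, `spearman_rs`,
#'   `n`), `scores`, `points` (paired prediction/rating points).
#' @export
run_benchmark <- function(manifest, ratings, group = NULL,
                          measures = standard_measure_set(), ...) {
  need <- unique(paste(ratings$condition, ratings$talker, sep = "/"))
  have <- unique(paste(manifest$condition, manifest$talker, sep = "/"))
  missing_keys <- setdiff(need, have)
  if (length(missing_keys) > 0)
    message(sprintf("run_benchmark: dropping %d rated cell(s) without stimuli: %s",
                    length(missing_keys), paste(missing_keys, collapse = ", ")))
  scores <- compute_scores(manifest, measures, ...)
  by_ct <- aggregate_ratings(ratings, group, average_across_talkers = FALSE)
  by_c <- aggregate_ratings(ratings, group, average_across_talkers = TRUE)
  rows <- list(); pts <- list()
  for (lbl in unique(scores$measure)) {
    sm <- scores[scores$measure == lbl & !is.na(scores$score), ]
    # individual-talker level: pool (condition, talker) points
    pred_ind <- stats::setNames(sm$score, paste(sm$condition, sm$talker,
                                                sep = "/"))
    rate_ind <- stats::setNames(by_ct$mean_rating,
                                paste(by_ct$condition, by_ct$talker,
                                      sep = "/"))
    # talker-averaged level
    pc <- stats::aggregate(score ~ condition, data = sm, FUN = mean)
    pred_av <- stats::setNames(pc$score, pc$condition)
    rate_av <- stats::setNames(by_c$mean_rating, by_c$condition)
    for (lev in c("ind", "av")) {
      pr <- if (lev == "ind") pred_ind else pred_av
      ra <- if (lev == "ind") rate_ind else rate_av
      cc <- correlate_scores(pr, ra)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = lbl, level = lev, pearson_r = cc$pearson_r,
        spearman_rs = cc$spearman_rs, n = cc$n, stringsAsFactors = FALSE)
      keys <- intersect(names(pr), names(ra))
      pts[[length(pts) + 1L]] <- data.frame(
        measure = lbl, level = lev, key = keys,
        prediction = unname(pr[keys]), mean_rating = unname(ra[keys]),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(correlations = do.call(rbind, rows),
                 scores = scores,
                 points = do.call(rbind, pts)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("benchmark correlations (prediction vs. mean MUSHRA rating):\n")
  tab <- x$correlations
  tab$pearson_r <- round(tab$pearson_r, 3)
  tab$spearman_rs <- round(tab$spearman_rs, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
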