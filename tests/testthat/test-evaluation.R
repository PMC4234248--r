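make_table <- function() {
  df <- expand.grid(subject = c("s1", "s2"), condition = c("ref", "lp", "cl"),
                    talker = c("m1", "f1"), stringsAsFactors = FALSE)
  df$group <- "NH"
  df$rating <- c(90, 80, 40, 30, 20, 25, 95, 85, 35, 45, 15, 20)
  rating_table(df)
}

test_that("rating tables are validated on load", {
  tab <- make_table()
  path <- tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(tab), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  got <- load_ratings(path)
  expect_s3_class(got, "rating_table")
  expect_equal(nrow(got), 12)
  unlink(path)

  bad <- as.data.frame(tab)
  bad$rating[4] <- 101
  expect_error(rating_table(bad), "row\\(s\\) 4")
  dup <- rbind(as.data.frame(tab), as.data.frame(tab)[1, ])
  expect_error(rating_table(dup), "duplicated")
  expect_error(rating_table(data.frame(subject = 1)), "missing columns")
})

test_that("aggregation averages subjects and optionally talkers", {
  tab <- make_table()
  by_ct <- aggregate_ratings(tab)
  expect_equal(nrow(by_ct), 6)                      # 3 conditions x 2 talkers
  # two subjects rating 90 and 80 -> mean 85
  expect_equal(by_ct$mean_rating[by_ct$condition == "ref" &
                                 by_ct$talker == "m1"], 85)
  by_c <- aggregate_ratings(tab, average_across_talkers = TRUE)
  expect_equal(nrow(by_c), 3)
  expect_equal(by_c$mean_rating[by_c$condition == "ref"], (85 + 90) / 2)
  # single-subject, single-talker table: means equal raw ratings
  one <- rating_table(data.frame(subject = "s1", group = "NH",
                                 condition = c("a", "b"), talker = "t",
                                 rating = c(10, 20)))
  expect_equal(aggregate_ratings(one)$mean_rating, c(10, 20))
  expect_error(aggregate_ratings(tab, group = "XX"), "no rows")
})

test_that("correlation matches hand formulas on a 5-point example", {
  p <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  m <- c(a = 10, b = 14, c = 11, d = 20, e = 25)
  cc <- correlate_scores(p, m)
  # brute-force Pearson
  brute <- sum((p - mean(p)) * (m - mean(m))) /
    sqrt(sum((p - mean(p))^2) * sum((m - mean(m))^2))
  expect_equal(cc$pearson_r, brute)
  # Spearman from ranks by hand: ranks of m are 1,3,2,4,5
  rm_ <- c(1, 3, 2, 4, 5); rp <- 1:5
  brute_s <- 1 - 6 * sum((rp - rm_)^2) / (5 * 24)
  expect_equal(cc$spearman_rs, brute_s)
  # identity and reversal
  expect_equal(correlate_scores(p, p * 3 + 1)$pearson_r, 1)
  expect_equal(correlate_scores(p, setNames(rev(p), names(p)))$spearman_rs, -1)
  expect_error(correlate_scores(p[1:2], m[1:2]), "at least 3")
  expect_error(correlate_scores(setNames(rep(1, 5), names(p)), m), "constant")
})

test_that("correlations are invariant to affine rescaling of the rating scale", {
  set.seed(61)
  p <- setNames(stats::runif(8), letters[1:8])
  m <- setNames(stats::runif(8) * 100, letters[1:8])
  c1 <- correlate_scores(p, m)
  c2 <- correlate_scores(p, m * 0.3 + 12)
  expect_equal(c1$pearson_r, c2$pearson_r)
  expect_equal(c1$spearman_rs, c2$spearman_rs)
  # rs invariant to monotone transform of predictions
  c3 <- correlate_scores(exp(3 * p), m)
  expect_equal(c1$spearman_rs, c3$spearman_rs)
})

test_that("benchmark is self-consistent when ratings follow the measure", {
  sp <- speech_fixture(duration_s = 0.5)
  conds <- list(ref = sp,
                mid = nfc_process(sp, nfc_settings(3000, 6)),
                low = clip_anchor(sp))
  manifest <- data.frame(condition = names(conds), talker = "t1",
                         stringsAsFactors = FALSE)
  manifest$ref <- list(sp, sp, sp)
  manifest$test <- conds
  measures <- standard_measure_set(include_lpc = FALSE)
  measures <- measures[measures$label == "PSM_lp-B", ]
  scores <- compute_scores(manifest, measures)
  # ratings defined as a strictly increasing function of the scores
  ratings <- make_synthetic_ratings(
    data.frame(condition = scores$condition, talker = scores$talker,
               score = scores$score), n_subjects = 3, noise_sd = 0)
  res <- run_benchmark(manifest, ratings, measures = measures)
  ind <- res$correlations[res$correlations$level == "ind", ]
  expect_equal(ind$spearman_rs, 1)
  expect_gt(ind$pearson_r, 0.99)
})

test_that("benchmark drops missing stimulus cells pairwise with a message", {
  sp <- speech_fixture(duration_s = 0.5)
  manifest <- data.frame(condition = c("ref", "cl"), talker = "t1",
                         stringsAsFactors = FALSE)
  manifest$ref <- list(sp, sp)
  manifest$test <- list(sp, clip_anchor(sp))
  df <- expand.grid(subject = c("s1", "s2"),
                    condition = c("ref", "cl", "lp"), talker = "t1",
                    stringsAsFactors = FALSE)
  df$group <- "NH"; df$rating <- c(90, 95, 20, 25, 40, 45)
  ratings <- rating_table(df)
  measures <- standard_measure_set(include_lpc = FALSE)
  measures <- measures[measures$label == "PSM_lp-B", ]
  # 2 stimulus cells vs 3 rated cells -> message, and correlation would
  # need >= 3 points so it errors cleanly
  expect_message(
    expect_error(run_benchmark(manifest, ratings, measures = measures),
                 "at least 3"),
    "dropping")
})
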