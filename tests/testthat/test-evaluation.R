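test_that("spearman_rho handles monotone transforms, ties and degenerate input", {
  expect_equal(spearman_rho(1:10, 1:10), 1)
  expect_equal(spearman_rho(1:10, 10:1), -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(spearman_rho(x, exp(x)), 1) # monotone-invariance
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(10, 20, 30, 40)),
               naive_spearman(c(1, 2, 2, 4), c(10, 20, 30, 40)))
  set.seed(301)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    x <- sample(0:10, n, replace = TRUE)
    y <- sample(0:10, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_rho(x, y), naive_spearman(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("per-speaker rho averages speakers, not rows", {
  pt <- data.frame(
    subject_id = rep(c("A", "B"), each = 5),
    y_true = c(1:5, 1:5),
    y_pred = c(1:5, 5:1),
    fold = 1
  )
  res <- per_speaker_rho(pt)
  expect_equal(res$mean_rho, 0) # one perfect, one reversed
  # duplicating one speaker's rows must not change the mean
  pt_dup <- rbind(pt, pt[pt$subject_id == "A", ])
  expect_equal(per_speaker_rho(pt_dup)$mean_rho, 0)
  # perfect predictions everywhere
  pt2 <- pt; pt2$y_pred <- pt2$y_true
  expect_equal(per_speaker_rho(pt2)$mean_rho, 1)
})

test_that("speakers with undefined rho are excluded and reported", {
  pt <- data.frame(
    subject_id = rep(c("A", "B", "C"), each = 4),
    y_true = c(1:4, rep(2, 4), 1:4),
    y_pred = c(1:4, 1:4, rep(3, 4)),
    fold = 1
  )
  res <- per_speaker_rho(pt)
  expect_setequal(res$excluded$subject_id, c("B", "C"))
  expect_equal(res$per_speaker$subject_id, "A")
  res0 <- per_speaker_rho(pt, undefined_as_zero = TRUE)
  expect_equal(res0$mean_rho, 1 / 3)
  all_flat <- data.frame(subject_id = "B", y_true = rep(1, 3), y_pred = 1:3,
                         fold = 1)
  expect_error(per_speaker_rho(all_flat), "every speaker")
})

test_that("null predictions give mean per-speaker rho near zero", {
  set.seed(302)
  n_spk <- 50; n_ses <- 42
  pt <- data.frame(
    subject_id = rep(sprintf("S%02d", 1:n_spk), each = n_ses),
    y_true = as.vector(replicate(n_spk, sample(0:10, n_ses, replace = TRUE))),
    y_pred = rnorm(n_spk * n_ses),
    fold = 1
  )
  res <- per_speaker_rho(pt)
  se <- 1 / sqrt(n_ses - 1) / sqrt(n_spk)
  expect_lt(abs(res$mean_rho), 3 * se)
})

test_that("global MAE matches brute-force recomputation per fold", {
  pt <- data.frame(subject_id = "A", y_true = c(0, 10), y_pred = c(5, 5),
                   fold = 1)
  expect_equal(global_mae(pt)$mean, 5)
  pt2 <- pt; pt2$y_pred <- pt2$y_true
  expect_equal(global_mae(pt2)$mean, 0)
  set.seed(303)
  pt3 <- data.frame(subject_id = "A", y_true = runif(100, 0, 10),
                    y_pred = runif(100, 0, 10),
                    fold = rep(1:4, each = 25))
  res <- global_mae(pt3)
  for (f in 1:4) {
    rows <- pt3$fold == f
    expect_equal(res$per_fold$mae[res$per_fold$fold == f],
                 naive_mae(pt3$y_true[rows], pt3$y_pred[rows]))
  }
  expect_equal(res$mean, mean(res$per_fold$mae))
})

test_that("gini index matches closed forms and the brute-force double sum", {
  expect_equal(gini_index(c(2, 2, 2, 2)), 0)
  expect_equal(gini_index(c(0, 1)), 0.5)
  set.seed(304)
  for (i in 1:100) {
    v <- runif(sample(2:20, 1), 0.01, 2)
    expect_equal(gini_index(v), naive_gini(v), tolerance = 1e-10)
  }
  # scale invariance, translation variance
  v <- runif(10, 0.1, 1)
  expect_equal(gini_index(3 * v), gini_index(v), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(gini_index(v + 1), gini_index(v))))
  # non-positive mean: standard formula refused, clip variant works
  neg <- c(-1, -2, 0.5)
  expect_error(gini_index(neg), "not positive")
  expect_equal(gini_index(neg, clip_negative = TRUE), naive_gini(c(0, 0, 0.5)))
})

test_that("winners and losers are counted by strict comparison", {
  b <- c(A = 0.2, B = 0.5, C = -0.1)
  expect_equal(winners_losers(b, b)$winners, 0)
  expect_equal(winners_losers(b, b)$losers, 0)
  expect_equal(winners_losers(b, b)$unchanged, 3)
  up <- winners_losers(b, b + 0.1)
  expect_equal(up$winners, 3)
  expect_equal(up$losers, 0)
  # constructed 3-speaker case against hand enumeration
  p <- c(A = 0.4, B = 0.4, C = -0.1)
  wl <- winners_losers(b, p)
  expect_equal(wl$winners, 1) # A: 0.2 -> 0.4
  expect_equal(wl$losers, 1) # B: 0.5 -> 0.4
  expect_equal(wl$unchanged, 1) # C unchanged
  expect_equal(wl$winner_mean_pct, 100) # (0.4-0.2)/0.2
  expect_equal(wl$loser_mean_pct, -20) # (0.4-0.5)/0.5
  # small-denominator fallback is flagged
  b2 <- c(A = 0.001, B = 0.5)
  wl2 <- winners_losers(b2, b2 + c(0.2, 0.1))
  expect_equal(wl2$fallback_speakers, "A")
  expect_error(winners_losers(c(A = 1, B = 2), c(A = 1, C = 2)), "misaligned")
})

test_that("prediction-questionnaire correlations behave at the extremes", {
  cohort <- tiny_cohort(4, seed = 61)
  tot <- questionnaire_summaries(cohort)
  pt <- data.frame(
    subject_id = rep(cohort$subject_id, each = 6),
    y_true = sample(0:10, nrow(cohort) * 6, replace = TRUE),
    fold = 1
  )
  pt$y_pred <- tot$phq9_total[match(pt$subject_id, tot$subject_id)]
  mc <- metadata_correlations(pt, cohort)
  expect_equal(mc["prediction", "phq"], 1)
  set.seed(62)
  pt$y_pred <- rnorm(nrow(pt))
  mc2 <- metadata_correlations(pt, cohort)
  expect_lt(abs(mc2["prediction", "phq"]), 0.35)
})

test_that("evaluation reports are reproducible byte for byte", {
  set.seed(305)
  cohort <- tiny_cohort(3, seed = 63)
  pt <- data.frame(
    subject_id = rep(cohort$subject_id, each = 8),
    day = 1, slot = "morning", session_index = rep(1:8, nrow(cohort)),
    content = rep(c("question", "answer", "positive_thought", "answer"),
                  2 * nrow(cohort)),
    repetition = 1,
    y_true = sample(0:10, nrow(cohort) * 8, replace = TRUE),
    y_pred = rnorm(nrow(cohort) * 8, 5, 2),
    fold = rep(1:2, each = 4 * nrow(cohort))
  )
  rep1 <- evaluate_predictions(pt, cohort)
  rep2 <- evaluate_predictions(pt, cohort)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, p1)
  write_report_json(rep2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # structure sanity
  expect_true(all(c("mae", "speaker_rho", "by_group", "by_content") %in%
                    names(rep1)))
  expect_true(all(names(rep1$by_content) %in%
                    c("question", "answer", "positive_thought")))
})
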