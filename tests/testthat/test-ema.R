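test_that("schedule arithmetic matches the protocol before missingness", {
  subject <- tiny_cohort(1)[1, ]
  cfg <- schedule_config(missingness_by_group = c(0, 0, 0))
  sch <- build_schedule(subject, cfg)
  expect_equal(nrow(sch$sessions), 42L)
  expect_equal(nrow(sch$recordings), 378L)
  # 9 recordings per non-missing session, 3 content types x 3 repetitions
  per_session <- table(sch$recordings$session_index)
  expect_true(all(per_session == 9L))
  expect_equal(sort(unique(sch$recordings$content)),
               sort(c("question", "answer", "positive_thought")))
  # totals scale linearly in days / slots / repetitions
  sch2 <- build_schedule(subject, schedule_config(n_days = 7, slots_per_day = 2,
                                                  recordings_per_content = 1,
                                                  missingness_by_group = c(0, 0, 0)))
  expect_equal(nrow(sch2$sessions), 14L)
  expect_equal(nrow(sch2$recordings), 14L * 3L)
})

test_that("missingness drops whole sessions; probability one leaves none", {
  subject <- tiny_cohort(1)[1, ]
  sch <- build_schedule(subject, schedule_config(missingness_by_group = c(1, 1, 1)))
  expect_equal(nrow(sch$sessions), 42L)
  expect_true(all(sch$sessions$missing))
  expect_equal(nrow(sch$recordings), 0L)
  # recordings only reference non-missing sessions at intermediate rates
  sch2 <- build_schedule(subject, schedule_config(seed = 2))
  expect_true(all(sch2$recordings$session_index %in%
                    sch2$sessions$session_index[!sch2$sessions$missing]))
})

test_that("mood ratings are clamped integers with the configured dynamics", {
  cohort <- tiny_cohort(2, seed = 4)
  subject <- cohort[1, ]
  sch <- build_schedule(subject, schedule_config(missingness_by_group = c(0, 0, 0)))
  sess <- sample_mood(subject, sch$sessions, mood_config(seed = 4))
  expect_true(all(sess$mood >= 0 & sess$mood <= 10))
  expect_true(all(sess$mood == round(sess$mood)))

  # severity at the floor with zero noise: clamped to all zeros
  low <- subject; low$severity <- -100
  sess_low <- sample_mood(low, sch$sessions,
                          mood_config(subject_sd = 0, ar_sd = 0, noise_sd = 0))
  expect_true(all(sess_low$mood == 0))

  # no persistence, no noise: constant mood per subject
  sess_const <- sample_mood(subject, sch$sessions,
                            mood_config(phi = 0, ar_sd = 0, noise_sd = 0,
                                        subject_sd = 0.5, seed = 4))
  expect_equal(length(unique(sess_const$mood)), 1L)
})

test_that("group mood marginals order stochastically at defaults", {
  cohort <- generate_cohort(cohort_config(seed = 6))
  ema <- generate_ema(cohort, schedule_config(seed = 6), mood_config(seed = 6),
                      feature_model(seed = 6))
  g <- cohort$group[match(ema$sessions$subject_id, cohort$subject_id)]
  mu <- tapply(ema$sessions$mood, g, mean, na.rm = TRUE)
  expect_lt(mu[["control"]], mu[["subclinical"]])
  expect_lt(mu[["subclinical"]], mu[["patient"]])
  med <- tapply(ema$sessions$mood, g, median, na.rm = TRUE)
  expect_lte(med[["control"]], med[["subclinical"]])
  expect_lte(med[["subclinical"]], med[["patient"]])
})

test_that("per-subject mean mood correlates with PHQ total in the target band", {
  cohort <- generate_cohort(cohort_config(seed = 8))
  ema <- generate_ema(cohort, schedule_config(seed = 8), mood_config(seed = 8),
                      feature_model(seed = 8))
  tot <- questionnaire_summaries(cohort)
  mm <- tapply(ema$sessions$mood, ema$sessions$subject_id, mean, na.rm = TRUE)
  rho <- cor(mm[cohort$subject_id], tot$phq9_total, method = "spearman")
  expect_gt(rho, 0.5)
  expect_lt(rho, 0.85)
})

test_that("features error on missing moods and couple with configured signs", {
  cohort <- tiny_cohort(2, seed = 12)
  subject <- cohort[1, ]
  sch <- build_schedule(subject, schedule_config(missingness_by_group = c(0, 0, 0)))
  sess <- sch$sessions # moods not sampled yet
  expect_error(sample_features(sch$recordings, sess, subject),
               "without an observed mood")
})

test_that("zero coupling yields no feature-mood association", {
  cohort <- generate_cohort(cohort_config(n_control = 8, n_subclinical = 8,
                                          n_patients = 8, seed = 13))
  fm0 <- feature_model(beta = c(f0_mean = 0, hnr = 0, jitter = 0, shimmer = 0,
                                nsyll = 0, npause = 0, duration = 0,
                                speech_rate = 0), seed = 13)
  ema <- generate_ema(cohort, schedule_config(seed = 13), mood_config(seed = 13),
                      fm0)
  est <- estimate_feature_mood_coupling(ema$recordings)
  expect_true(all(abs(est$slope) < 4 * est$se))
})

test_that("question content with zero gain carries no mood signal", {
  cohort <- generate_cohort(cohort_config(n_control = 8, n_subclinical = 8,
                                          n_patients = 8, seed = 14))
  fm <- feature_model(question_feature_gain = c(
    f0_mean = 0, hnr = 0, jitter = 0, shimmer = 0, nsyll = 0, npause = 0,
    duration = 0, speech_rate = 0), seed = 14)
  ema <- generate_ema(cohort, schedule_config(seed = 14), mood_config(seed = 14),
                      fm)
  recs_q <- ema$recordings[ema$recordings$content == "question", ]
  est <- estimate_feature_mood_coupling(recs_q)
  expect_true(all(abs(est$slope) < 4 * est$se))
})

test_that("attenuation shrinks within-speaker slopes for high-PHQ subjects", {
  cohort <- generate_cohort(cohort_config(n_control = 25, n_subclinical = 25,
                                          n_patients = 25, seed = 15))
  ema <- generate_ema(cohort, schedule_config(seed = 15), mood_config(seed = 15),
                      feature_model(seed = 15))
  recs <- ema$recordings[ema$recordings$content == "answer", ]
  hi <- estimate_feature_mood_coupling(recs[recs$high_phq, ])
  lo <- estimate_feature_mood_coupling(recs[!recs$high_phq, ])
  strong <- c("f0_mean", "nsyll", "npause", "duration", "speech_rate")
  for (f in strong) {
    expect_lt(abs(hi$slope[hi$feature == f]), abs(lo$slope[lo$feature == f]),
              label = paste("attenuated slope for", f))
  }
})

test_that("frame matrices average back to the functional vector", {
  cohort <- tiny_cohort(1, seed = 16)
  ema <- tiny_ema(cohort, seed = 16)
  fm <- feature_model(seed = 16)
  fr <- recording_frames(ema$recordings, fm, n_frames = 200L)
  means <- apply(fr, c(1, 3), mean)
  vals <- as.matrix(ema$recordings[, fm$feature_names])
  # frame noise sd is frame_noise_sd * scale; the mean of 200 frames should
  # sit within ~4 standard errors for nearly every recording
  se <- matrix(fm$frame_noise_sd * fm$scale / sqrt(200), nrow(vals),
               ncol(vals), byrow = TRUE)
  expect_gt(mean(abs(means - vals) < 4 * se), 0.995)
})

test_that("coupling estimator is exact on constructed data and excludes flat speakers", {
  # feature that equals mood exactly gives slope 1 after within-speaker z-scoring
  recs <- data.frame(subject_id = rep(c("A", "B"), each = 20),
                     mood = c(1:20, 20:1))
  recs$f <- recs$mood
  est <- estimate_feature_mood_coupling(recs, features = "f", min_rows = 3)
  expect_equal(est$slope, 1, tolerance = 1e-12)

  # zero-variance speaker is excluded and reported
  recs2 <- rbind(recs,
                 data.frame(subject_id = "C", mood = rep(5, 10), f = rnorm(10)))
  est2 <- estimate_feature_mood_coupling(recs2, features = "f")
  expect_equal(attr(est2, "excluded"), "C")
  expect_error(estimate_feature_mood_coupling(
    data.frame(subject_id = "A", mood = 1:5, f = rnorm(5)), features = "f"),
    "two evaluable speakers")
})

test_that("EMA generation is deterministic and insertion-stable", {
  cohort <- tiny_cohort(2, seed = 21)
  a <- tiny_ema(cohort, seed = 21)
  b <- tiny_ema(cohort, seed = 21)
  expect_identical(a, b)
  # a subject's recordings do not depend on who else is in the cohort
  solo <- tiny_ema(cohort[1, ], seed = 21)
  joint_rows <- a$recordings[a$recordings$subject_id == cohort$subject_id[1], ]
  rownames(joint_rows) <- NULL
  expect_equal(joint_rows[, setdiff(names(joint_rows), "high_phq")],
               solo$recordings[, setdiff(names(solo$recordings), "high_phq")])
})
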