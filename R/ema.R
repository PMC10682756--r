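# Synthetic longitudinal EMA --------------------------------------------
#
# Emulates a 2-week ecological momentary assessment: three sessions per day
# (morning / noon / evening), each with 3 repetitions of 3 speech content
# types (question, answer, positive thought) and one 0-10 depressed-mood
# rating. Whole sessions go missing with a group-dependent probability.
# Acoustic-functional feature vectors couple to within-subject mood with
# configurable sign, content-dependent gain and severity-dependent
# attenuation.

#' EMA schedule configuration
#'
#' Defaults give each subject `14 x 3 = 42` sessions and
#' `(3 + 3 + 3) x 42 = 378` recordings. Default per-group missingness
#' rates are the emulated study's missing-session counts divided by the
#' per-group maxima (about 8.6%, 9.9% and 11.6% for control, subclinical
#' and patient groups).
#'
#' @param n_days Number of EMA days.
#' @param slots_per_day Sessions per day (morning, noon, evening).
#' @param recordings_per_content Repetitions of each content type per
#'   session.
#' @param content_types Ordered content types.
#' @param missingness_by_group Session-level Bernoulli missingness
#'   probabilities for (control, subclinical, patient).
#' @param seed Integer base seed for missingness draws.
#' @return A list of class `schedule_config`.
#' @export
schedule_config <- function(n_days = 14L, slots_per_day = 3L,
                            recordings_per_content = 3L,
                            content_types = c("question", "answer", "positive_thought"),
                            missingness_by_group = c(169 / 1974, 200 / 2016, 233 / 2016),
                            seed = 1L) {
  stop_if_not(all(missingness_by_group >= 0 & missingness_by_group <= 1),
              "missingness probabilities must lie in [0, 1]")
  structure(list(
    n_days = as.integer(n_days),
    slots_per_day = as.integer(slots_per_day),
    recordings_per_content = as.integer(recordings_per_content),
    content_types = content_types,
    missingness_by_group = missingness_by_group,
    seed = as.integer(seed)
  ), class = "schedule_config")
}

slot_names <- function(n) {
  base <- c("morning", "noon", "evening")
  if (n <= 3L) base[seq_len(n)] else c(base, paste0("slot", 4:n))[seq_len(n)]
}

#' Mood process configuration
#'
#' Session moods follow
#' `mood_t = clamp(round(mu_S + ar_t + eps_t), 0, 10)` where `mu_S` is an
#' affine function of the subject's latent severity plus a subject-level
#' disturbance, `ar_t` an AR(1) process over session index and `eps_t`
#' white noise. The affine map and noise scales were calibrated once so
#' that group mood medians order control < subclinical < patient and the
#' cohort-level Spearman correlation between mean mood and PHQ-9 total
#' lands near 0.7.
#'
#' @param intercept,slope Affine map from severity to the subject's mean
#'   mood (0-10 scale).
#' @param subject_sd SD of the subject-level mean-mood disturbance
#'   (independent of severity, hence of the questionnaires).
#' @param phi AR(1) persistence of session-to-session mood.
#' @param ar_sd Stationary SD of the AR(1) component.
#' @param noise_sd SD of the white-noise component.
#' @param seed Integer base seed.
#' @return A list of class `mood_config`.
#' @export
mood_config <- function(intercept = 1.8, slope = 2.2, subject_sd = 2.4,
                        phi = 0.5, ar_sd = 1.0, noise_sd = 0.6, seed = 1L) {
  stop_if_not(abs(phi) < 1, "phi must lie in (-1, 1)")
  structure(list(intercept = intercept, slope = slope, subject_sd = subject_sd,
                 phi = phi, ar_sd = ar_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "mood_config")
}

#' Acoustic feature model
#'
#' Eight acoustic-functional features couple to the subject's
#' within-subject standardized mood `z`:
#' `feature_k = base_k + scale_k * (intercept_Sk + sign_k * gain[content, k]
#'  * atten_k(S) * beta_k * z + noise)`.
#' `beta_k` is the standardized effect size (in units of the unit-variance
#' recording noise), so the pooled within-speaker standardized slope of a
#' feature approaches `sign_k * gain * beta_k` for moderate effects.
#'
#' Defaults encode: lower F0, more syllables and pauses, longer duration
#' and slower speech rate with worse mood; voice-quality perturbations
#' (HNR, jitter, shimmer) only weakly coupled. The content gain orders
#' answer > positive thought > question, except that the (read-aloud)
#' question content retains most of its F0 coupling while carrying almost
#' no timing signal. Subjects whose PHQ-9 total lies above the cohort
#' median have their coupling attenuated per feature (most strongly for
#' F0) on the freely spoken contents only.
#'
#' @param feature_names Feature vector names.
#' @param coupling_signs Named vector in `{-1, +1}`.
#' @param beta Named standardized effect sizes (>= 0).
#' @param content_gain Named per-content scalar gains; must be
#'   non-increasing over (answer, positive_thought, question).
#' @param question_feature_gain Named per-feature gain overriding the
#'   scalar gain for the question content.
#' @param severity_attenuation Named per-feature multipliers in `(0, 1]`
#'   applied to above-median-PHQ subjects.
#' @param attenuate_contents Contents the attenuation applies to.
#' @param base,scale Location and unit scale of each feature.
#' @param intercept_sd Per-subject random-intercept SD (in `scale` units).
#' @param noise_sd Recording-level noise SD (in `scale` units).
#' @param frame_noise_sd Frame-level noise SD for sequence mode.
#' @param seed Integer base seed.
#' @return A list of class `feature_model`.
#' @export
feature_model <- function(
    feature_names = c("f0_mean", "hnr", "jitter", "shimmer",
                      "nsyll", "npause", "duration", "speech_rate"),
    coupling_signs = c(f0_mean = -1, hnr = -1, jitter = 1, shimmer = 1,
                       nsyll = 1, npause = 1, duration = 1, speech_rate = -1),
    beta = c(f0_mean = 0.38, hnr = 0.08, jitter = 0.08, shimmer = 0.08,
             nsyll = 0.30, npause = 0.30, duration = 0.32, speech_rate = 0.30),
    content_gain = c(answer = 1.0, positive_thought = 0.65, question = 0.3),
    question_feature_gain = c(f0_mean = 0.65, hnr = 0.3, jitter = 0.3,
                              shimmer = 0.3, nsyll = 0.05, npause = 0.05,
                              duration = 0.05, speech_rate = 0.05),
    severity_attenuation = c(f0_mean = 0.25, hnr = 0.7, jitter = 0.7,
                             shimmer = 0.7, nsyll = 0.5, npause = 0.5,
                             duration = 0.5, speech_rate = 0.5),
    attenuate_contents = c("answer", "positive_thought"),
    base = c(f0_mean = 180, hnr = 12, jitter = 1.5, shimmer = 8,
             nsyll = 35, npause = 6, duration = 12, speech_rate = 3.2),
    scale = c(f0_mean = 25, hnr = 2.5, jitter = 0.4, shimmer = 1.5,
              nsyll = 8, npause = 2.5, duration = 3.5, speech_rate = 0.5),
    intercept_sd = 1.0, noise_sd = 1.0, frame_noise_sd = 0.5,
    seed = 1L) {
  stop_if_not(content_gain["answer"] >= content_gain["positive_thought"] &&
                content_gain["positive_thought"] >= content_gain["question"],
              "content gains must order answer >= positive_thought >= question")
  stop_if_not(all(severity_attenuation > 0 & severity_attenuation <= 1),
              "severity_attenuation entries must lie in (0, 1]")
  stop_if_not(all(coupling_signs %in% c(-1, 1)), "coupling signs must be +/-1")
  for (v in c("coupling_signs", "beta", "question_feature_gain",
              "severity_attenuation", "base", "scale")) {
    stop_if_not(all(feature_names %in% names(get(v))),
                paste(v, "must name every feature"))
  }
  structure(list(
    feature_names = feature_names,
    coupling_signs = coupling_signs[feature_names],
    beta = beta[feature_names],
    content_gain = content_gain,
    question_feature_gain = question_feature_gain[feature_names],
    severity_attenuation = severity_attenuation[feature_names],
    attenuate_contents = attenuate_contents,
    base = base[feature_names], scale = scale[feature_names],
    intercept_sd = intercept_sd, noise_sd = noise_sd,
    frame_noise_sd = frame_noise_sd, seed = as.integer(seed)
  ), class = "feature_model")
}

# Effective per-content x per-feature gain matrix. The question content
# carries a per-feature override (F0 retained, timing nearly silent).
gain_matrix <- function(fm) {
  K <- length(fm$feature_names)
  contents <- names(fm$content_gain)
  g <- do.call(rbind, lapply(contents, function(ct) {
    if (ct == "question") as.numeric(fm$question_feature_gain)
    else rep(fm$content_gain[[ct]], K)
  }))
  dimnames(g) <- list(contents, fm$feature_names)
  g
}

#' Build one subject's EMA schedule
#'
#' Before missingness, a subject has exactly
#' `n_days * slots_per_day` sessions and
#' `length(content_types) * recordings_per_content` recordings per
#' session. Missingness independently drops whole sessions with the
#' subject's group probability; recordings of missing sessions are never
#' materialized.
#'
#' @param subject One cohort row (needs `subject_id` and `group`).
#' @param cfg A [schedule_config()].
#' @return A list with `sessions` (one row per scheduled session, with a
#'   `missing` flag and an empty `mood` column) and `recordings`
#'   (skeleton rows for non-missing sessions).
#' @export
build_schedule <- function(subject, cfg = schedule_config()) {
  stop_if_not(inherits(cfg, "schedule_config"), "cfg must be a schedule_config")
  n_sessions <- cfg$n_days * cfg$slots_per_day
  slots <- slot_names(cfg$slots_per_day)
  sessions <- data.frame(
    subject_id = rep(subject$subject_id, n_sessions),
    day = rep(seq_len(cfg$n_days), each = cfg$slots_per_day),
    slot = rep(slots, times = cfg$n_days),
    session_index = seq_len(n_sessions),
    stringsAsFactors = FALSE
  )
  p_miss <- cfg$missingness_by_group[
    match(subject$group, c("control", "subclinical", "patient"))]
  sessions$missing <- with_local_seed(
    substream_seed(cfg$seed, "missing", subject$subject_id),
    stats::runif(n_sessions) < p_miss
  )
  sessions$mood <- NA_integer_

  kept <- sessions[!sessions$missing, , drop = FALSE]
  n_per_session <- length(cfg$content_types) * cfg$recordings_per_content
  if (nrow(kept) == 0L || n_per_session == 0L) {
    recordings <- data.frame(subject_id = character(0), day = integer(0),
                             slot = character(0), session_index = integer(0),
                             content = character(0), repetition = integer(0),
                             stringsAsFactors = FALSE)
  } else {
    recordings <- data.frame(
      subject_id = rep(kept$subject_id, each = n_per_session),
      day = rep(kept$day, each = n_per_session),
      slot = rep(kept$slot, each = n_per_session),
      session_index = rep(kept$session_index, each = n_per_session),
      content = rep(rep(cfg$content_types, each = cfg$recordings_per_content),
                    times = nrow(kept)),
      repetition = rep(rep(seq_len(cfg$recordings_per_content),
                           times = length(cfg$content_types)),
                       times = nrow(kept)),
      stringsAsFactors = FALSE
    )
  }
  list(sessions = sessions, recordings = recordings)
}

#' Sample the session mood trajectory for one subject
#'
#' @param subject One cohort row (needs `subject_id` and `severity`).
#' @param sessions Sessions data.frame from [build_schedule()].
#' @param cfg A [mood_config()].
#' @return `sessions` with integer `mood` filled for non-missing sessions.
#' @export
sample_mood <- function(subject, sessions, cfg = mood_config()) {
  n <- nrow(sessions)
  with_local_seed(substream_seed(cfg$seed, "mood", subject$subject_id), {
    mu <- cfg$intercept + cfg$slope * subject$severity +
      stats::rnorm(1, 0, cfg$subject_sd)
    innov_sd <- cfg$ar_sd * sqrt(1 - cfg$phi^2)
    ar <- numeric(n)
    if (n > 0) {
      ar[1] <- stats::rnorm(1, 0, cfg$ar_sd)
      for (t in seq_len(n)[-1]) {
        ar[t] <- cfg$phi * ar[t - 1] + stats::rnorm(1, 0, innov_sd)
      }
    }
    eps <- stats::rnorm(n, 0, cfg$noise_sd)
    mood <- pmin(pmax(round(mu + ar + eps), 0), 10)
    sessions$mood <- ifelse(sessions$missing, NA_integer_, as.integer(mood))
  })
  sessions
}

# Within-subject standardized mood per session (0 if the subject's moods
# are constant).
standardize_mood <- function(mood) {
  s <- stats::sd(mood)
  if (!is.finite(s) || s == 0) return(rep(0, length(mood)))
  (mood - mean(mood)) / s
}

#' Sample acoustic-functional features for one subject's recordings
#'
#' Applies the [feature_model()] coupling equation to every recording row.
#' Every recording must belong to a session with an observed mood.
#'
#' @param recordings Recording skeleton rows from [build_schedule()].
#' @param sessions The subject's sessions with `mood` filled by
#'   [sample_mood()].
#' @param subject One cohort row.
#' @param fm A [feature_model()].
#' @param attenuate Logical: is this subject in the above-median-PHQ
#'   stratum (see [generate_ema()])?
#' @return `recordings` with a `mood` column and one numeric column per
#'   feature.
#' @export
sample_features <- function(recordings, sessions, subject, fm = feature_model(),
                            attenuate = FALSE) {
  mood_by_session <- sessions$mood[match(recordings$session_index,
                                         sessions$session_index)]
  stop_if_not(!anyNA(mood_by_session),
              "recordings reference sessions without an observed mood")
  obs <- sessions$mood[!sessions$missing]
  z_by_session <- standardize_mood(obs)
  z <- z_by_session[match(recordings$session_index,
                          sessions$session_index[!sessions$missing])]

  K <- length(fm$feature_names)
  n <- nrow(recordings)
  gm <- gain_matrix(fm)

  feat <- with_local_seed(substream_seed(fm$seed, "features", subject$subject_id), {
    intercepts <- stats::rnorm(K, 0, fm$intercept_sd)
    noise <- matrix(stats::rnorm(n * K, 0, fm$noise_sd), n, K)
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      g <- gm[recordings$content, k]
      a <- ifelse(attenuate & recordings$content %in% fm$attenuate_contents,
                  fm$severity_attenuation[k], 1)
      coupling <- fm$coupling_signs[k] * g * a * fm$beta[k] * z
      out[, k] <- fm$base[k] +
        fm$scale[k] * (intercepts[k] + coupling + noise[, k])
    }
    out
  })
  colnames(feat) <- fm$feature_names
  recordings$mood <- as.integer(mood_by_session)
  cbind(recordings, as.data.frame(feat))
}

#' Generate a full synthetic EMA dataset for a cohort
#'
#' Convenience wrapper running [build_schedule()], [sample_mood()] and
#' [sample_features()] for every subject. The above-median-PHQ stratum for
#' coupling attenuation is computed on the supplied cohort's PHQ-9 totals
#' (strictly above the median).
#'
#' @param cohort A cohort data.frame from [generate_cohort()].
#' @param schedule_cfg,mood_cfg,fm Component configurations.
#' @return A list with `sessions` (all subjects' sessions) and
#'   `recordings` (long data.frame: keys, `mood`, feature columns). The
#'   attenuation stratum is attached as the logical column
#'   `recordings$high_phq` and the PHQ median as an attribute
#'   `phq_median`.
#' @export
generate_ema <- function(cohort, schedule_cfg = schedule_config(),
                         mood_cfg = mood_config(), fm = feature_model()) {
  totals <- questionnaire_summaries(cohort)
  med <- stats::median(totals$phq9_total)
  high <- totals$phq9_total > med
  sess_list <- vector("list", nrow(cohort))
  rec_list <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    sch <- build_schedule(subject, schedule_cfg)
    sessions <- sample_mood(subject, sch$sessions, mood_cfg)
    recs <- sample_features(sch$recordings, sessions, subject, fm,
                            attenuate = high[i])
    recs$high_phq <- high[i]
    sess_list[[i]] <- sessions
    rec_list[[i]] <- recs
  }
  out <- list(sessions = do.call(rbind, sess_list),
              recordings = do.call(rbind, rec_list))
  rownames(out$sessions) <- rownames(out$recordings) <- NULL
  attr(out, "phq_median") <- med
  out
}

#' Materialize frame matrices for recordings (sequence mode)
#'
#' Emits, for each recording, `n_frames` noisy copies of its functional
#' feature vector (frame noise scaled by each feature's unit scale), so
#' that temporal mean pooling recovers the functional vector in
#' expectation. Frames are deterministic given `(seed, subject, session,
#' content, repetition)` ordering within subject.
#'
#' @param recordings Recordings data.frame with feature columns.
#' @param fm The [feature_model()] used to generate them.
#' @param n_frames Frames per recording.
#' @return A 3-d array `[recording, frame, feature]`.
#' @export
recording_frames <- function(recordings, fm = feature_model(), n_frames = 4L) {
  K <- length(fm$feature_names)
  vals <- as.matrix(recordings[, fm$feature_names, drop = FALSE])
  n <- nrow(recordings)
  frames <- array(0, dim = c(n, n_frames, K),
                  dimnames = list(NULL, NULL, fm$feature_names))
  for (sid in unique(recordings$subject_id)) {
    idx <- which(recordings$subject_id == sid)
    noise <- with_local_seed(substream_seed(fm$seed, "frames", sid), {
      array(stats::rnorm(length(idx) * n_frames * K, 0, fm$frame_noise_sd),
            dim = c(length(idx), n_frames, K))
    })
    for (k in seq_len(K)) {
      frames[idx, , k] <- vals[idx, k] + fm$scale[k] * noise[, , k]
    }
  }
  frames
}

#' Pooled within-speaker feature-mood coupling
#'
#' For each feature: z-score the feature and the mood within each speaker,
#' pool all rows, and return the ordinary least-squares slope (computed
#' from first principles as `cov/var`) with a normal-approximation
#' confidence interval. Speakers with zero mood variance (or fewer than
#' `min_rows` rows) are excluded from the pool and reported.
#'
#' @param recordings Long recordings data.frame with `subject_id`, `mood`
#'   and feature columns.
#' @param features Feature column names (default: the standard eight).
#' @param min_rows Minimum rows per speaker.
#' @param conf_level Confidence level of the normal CI.
#' @return A data.frame (one row per feature: `slope`, `se`, `ci_lo`,
#'   `ci_hi`, `n`) with excluded speakers in attribute `excluded`.
#' @export
estimate_feature_mood_coupling <- function(recordings,
                                           features = feature_model()$feature_names,
                                           min_rows = 3L,
                                           conf_level = 0.95) {
  split_idx <- split(seq_len(nrow(recordings)), recordings$subject_id)
  excluded <- character(0)
  keep_rows <- integer(0)
  zmood <- rep(NA_real_, nrow(recordings))
  zfeat <- matrix(NA_real_, nrow(recordings), length(features))
  for (sid in names(split_idx)) {
    idx <- split_idx[[sid]]
    m <- recordings$mood[idx]
    if (length(idx) < min_rows || stats::sd(m) == 0) {
      excluded <- c(excluded, sid)
      next
    }
    keep_rows <- c(keep_rows, idx)
    zmood[idx] <- (m - mean(m)) / stats::sd(m)
    for (k in seq_along(features)) {
      f <- recordings[[features[k]]][idx]
      s <- stats::sd(f)
      zfeat[idx, k] <- if (s == 0) 0 else (f - mean(f)) / s
    }
  }
  stop_if_not(length(unique(recordings$subject_id[keep_rows])) >= 2,
              "need at least two evaluable speakers")
  x <- zmood[keep_rows]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- lapply(seq_along(features), function(k) {
    y <- zfeat[keep_rows, k]
    xc <- x - mean(x); yc <- y - mean(y)
    slope <- sum(xc * yc) / sum(xc^2)
    resid <- yc - slope * xc
    n <- length(x)
    se <- sqrt(sum(resid^2) / (n - 2) / sum(xc^2))
    data.frame(feature = features[k], slope = slope, se = se,
               ci_lo = slope - zq * se, ci_hi = slope + zq * se, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write recordings to CSV (long format)
#'
#' @param ema Result of [generate_ema()].
#' @param path Output file path for the recordings table.
#' @return `path`, invisibly.
#' @export
write_ema_csv <- function(ema, path) {
  utils::write.csv(ema$recordings, path, row.names = FALSE)
  invisible(path)
}
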