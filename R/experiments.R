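# Canned experiments -----------------------------------------------------
#
# Reference experiments at desk scale, shared by the test suite and the
# acceptance script. Each experiment generates its synthetic study from
# the default generator conditions, trains the relevant models on one
# speaker-independent fold per seed and evaluates on that fold's test
# speakers.

#' Personalization-gain experiment
#'
#' For each seed: generate a cohort (default generator settings) with a
#' balanced three-group composition, train the fine-tuned-encoder
#' baseline, then train the hyperformer initialized from it (backbone
#' frozen), and compare mean per-speaker rank correlations, per-content
#' correlations and fairness (Gini over speaker-level rho,
#' winners/losers) on the fold's test speakers.
#'
#' Recordings are thinned to one repetition per content type per session
#' -- repetitions are near-duplicates by construction, so this keeps the
#' information while cutting compute threefold.
#'
#' @param n_per_group Subjects per diagnostic group.
#' @param seeds Integer vector of experiment seeds.
#' @param metadata_subset Conditioning subset for the hyperformer.
#' @param fine_epochs,hyper_epochs Epoch budgets.
#' @param enc_cfg Encoder configuration.
#' @param progress Print one line per seed.
#' @return A data.frame with one row per seed: `rho_finetune`,
#'   `rho_hyper`, per-content hyperformer correlations, Gini indices
#'   (clip-at-zero variant, defined for negative rho values), winner and
#'   loser counts, and the evaluated speaker count.
#' @export
personalization_experiment <- function(n_per_group = 30L, seeds = 1:5,
                                       metadata_subset = "all",
                                       fine_epochs = 5L, hyper_epochs = 5L,
                                       enc_cfg = encoder_config(),
                                       progress = FALSE) {
  rows <- lapply(seeds, function(sd) {
    cohort <- generate_cohort(cohort_config(
      n_control = n_per_group, n_subclinical = n_per_group,
      n_patients = n_per_group, seed = sd))
    ema <- generate_ema(cohort, schedule_config(seed = sd),
                        mood_config(seed = sd), feature_model(seed = sd))
    ema$recordings <- ema$recordings[ema$recordings$repetition == 1L, ]
    data <- prepare_training_data(ema, cohort, enc_cfg = enc_cfg)
    split <- make_splits(cohort, k = 5L, seed = sd)[[1]]

    ck_fine <- train_model(data, split,
                           train_config("finetune", max_epochs = fine_epochs,
                                        seed = sd),
                           enc_cfg = enc_cfg)
    ck_hyp <- train_model(data, split,
                          train_config("hyperformer", max_epochs = hyper_epochs,
                                       seed = sd),
                          metadata_subset = metadata_subset,
                          enc_cfg = enc_cfg, init_backbone = ck_fine)

    pt_fine <- predict_fold(ck_fine, data, split, fold = 1L)
    pt_hyp <- predict_fold(ck_hyp, data, split, fold = 1L)
    ev_fine <- evaluate_predictions(pt_fine, cohort)
    ev_hyp <- evaluate_predictions(pt_hyp, cohort)
    fr <- fairness_report(pt_fine, pt_hyp)

    cont <- function(ev, ct) {
      v <- ev$by_content[[ct]]
      if (is.null(v)) NA_real_ else unname(v["mean"])
    }
    out <- data.frame(
      seed = sd,
      rho_finetune = ev_fine$speaker_rho$mean,
      rho_hyper = ev_hyp$speaker_rho$mean,
      mae_finetune = ev_fine$mae$mean,
      mae_hyper = ev_hyp$mae$mean,
      rho_question = cont(ev_hyp, "question"),
      rho_answer = cont(ev_hyp, "answer"),
      rho_positive_thought = cont(ev_hyp, "positive_thought"),
      gini_finetune = fr$gini_baseline$clip_mean,
      gini_hyper = fr$gini_personalized$clip_mean,
      winners = fr$winners_losers$winners,
      losers = fr$winners_losers$losers,
      n_speakers = fr$n_speakers
    )
    if (progress) {
      message(sprintf("seed %d: rho fine %.3f hyper %.3f (winners %d/%d)",
                      sd, out$rho_finetune, out$rho_hyper, out$winners,
                      out$n_speakers))
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Level-shift pathology experiment
#'
#' Generates a regime in which metadata predicts only each subject's mean
#' mood: no metadata interaction with the feature-mood coupling
#' (attenuation disabled) and a weak acoustic coupling
#' (`beta_scale` times the default effect sizes), emulating the low
#' signal-to-noise ratio of functional acoustic features for
#' within-subject mood. The additive-metadata FFNN can shift its
#' predictions per subject -- improving global MAE substantially -- while
#' mean per-speaker rho barely moves, since the within-subject ranking
#' signal is at its floor for both models.
#'
#' @param n_per_group Subjects per group.
#' @param seed Experiment seed.
#' @param epochs FFNN epoch budget.
#' @param metadata_subset Conditioning subset.
#' @param beta_scale Multiplier on the default coupling effect sizes.
#' @return One-row data.frame: `mae_base`, `mae_pers`, `rho_base`,
#'   `rho_pers`.
#' @export
level_shift_experiment <- function(n_per_group = 12L, seed = 1L, epochs = 40L,
                                   metadata_subset = "phq9",
                                   beta_scale = 0.3) {
  cohort <- generate_cohort(cohort_config(
    n_control = n_per_group, n_subclinical = n_per_group,
    n_patients = n_per_group, seed = seed))
  fm0 <- feature_model()
  fm <- feature_model(
    beta = fm0$beta * beta_scale,
    severity_attenuation = c(
      f0_mean = 1, hnr = 1, jitter = 1, shimmer = 1,
      nsyll = 1, npause = 1, duration = 1, speech_rate = 1),
    seed = seed)
  ema <- generate_ema(cohort, schedule_config(seed = seed),
                      mood_config(seed = seed), fm)
  data <- prepare_training_data(ema, cohort, fm = fm)
  split <- make_splits(cohort, k = 5L, seed = seed)[[1]]

  ck_base <- train_model(data, split,
                         train_config("ffnn", max_epochs = epochs, seed = seed))
  ck_pers <- train_model(data, split,
                         train_config("ffnn_pers", max_epochs = epochs,
                                      seed = seed),
                         metadata_subset = metadata_subset)
  pt_base <- predict_fold(ck_base, data, split, fold = 1L)
  pt_pers <- predict_fold(ck_pers, data, split, fold = 1L)
  ev_base <- evaluate_predictions(pt_base, cohort)
  ev_pers <- evaluate_predictions(pt_pers, cohort)
  data.frame(mae_base = ev_base$mae$mean, mae_pers = ev_pers$mae$mean,
             rho_base = ev_base$speaker_rho$mean,
             rho_pers = ev_pers$speaker_rho$mean)
}
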