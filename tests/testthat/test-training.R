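make_tiny_training_setup <- function(n_per_group = 4L, seed = 50L,
                                     n_days = 4L) {
  cohort <- generate_cohort(cohort_config(n_control = n_per_group,
                                          n_subclinical = n_per_group,
                                          n_patients = n_per_group,
                                          seed = seed))
  ema <- generate_ema(cohort,
                      schedule_config(n_days = n_days,
                                      recordings_per_content = 1L,
                                      missingness_by_group = c(0, 0, 0),
                                      seed = seed),
                      mood_config(seed = seed), feature_model(seed = seed))
  cfg <- encoder_config()
  data <- prepare_training_data(ema, cohort, enc_cfg = cfg)
  splits <- make_splits(cohort, k = 3, seed = seed)
  list(cohort = cohort, data = data, splits = splits, enc_cfg = cfg)
}

test_that("splits partition subjects with stratification and no leakage", {
  cohort <- generate_cohort(cohort_config(seed = 51))
  splits <- make_splits(cohort, k = 5, seed = 51)
  test_sets <- lapply(splits, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), sort(cohort$subject_id))
  expect_equal(anyDuplicated(unlist(test_sets)), 0L)
  global_prop <- table(cohort$group) / nrow(cohort)
  for (s in splits) {
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$val, s$test), 0)
    expect_length(intersect(s$train, s$val), 0)
    expect_setequal(c(s$train, s$val, s$test), cohort$subject_id)
    # per-fold group counts within one subject of the proportional share
    tg <- table(factor(cohort$group[cohort$subject_id %in% s$test],
                       levels = names(global_prop)))
    expect_true(all(abs(tg - global_prop * length(s$test)) <= 1))
  }
  # 10 subjects, 5 folds: test folds of size 2
  small <- generate_cohort(cohort_config(n_control = 4, n_subclinical = 3,
                                         n_patients = 3, seed = 52))
  sp <- make_splits(small, k = 5, seed = 1)
  expect_true(all(vapply(sp, function(s) length(s$test), integer(1)) == 2L))
  expect_error(make_splits(small, k = 20), "more folds")
})

test_that("warmup schedule is nondecreasing then flat at the peak", {
  lrs <- vapply(1:100, warmup_lr, numeric(1), total_steps = 100, peak = 3e-4,
                warmup_fraction = 0.1)
  expect_true(all(diff(lrs) >= 0))
  expect_equal(max(lrs), 3e-4)
  expect_true(all(lrs[11:100] == 3e-4))
  expect_true(all(lrs[1:9] < 3e-4))
})

test_that("training is deterministic under a fixed seed", {
  st <- make_tiny_training_setup()
  cfg <- train_config("ffnn", max_epochs = 2, seed = 3)
  a <- train_model(st$data, st$splits[[1]], cfg)
  b <- train_model(st$data, st$splits[[1]], cfg)
  expect_identical(a$ffnn, b$ffnn)
  expect_identical(a$val_score, b$val_score)
})

test_that("training loss decreases over the first epochs", {
  st <- make_tiny_training_setup(n_per_group = 5L, n_days = 8L)
  cfg <- train_config("ffnn", max_epochs = 12, seed = 4)
  ck <- train_model(st$data, st$splits[[1]], cfg)
  h <- ck$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("the reported checkpoint is the best-on-validation epoch", {
  st <- make_tiny_training_setup(n_per_group = 5L)
  ck <- train_model(st$data, st$splits[[1]],
                    train_config("ffnn", max_epochs = 8, seed = 5))
  expect_equal(ck$val_score, max(ck$history$val_score))
  expect_equal(ck$epoch, which.max(ck$history$val_score))
})

test_that("hyperformer training freezes the backbone", {
  st <- make_tiny_training_setup()
  ck_f <- train_model(st$data, st$splits[[1]],
                      train_config("finetune", max_epochs = 1, seed = 6),
                      enc_cfg = st$enc_cfg)
  expect_gt(ck_f$grad_norms[["backbone"]], 0)
  ck_h <- train_model(st$data, st$splits[[1]],
                      train_config("hyperformer", max_epochs = 1, seed = 6),
                      metadata_subset = "phq9", enc_cfg = st$enc_cfg,
                      init_backbone = ck_f)
  expect_identical(ck_h$grad_norms[["backbone"]], 0)
  expect_gt(ck_h$grad_norms[["trainable"]], 0)
  # the frozen backbone body is bitwise unchanged by hyperformer training
  expect_identical(ck_h$backbone$layers, ck_f$backbone$layers)
  expect_identical(ck_h$backbone$in_proj, ck_f$backbone$in_proj)
  expect_identical(ck_h$backbone$ln_f, ck_f$backbone$ln_f)
})

test_that("errors on degenerate folds and non-finite losses are explicit", {
  st <- make_tiny_training_setup()
  bad_split <- list(train = character(0), val = st$splits[[1]]$val,
                    test = st$splits[[1]]$test)
  expect_error(train_model(st$data, bad_split, train_config("ffnn")),
               "empty training set")
  poisoned <- st$data
  train_row <- which(poisoned$recordings$subject_id %in% st$splits[[1]]$train)[1]
  poisoned$y[train_row] <- NaN
  expect_error(train_model(poisoned, st$splits[[1]],
                           train_config("ffnn", max_epochs = 2)),
               "non-finite loss")
})

test_that("checkpoints survive a JSON round trip and predict identically", {
  st <- make_tiny_training_setup()
  ck <- train_model(st$data, st$splits[[1]],
                    train_config("ffnn_pers", max_epochs = 2, seed = 7),
                    metadata_subset = "phq9")
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint_json(ck, path)
  back <- load_checkpoint_json(path)
  rows <- which(st$data$recordings$subject_id %in% st$splits[[1]]$test)
  expect_equal(predict_checkpoint(back, st$data, rows),
               predict_checkpoint(ck, st$data, rows), tolerance = 1e-12)

  ck2 <- train_model(st$data, st$splits[[1]],
                     train_config("finetune", max_epochs = 1, seed = 8),
                     enc_cfg = st$enc_cfg)
  path2 <- withr::local_tempfile(fileext = ".json")
  save_checkpoint_json(ck2, path2)
  back2 <- load_checkpoint_json(path2)
  expect_equal(predict_checkpoint(back2, st$data, rows[1:20]),
               predict_checkpoint(ck2, st$data, rows[1:20]), tolerance = 1e-10)
})
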