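# Training ---------------------------------------------------------------
#
# Speaker-independent cross-validation splits, AdamW with linear warmup,
# per-model freeze policies and validation-based checkpoint selection.
# Reported test metrics always come from the epoch that maximized the
# validation-set global rank correlation.

#' Speaker-independent, group-stratified cross-validation splits
#'
#' Every subject appears in exactly one test fold; validation speakers are
#' drawn from the training side only; splits are by subject, never by
#' recording. Within each diagnostic group subjects are shuffled
#' (seeded) and dealt round-robin to folds, so per-fold group counts
#' differ by at most one subject.
#'
#' @param subjects Cohort data.frame (needs `subject_id`, `group`).
#' @param k Number of folds.
#' @param val_fraction Fraction of the training side held out for
#'   validation (per fold).
#' @param seed Integer seed.
#' @return List of `k` folds, each `list(train, val, test)` of subject
#'   ids.
#' @export
make_splits <- function(subjects, k = 5L, val_fraction = 0.2, seed = 1L) {
  stop_if_not(nrow(subjects) >= k, "more folds than subjects")
  test_sets <- rep(list(character(0)), k)
  offset <- 0L # carried across groups so total fold sizes differ by <= 1
  for (g in unique(subjects$group)) {
    ids <- subjects$subject_id[subjects$group == g]
    ids <- with_local_seed(substream_seed(seed, "split", g), sample(ids))
    for (i in seq_along(ids)) {
      f <- ((offset + i - 1L) %% k) + 1L
      test_sets[[f]] <- c(test_sets[[f]], ids[i])
    }
    offset <- (offset + length(ids)) %% k
  }
  lapply(seq_len(k), function(f) {
    test <- test_sets[[f]]
    pool <- setdiff(subjects$subject_id, test)
    val <- character(0)
    for (g in unique(subjects$group)) {
      ids <- intersect(pool, subjects$subject_id[subjects$group == g])
      ids <- with_local_seed(substream_seed(seed, "val", f, g), sample(ids))
      n_val <- max(if (length(ids) > 1) 1L else 0L,
                   round(val_fraction * length(ids)))
      val <- c(val, ids[seq_len(min(n_val, length(ids) - 1L))])
    }
    list(train = setdiff(pool, val), val = val, test = test)
  })
}

#' Training configuration
#'
#' Defaults follow the emulated study's protocol: encoder paths use batch
#' size 16, learning rate 3e-4 and at most 10 epochs; FFNN paths use
#' batch size 128, learning rate 1e-4 and at most 100 epochs; AdamW with
#' linear warmup over the first 10% of steps.
#'
#' @param model One of `"ffnn"`, `"ffnn_pers"`, `"finetune"`,
#'   `"hyperformer"`.
#' @param batch_size,learning_rate,max_epochs Optimization settings;
#'   defaults depend on the model family.
#' @param warmup_fraction Fraction of total steps with linearly increasing
#'   learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param loss `"mse"` (default) or `"l1"`.
#' @param seed Integer seed controlling initialization and batch order.
#' @return A list of class `train_config`.
#' @export
train_config <- function(model = c("ffnn", "ffnn_pers", "finetune", "hyperformer"),
                         batch_size = NULL, learning_rate = NULL,
                         max_epochs = NULL, warmup_fraction = 0.1,
                         weight_decay = 0.01, loss = c("mse", "l1"),
                         seed = 1L) {
  model <- match.arg(model)
  loss <- match.arg(loss)
  enc <- model %in% c("finetune", "hyperformer")
  structure(list(
    model = model,
    batch_size = as.integer(batch_size %||% if (enc) 16L else 128L),
    learning_rate = learning_rate %||% if (enc) 3e-4 else 1e-4,
    max_epochs = as.integer(max_epochs %||% if (enc) 10L else 100L),
    warmup_fraction = warmup_fraction,
    weight_decay = weight_decay,
    loss = loss,
    seed = as.integer(seed)
  ), class = "train_config")
}

#' Learning-rate schedule with linear warmup
#'
#' Nondecreasing during the warmup span, equal to the configured peak
#' afterwards.
#'
#' @param step 1-based optimizer step.
#' @param total_steps Total steps of the run.
#' @param peak Peak learning rate.
#' @param warmup_fraction Fraction of `total_steps` used for warmup.
#' @return Learning rate at `step`.
#' @export
warmup_lr <- function(step, total_steps, peak, warmup_fraction = 0.1) {
  w <- max(1, ceiling(warmup_fraction * total_steps))
  peak * pmin(1, step / w)
}

# AdamW on flat parameter lists ------------------------------------------

adamw_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

adamw_step <- function(flat, grads, state, lr, weight_decay,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    flat[[nm]] <- flat[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                       weight_decay * flat[[nm]])
  }
  list(flat = flat, state = state)
}

flat_sq_norm <- function(flat) sum(vapply(flat, function(x) sum(x * x), numeric(1)))

# Feature standardization (train-fold statistics only).
fit_feature_stats <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(center = mu, scale = sd)
}

apply_feature_stats <- function(X, st) {
  sweep(sweep(X, 2, st$center), 2, st$scale, "/")
}

#' Assemble model-ready training data from a synthetic EMA
#'
#' Standardizes nothing (standardizers are fitted per training fold inside
#' [train_model()]); materializes the frame array once so training is
#' deterministic across epochs.
#'
#' @param ema Result of [generate_ema()].
#' @param cohort The cohort the EMA was generated from.
#' @param fm The [feature_model()] used.
#' @param enc_cfg An [encoder_config()] (controls frames per recording).
#' @return A list with `recordings`, `features` (N x F), `frames`
#'   (N x T x F), `y` (moods), `subjects`.
#' @export
prepare_training_data <- function(ema, cohort, fm = feature_model(),
                                  enc_cfg = encoder_config()) {
  recs <- ema$recordings
  features <- as.matrix(recs[, fm$feature_names, drop = FALSE])
  frames <- recording_frames(recs, fm, n_frames = enc_cfg$n_frames)
  list(recordings = recs, features = features, frames = frames,
       y = as.numeric(recs$mood), subjects = cohort)
}

loss_grad <- function(pred, y, kind) {
  n <- length(y)
  if (kind == "mse") {
    list(loss = mean((pred - y)^2), dpred = 2 * (pred - y) / n)
  } else {
    list(loss = mean(abs(pred - y)), dpred = sign(pred - y) / n)
  }
}

# Flatten frame array rows for a set of recording indices into the
# sample-major (B*T) x F matrix.
frame_rows_matrix <- function(frames_flat, Tlen, rows) {
  idx <- as.vector(t(outer(rows - 1L, seq_len(Tlen), function(r, t) r * Tlen + t)))
  frames_flat[idx, , drop = FALSE]
}

flatten_frames <- function(frames) {
  d <- dim(frames)
  X <- matrix(0, d[1] * d[2], d[3])
  for (t in seq_len(d[2])) {
    X[seq(t, by = d[2], length.out = d[1]), ] <- frames[, t, ]
  }
  X
}

#' Train a model on one cross-validation fold
#'
#' Dispatches on the model kind, applies the freeze policy (for the
#' hyperformer, only the hypernetworks and the final prediction layer
#' receive gradients; the backbone is frozen), optimizes with AdamW and
#' linear warmup, and returns the checkpoint whose validation-set global
#' Spearman correlation was highest (never simply the last epoch).
#'
#' @param data From [prepare_training_data()].
#' @param split One fold from [make_splits()].
#' @param cfg A [train_config()].
#' @param metadata_subset Metadata subset name for personalized models.
#' @param enc_cfg An [encoder_config()] (encoder paths).
#' @param ffnn_hidden Hidden width for FFNN paths.
#' @param init_backbone Optional checkpoint of a trained `"finetune"`
#'   model: the hyperformer is initialized from it (backbone and head), as
#'   the personalized model continues from the fine-tuned baseline.
#' @return A checkpoint list: parameters, best epoch, validation score,
#'   per-epoch history, fitted standardizers, accumulated gradient norms
#'   per parameter group, and configuration snapshot.
#' @export
train_model <- function(data, split, cfg = train_config(),
                        metadata_subset = "all",
                        enc_cfg = encoder_config(), ffnn_hidden = 30L,
                        init_backbone = NULL) {
  kind <- cfg$model
  recs <- data$recordings
  train_rows <- which(recs$subject_id %in% split$train)
  val_rows <- which(recs$subject_id %in% split$val)
  stop_if_not(length(train_rows) > 0, "empty training set")
  stop_if_not(length(val_rows) > 0, "empty validation set")

  feat_stats <- fit_feature_stats(data$features[train_rows, , drop = FALSE])
  needs_meta <- kind %in% c("ffnn_pers", "hyperformer")
  meta_stats <- NULL; meta_mat <- NULL
  if (needs_meta) {
    train_subj <- data$subjects[data$subjects$subject_id %in% split$train, ]
    meta_stats <- fit_normalizer(train_subj, metadata_subset)
    meta_mat <- encode_metadata(data$subjects, metadata_subset, meta_stats)
  }

  enc_path <- kind %in% c("finetune", "hyperformer")
  if (enc_path) {
    Tlen <- enc_cfg$n_frames
    frames_flat <- flatten_frames(data$frames)
    frames_flat <- apply_feature_stats(frames_flat, feat_stats)
  } else {
    Xall <- apply_feature_stats(data$features, feat_stats)
  }

  y <- data$y
  # Model-specific initialization and trainable partition.
  backbone <- NULL; hp <- NULL; fpar <- NULL
  if (kind == "ffnn" || kind == "ffnn_pers") {
    fcfg <- ffnn_config(ncol(data$features), hidden = ffnn_hidden,
                        meta_dim = if (kind == "ffnn_pers") ncol(meta_mat) else NULL)
    fpar <- init_ffnn_params(fcfg, seed = cfg$seed)
    fpar$b <- mean(y[train_rows])
    trainable <- flatten_params(fpar)
  } else if (kind == "finetune") {
    backbone <- init_encoder_params(enc_cfg, seed = cfg$seed)
    backbone$head$b <- mean(y[train_rows])
    trainable <- flatten_params(list(layers = backbone$layers,
                                     ln_f = backbone$ln_f,
                                     head = backbone$head))
  } else { # hyperformer
    if (!is.null(init_backbone)) {
      stop_if_not(identical(init_backbone$model, "finetune"),
                  "init_backbone must be a finetune checkpoint")
      backbone <- init_backbone$backbone
      feat_stats <- init_backbone$feat_stats
      frames_flat <- flatten_frames(data$frames)
      frames_flat <- apply_feature_stats(frames_flat, feat_stats)
    } else {
      backbone <- init_encoder_params(enc_cfg, seed = cfg$seed)
      backbone$head$b <- mean(y[train_rows])
    }
    hp <- init_hypernet_params(enc_cfg, meta_dim = ncol(meta_mat),
                               seed = cfg$seed)
    trainable <- c(flatten_params(list(hyper = hp)),
                   flatten_params(list(head = backbone$head)))
  }

  opt <- adamw_init(trainable)
  n_train <- length(train_rows)
  steps_per_epoch <- ceiling(n_train / cfg$batch_size)
  total_steps <- steps_per_epoch * cfg$max_epochs
  step <- 0L
  grad_norms <- c(backbone = 0, trainable = 0)
  history <- list()
  best <- list(score = -Inf, epoch = 0L)

  subj_index <- match(recs$subject_id, data$subjects$subject_id)

  predict_rows <- function(rows) {
    if (!enc_path) {
      Xb <- Xall[rows, , drop = FALSE]
      if (kind == "ffnn_pers") {
        Mb <- meta_mat[subj_index[rows], , drop = FALSE]
        ffnn_forward_cached(Xb, fpar, Mb)$pred
      } else ffnn_forward_cached(Xb, fpar)$pred
    } else {
      out <- numeric(length(rows))
      chunk <- 256L
      for (start in seq(1, length(rows), by = chunk)) {
        rr <- rows[start:min(start + chunk - 1L, length(rows))]
        Xb <- frame_rows_matrix(frames_flat, Tlen, rr)
        if (kind == "hyperformer") {
          groups <- make_adapter_groups(rr, subj_index, meta_mat, hp, enc_cfg,
                                        Tlen)
          p <- encoder_forward(Xb, length(rr), Tlen, backbone, enc_cfg,
                               adapter_groups = groups)$pred
        } else {
          p <- encoder_forward(Xb, length(rr), Tlen, backbone, enc_cfg)$pred
        }
        out[start:(start + length(rr) - 1L)] <- p
      }
      out
    }
  }

  for (ep in seq_len(cfg$max_epochs)) {
    order_rows <- with_local_seed(substream_seed(cfg$seed, "epoch", ep),
                                  sample(train_rows))
    ep_loss <- 0
    for (bstart in seq(1, n_train, by = cfg$batch_size)) {
      rows <- order_rows[bstart:min(bstart + cfg$batch_size - 1L, n_train)]
      step <- step + 1L
      lr <- warmup_lr(step, total_steps, cfg$learning_rate, cfg$warmup_fraction)

      if (!enc_path) {
        Xb <- Xall[rows, , drop = FALSE]
        Mb <- if (kind == "ffnn_pers") meta_mat[subj_index[rows], , drop = FALSE]
              else NULL
        fw <- ffnn_forward_cached(Xb, fpar, Mb)
        lg <- loss_grad(fw$pred, y[rows], cfg$loss)
        g <- ffnn_backward(lg$dpred, fw, fpar)
        flat_g <- flatten_params(g)[names(trainable)]
      } else if (kind == "finetune") {
        Xb <- frame_rows_matrix(frames_flat, Tlen, rows)
        fw <- encoder_forward(Xb, length(rows), Tlen, backbone, enc_cfg,
                              keep_cache = TRUE)
        lg <- loss_grad(fw$pred, y[rows], cfg$loss)
        bk <- encoder_backward(lg$dpred, fw, backbone, enc_cfg,
                               backbone_grads = TRUE)
        flat_g <- flatten_params(bk$grads)[names(trainable)]
        grad_norms["backbone"] <- grad_norms["backbone"] +
          flat_sq_norm(flatten_params(list(layers = bk$grads$layers,
                                           ln_f = bk$grads$ln_f)))
      } else { # hyperformer
        Xb <- frame_rows_matrix(frames_flat, Tlen, rows)
        groups <- make_adapter_groups(rows, subj_index, meta_mat, hp, enc_cfg,
                                      Tlen)
        fw <- encoder_forward(Xb, length(rows), Tlen, backbone, enc_cfg,
                              adapter_groups = groups, keep_cache = TRUE)
        lg <- loss_grad(fw$pred, y[rows], cfg$loss)
        bk <- encoder_backward(lg$dpred, fw, backbone, enc_cfg,
                               backbone_grads = FALSE)
        acc <- new_hypernet_grad_acc(hp)
        meta_dim <- ncol(meta_mat)
        for (gi in seq_along(groups)) {
          sites <- groups[[gi]]$adapters
          agr <- bk$adapter_grads[[gi]]
          for (li in seq_len(enc_cfg$L)) {
            hypernet_site_backward(agr[[li]][[1]], sites[[li]][[1]], hp,
                                   enc_cfg, meta_dim, acc)
            hypernet_site_backward(agr[[li]][[2]], sites[[li]][[2]], hp,
                                   enc_cfg, meta_dim, acc)
          }
        }
        hyper_g <- list(layer_emb = acc$layer_emb, pos_emb = acc$pos_emb,
                        hI = acc$hI, gen_D = acc$gen_D, gen_U = acc$gen_U,
                        gen_ln = acc$gen_ln)
        flat_g <- c(flatten_params(list(hyper = hyper_g)),
                    flatten_params(list(head = bk$grads$head)))
        flat_g <- flat_g[names(trainable)]
      }

      if (!is.finite(lg$loss)) {
        stop(sprintf("non-finite loss at epoch %d (model %s); aborting",
                     ep, kind), call. = FALSE)
      }
      ep_loss <- ep_loss + lg$loss * length(rows)
      grad_norms["trainable"] <- grad_norms["trainable"] + flat_sq_norm(flat_g)
      upd <- adamw_step(trainable, flat_g, opt, lr, cfg$weight_decay)
      trainable <- upd$flat; opt <- upd$state

      # write updated values back into the structured parameter objects
      if (!enc_path) {
        for (nm in names(trainable)) fpar <- set_flat_param(fpar, nm, trainable[[nm]])
      } else if (kind == "finetune") {
        for (nm in names(trainable)) backbone <- set_flat_param(backbone, nm, trainable[[nm]])
      } else {
        for (nm in names(trainable)) {
          if (startsWith(nm, "hyper.")) {
            hp <- set_flat_param(hp, sub("^hyper\\.", "", nm), trainable[[nm]])
          } else {
            backbone <- set_flat_param(backbone, nm, trainable[[nm]])
          }
        }
      }
    }

    val_pred <- predict_rows(val_rows)
    val_score <- spearman_rho(val_pred, y[val_rows])
    if (!is.finite(val_score)) val_score <- -1
    history[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n_train,
                                val_score = val_score)
    if (val_score > best$score) {
      best <- list(score = val_score, epoch = ep,
                   fpar = fpar, backbone = backbone, hp = hp)
    }
  }

  structure(list(
    model = kind,
    ffnn = best$fpar, backbone = best$backbone, hypernet = best$hp,
    epoch = best$epoch, val_score = best$score,
    history = do.call(rbind, history),
    feat_stats = feat_stats, meta_stats = meta_stats,
    metadata_subset = if (needs_meta) metadata_subset else NULL,
    enc_cfg = if (enc_path) enc_cfg else NULL,
    train_cfg = cfg, grad_norms = grad_norms
  ), class = "hypermood_checkpoint")
}

# Group a batch's recording rows by subject and generate each subject's
# adapter parameters once.
make_adapter_groups <- function(rows, subj_index, meta_mat, hp, cfg, Tlen) {
  sp <- split(seq_along(rows), subj_index[rows])
  lapply(names(sp), function(si) {
    pos <- sp[[si]]
    rr <- as.vector(t(outer(pos - 1L, seq_len(Tlen), function(r, t) r * Tlen + t)))
    list(rows = rr,
         adapters = generate_subject_adapters(meta_mat[as.integer(si), ], hp, cfg))
  })
}

#' Predict with a trained checkpoint
#'
#' @param ckpt A checkpoint from [train_model()].
#' @param data From [prepare_training_data()] (same generator settings as
#'   in training).
#' @param rows Row indices of `data$recordings` to predict (default all).
#' @return Numeric predictions.
#' @export
predict_checkpoint <- function(ckpt, data, rows = seq_len(nrow(data$recordings))) {
  kind <- ckpt$model
  subj_index <- match(data$recordings$subject_id, data$subjects$subject_id)
  if (kind %in% c("ffnn", "ffnn_pers")) {
    X <- apply_feature_stats(data$features, ckpt$feat_stats)[rows, , drop = FALSE]
    if (kind == "ffnn_pers") {
      meta_mat <- encode_metadata(data$subjects, ckpt$metadata_subset,
                                  ckpt$meta_stats)
      M <- meta_mat[subj_index[rows], , drop = FALSE]
      return(ffnn_forward_cached(X, ckpt$ffnn, M)$pred)
    }
    return(ffnn_forward_cached(X, ckpt$ffnn)$pred)
  }
  enc_cfg <- ckpt$enc_cfg
  Tlen <- enc_cfg$n_frames
  frames_flat <- apply_feature_stats(flatten_frames(data$frames),
                                     ckpt$feat_stats)
  meta_mat <- NULL
  if (kind == "hyperformer") {
    meta_mat <- encode_metadata(data$subjects, ckpt$metadata_subset,
                                ckpt$meta_stats)
  }
  out <- numeric(length(rows))
  chunk <- 256L
  for (start in seq(1, length(rows), by = chunk)) {
    rr <- rows[start:min(start + chunk - 1L, length(rows))]
    Xb <- frame_rows_matrix(frames_flat, Tlen, rr)
    if (kind == "hyperformer") {
      groups <- make_adapter_groups(rr, subj_index, meta_mat, ckpt$hypernet,
                                    enc_cfg, Tlen)
      p <- encoder_forward(Xb, length(rr), Tlen, ckpt$backbone, enc_cfg,
                           adapter_groups = groups)$pred
    } else {
      p <- encoder_forward(Xb, length(rr), Tlen, ckpt$backbone, enc_cfg)$pred
    }
    out[start:(start + length(rr) - 1L)] <- p
  }
  out
}

#' Build a prediction table for a fold's test subjects
#'
#' @param ckpt Checkpoint from [train_model()].
#' @param data From [prepare_training_data()].
#' @param split The fold the checkpoint was trained on.
#' @param fold Fold identifier stored in the table.
#' @return A data.frame with keys, `y_true`, `y_pred`, `fold`.
#' @export
predict_fold <- function(ckpt, data, split, fold = 1L) {
  rows <- which(data$recordings$subject_id %in% split$test)
  preds <- predict_checkpoint(ckpt, data, rows)
  recs <- data$recordings[rows, c("subject_id", "day", "slot", "session_index",
                                  "content", "repetition")]
  recs$y_true <- data$y[rows]
  recs$y_pred <- preds
  recs$fold <- fold
  rownames(recs) <- NULL
  recs
}

# Checkpoint serialization ------------------------------------------------

params_to_json_list <- function(x) {
  if (is.list(x)) return(lapply(x, params_to_json_list))
  if (is.matrix(x)) return(list(.matrix = TRUE, dim = dim(x), data = as.vector(x)))
  x
}

params_from_json_list <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    return(matrix(as.numeric(unlist(x$data)), x$dim[[1]], x$dim[[2]]))
  }
  if (is.list(x)) {
    scalar <- vapply(x, function(e) is.numeric(e) && length(e) == 1, logical(1))
    if (length(x) > 0 && all(scalar) && is.null(names(x))) {
      return(as.numeric(unlist(x)))
    }
    return(lapply(x, params_from_json_list))
  }
  if (is.numeric(x)) return(as.numeric(x))
  x
}

#' Save / load a checkpoint as a single JSON file
#'
#' The file contains the configuration snapshot and all named parameter
#' arrays; it can be reloaded for prediction without any training state.
#'
#' @param ckpt A checkpoint from [train_model()].
#' @param path Output path.
#' @return `path` invisibly (writer); a checkpoint (reader).
#' @export
save_checkpoint_json <- function(ckpt, path) {
  x <- unclass(ckpt)
  x$history <- NULL
  for (f in c("ffnn", "backbone", "hypernet")) {
    if (!is.null(x[[f]])) x[[f]] <- params_to_json_list(x[[f]])
  }
  if (!is.null(x$meta_stats)) x$meta_stats <- unclass(x$meta_stats)
  if (!is.null(x$enc_cfg)) x$enc_cfg <- unclass(x$enc_cfg)
  x$train_cfg <- unclass(x$train_cfg)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_checkpoint_json
#' @export
load_checkpoint_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("ffnn", "backbone", "hypernet")) {
    if (!is.null(x[[f]])) x[[f]] <- params_from_json_list(x[[f]])
  }
  scal <- function(v) if (is.null(v)) NULL else unlist(v)
  if (!is.null(x$meta_stats)) {
    x$meta_stats <- structure(list(
      subset = x$meta_stats$subset,
      fields = as.character(scal(x$meta_stats$fields)),
      center = as.numeric(scal(x$meta_stats$center)),
      scale = as.numeric(scal(x$meta_stats$scale))), class = "normalization_stats")
  }
  x$feat_stats <- lapply(x$feat_stats, function(v) unlist(v))
  if (!is.null(x$enc_cfg)) {
    ec <- lapply(x$enc_cfg, function(v) if (is.logical(v[[1]] %||% v)) v else v)
    x$enc_cfg <- structure(lapply(x$enc_cfg, unlist), class = "encoder_config")
  }
  x$train_cfg <- structure(lapply(x$train_cfg, unlist), class = "train_config")
  x$grad_norms <- unlist(x$grad_norms)
  structure(x, class = "hypermood_checkpoint")
}
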