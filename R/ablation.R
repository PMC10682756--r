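# Experiment grid runner -------------------------------------------------
#
# Orchestrates model x metadata-subset x fold x seed grids over the
# cross-validation, writing one small JSON result per cell so grids are
# resumable and embarrassingly parallel (per-cell seeds are derived by
# hashing the base seed with the cell key, so execution order never
# matters).

#' Define an experiment grid
#'
#' @param models Model kinds (see [train_config()]).
#' @param subsets Metadata subset names (ignored for non-personalized
#'   models, which occupy a single `"none"` cell per fold/seed).
#' @param folds Fold indices to run.
#' @param seeds Base seeds.
#' @param out_dir Output directory for per-cell JSON results.
#' @return A data.frame with one row per grid cell and a unique,
#'   collision-free `path` per cell.
#' @export
experiment_grid <- function(models, subsets = "all", folds = 1L, seeds = 1L,
                            out_dir = tempfile("grid")) {
  cells <- expand.grid(model = models, subset = subsets, fold = folds,
                       seed = seeds, stringsAsFactors = FALSE)
  pers <- cells$model %in% c("ffnn_pers", "hyperformer")
  cells$subset[!pers] <- "none"
  cells <- unique(cells)
  cells$path <- file.path(out_dir, sprintf("%s_%s_fold%d_seed%d.json",
                                           cells$model, cells$subset,
                                           cells$fold, cells$seed))
  stop_if_not(!anyDuplicated(cells$path), "grid cells collide")
  attr(cells, "out_dir") <- out_dir
  cells
}

#' Run an experiment grid
#'
#' Trains and evaluates every cell of the grid on its fold's test
#' speakers. Cells whose output file already exists are skipped unless
#' `force`; failing cells are recorded and the run continues.
#'
#' @param grid From [experiment_grid()].
#' @param data From [prepare_training_data()].
#' @param splits From [make_splits()].
#' @param enc_cfg,ffnn_hidden,train_opts Forwarded to [train_model()];
#'   `train_opts` is a list of [train_config()] overrides (e.g.
#'   `max_epochs`).
#' @param force Re-run cells with existing outputs.
#' @return A list: `cells` (the grid with a `status` column),
#'   `aggregate` (mean and SD over folds+seeds per model/subset),
#'   `failures`.
#' @export
run_grid <- function(grid, data, splits, enc_cfg = encoder_config(),
                     ffnn_hidden = 30L, train_opts = list(), force = FALSE) {
  out_dir <- attr(grid, "out_dir") %||% dirname(grid$path[1])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- character(nrow(grid))
  failures <- list()
  for (i in seq_len(nrow(grid))) {
    cell <- grid[i, ]
    if (file.exists(cell$path) && !force) {
      status[i] <- "cached"
      next
    }
    res <- tryCatch({
      cell_seed <- substream_seed(cell$seed, "cell", cell$model, cell$subset,
                                  cell$fold)
      cfg_args <- c(list(model = cell$model, seed = cell_seed), train_opts)
      cfg <- do.call(train_config, cfg_args)
      split <- splits[[cell$fold]]
      ckpt <- train_model(data, split, cfg,
                          metadata_subset = if (cell$subset == "none") "all"
                                            else cell$subset,
                          enc_cfg = enc_cfg, ffnn_hidden = ffnn_hidden)
      pt <- predict_fold(ckpt, data, split, fold = cell$fold)
      rep <- evaluate_predictions(pt, data$subjects)
      summary <- list(
        model = cell$model, subset = cell$subset, fold = cell$fold,
        seed = cell$seed, epoch = ckpt$epoch, val_score = ckpt$val_score,
        mean_rho = rep$speaker_rho$mean, mae = rep$mae$mean,
        by_group = lapply(rep$by_group, function(x) unname(x["mean"])),
        by_content = lapply(rep$by_content, function(x) unname(x["mean"]))
      )
      jsonlite::write_json(summary, cell$path, auto_unbox = TRUE, digits = 10)
      "done"
    }, error = function(e) {
      failures[[cell$path]] <<- conditionMessage(e)
      "failed"
    })
    status[i] <- res
  }
  grid$status <- status
  ok <- grid$path[file.exists(grid$path)]
  cells <- lapply(ok, function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  aggregate <- NULL
  if (length(cells) > 0) {
    df <- do.call(rbind, lapply(cells, function(x) {
      data.frame(model = x$model, subset = x$subset, fold = x$fold,
                 seed = x$seed, mean_rho = x$mean_rho, mae = x$mae,
                 stringsAsFactors = FALSE)
    }))
    sp <- split(df, paste(df$model, df$subset))
    aggregate <- do.call(rbind, lapply(sp, function(d) {
      data.frame(model = d$model[1], subset = d$subset[1], n_cells = nrow(d),
                 mean_rho = mean(d$mean_rho),
                 sd_rho = if (nrow(d) > 1) stats::sd(d$mean_rho) else NA_real_,
                 mean_mae = mean(d$mae),
                 sd_mae = if (nrow(d) > 1) stats::sd(d$mae) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rownames(aggregate) <- NULL
  }
  list(cells = grid, aggregate = aggregate, failures = failures)
}
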