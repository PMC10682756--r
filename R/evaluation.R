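# Evaluation -------------------------------------------------------------
#
# Per-speaker and global metrics: MAE over all predictions per fold,
# Spearman's rho computed for each speaker independently and then
# averaged, group and content-type breakdowns, prediction-questionnaire
# correlations, and individual-fairness summaries (Gini index over
# speaker-level rho, winners/losers of personalization).

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties); invariant to
#' strictly monotone transforms of either argument.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`; `NA` if either argument has zero
#'   rank variance.
#' @export
spearman_rho <- function(x, y) {
  stop_if_not(length(x) == length(y) && length(x) >= 2,
              "need two vectors of equal length >= 2")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Per-speaker rank correlations and their mean
#'
#' Computes Spearman's rho between predictions and truths for each
#' speaker independently and averages over speakers (each speaker has
#' weight one regardless of row count). Speakers with undefined rho
#' (constant truths or constant predictions) are excluded from the mean
#' and listed, unless `undefined_as_zero` assigns them 0 instead.
#'
#' @param pred_table Data.frame with `subject_id`, `y_true`, `y_pred`.
#' @param undefined_as_zero Score undefined speakers as 0 instead of
#'   excluding them.
#' @return A list: `per_speaker` (data.frame subject_id, rho, n_rows),
#'   `mean_rho`, `excluded` (subject ids with reasons).
#' @export
per_speaker_rho <- function(pred_table, undefined_as_zero = FALSE) {
  sp <- split(pred_table, pred_table$subject_id)
  rows <- lapply(names(sp), function(sid) {
    d <- sp[[sid]]
    if (nrow(d) < 2) {
      return(data.frame(subject_id = sid, rho = NA_real_, n_rows = nrow(d),
                        reason = "fewer than 2 rows", stringsAsFactors = FALSE))
    }
    r <- spearman_rho(d$y_pred, d$y_true)
    data.frame(subject_id = sid, rho = r, n_rows = nrow(d),
               reason = if (is.na(r)) "constant predictions or truths" else "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  excluded <- tab[is.na(tab$rho), c("subject_id", "reason")]
  if (undefined_as_zero) tab$rho[is.na(tab$rho)] <- 0
  ok <- tab[!is.na(tab$rho), c("subject_id", "rho", "n_rows")]
  stop_if_not(nrow(ok) > 0, "per-speaker rho undefined for every speaker")
  list(per_speaker = ok, mean_rho = mean(ok$rho), excluded = excluded)
}

#' Global mean absolute error, per fold
#'
#' MAE takes all predictions of a fold into account (row-weighted, unlike
#' the speaker-weighted rank correlations).
#'
#' @param pred_table Data.frame with `y_true`, `y_pred` and a `fold`
#'   column.
#' @return A list: `per_fold` (data.frame fold, mae, n), `mean`, `sd`
#'   (over folds).
#' @export
global_mae <- function(pred_table) {
  stop_if_not(nrow(pred_table) > 0, "empty prediction table")
  sp <- split(pred_table, pred_table$fold)
  per_fold <- do.call(rbind, lapply(names(sp), function(f) {
    d <- sp[[f]]
    data.frame(fold = f, mae = mean(abs(d$y_true - d$y_pred)), n = nrow(d),
               stringsAsFactors = FALSE)
  }))
  list(per_fold = per_fold, mean = mean(per_fold$mae),
       sd = if (nrow(per_fold) > 1) stats::sd(per_fold$mae) else NA_real_)
}

#' Full evaluation report for a prediction table
#'
#' Overall numbers are computed per fold and then averaged over folds.
#' Breakdowns by diagnostic group and by speech content use the
#' corresponding row subsets (per-speaker rho stays speaker-weighted
#' within each subset).
#'
#' @param pred_table Data.frame with keys, `y_true`, `y_pred`, `fold`.
#' @param subjects Cohort data.frame (for group membership).
#' @param undefined_as_zero See [per_speaker_rho()].
#' @return A list of class `eval_report`: `mae` (mean, sd, per fold),
#'   `speaker_rho` (mean, sd over folds, per-fold means, per-speaker
#'   table), `by_group`, `by_content`, `excluded`.
#' @export
evaluate_predictions <- function(pred_table, subjects,
                                 undefined_as_zero = FALSE) {
  pt <- pred_table
  pt$group <- subjects$group[match(pt$subject_id, subjects$subject_id)]
  folds <- sort(unique(pt$fold))

  fold_stat <- function(d) {
    tryCatch(per_speaker_rho(d, undefined_as_zero)$mean_rho,
             error = function(e) NA_real_)
  }
  mean_sd_over_folds <- function(d) {
    vals <- vapply(folds[folds %in% d$fold],
                   function(f) fold_stat(d[d$fold == f, ]), numeric(1))
    vals <- vals[!is.na(vals)]
    c(mean = if (length(vals) > 0) mean(vals) else NA_real_,
      sd = if (length(vals) > 1) stats::sd(vals) else NA_real_)
  }

  all_ps <- per_speaker_rho(pt, undefined_as_zero)
  by_group <- lapply(split(pt, pt$group), mean_sd_over_folds)
  by_content <- lapply(split(pt, pt$content), mean_sd_over_folds)

  structure(list(
    mae = global_mae(pt),
    speaker_rho = list(
      mean = mean_sd_over_folds(pt)[["mean"]],
      sd = mean_sd_over_folds(pt)[["sd"]],
      per_speaker = all_ps$per_speaker
    ),
    by_group = by_group,
    by_content = by_content,
    excluded = all_ps$excluded
  ), class = "eval_report")
}

#' Correlations of predictions with questionnaire totals
#'
#' Pairs every prediction row with its subject's PHQ-9, HRSD-24 and
#' SEK-27 totals (and with the ground-truth mood rating), computes the
#' global Spearman correlation per fold and averages over folds. The
#' ground-truth row (`y_true` against the same totals) calibrates the
#' generator itself.
#'
#' @param pred_table Data.frame with `subject_id`, `y_true`, `y_pred`,
#'   `fold`.
#' @param subjects Cohort data.frame with item columns.
#' @return A data.frame: rows `prediction` and `ground_truth`, columns
#'   `phq`, `hrsd`, `sek`, `ground_truth` (mean over folds).
#' @export
metadata_correlations <- function(pred_table, subjects) {
  totals <- questionnaire_summaries(subjects)
  idx <- match(pred_table$subject_id, totals$subject_id)
  stop_if_not(!anyNA(idx), "questionnaire totals missing for some subjects")
  phq <- totals$phq9_total[idx]
  hrsd <- totals$hrsd_total[idx]
  sek <- totals$sek_total[idx]
  per_fold <- function(v) {
    vapply(split(seq_len(nrow(pred_table)), pred_table$fold), function(r) {
      c(phq = spearman_rho(v[r], phq[r]),
        hrsd = spearman_rho(v[r], hrsd[r]),
        sek = spearman_rho(v[r], sek[r]),
        ground_truth = spearman_rho(v[r], pred_table$y_true[r]))
    }, numeric(4))
  }
  pred_m <- rowMeans(per_fold(pred_table$y_pred))
  gt_m <- rowMeans(per_fold(pred_table$y_true))
  out <- rbind(prediction = pred_m, ground_truth = gt_m)
  colnames(out) <- c("phq", "hrsd", "sek", "ground_truth")
  as.data.frame(out)
}

#' Gini index of a set of values
#'
#' `G = sum_ij |v_i - v_j| / (2 n^2 vbar)` on raw values. When negative
#' values are present the standard formula is only reported if the mean
#' is positive; a clip-at-zero variant is always available.
#'
#' @param values Numeric vector (>= 2 values).
#' @param clip_negative Clip values at zero before applying the formula.
#' @return Scalar Gini index.
#' @export
gini_index <- function(values, clip_negative = FALSE) {
  stop_if_not(length(values) >= 2, "need at least two values")
  v <- if (clip_negative) pmax(values, 0) else values
  vbar <- mean(v)
  if (vbar <= 0) {
    stop("Gini index undefined: mean of values is not positive; ",
         "use clip_negative = TRUE", call. = FALSE)
  }
  n <- length(v)
  sv <- sort(v)
  # O(n log n) equivalent of the double sum
  sum((2 * seq_len(n) - n - 1) * sv) / (n^2 * vbar)
}

#' Winners and losers of a personalization intervention
#'
#' A speaker is a winner iff the personalized model's per-speaker rho
#' strictly exceeds the baseline's, a loser iff it is strictly lower.
#' Percent change is `(rho_pers - rho_base) / |rho_base|`; speakers with
#' `|rho_base|` below `floor` fall back to absolute change and are
#' flagged.
#'
#' @param rho_baseline,rho_personalized Named numeric vectors (names =
#'   subject ids) over the same speaker set.
#' @param floor Denominator floor for percent changes.
#' @return A list: `winners`, `losers`, `unchanged` (counts),
#'   `winner_mean_pct`, `loser_mean_pct` (mean percent change within each
#'   camp, in percent), `fallback_speakers`.
#' @export
winners_losers <- function(rho_baseline, rho_personalized, floor = 0.01) {
  stop_if_not(length(rho_baseline) == length(rho_personalized),
              "speaker sets differ in length")
  if (!is.null(names(rho_baseline)) && !is.null(names(rho_personalized))) {
    stop_if_not(setequal(names(rho_baseline), names(rho_personalized)),
                "speaker sets are misaligned")
    rho_personalized <- rho_personalized[names(rho_baseline)]
  }
  delta <- rho_personalized - rho_baseline
  win <- delta > 0; lose <- delta < 0
  small <- abs(rho_baseline) < floor
  pct <- ifelse(small, delta, delta / abs(rho_baseline)) * 100
  list(
    winners = sum(win), losers = sum(lose), unchanged = sum(delta == 0),
    winner_mean_pct = if (any(win)) mean(pct[win]) else NA_real_,
    loser_mean_pct = if (any(lose)) mean(pct[lose]) else NA_real_,
    fallback_speakers = names(rho_baseline)[small] %||% character(0)
  )
}

#' Fairness report comparing a baseline and a personalized model
#'
#' @param pred_baseline,pred_personalized Prediction tables over the same
#'   speakers and folds.
#' @param group_filter Optional diagnostic group to restrict to (with
#'   `subjects` supplied).
#' @param subjects Cohort data.frame (needed for `group_filter`).
#' @return A list of class `fairness_report`: per-fold and mean Gini for
#'   both models (raw and clipped variants when they differ),
#'   winners/losers summary.
#' @export
fairness_report <- function(pred_baseline, pred_personalized,
                            group_filter = NULL, subjects = NULL) {
  filt <- function(pt) {
    if (is.null(group_filter)) return(pt)
    stop_if_not(!is.null(subjects), "subjects required for group_filter")
    keep <- subjects$subject_id[subjects$group == group_filter]
    pt[pt$subject_id %in% keep, ]
  }
  pb <- filt(pred_baseline); pp <- filt(pred_personalized)
  gini_by_fold <- function(pt) {
    vapply(split(pt, pt$fold), function(d) {
      rho <- per_speaker_rho(d)$per_speaker$rho
      has_neg <- any(rho < 0)
      raw <- if (mean(rho) > 0) gini_index(rho) else NA_real_
      clip <- gini_index(rho, clip_negative = TRUE)
      c(raw = raw, clip = clip, has_neg = as.numeric(has_neg))
    }, numeric(3))
  }
  gb <- gini_by_fold(pb); gp <- gini_by_fold(pp)
  rb <- per_speaker_rho(pb)$per_speaker
  rp <- per_speaker_rho(pp)$per_speaker
  common <- intersect(rb$subject_id, rp$subject_id)
  wl <- winners_losers(stats::setNames(rb$rho, rb$subject_id)[common],
                       stats::setNames(rp$rho, rp$subject_id)[common])
  structure(list(
    gini_baseline = list(per_fold = gb["raw", ], mean = mean(gb["raw", ]),
                         clip_per_fold = gb["clip", ],
                         clip_mean = mean(gb["clip", ])),
    gini_personalized = list(per_fold = gp["raw", ], mean = mean(gp["raw", ]),
                             clip_per_fold = gp["clip", ],
                             clip_mean = mean(gp["clip", ])),
    winners_losers = wl, n_speakers = length(common)
  ), class = "fairness_report")
}

#' Write an evaluation report as JSON
#'
#' The serialization is deterministic: the same prediction table yields a
#' byte-identical file.
#'
#' @param report An `eval_report` (or any list of numbers/data.frames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
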