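# Metadata conditioning vectors -----------------------------------------
#
# Turns subject profiles into the numeric conditioning vector m_S for a
# chosen metadata subset. Questionnaires are encoded item-level (not as
# totals), continuous fields are z-scored with statistics fitted on
# training-fold subjects only, ordinals are passed as scaled integers and
# categoricals one-hot.

METADATA_SUBSETS <- c("all", "phq9", "hrsd", "bdi", "depression_tests",
                      "demographics_medication", "sek", "personality")

#' Resolve a metadata subset name to its field list
#'
#' Subsets mirror the ablation families of the emulated study: single
#' instruments, the union of the three depression tests, demographics plus
#' medication, and the full set.
#'
#' @param name One of `"all"`, `"phq9"`, `"hrsd"`, `"bdi"`,
#'   `"depression_tests"`, `"demographics_medication"`, `"sek"`,
#'   `"personality"`.
#' @return A list with `name`, `demographics` (logical) and `items`
#'   (instrument item column names, possibly empty).
#' @export
resolve_subset <- function(name) {
  stop_if_not(is.character(name) && length(name) == 1 && name %in% METADATA_SUBSETS,
              paste("unknown metadata subset; choose one of:",
                    paste(METADATA_SUBSETS, collapse = ", ")))
  instruments <- switch(name,
    all = c("phq9", "hrsd", "bdi", "sek", "tipi"),
    phq9 = "phq9", hrsd = "hrsd", bdi = "bdi",
    depression_tests = c("phq9", "hrsd", "bdi"),
    demographics_medication = character(0),
    sek = "sek", personality = "tipi")
  list(
    name = name,
    demographics = name %in% c("all", "demographics_medication"),
    items = unlist(lapply(instruments, instrument_columns), use.names = FALSE)
  )
}

demographic_block_names <- function() {
  c("age", "gender_m", "gender_f", "gender_diverse",
    "school_degree", "professional_degree", "full_time_job",
    "med_voice", "med_mood")
}

#' Dimension of a metadata subset's encoding
#'
#' @param name Subset name (see [resolve_subset()]).
#' @return Integer encoding dimension.
#' @export
subset_dimension <- function(name) {
  spec <- resolve_subset(name)
  length(spec$items) + if (spec$demographics) length(demographic_block_names()) else 0L
}

#' Fit normalization statistics on training-fold subjects
#'
#' Estimates per-field mean and scale for the continuous fields of a
#' subset (age and all questionnaire items) on training subjects only.
#' Constant fields get scale 1 so no field is divided by (near) zero.
#'
#' @param train_subjects Cohort rows of the training fold (>= 2 subjects).
#' @param subset Subset name.
#' @return A list of class `normalization_stats` with `subset`, `fields`,
#'   `center`, `scale`.
#' @export
fit_normalizer <- function(train_subjects, subset) {
  stop_if_not(nrow(train_subjects) >= 2, "need at least two training subjects")
  spec <- resolve_subset(subset)
  fields <- c(if (spec$demographics) "age", spec$items)
  if (length(fields) == 0) {
    center <- numeric(0); scale <- numeric(0)
  } else {
    m <- as.matrix(train_subjects[, fields, drop = FALSE])
    stop_if_not(!anyNA(m), "missing metadata values in training subjects")
    center <- colMeans(m)
    scale <- apply(m, 2, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  }
  structure(list(subset = subset, fields = fields,
                 center = as.numeric(center), scale = as.numeric(scale)),
            class = "normalization_stats")
}

#' Encode subjects as metadata conditioning vectors
#'
#' Deterministically maps cohort rows to the numeric vector `m_S` of a
#' subset: z-scored continuous fields (age, questionnaire items), ordinal
#' degrees scaled to `[0, 1]` (`{0,1,2,3}/3`), binary flags as 0/1 and
#' gender one-hot over (m, f, diverse).
#'
#' @param subjects One or more cohort rows.
#' @param subset Subset name.
#' @param stats A [fit_normalizer()] result for the same subset, fitted on
#'   subjects disjoint from any test fold.
#' @return A numeric matrix (subjects x dimension) with named columns;
#'   the index ranges of each block are attached as attribute
#'   `field_map`.
#' @export
encode_metadata <- function(subjects, subset, stats) {
  spec <- resolve_subset(subset)
  stop_if_not(inherits(stats, "normalization_stats"),
              "stats must come from fit_normalizer()")
  stop_if_not(identical(stats$subset, subset),
              "normalization stats were fitted for a different subset")
  n <- nrow(subjects)
  blocks <- list()
  if (spec$demographics) {
    stop_if_not(!anyNA(subjects[, c("age", "gender", "school_degree",
                                    "professional_degree", "full_time_job",
                                    "med_voice", "med_mood")]),
                "missing demographic metadata")
    age_i <- match("age", stats$fields)
    demo <- cbind(
      age = (subjects$age - stats$center[age_i]) / stats$scale[age_i],
      gender_m = as.numeric(subjects$gender == "m"),
      gender_f = as.numeric(subjects$gender == "f"),
      gender_diverse = as.numeric(subjects$gender == "diverse"),
      school_degree = subjects$school_degree / 3,
      professional_degree = subjects$professional_degree / 3,
      full_time_job = as.numeric(subjects$full_time_job),
      med_voice = as.numeric(subjects$med_voice),
      med_mood = as.numeric(subjects$med_mood)
    )
    blocks$demographics_medication <- demo
  }
  if (length(spec$items) > 0) {
    m <- as.matrix(subjects[, spec$items, drop = FALSE])
    stop_if_not(!anyNA(m), "missing questionnaire metadata")
    idx <- match(spec$items, stats$fields)
    stop_if_not(!anyNA(idx), "normalization stats do not cover subset items")
    z <- sweep(sweep(m, 2, stats$center[idx]), 2, stats$scale[idx], "/")
    blocks$items <- z
  }
  out <- do.call(cbind, unname(blocks))
  rownames(out) <- subjects$subject_id
  field_map <- list()
  pos <- 0L
  for (nm in names(blocks)) {
    field_map[[nm]] <- c(pos + 1L, pos + ncol(blocks[[nm]]))
    pos <- pos + ncol(blocks[[nm]])
  }
  attr(out, "field_map") <- field_map
  attr(out, "subset") <- subset
  out
}

#' Serialize / restore normalization statistics as JSON
#'
#' @param stats A `normalization_stats` object.
#' @param path File path.
#' @return `path` invisibly (writer); a `normalization_stats` (reader).
#' @export
write_normalizer_json <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalizer_json
#' @export
read_normalizer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(subset = x$subset, fields = x$fields,
                 center = as.numeric(x$center), scale = as.numeric(x$scale)),
            class = "normalization_stats")
}
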