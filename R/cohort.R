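# Synthetic study cohort ------------------------------------------------
#
# Emulates a three-group longitudinal depression study: healthy controls
# (PHQ-9 total <= 4), a subclinical group and a patient group (both
# PHQ-9 > 4), each subject carrying demographics, medication flags and
# item-level scores for five instruments (HRSD-24, PHQ-9, BDI, SEK-27,
# TIPI). A single latent severity scalar per subject drives all
# depression-instrument means (and later the mood process), so instrument
# totals are mutually correlated as they are clinically.

#' Instrument item counts and ranges
#'
#' Item counts and per-item score ranges for the five instruments carried
#' by every synthetic subject.
#'
#' @return A data.frame with columns `instrument`, `n_items`, `k_max`
#'   (maximum per-item score).
#' @export
instrument_table <- function() {
  data.frame(
    instrument = c("hrsd", "phq9", "bdi", "sek", "tipi"),
    n_items = c(24L, 9L, 21L, 27L, 10L),
    k_max = c(4L, 3L, 3L, 4L, 6L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the composition of the emulated study: 47 controls,
#' 48 subclinical subjects and 48 patients aged 18-63, with a gender mix
#' of roughly one third male, two thirds female and a small diverse
#' fraction.
#'
#' @param n_control,n_subclinical,n_patients Group sizes (exact, not
#'   expected values).
#' @param age_range Inclusive age bounds in years.
#' @param gender_probs Length-3 probability vector (m, f, diverse).
#' @param severity_means,severity_sd Group means (control, subclinical,
#'   patient) and common SD of the latent severity scalar shared by all
#'   depression instruments and the mood process.
#' @param severity_coupling Multiplier in `[0, 1]` on the item-mean loading
#'   of the shared severity latent; 1 gives the default inter-instrument
#'   correlation, 0 decouples the instruments.
#' @param sek_direction Sign of the SEK item-mean loading on severity.
#'   `-1` (default) encodes that better emotion-regulation skills go with
#'   lower severity; `+1` flips the direction.
#' @param seed Integer base seed; every subject derives an independent
#'   substream from `(seed, subject_id)`.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 47L, n_subclinical = 48L, n_patients = 48L,
                          age_range = c(18L, 63L),
                          gender_probs = c(0.335, 0.658, 0.007),
                          severity_means = c(-1.3, 0.1, 1.4),
                          severity_sd = 0.55,
                          severity_coupling = 1,
                          sek_direction = -1,
                          seed = 1L) {
  stop_if_not(all(c(n_control, n_subclinical, n_patients) >= 0),
              "group sizes must be non-negative")
  stop_if_not(length(gender_probs) == 3 && all(gender_probs >= 0) &&
                abs(sum(gender_probs) - 1) < 1e-8,
              "gender_probs must be a 3-vector of probabilities summing to 1")
  stop_if_not(length(age_range) == 2 && age_range[1] <= age_range[2],
              "age_range must be increasing")
  stop_if_not(sek_direction %in% c(-1, 1), "sek_direction must be -1 or +1")
  structure(list(
    n_control = as.integer(n_control),
    n_subclinical = as.integer(n_subclinical),
    n_patients = as.integer(n_patients),
    age_range = age_range,
    gender_probs = gender_probs,
    severity_means = severity_means,
    severity_sd = severity_sd,
    severity_coupling = severity_coupling,
    sek_direction = sek_direction,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Item-mean models: mean item score is an affine, clipped function of the
# subject's latent severity. Loadings were fixed once so that group totals
# separate monotonically (patients > subclinical > control on depression
# instruments, reversed for SEK) with realistic overlap.
item_mean_model <- function(instrument, severity, cfg) {
  cpl <- cfg$severity_coupling
  switch(instrument,
    phq9 = 0.55 + 0.75 * cpl * severity,
    hrsd = 0.40 + 0.60 * cpl * severity,
    bdi  = 0.35 + 0.55 * cpl * severity,
    sek  = 2.60 + cfg$sek_direction * 0.55 * cpl * severity,
    tipi = 3.0, # handled per item below
    stop("unknown instrument")
  )
}

item_sd_model <- function(instrument) {
  switch(instrument,
    phq9 = 0.55, hrsd = 0.60, bdi = 0.50, sek = 0.70, tipi = 1.2)
}

# TIPI: only the neuroticism-flavoured items load on severity.
tipi_loadings <- c(0, 0, 0, 0.5, 0, 0, 0, 0, -0.4, 0)

phq_constraint_ok <- function(items, group) {
  total <- sum(items)
  if (group == "control") total <= 4 else total > 4
}

# Deterministic fix-up used only if rejection sampling fails to satisfy the
# PHQ screening constraint after many tries (essentially impossible at
# default settings but guarantees termination for extreme configs).
force_phq_constraint <- function(items, group) {
  if (group == "control") {
    while (sum(items) > 4) items[which.max(items)] <- items[which.max(items)] - 1L
  } else {
    while (sum(items) <= 4) items[which.min(items)] <- items[which.min(items)] + 1L
  }
  items
}

generate_subject <- function(subject_id, group, cfg) {
  it <- instrument_table()
  with_local_seed(substream_seed(cfg$seed, "subject", subject_id), {
    g_idx <- match(group, c("control", "subclinical", "patient"))
    severity <- stats::rnorm(1, cfg$severity_means[g_idx], cfg$severity_sd)

    age <- round(min(max(stats::rnorm(1, 32.7, 11.0), cfg$age_range[1]),
                     cfg$age_range[2]))
    gender <- sample(c("m", "f", "diverse"), 1, prob = cfg$gender_probs)
    school_degree <- sample(0:3, 1, prob = c(0.05, 0.15, 0.30, 0.50))
    professional_degree <- sample(0:3, 1, prob = c(0.10, 0.25, 0.30, 0.35))
    full_time_job <- stats::rbinom(1, 1, 0.55)
    med_voice <- stats::rbinom(1, 1, c(0.05, 0.08, 0.12)[g_idx])
    med_mood <- stats::rbinom(1, 1, c(0.02, 0.10, 0.50)[g_idx])

    items <- list()
    for (r in seq_len(nrow(it))) {
      ins <- it$instrument[r]
      if (ins == "tipi") {
        mu <- 3.0 + tipi_loadings * cfg$severity_coupling * severity
      } else {
        mu <- rep(item_mean_model(ins, severity, cfg), it$n_items[r])
      }
      sc <- sample_item_scores(it$n_items[r], mu, item_sd_model(ins), it$k_max[r])
      if (ins == "phq9") {
        tries <- 0L
        while (!phq_constraint_ok(sc, group) && tries < 100L) {
          sc <- sample_item_scores(it$n_items[r], mu, item_sd_model(ins), it$k_max[r])
          tries <- tries + 1L
        }
        if (!phq_constraint_ok(sc, group)) sc <- force_phq_constraint(sc, group)
      }
      items[[ins]] <- as.integer(sc)
    }

    c(
      list(subject_id = subject_id, group = group, severity = severity,
           age = age, gender = gender,
           school_degree = school_degree,
           professional_degree = professional_degree,
           full_time_job = full_time_job,
           med_voice = med_voice, med_mood = med_mood),
      stats::setNames(
        lapply(seq_len(nrow(it)), function(r) items[[it$instrument[r]]]),
        paste0(it$instrument, "_items"))
    )
  })
}

#' Generate a synthetic study cohort
#'
#' Draws a cohort of subjects in three diagnostic groups. Group sizes are
#' exact; within each group the PHQ-9 screening constraint (controls
#' total <= 4, others > 4) holds for every subject by rejection
#' resampling of the PHQ items. Fixing the seed fixes every sampled field,
#' and each subject's draws come from a substream keyed by
#' `(seed, subject_id)` so enlarging the cohort never perturbs existing
#' subjects.
#'
#' @param cfg A [cohort_config()].
#' @return A data.frame with one row per subject: identifiers, group,
#'   latent `severity` (ground truth, not observable metadata),
#'   demographics, medication flags, and one integer column per
#'   questionnaire item (`phq9_01` ... `tipi_10`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_control = 2, n_subclinical = 2,
#'                                         n_patients = 2, seed = 7))
#' nrow(cohort)
generate_cohort <- function(cfg = cohort_config()) {
  stop_if_not(inherits(cfg, "cohort_config"), "cfg must be a cohort_config")
  n_total <- cfg$n_control + cfg$n_subclinical + cfg$n_patients
  if (n_total == 0L) return(empty_cohort_frame())
  groups <- rep(c("control", "subclinical", "patient"),
                times = c(cfg$n_control, cfg$n_subclinical, cfg$n_patients))
  ids <- sprintf("S%03d", seq_len(n_total))
  rows <- lapply(seq_len(n_total),
                 function(i) subject_to_row(generate_subject(ids[i], groups[i], cfg)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

item_col_names <- function() {
  it <- instrument_table()
  unlist(lapply(seq_len(nrow(it)), function(r) {
    sprintf("%s_%02d", it$instrument[r], seq_len(it$n_items[r]))
  }), use.names = FALSE)
}

subject_to_row <- function(s) {
  it <- instrument_table()
  base <- data.frame(
    subject_id = s$subject_id, group = s$group, severity = s$severity,
    age = s$age, gender = s$gender,
    school_degree = s$school_degree,
    professional_degree = s$professional_degree,
    full_time_job = s$full_time_job,
    med_voice = s$med_voice, med_mood = s$med_mood,
    stringsAsFactors = FALSE
  )
  items <- unlist(lapply(seq_len(nrow(it)), function(r) {
    s[[paste0(it$instrument[r], "_items")]]
  }))
  item_df <- as.data.frame(as.list(as.integer(items)))
  names(item_df) <- item_col_names()
  cbind(base, item_df)
}

empty_cohort_frame <- function() {
  cols <- c("subject_id", "group", "severity", "age", "gender",
            "school_degree", "professional_degree", "full_time_job",
            "med_voice", "med_mood", item_col_names())
  out <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
  out
}

#' Instrument columns of a cohort data.frame
#'
#' @param instrument One of `"hrsd"`, `"phq9"`, `"bdi"`, `"sek"`, `"tipi"`.
#' @return Character vector of item column names.
#' @export
instrument_columns <- function(instrument) {
  it <- instrument_table()
  r <- match(instrument, it$instrument)
  stop_if_not(!is.na(r), "unknown instrument")
  sprintf("%s_%02d", instrument, seq_len(it$n_items[r]))
}

#' Questionnaire total scores for one or more subjects
#'
#' Totals are plain item sums: PHQ-9 in `[0, 27]`, HRSD-24 in `[0, 96]`,
#' BDI in `[0, 63]`, SEK-27 in `[0, 108]`, TIPI in `[0, 60]`.
#'
#' @param subjects A cohort data.frame (one or more rows) as returned by
#'   [generate_cohort()].
#' @return A data.frame with `subject_id` and one total column per
#'   instrument (`phq9_total`, `hrsd_total`, ...).
#' @export
questionnaire_summaries <- function(subjects) {
  it <- instrument_table()
  out <- data.frame(subject_id = subjects$subject_id, stringsAsFactors = FALSE)
  for (ins in it$instrument) {
    cols <- instrument_columns(ins)
    m <- as.matrix(subjects[, cols, drop = FALSE])
    out[[paste0(ins, "_total")]] <- as.integer(rowSums(m))
  }
  out
}

#' Write / read a cohort as CSV
#'
#' @param cohort A cohort data.frame.
#' @param path Output file path.
#' @return `path`, invisibly (writer); a cohort data.frame (reader).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
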