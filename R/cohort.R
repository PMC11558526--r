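#' Canonical observation columns
#'
#' Column names of the canonical per-observation table used throughout the
#' package. One row is one timed clinical record: hospitalization day,
#' leukocyte differential (percentages and optional absolute counts),
#' serum markers, blood-culture result, vitals for SIRS scoring, and the
#' 30-day in-hospital outcome.
#'
#' @return Character vector of canonical column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "day",
    "lymph_pct", "neut_pct", "mono_pct", "eos_pct", "baso_pct",
    "wbc_count", "lymph_count", "neut_count", "mono_count",
    "crp", "urea", "creatinine",
    "temperature_c", "heart_rate_bpm", "resp_rate_bpm", "paco2_mmhg",
    "culture", "pathogen_class", "outcome", "chronic_disease")
}

required_columns <- function() {
  c("patient_id", "day", "lymph_pct", "neut_pct", "mono_pct",
    "wbc_count", "outcome")
}

culture_levels  <- function() c("positive", "negative", "not_done")
pathogen_levels <- function() c("MRSA", "MSSA", "ESBL_MBL", "other", "none")
outcome_levels  <- function() c("survived", "died")

#' Construct a validated sepsis cohort
#'
#' Validates a per-observation table against the cohort invariants (strictly
#' positive reported percentages, day >= 1, differential sum <= 100, one
#' outcome per patient), derives the hospitalization week and the per-patient
#' septic status from culture results (septic = at least one positive culture;
#' non-septic = cultures done, none positive; not assigned = no culture done),
#' and collects rows violating row-level invariants into a rejects table
#' rather than dropping them silently.
#'
#' @param observations data.frame using the canonical columns of
#'   [cohort_columns()]; missing optional columns are added as `NA`.
#' @param pct_tol tolerance on the five-part differential sum exceeding 100.
#' @return An object of class `sepsis_cohort`: a list with elements
#'   `observations` (validated, sorted by patient and day, with derived
#'   `week` and `septic_status`), `patients` (one row per patient with
#'   `septic_status` and `outcome`), and `rejects` (rejected input rows with
#'   a `reject_reason` column).
#' @export
sepsis_cohort <- function(observations, pct_tol = 0.5) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  for (cn in setdiff(cohort_columns(), names(obs)))
    obs[[cn]] <- rep(NA, nrow(obs))
  obs <- obs[, cohort_columns()]

  num_cols <- setdiff(cohort_columns(),
                      c("patient_id", "culture", "pathogen_class", "outcome",
                        "chronic_disease"))
  for (cn in num_cols) obs[[cn]] <- suppressWarnings(as.numeric(obs[[cn]]))
  obs$patient_id <- as.character(obs$patient_id)
  obs$culture[is.na(obs$culture)] <- "not_done"
  obs$pathogen_class[is.na(obs$pathogen_class)] <- "none"

  reason <- rep(NA_character_, nrow(obs))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why

  req_na <- Reduce(`|`, lapply(required_columns(),
                               function(cn) is.na(obs[[cn]]) |
                                 (cn == "patient_id" & obs[[cn]] == "")))
  flag(req_na, "missing required field")
  flag(!is.na(obs$day) & (obs$day < 1 | obs$day != floor(obs$day)),
       "invalid hospitalization day")
  pct_cols <- c("lymph_pct", "neut_pct", "mono_pct", "eos_pct", "baso_pct")
  for (cn in pct_cols)
    flag(!is.na(obs[[cn]]) & obs[[cn]] <= 0, "zero percentage")
  for (cn in c("lymph_pct", "neut_pct", "mono_pct"))
    flag(!is.na(obs[[cn]]) & obs[[cn]] > 100, "percentage above 100")
  psum <- rowSums(obs[, pct_cols])   # NA when any of the five is absent
  flag(!is.na(psum) & psum > 100 + pct_tol, "differential exceeds 100")
  flag(!is.na(obs$wbc_count) & obs$wbc_count <= 0, "non-positive WBC count")
  for (cn in c("lymph_count", "neut_count", "mono_count", "crp", "urea",
               "creatinine"))
    flag(!is.na(obs[[cn]]) & obs[[cn]] < 0, paste("negative", cn))
  flag(!obs$culture %in% culture_levels(), "unknown culture value")
  flag(!obs$pathogen_class %in% pathogen_levels(), "unknown pathogen class")
  flag(!is.na(obs$outcome) & !obs$outcome %in% outcome_levels(),
       "unknown outcome value")
  dup <- duplicated(obs[, c("patient_id", "day")]) & is.na(reason)
  flag(dup, "duplicate day for patient")

  rejects <- obs[!is.na(reason), , drop = FALSE]
  rejects$reject_reason <- reason[!is.na(reason)]
  obs <- obs[is.na(reason), , drop = FALSE]

  if (nrow(obs) > 0) {
    if (any(tapply(obs$outcome, obs$patient_id,
                   function(x) length(unique(x))) > 1))
      stopf("outcome differs across observations of the same patient")
    obs <- obs[order(obs$patient_id, obs$day), , drop = FALSE]
    obs$week <- week_of_day(obs$day)
    status <- vapply(split(obs$culture, obs$patient_id), function(cu) {
      if (any(cu == "positive")) "septic"
      else if (any(cu == "negative")) "non_septic"
      else "not_assigned"
    }, character(1))
    obs$septic_status <- unname(status[obs$patient_id])
    patients <- data.frame(
      patient_id = names(status),
      septic_status = unname(status),
      outcome = vapply(split(obs$outcome, obs$patient_id), `[`, character(1), 1),
      n_obs = as.integer(table(obs$patient_id)[names(status)]),
      stringsAsFactors = FALSE)
    rownames(obs) <- rownames(patients) <- NULL
  } else {
    obs$week <- integer(0)
    obs$septic_status <- character(0)
    patients <- data.frame(patient_id = character(0),
                           septic_status = character(0),
                           outcome = character(0), n_obs = integer(0),
                           stringsAsFactors = FALSE)
  }

  structure(list(observations = obs, patients = patients, rejects = rejects),
            class = "sepsis_cohort")
}

#' @export
print.sepsis_cohort <- function(x, ...) {
  cat("Sepsis cohort:", nrow(x$patients), "patients,",
      nrow(x$observations), "observations\n")
  if (nrow(x$patients) > 0)
    print(table(status = x$patients$septic_status))
  if (nrow(x$rejects) > 0)
    cat(nrow(x$rejects), "rejected input rows (see $rejects)\n")
  invisible(x)
}

#' Read a longitudinal cohort table
#'
#' Reads a delimited per-observation file, applies an optional column-mapping
#' configuration, and validates it into a [sepsis_cohort()]. Rows violating
#' row-level invariants (zero percentages, invalid days, unknown enum values,
#' ...) are collected into the cohort's rejects table with a reason, never
#' silently dropped.
#'
#' @param path path to a CSV/TSV file with a header row (UTF-8).
#' @param config `NULL`, a path to a YAML file, or a list. Recognized entries:
#'   `sep` (field separator; default inferred from the file extension) and
#'   `columns`, a named mapping `canonical_name: file_column_name`.
#' @return A `sepsis_cohort`.
#' @export
read_cohort <- function(path, config = NULL) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- config %||% list()
  sep <- config$sep %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, encoding = "UTF-8")
  map <- config$columns
  if (!is.null(map)) {
    for (canon in names(map)) {
      src <- map[[canon]]
      if (!src %in% names(raw))
        stopf("mapped column '%s' (for '%s') not found in %s", src, canon, path)
      names(raw)[names(raw) == src] <- canon
    }
  }
  missing_req <- setdiff(required_columns(), names(raw))
  if (length(missing_req) > 0)
    stopf("missing required column(s): %s", paste(missing_req, collapse = ", "))
  sepsis_cohort(raw)
}

#' Write a cohort back to CSV
#'
#' Inverse of [read_cohort()]: writes the validated observation table using
#' the canonical column names, so that reading it back reproduces all
#' retained fields.
#'
#' @param cohort a `sepsis_cohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  out <- cohort$observations[, cohort_columns(), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' SIRS criteria count
#'
#' Counts how many of the four systemic inflammatory response syndrome
#' criteria are met: (i) body temperature > 38 C, (ii) heart rate > 90
#' beats/minute, (iii) tachypnea or hyperventilation (> 20 breaths/minute or
#' arterial PaCO2 < 32 mm Hg), and (iv) white blood cells >= 12000 or
#' <= 4000 per microliter. Criterion (iii) counts once if either sub-condition
#' holds. Missing inputs contribute nothing; if every input of an observation
#' is missing the count is `NA` (unassessable), not 0.
#'
#' @param temperature_c,heart_rate_bpm,resp_rate_bpm,paco2_mmhg,wbc_count
#'   numeric vectors (recycled to a common length); `NA` allowed.
#' @return Integer vector of counts in 0..4, `NA` where unassessable.
#' @export
sirs_count <- function(temperature_c, heart_rate_bpm, resp_rate_bpm,
                       paco2_mmhg, wbc_count) {
  n <- max(length(temperature_c), length(heart_rate_bpm),
           length(resp_rate_bpm), length(paco2_mmhg), length(wbc_count))
  t  <- rep_len(as.numeric(temperature_c), n)
  hr <- rep_len(as.numeric(heart_rate_bpm), n)
  rr <- rep_len(as.numeric(resp_rate_bpm), n)
  pc <- rep_len(as.numeric(paco2_mmhg), n)
  wb <- rep_len(as.numeric(wbc_count), n)
  ok <- function(x) !is.na(x) & x
  cnt <- ok(t > 38) + ok(hr > 90) + (ok(rr > 20) | ok(pc < 32)) +
    ok(wb >= 12000 | wb <= 4000)
  cnt[is.na(t) & is.na(hr) & is.na(rr) & is.na(pc) & is.na(wb)] <- NA_integer_
  as.integer(cnt)
}

#' Apply the study inclusion rules
#'
#' Retains patients meeting at least two SIRS criteria at admission (the
#' day-1 observation). Patients without a day-1 observation are excluded with
#' reason "no admission sample"; a truthy `chronic_disease` column triggers
#' exclusion. The exclusion report lists every observation of every excluded
#' patient with the reason, so that report rows plus included observations
#' account for every input observation. The operation is idempotent.
#'
#' @param cohort a `sepsis_cohort`.
#' @return List with `cohort` (the included sub-cohort) and `exclusions`
#'   (data.frame: `patient_id`, `day`, `reason`).
#' @export
apply_inclusion <- function(cohort) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  obs <- cohort$observations
  empty <- data.frame(patient_id = character(0), day = numeric(0),
                      reason = character(0), stringsAsFactors = FALSE)
  if (nrow(obs) == 0)
    return(list(cohort = cohort, exclusions = empty))

  reason_by_patient <- vapply(split(obs, obs$patient_id), function(p) {
    if (any(!is.na(p$chronic_disease) &
            (p$chronic_disease %in% c(TRUE, "TRUE", "true", 1, "1", "yes"))))
      return("chronic disease history")
    d1 <- p[p$day == 1, , drop = FALSE]
    if (nrow(d1) == 0) return("no admission sample")
    s <- sirs_count(d1$temperature_c[1], d1$heart_rate_bpm[1],
                    d1$resp_rate_bpm[1], d1$paco2_mmhg[1], d1$wbc_count[1])
    if (is.na(s)) return("SIRS unassessable at admission")
    if (s < 2) return("fewer than two SIRS criteria at admission")
    NA_character_
  }, character(1))

  excluded <- names(reason_by_patient)[!is.na(reason_by_patient)]
  keep <- !(obs$patient_id %in% excluded)
  exclusions <- if (length(excluded) > 0) {
    ex <- obs[!keep, c("patient_id", "day")]
    ex$reason <- unname(reason_by_patient[ex$patient_id])
    rownames(ex) <- NULL
    ex
  } else empty
  list(cohort = sepsis_cohort(obs[keep, , drop = FALSE]),
       exclusions = exclusions)
}

#' Mortality percentage as printed in clinical tables
#'
#' @param deaths,total nonnegative counts.
#' @return `100 * deaths / total` rounded half-up to one decimal; `NA` when
#'   `total` is 0 (undefined, never reported as 0).
#' @export
mortality_pct <- function(deaths, total) {
  out <- ifelse(total > 0, round_half_up(100 * deaths / total, 1), NA_real_)
  unname(out)
}

#' Summarize 30-day in-hospital mortality by septic status
#'
#' For scope `"all_observations"` the unit is the longitudinal observation
#' (each observation inherits its patient's outcome); for `"day1_only"` the
#' unit is the patient with a day-1 sample. Percentages are rounded half-up
#' to one decimal. Groups with no members get an undefined (`NA`) proportion.
#'
#' @param cohort a `sepsis_cohort`.
#' @param scope `"all_observations"` or `"day1_only"`.
#' @return Object of class `cohort_summary`: list with the per-group `table`
#'   (`group`, `total`, `deaths`, `mortality_pct`), overall counts, and the
#'   scope used.
#' @export
summarize_mortality <- function(cohort,
                                scope = c("all_observations", "day1_only")) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  scope <- match.arg(scope)
  unit <- if (scope == "day1_only") {
    d1 <- cohort$observations[cohort$observations$day == 1, , drop = FALSE]
    d1[!duplicated(d1$patient_id), c("septic_status", "outcome")]
  } else {
    cohort$observations[, c("septic_status", "outcome")]
  }
  groups <- c("septic", "non_septic", "not_assigned")
  tab <- do.call(rbind, lapply(groups, function(g) {
    u <- unit[unit$septic_status == g, , drop = FALSE]
    data.frame(group = g, total = nrow(u),
               deaths = sum(u$outcome == "died"),
               stringsAsFactors = FALSE)
  }))
  tab$mortality_pct <- mortality_pct(tab$deaths, tab$total)
  structure(list(scope = scope, table = tab,
                 n_patients = nrow(cohort$patients),
                 n_observations = nrow(cohort$observations),
                 n_septic = sum(cohort$patients$septic_status == "septic"),
                 n_non_septic = sum(cohort$patients$septic_status == "non_septic")),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("30-day in-hospital mortality (",
      if (x$scope == "day1_only") "day-1 patients" else "all observations",
      ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) x$table

#' Day-1 medians of a named ratio by outcome
#'
#' Convenience summary used to compare admission-day ratio distributions of
#' survivors and non-survivors (e.g. the neutrophil/lymphocyte ratio), with
#' the accompanying rank-sum comparison.
#'
#' @param cohort a `sepsis_cohort`.
#' @param ratio one of `"NL"`, `"MN"`, `"NL_over_MN"`, `"MN_over_NL"`.
#' @return List: `median_survived`, `median_died`, `n_survived`, `n_died`,
#'   `p_value` (two-sided rank-sum).
#' @export
day1_ratio_medians <- function(cohort, ratio = "NL") {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  d1 <- cohort$observations[cohort$observations$day == 1, , drop = FALSE]
  d1 <- d1[!duplicated(d1$patient_id), , drop = FALSE]
  if (nrow(d1) == 0) stopf("no day-1 observations")
  r <- named_ratios(d1)[[ratio]]
  a <- r[d1$outcome == "survived"]
  b <- r[d1$outcome == "died"]
  rc <- rank_compare(a, b)
  list(median_survived = stats::median(a), median_died = stats::median(b),
       n_survived = length(a), n_died = length(b), p_value = rc$p_value)
}
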