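# Personalized temporal assessment: per-patient stage sequences, movement in
# indicator space, position against the population reference curve, and
# persistence (immunoparalysis-like) detection.

stage_profile <- function(stage) {
  c(early_inflammation = "inflammation",
    early_immunocompetence = "immunocompetence",
    intermediary_suppression = "immunosuppression",
    late_suppression = "immunosuppression",
    other = "other")[as.character(stage)]
}

#' Build a personalized trajectory
#'
#' Assembles one patient's time-ordered sequence of indicator coordinates
#' and stage labels, the displacement (direction) vectors between
#' consecutive observations, and the patient's percentile position along
#' the population's ordered reference curve at each visit.
#'
#' @param patient_id the patient to extract.
#' @param cohort the `sepsis_cohort` the pattern was computed on.
#' @param pattern a [spatial_pattern()] over the cohort's DI matrix (the
#'   population reference: its curve ordering positions every observation).
#' @param stages stage labels per cohort observation (e.g.
#'   `fitted(immunostage(cohort))`).
#' @return Object of class `trajectory`: list with `patient_id`, `days`,
#'   `weeks`, `coords` (standardized triplet coordinates), `raw` (raw DI
#'   values), `stages`, `directions` (consecutive displacement vectors),
#'   `positions` (population percentile, 0-100), `outcome`, and `flagged`
#'   (`"no dynamics"` for single-observation patients).
#' @export
build_trajectory <- function(patient_id, cohort, pattern, stages) {
  stopifnot(inherits(cohort, "sepsis_cohort"),
            inherits(pattern, "spatial_pattern"))
  obs <- cohort$observations
  stopifnot(length(stages) == nrow(obs))
  idx <- which(obs$patient_id == patient_id)
  if (length(idx) == 0) stopf("unknown patient: %s", patient_id)
  idx <- idx[order(obs$day[idx])]
  n_all <- length(pattern$order)
  pos_in_order <- match(idx, pattern$order)
  coords <- pattern$coords[idx, , drop = FALSE]
  structure(list(
    patient_id = patient_id,
    days = obs$day[idx], weeks = obs$week[idx],
    coords = coords,
    raw = if (!is.null(pattern$raw)) pattern$raw[idx, , drop = FALSE] else coords,
    stages = factor(as.character(stages[idx]), levels = stage_levels()),
    directions = if (length(idx) >= 2) diff(coords) else
      matrix(numeric(0), 0, ncol(coords)),
    positions = 100 * (pos_in_order - 0.5) / n_all,
    outcome = obs$outcome[idx][1],
    flagged = if (length(idx) < 2) "no dynamics" else NA_character_),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory of patient ", x$patient_id, ": ", length(x$days),
      " observation(s), outcome ", x$outcome,
      if (!is.na(x$flagged)) paste0(" [", x$flagged, "]") else "", "\n",
      sep = "")
  print(data.frame(day = x$days, week = x$weeks, stage = x$stages,
                   position_pct = round(x$positions, 1)), row.names = FALSE)
  invisible(x)
}

#' Detect a persistent (immunoparalysis-like) profile
#'
#' `TRUE` when the patient holds a constant stage label with indicator
#' coordinates varying less than `tol` (relative range on the raw DI scale,
#' per axis) over at least `min_weeks` distinct consecutive weeks — the
#' unaltered-profile signature suggesting long-term immunosuppression.
#' Monotone in `tol`.
#'
#' @param trajectory a [build_trajectory()] object carrying raw DI values,
#'   or any list with `weeks`, `stages` and a numeric coordinate matrix in
#'   `raw` (falling back to `coords`).
#' @param min_weeks minimal number of distinct weeks (default 3).
#' @param tol maximal relative coordinate variation (default 0.10).
#' @return List: `persistent` (logical), `span` (first/last day of the
#'   qualifying run, or `NULL`), `reason`.
#' @export
detect_persistence <- function(trajectory, min_weeks = 3, tol = 0.10) {
  wk <- trajectory$weeks
  if (length(unique(wk)) < min_weeks)
    return(list(persistent = FALSE, span = NULL, reason = "insufficient span"))
  co <- trajectory$raw %||% trajectory$coords
  runs <- split(seq_along(wk), cumsum(c(1, diff(as.integer(trajectory$stages)) != 0)))
  for (r in runs) {
    if (length(unique(wk[r])) < min_weeks) next
    seg <- co[r, , drop = FALSE]
    rel <- apply(seg, 2, function(v) {
      ctr <- mean(abs(v))
      if (ctr == 0) 0 else diff(range(v)) / ctr
    })
    if (all(rel < tol))
      return(list(persistent = TRUE,
                  span = c(trajectory$days[r[1]], trajectory$days[r[length(r)]]),
                  reason = sprintf("stage %s unaltered over %d weeks",
                                   as.character(trajectory$stages[r[1]]),
                                   length(unique(wk[r])))))
  }
  list(persistent = FALSE, span = NULL, reason = "no persistent run")
}

#' Per-patient trajectory report for a cohort
#'
#' Summarizes every patient: dominant profile (inflammation,
#' immunocompetence, immunosuppression, or other; ties resolved toward the
#' most severe), persistence flag, terminal population position, and
#' outcome, with cohort roll-up counts as an attribute.
#'
#' @param cohort a `sepsis_cohort`.
#' @param pattern a [spatial_pattern()] over the cohort.
#' @param stages stage labels per cohort observation.
#' @param min_weeks,tol passed to [detect_persistence()].
#' @return data.frame, one row per patient: `patient_id`, `n_obs`,
#'   `dominant_profile`, `persistent`, `terminal_position`, `outcome`;
#'   attribute `rollup` tabulates dominant profiles.
#' @export
cohort_trajectory_report <- function(cohort, pattern, stages,
                                     min_weeks = 3, tol = 0.10) {
  stopifnot(inherits(cohort, "sepsis_cohort"))
  ids <- cohort$patients$patient_id
  if (length(ids) == 0) {
    out <- data.frame(patient_id = character(0), n_obs = integer(0),
                      dominant_profile = character(0), persistent = logical(0),
                      terminal_position = numeric(0), outcome = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "rollup") <- table(character(0))
    return(out)
  }
  severity <- c(immunosuppression = 4, inflammation = 3, other = 2,
                immunocompetence = 1)
  rows <- lapply(ids, function(pid) {
    tr <- build_trajectory(pid, cohort, pattern, stages)
    prof <- stage_profile(tr$stages)
    cnt <- table(prof)
    top <- names(cnt)[cnt == max(cnt)]
    dominant <- top[order(-severity[top])][1]
    pers <- detect_persistence(tr, min_weeks = min_weeks, tol = tol)
    data.frame(patient_id = pid, n_obs = length(tr$days),
               dominant_profile = dominant, persistent = pers$persistent,
               terminal_position = tr$positions[length(tr$positions)],
               outcome = tr$outcome, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rollup") <- table(profile = out$dominant_profile)
  out
}
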