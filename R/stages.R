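# Five-stage inflammatory classification. The stage signatures are directions
# (ratios "increased" or "approaching zero", renal markers elevated) made
# quantitative as cohort quantiles; temporal constraints restrict suppression
# to weeks >= 2 and early immunocompetence to week 1.

#' Inflammatory stage labels
#' @return Character vector of the five stage labels, in rule-precedence order
#'   of their signatures' specificity.
#' @export
stage_levels <- function() {
  c("early_inflammation", "early_immunocompetence",
    "intermediary_suppression", "late_suppression", "other")
}

stage_marker_names <- function() c("NL", "NL_over_MN", "MN", "urea", "creatinine")

# marker frame (classifier inputs) from an observation table
stage_markers <- function(obs) {
  if (inherits(obs, "sepsis_cohort")) obs <- obs$observations
  r <- named_ratios(obs)
  data.frame(week = if ("week" %in% names(obs)) obs$week else week_of_day(obs$day),
             NL = r$NL, NL_over_MN = r$NL_over_MN, MN = r$MN,
             urea = if ("urea" %in% names(obs)) obs$urea else NA_real_,
             creatinine = if ("creatinine" %in% names(obs)) obs$creatinine else NA_real_)
}

#' Fit cohort-quantile cutpoints for the stage rules
#'
#' Resolves the qualitative stage signatures ("increased", "approaching
#' zero") into numeric cutpoints: "high" is the `q_high` cohort quantile
#' (default 0.75) and "low"/"approaching zero" the `q_low` quantile (default
#' 0.10) of each marker's cohort distribution. Deterministic (type-7
#' quantiles). Constant markers are flagged degenerate.
#'
#' @param markers a `sepsis_cohort`, an observation data.frame, or a marker
#'   data.frame with columns `NL`, `NL_over_MN`, `MN`, `urea`, `creatinine`
#'   (>= 20 rows of observations).
#' @param q_low,q_high cutpoint quantiles, `0 <= q_low < q_high <= 1`.
#' @return Object of class `stage_rules`: list with the `cutpoints` matrix
#'   (marker x low/high), the quantiles used, `n`, and `degenerate` flags.
#' @export
fit_cutpoints <- function(markers, q_low = 0.10, q_high = 0.75) {
  if (!(q_low >= 0 && q_low < q_high && q_high <= 1))
    stopf("fit_cutpoints: need 0 <= q_low < q_high <= 1")
  if (inherits(markers, "sepsis_cohort") ||
      all(c("lymph_pct", "neut_pct") %in% names(markers)))
    markers <- stage_markers(markers)
  if (nrow(markers) < 20)
    stopf("fit_cutpoints: need >= 20 observations, got %d", nrow(markers))
  mn <- stage_marker_names()
  cp <- matrix(NA_real_, length(mn), 2, dimnames = list(mn, c("low", "high")))
  for (m in mn) {
    v <- markers[[m]]
    if (is.null(v) || all(is.na(v)))
      stopf("fit_cutpoints: marker '%s' entirely missing", m)
    cp[m, ] <- stats::quantile(v, c(q_low, q_high), na.rm = TRUE, names = FALSE)
  }
  structure(list(cutpoints = cp, q_low = q_low, q_high = q_high,
                 n = nrow(markers),
                 degenerate = cp[, "low"] == cp[, "high"]),
            class = "stage_rules")
}

#' @export
print.stage_rules <- function(x, ...) {
  cat(sprintf("Stage rules: quantile cutpoints (low = %.2f, high = %.2f) from %d observations\n",
              x$q_low, x$q_high, x$n))
  print(round(x$cutpoints, 4))
  if (any(x$degenerate))
    cat("degenerate (constant) marker(s):",
        paste(names(which(x$degenerate)), collapse = ", "), "\n")
  invisible(x)
}

#' Classify observations into inflammatory stages
#'
#' Applies the stage rules in fixed precedence order, first match wins:
#' \enumerate{
#'   \item late suppression: week >= 2 and urea high and creatinine high
#'     (renal dysfunction; structurally impossible in week 1);
#'   \item intermediary suppression: week >= 2 and N/L high and
#'     \eqn{[N/L]/[M/N]} high, without the joint renal elevation
#'     (monocyte-mediated suppression);
#'   \item early immunocompetence: week 1 only, N/L and urea approaching
#'     zero with a high monocyte/neutrophil ratio;
#'   \item early inflammation: N/L high while \eqn{[N/L]/[M/N]} approaches
#'     zero;
#'   \item otherwise: other.
#' }
#' Rules whose markers are missing are skipped with an "unassessable" note
#' in the provenance and evaluation falls through.
#'
#' @param newdata a `sepsis_cohort`, observation data.frame, or marker
#'   data.frame (columns `week`, `NL`, `NL_over_MN`, `MN`, `urea`,
#'   `creatinine`).
#' @param rules a fitted [fit_cutpoints()] object.
#' @return Factor of stage labels (levels [stage_levels()]) with a
#'   `provenance` attribute: a data.frame recording every evaluated
#'   condition, missing-marker notes, and the matched rule.
#' @export
classify_stage <- function(newdata, rules) {
  stopifnot(inherits(rules, "stage_rules"))
  if (inherits(newdata, "sepsis_cohort") ||
      all(c("lymph_pct", "neut_pct") %in% names(newdata)))
    newdata <- stage_markers(newdata)
  cp <- rules$cutpoints
  hi <- function(m) !is.na(newdata[[m]]) & newdata[[m]] >= cp[m, "high"]
  lo <- function(m) !is.na(newdata[[m]]) & newdata[[m]] <= cp[m, "low"]
  wk <- newdata$week
  if (anyNA(wk)) stopf("classify_stage: missing week")

  renal_hi <- hi("urea") & hi("creatinine")
  r_late <- wk >= 2 & renal_hi
  r_int  <- wk >= 2 & hi("NL") & hi("NL_over_MN") & !renal_hi
  r_comp <- wk == 1 & lo("NL") & lo("urea") & hi("MN")
  r_infl <- hi("NL") & lo("NL_over_MN")

  lab <- rep("other", nrow(newdata))
  lab[r_infl] <- "early_inflammation"
  lab[r_comp] <- "early_immunocompetence"
  lab[r_int]  <- "intermediary_suppression"
  lab[r_late] <- "late_suppression"

  prov <- data.frame(
    week = wk,
    NL_high = hi("NL"), NL_low = lo("NL"),
    NLMN_high = hi("NL_over_MN"), NLMN_low = lo("NL_over_MN"),
    MN_high = hi("MN"), urea_high = hi("urea"), urea_low = lo("urea"),
    creatinine_high = hi("creatinine"),
    renal_unassessable = is.na(newdata$urea) | is.na(newdata$creatinine),
    matched_rule = lab, stringsAsFactors = FALSE)
  structure(factor(lab, levels = stage_levels()), provenance = prov)
}

#' Per-stage mortality table
#'
#' Counts, deaths and mortality percentages per stage label, with the
#' chi-square association between stage and outcome across the occupied
#' stages. Stages with no observations are reported with an undefined
#' (`NA`) proportion.
#'
#' @param stages factor of stage labels per observation.
#' @param outcome `"survived"`/`"died"` per observation.
#' @return Object of class `stage_outcome`: list with `table` (stage, n,
#'   deaths, mortality_pct) and `association` (chi2/df/p, or `NULL` when
#'   the margins are degenerate).
#' @export
stage_outcome_table <- function(stages, outcome) {
  if (length(stages) == 0) stopf("stage_outcome_table: empty cohort")
  stopifnot(length(stages) == length(outcome))
  stages <- factor(stages, levels = stage_levels())
  tab <- do.call(rbind, lapply(levels(stages), function(s) {
    o <- outcome[stages == s]
    data.frame(stage = s, n = length(o), deaths = sum(o == "died"),
               stringsAsFactors = FALSE)
  }))
  tab$mortality_pct <- mortality_pct(tab$deaths, tab$n)
  occ <- tab[tab$n > 0, , drop = FALSE]
  ct <- cbind(died = occ$deaths, survived = occ$n - occ$deaths)
  assoc <- if (nrow(ct) >= 2 && all(colSums(ct) > 0))
    contingency_test(ct) else NULL
  structure(list(table = tab, association = assoc), class = "stage_outcome")
}

#' @export
print.stage_outcome <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.null(x$association))
    cat(sprintf("stage-outcome association: chi2 = %.2f, df = %d, p = %.3g\n",
                x$association$chi2, x$association$df, x$association$p_value))
  invisible(x)
}

#' Fit the five-stage inflammatory classifier to a cohort
#'
#' The central model of the package: computes the classifier markers (N/L,
#' \eqn{[N/L]/[M/N]}, M/N ratios from the leukocyte differential; serum urea
#' and creatinine), resolves the qualitative stage signatures into cohort
#' quantile cutpoints ([fit_cutpoints()]), assigns every observation one of
#' the five inflammatory stages ([classify_stage()]), and tabulates stage
#' against the 30-day outcome.
#'
#' @param cohort a `sepsis_cohort` (or observation data.frame with the
#'   canonical columns).
#' @param q_low,q_high the "approaching zero" / "increased" cohort
#'   quantiles (defaults 0.10 and 0.75).
#' @return Object of class `immunostage`: list with `rules` (the fitted
#'   cutpoints), `stages` (factor per observation, with provenance),
#'   `outcome_table`, the observation keys, and the call. Methods:
#'   `print`, `summary`, `coef` (cutpoint matrix), `fitted` (stage labels),
#'   `predict` (classify new observations with the fitted cutpoints),
#'   `plot` (per-stage mortality).
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_patients = 60, seed = 7))$cohort
#' fit <- immunostage(cohort)
#' fit
#' head(fitted(fit))
#' @export
immunostage <- function(cohort, q_low = 0.10, q_high = 0.75) {
  if (!inherits(cohort, "sepsis_cohort")) cohort <- sepsis_cohort(cohort)
  obs <- cohort$observations
  mk <- stage_markers(obs)
  rules <- fit_cutpoints(mk, q_low = q_low, q_high = q_high)
  stages <- classify_stage(mk, rules)
  structure(list(rules = rules, stages = stages,
                 outcome_table = stage_outcome_table(stages, obs$outcome),
                 keys = paste(obs$patient_id, obs$day, sep = ":"),
                 n_patients = nrow(cohort$patients),
                 n_observations = nrow(obs),
                 call = match.call()),
            class = "immunostage")
}

#' @export
print.immunostage <- function(x, ...) {
  cat("Five-stage inflammatory classification\n")
  cat("  ", x$n_observations, " observations from ", x$n_patients,
      " patients\n", sep = "")
  print(table(stage = x$stages))
  invisible(x)
}

#' @export
summary.immunostage <- function(object, ...) {
  cat("Five-stage inflammatory classification\n\n")
  print(object$rules)
  cat("\nStage-outcome table:\n")
  print(object$outcome_table)
  invisible(object)
}

#' @export
coef.immunostage <- function(object, ...) object$rules$cutpoints

#' @export
fitted.immunostage <- function(object, ...) object$stages

#' @rdname immunostage
#' @param object a fitted `immunostage` model.
#' @param newdata observations to classify with the fitted cutpoints; the
#'   training stages are returned when omitted.
#' @param ... unused.
#' @export
predict.immunostage <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$stages)
  classify_stage(newdata, object$rules)
}

#' @export
plot.immunostage <- function(x, ...) {
  tab <- x$outcome_table$table
  graphics::barplot(tab$mortality_pct, names.arg = tab$stage, las = 2,
                    ylab = "30-day mortality (%)",
                    main = "Mortality by inflammatory stage", ...)
  invisible(x)
}
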