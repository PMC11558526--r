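# Seeded generator of stage-structured longitudinal cohorts. Stage signatures
# are drawn directly in ratio space (N/L and [N/L]/[M/N]; M/N follows) and the
# leukocyte differential is recovered by compositional closure, so the
# generated cohort realizes the stage definitions the classifier targets.

#' Configuration of the synthetic cohort generator
#'
#' Full parameterization of the stage-structured generator: cohort
#' composition, visit process, week-indexed stage transitions (suppression
#' states structurally unreachable in week 1; early immunocompetence only
#' in week 1, and immunocompetent patients never progress to suppression),
#' stage-conditional marker distributions (log-normal ratios, gamma serum
#' markers), leukocyte closure, stage-path-dependent mortality, and pathogen
#' enrichment in the high-mortality stages.
#'
#' @param n_patients total patients (default 331).
#' @param n_septic patients with at least one positive culture (default 286).
#' @param n_not_assigned patients with no culture performed (default 2); the
#'   remainder are non-septic (cultures drawn, all negative).
#' @param visit_lambda Poisson rate of extra visits beyond 3 per patient
#'   (default tuned so 331 patients yield about 4072 observations and well
#'   over 80\% of patients have >= 5 visits).
#' @param init_septic,init_other week-1 stage probabilities
#'   (inflammation/competence/other) for septic and for non-septic or
#'   unassigned patients.
#' @param transitions named list of per-week transition probability vectors
#'   over the reachable states; rows must sum to 1.
#' @param stage_params data.frame of stage-conditional distribution
#'   parameters (log-normal median/sdlog for N/L, [N/L]/[M/N] and WBC;
#'   gamma mean/cv for urea (mg/dL), creatinine (mg/dL) and CRP (mg/L)).
#' @param mortality death probability per stage-path category: patients are
#'   scored by the most severe stage visited (suppression, then
#'   inflammation, then other), except that any immunocompetent visit fixes
#'   survival.
#' @param pathogen_supp,pathogen_base pathogen-class probabilities
#'   (MRSA/MSSA/ESBL_MBL/other) for septic patients with and without a
#'   suppression visit.
#' @param seed RNG seed; the generator is byte-reproducible under it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 331, n_septic = 286,
                          n_not_assigned = 2,
                          visit_lambda = 4072 / 331 - 3,
                          init_septic = c(early_inflammation = 0.22,
                                          early_immunocompetence = 0.15,
                                          other = 0.63),
                          init_other = c(early_inflammation = 0.10,
                                         early_immunocompetence = 0.35,
                                         other = 0.55),
                          transitions = default_transitions(),
                          stage_params = default_stage_params(),
                          mortality = c(late_suppression = 1.0,
                                        intermediary_suppression = 1.0,
                                        early_immunocompetence = 0.0,
                                        early_inflammation = 0.2,
                                        other = 0.15),
                          pathogen_supp = c(MRSA = 0.20, MSSA = 0.15,
                                            ESBL_MBL = 0.45, other = 0.20),
                          pathogen_base = c(MRSA = 0.10, MSSA = 0.15,
                                            ESBL_MBL = 0.15, other = 0.60),
                          seed = 1) {
  if (n_patients < 0 || n_septic + n_not_assigned > n_patients)
    stopf("invalid cohort composition")
  chk_prob <- function(p, what) {
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stopf("%s must be probabilities summing to 1", what)
  }
  if (n_patients > 0) {
    chk_prob(init_septic, "init_septic"); chk_prob(init_other, "init_other")
    for (nm in names(transitions))
      for (g in names(transitions[[nm]]))
        chk_prob(transitions[[nm]][[g]], paste("transition row", nm, g))
    supp <- c("intermediary_suppression", "late_suppression")
    if (any(c(names(init_septic), names(init_other)) %in% supp))
      stopf("suppression states are unreachable in week 1 by construction")
    if (any(mortality < 0 | mortality > 1)) stopf("mortality must be in [0,1]")
  }
  structure(list(n_patients = n_patients, n_septic = n_septic,
                 n_not_assigned = n_not_assigned,
                 visit_lambda = visit_lambda,
                 init_septic = init_septic, init_other = init_other,
                 transitions = transitions, stage_params = stage_params,
                 mortality = mortality, pathogen_supp = pathogen_supp,
                 pathogen_base = pathogen_base, seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_transitions <- function() {
  # per origin state: probabilities over destination states for weeks >= 2;
  # early_immunocompetence is absent from every destination (week-1 only) and
  # suppression is absent from the competent and the non-septic rows
  list(
    septic = list(
      early_inflammation = c(early_inflammation = 0.10,
                             intermediary_suppression = 0.12,
                             late_suppression = 0.04, other = 0.74),
      early_immunocompetence = c(early_inflammation = 0.10, other = 0.90),
      other = c(early_inflammation = 0.10, intermediary_suppression = 0.04,
                late_suppression = 0.04, other = 0.82),
      intermediary_suppression = c(intermediary_suppression = 0.55,
                                   late_suppression = 0.25, other = 0.20),
      late_suppression = c(late_suppression = 0.85, other = 0.15)),
    non_septic = list(
      early_inflammation = c(early_inflammation = 0.10, other = 0.90),
      early_immunocompetence = c(early_inflammation = 0.05, other = 0.95),
      other = c(early_inflammation = 0.05, other = 0.95)))
}

#' @rdname cohort_config
#' @export
default_stage_params <- function() {
  data.frame(
    stage = c("early_inflammation", "early_immunocompetence",
              "intermediary_suppression", "late_suppression", "other"),
    nl_med   = c(12,   0.5,  20,   6,    4),
    nl_sd    = c(0.20, 0.25, 0.20, 0.30, 0.35),
    nlmn_med = c(0.3,  0.8,  400,  80,   20),
    nlmn_sd  = c(0.25, 0.25, 0.30, 0.40, 0.40),
    urea_mean = c(40, 12, 45, 160, 35),
    urea_cv   = c(0.25, 0.22, 0.25, 0.22, 0.22),
    creat_mean = c(1.0, 0.7, 1.1, 3.5, 0.9),
    creat_cv   = c(0.22, 0.20, 0.22, 0.22, 0.22),
    crp_mean = c(180, 25, 120, 100, 60),
    crp_cv   = c(0.35, 0.35, 0.35, 0.35, 0.40),
    wbc_med = c(16000, 7000, 15000, 11000, 9000),
    wbc_sd  = c(0.20, 0.20, 0.20, 0.25, 0.25),
    stringsAsFactors = FALSE)
}

rlnorm_med <- function(n, med, sdlog) stats::rlnorm(n, log(med), sdlog)
rgamma_cv <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a synthetic longitudinal septic cohort
#'
#' Simulates the full study structure: patients with seeded visit schedules,
#' a week-indexed stage process respecting the temporal constraints (no
#' suppression in week 1, immunocompetence only in week 1, immunocompetent
#' patients never suppress), stage-conditional leukocyte ratios closed into
#' a valid differential, serum markers, vitals meeting at least two SIRS
#' criteria at admission, cultures/pathogens consistent with septic status,
#' and one outcome per patient drawn from the stage-path mortality rule.
#' Ground-truth stage labels are returned separately from the observed
#' table.
#'
#' @param config a [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `cohort` (a
#'   validated [sepsis_cohort()]), `truth` (data.frame `patient_id`, `day`,
#'   `stage`, row-aligned with the cohort observations), and `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_patients
  if (n == 0) {
    return(structure(list(cohort = sepsis_cohort(
      data.frame(patient_id = character(0))[, 0]),
      truth = data.frame(patient_id = character(0), day = integer(0),
                         stage = character(0), stringsAsFactors = FALSE),
      config = config), class = "synthetic_cohort"))
  }
  wd <- max(3, nchar(as.integer(n)))
  ids <- sprintf(paste0("P%0", wd, "d"), seq_len(n))
  status <- rep(c("septic", "non_septic", "not_assigned"),
                c(config$n_septic,
                  n - config$n_septic - config$n_not_assigned,
                  config$n_not_assigned))
  sp <- config$stage_params

  obs_list <- vector("list", n)
  for (i in seq_len(n)) {
    septic <- status[i] == "septic"
    n_vis <- 3 + stats::rpois(1, config$visit_lambda)
    days <- cumsum(c(1, sample(1:3, n_vis - 1, replace = TRUE)))
    weeks <- week_of_day(days)
    n_week <- max(weeks)

    # weekly stage path
    init <- if (septic) config$init_septic else config$init_other
    trans <- config$transitions[[if (septic) "septic" else "non_septic"]]
    path <- character(n_week)
    path[1] <- sample(names(init), 1, prob = init)
    ever_comp <- path[1] == "early_immunocompetence"
    if (n_week > 1) for (w in 2:n_week) {
      row <- trans[[path[w - 1]]]
      if (ever_comp) {  # immunocompetent patients never progress to suppression
        keep <- !names(row) %in% c("intermediary_suppression", "late_suppression")
        row <- row[keep] / sum(row[keep])
      }
      path[w] <- sample(names(row), 1, prob = row)
    }
    stage <- path[weeks]

    m <- length(days)
    pi_ <- match(stage, sp$stage)
    nl   <- rlnorm_med(m, sp$nl_med[pi_], sp$nl_sd[pi_])
    nlmn <- rlnorm_med(m, sp$nlmn_med[pi_], sp$nlmn_sd[pi_])
    mnr  <- nl / nlmn                      # M/N ratio implied by the signature
    rest <- stats::runif(m, 5, 15)
    S <- 100 - rest
    L <- S / (1 + nl + nl * mnr)
    N <- nl * L
    M <- mnr * N
    eos  <- rest * stats::runif(m, 0.2, 0.5)
    baso <- rest * stats::runif(m, 0.05, 0.2)
    wbc <- round(rlnorm_med(m, sp$wbc_med[pi_], sp$wbc_sd[pi_]))
    pct <- function(x) pmax(round_half_up(x, 1), 0.1)

    urea  <- rgamma_cv(m, sp$urea_mean[pi_], sp$urea_cv[pi_])
    creat <- rgamma_cv(m, sp$creat_mean[pi_], sp$creat_cv[pi_])
    crp   <- rgamma_cv(m, sp$crp_mean[pi_], sp$crp_cv[pi_])

    # vitals: admission meets >= 2 SIRS criteria, later visits are milder
    temp <- round(c(stats::rnorm(1, 38.7, 0.5), stats::rnorm(m - 1, 37.6, 0.7)), 1)
    hr   <- round(c(stats::rnorm(1, 105, 15),  stats::rnorm(m - 1, 92, 14)))
    rr   <- round(c(stats::rnorm(1, 24, 4),    stats::rnorm(m - 1, 19, 4)))
    paco2 <- round(stats::rnorm(m, 38, 6), 1)
    if (sirs_count(temp[1], hr[1], rr[1], paco2[1], wbc[1]) < 2) {
      temp[1] <- 38.6; hr[1] <- 100
    }

    # cultures and pathogen class
    ever_supp <- any(stage %in% c("intermediary_suppression", "late_suppression"))
    if (septic) {
      culture <- ifelse(stats::runif(m) < 0.6, "positive", "negative")
      if (!any(culture == "positive")) culture[1] <- "positive"
      pp <- if (ever_supp) config$pathogen_supp else config$pathogen_base
      pathogen <- sample(names(pp), 1, prob = pp)
    } else if (status[i] == "non_septic") {
      culture <- ifelse(stats::runif(m) < 0.7, "negative", "not_done")
      if (!any(culture == "negative")) culture[1] <- "negative"
      pathogen <- "none"
    } else {
      culture <- rep("not_done", m)
      pathogen <- "none"
    }

    # outcome: one draw per patient from the stage-path mortality rule
    p_die <- if (ever_supp) {
      if (any(stage == "late_suppression"))
        config$mortality[["late_suppression"]]
      else config$mortality[["intermediary_suppression"]]
    } else if (any(stage == "early_immunocompetence")) {
      config$mortality[["early_immunocompetence"]]
    } else if (any(stage == "early_inflammation")) {
      config$mortality[["early_inflammation"]]
    } else config$mortality[["other"]]
    outcome <- if (stats::rbinom(1, 1, p_die) == 1) "died" else "survived"

    Lp <- pct(L); Np <- pct(N); Mp <- pct(M)
    obs_list[[i]] <- data.frame(
      patient_id = ids[i], day = days,
      lymph_pct = Lp, neut_pct = Np, mono_pct = Mp,
      eos_pct = pct(eos), baso_pct = pct(baso),
      wbc_count = wbc,
      lymph_count = round(wbc * Lp / 100),
      neut_count = round(wbc * Np / 100),
      mono_count = round(wbc * Mp / 100),
      crp = round(crp, 1), urea = round(urea, 1),
      creatinine = round(creat, 2),
      temperature_c = temp, heart_rate_bpm = hr,
      resp_rate_bpm = rr, paco2_mmhg = paco2,
      culture = culture, pathogen_class = pathogen, outcome = outcome,
      chronic_disease = FALSE,
      stage = stage, stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs_list)
  truth <- obs[, c("patient_id", "day", "stage")]
  rownames(truth) <- NULL
  cohort <- sepsis_cohort(obs[, setdiff(names(obs), "stage")])
  if (nrow(cohort$rejects) > 0)
    stopf("internal error: generator produced %d invalid rows",
          nrow(cohort$rejects))
  structure(list(cohort = cohort, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$config$seed, ")\n", sep = "")
  print(x$cohort)
  if (nrow(x$truth) > 0) print(table(stage = x$truth$stage))
  invisible(x)
}

#' Verify a generated cohort against its configuration
#'
#' Diagnostic checks of the generator's structural guarantees: leukocyte
#' closure, week constraints on the ground-truth stages, the visit-count
#' contract (>= 80\% of patients with >= 5 visits), stage-conditional
#' marker separation (per-stage N/L and [N/L]/[M/N] medians within 20\% of
#' the configured medians), and per-stage-path mortality within the central
#' 95\% binomial interval of the configured probabilities.
#'
#' @param sim a [simulate_cohort()] result.
#' @param config the configuration to check against (defaults to the one
#'   stored in `sim`).
#' @return List with `pass` (all checks), `checks` (data.frame: check,
#'   pass, detail). An empty cohort passes vacuously with a warning.
#' @export
verify_cohort <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  obs <- sim$cohort$observations
  truth <- sim$truth
  if (nrow(obs) == 0) {
    warnf("verify_cohort: empty cohort, checks pass vacuously")
    return(list(pass = TRUE,
                checks = data.frame(check = character(0), pass = logical(0),
                                    detail = character(0))))
  }
  key <- function(d) paste(d$patient_id, d$day)
  truth <- truth[match(key(obs), key(truth)), ]
  checks <- list()
  add <- function(name, pass, detail = "")
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = pass,
                                                detail = detail,
                                                stringsAsFactors = FALSE)

  psum <- obs$lymph_pct + obs$neut_pct + obs$mono_pct + obs$eos_pct + obs$baso_pct
  add("closure", all(psum <= 100.5) && all(obs$lymph_pct > 0) &&
        all(obs$neut_pct > 0) && all(obs$mono_pct > 0),
      sprintf("max differential sum %.2f", max(psum)))

  wk <- week_of_day(truth$day)
  supp <- truth$stage %in% c("intermediary_suppression", "late_suppression")
  add("no suppression in week 1", !any(supp & wk == 1))
  add("immunocompetence only in week 1",
      !any(truth$stage == "early_immunocompetence" & wk > 1))

  nv <- table(obs$patient_id)
  add("visit counts", mean(nv >= 5) >= 0.8,
      sprintf("%.1f%% of patients with >= 5 visits", 100 * mean(nv >= 5)))

  sp <- config$stage_params
  r <- named_ratios(obs)
  for (marker in c("nl", "nlmn")) {
    v <- if (marker == "nl") r$NL else r$NL_over_MN
    conf <- sp[[paste0(marker, "_med")]]
    ok <- TRUE; det <- character(0)
    for (j in seq_len(nrow(sp))) {
      x <- v[truth$stage == sp$stage[j]]
      if (length(x) < 10) next
      relerr <- abs(stats::median(x) / conf[j] - 1)
      if (relerr > 0.20) {
        ok <- FALSE
        det <- c(det, sprintf("%s %s off by %.0f%%", sp$stage[j], marker,
                              100 * relerr))
      }
    }
    add(paste("marker separation:", marker), ok, paste(det, collapse = "; "))
  }

  # mortality per stage-path category vs configured binomial
  pat <- split(truth$stage, truth$patient_id)
  category <- vapply(pat, function(st) {
    if (any(st == "late_suppression")) "late_suppression"
    else if (any(st == "intermediary_suppression")) "intermediary_suppression"
    else if (any(st == "early_immunocompetence")) "early_immunocompetence"
    else if (any(st == "early_inflammation")) "early_inflammation"
    else "other"
  }, character(1))
  died <- vapply(split(obs$outcome, obs$patient_id), function(o)
    o[1] == "died", logical(1))
  ok <- TRUE; det <- character(0)
  for (cat_ in unique(category)) {
    idx <- category == cat_
    k <- sum(died[idx]); nn <- sum(idx)
    p <- config$mortality[[cat_]]
    lim <- stats::qbinom(c(0.025, 0.975), nn, p)
    if (k < lim[1] || k > lim[2]) {
      ok <- FALSE
      det <- c(det, sprintf("%s: %d/%d deaths vs p=%.2f", cat_, k, nn, p))
    }
  }
  add("stage-path mortality", ok, paste(det, collapse = "; "))

  checks <- do.call(rbind, checks)
  list(pass = all(checks$pass), checks = checks)
}
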