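# Orchestration: each command reads its inputs (or the artifacts of earlier
# commands in the same run directory), executes one pipeline stage, and writes
# plain-text artifacts plus a run manifest.

pipeline_commands <- function() {
  c("validate", "simulate", "expand", "scan", "partition", "stage",
    "trajectory", "report")
}

# cheap deterministic content fingerprint for the manifest (position-weighted
# byte sum; auditing aid, not cryptographic)
content_hash <- function(path) {
  x <- as.integer(readBin(path, "raw", file.size(path)))
  sprintf("%08x", sum(x * (seq_along(x) %% 97 + 1)) %% 2147483647)
}

write_manifest <- function(out, command, config, seed, artifacts) {
  mpath <- file.path(out, "manifest.json")
  manifest <- if (file.exists(mpath))
    jsonlite::read_json(mpath, simplifyVector = FALSE) else list(runs = list())
  manifest$runs[[length(manifest$runs) + 1]] <- list(
    command = command, seed = seed,
    package_version = as.character(utils::packageVersion("immunostage")),
    config = config,
    artifacts = lapply(artifacts, function(a)
      list(file = basename(a), hash = content_hash(a))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

load_run_cohort <- function(out, config) {
  path <- config$input %||% file.path(out, "cohort.csv")
  if (!file.exists(path))
    stopf("no cohort available: run 'validate' or 'simulate' first, or set config$input")
  read_cohort(path)
}

load_run_matrix <- function(out) {
  path <- file.path(out, "di_matrix.csv")
  if (!file.exists(path)) stopf("no DI matrix: run 'expand' first")
  m <- utils::read.csv(path, check.names = FALSE)
  rn <- m[[1]]
  m <- as.matrix(m[, -1, drop = FALSE])
  rownames(m) <- rn
  m
}

#' Run one pipeline command
#'
#' Thin orchestration over the package's functions. Commands form a chain
#' sharing the run directory `out`: `validate` (or `simulate`) produces the
#' canonical cohort, `expand` the DI matrix, `scan` the overlap ranking,
#' `partition` the spatial pattern and subsets, `stage` the five-stage
#' classification, `trajectory` the per-patient report, and `report` the
#' final roll-up. Every command appends to `manifest.json` (config
#' snapshot, seed, package version, artifact fingerprints).
#'
#' @param command one of `validate`, `simulate`, `expand`, `scan`,
#'   `partition`, `stage`, `trajectory`, `report`.
#' @param config list (or YAML file path) of options: `input` (cohort CSV
#'   for `validate`/downstream), generator overrides under `simulate`
#'   (e.g. `n_patients`), `expand$max_depth` (DI matrix depth, default 1),
#'   geometry options under `partition` (`window`, `angle_threshold`,
#'   `thinness_threshold`, `top_k`), `stage$q_low`/`stage$q_high`,
#'   `trajectory$min_weeks`/`trajectory$tol`.
#' @param seed integer seed used for every stochastic step.
#' @param out run directory (created if needed).
#' @param verbose print progress and resolved cutpoints.
#' @return List of the artifact paths written, invisibly.
#' @export
run_pipeline <- function(command, config = list(), seed = 1,
                         out = file.path(tempdir(), "immunostage-run"),
                         verbose = TRUE) {
  if (!command %in% pipeline_commands())
    stopf("unknown command '%s' (expected one of: %s)", command,
          paste(pipeline_commands(), collapse = ", "))
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  art <- character(0)
  add <- function(p) art <<- c(art, p)

  if (command == "validate") {
    cohort <- read_cohort(config$input %||% stopf("validate: config$input required"),
                          config$dialect)
    write_cohort(cohort, file.path(out, "cohort.csv")); add(file.path(out, "cohort.csv"))
    utils::write.csv(cohort$rejects, file.path(out, "rejects.csv"),
                     row.names = FALSE); add(file.path(out, "rejects.csv"))
    s <- summarize_mortality(cohort)
    jsonlite::write_json(list(scope = s$scope, table = s$table,
                              n_patients = s$n_patients,
                              n_observations = s$n_observations),
                         file.path(out, "summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    add(file.path(out, "summary.json"))
    if (nrow(cohort$rejects) > 0)
      stopf("validate: %d row(s) rejected (see %s)", nrow(cohort$rejects),
            file.path(out, "rejects.csv"))
  } else if (command == "simulate") {
    cc <- do.call(cohort_config,
                  utils::modifyList(list(seed = seed), config$simulate %||% list()))
    sim <- simulate_cohort(cc)
    write_cohort(sim$cohort, file.path(out, "cohort.csv")); add(file.path(out, "cohort.csv"))
    utils::write.csv(sim$truth, file.path(out, "truth.csv"), row.names = FALSE)
    add(file.path(out, "truth.csv"))
    say(sprintf("simulated %d patients, %d observations",
                nrow(sim$cohort$patients), nrow(sim$cohort$observations)))
  } else if (command == "expand") {
    cohort <- load_run_cohort(out, config)
    depth <- (config$expand %||% list())$max_depth %||% 1
    defs <- enumerate_dis(di_grammar(
      variables = c("lymph_pct", "neut_pct", "mono_pct"), max_depth = depth))
    M <- cbind(evaluate_dis(cohort, defs),
               as.matrix(named_ratios(cohort)[c("NL", "MN", "NL_over_MN")]))
    utils::write.csv(data.frame(key = rownames(M), M, check.names = FALSE),
                     file.path(out, "di_matrix.csv"), row.names = FALSE)
    add(file.path(out, "di_matrix.csv"))
    jsonlite::write_json(data.frame(id = defs$id, formula = defs$formula),
                         file.path(out, "di_definitions.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    add(file.path(out, "di_definitions.json"))
    say(sprintf("evaluated %d indicators on %d observations", ncol(M), nrow(M)))
  } else if (command == "scan") {
    cohort <- load_run_cohort(out, config)
    M <- load_run_matrix(out)
    sc <- scan_discriminators(M, cohort$observations$outcome,
                              trim = config$trim %||% c(0, 1))
    utils::write.csv(sc, file.path(out, "overlap_scan.csv"), row.names = FALSE)
    add(file.path(out, "overlap_scan.csv"))
  } else if (command == "partition") {
    cohort <- load_run_cohort(out, config)
    M <- load_run_matrix(out)
    pc <- config$partition %||% list()
    found <- search_patterns(M, cohort$observations$outcome,
                             top_k = pc$top_k %||% 5,
                             thinness_threshold = pc$thinness_threshold %||% 0.9,
                             window = pc$window %||% 5,
                             angle_threshold = pc$angle_threshold %||% 60,
                             seed = seed)
    utils::write.csv(found, file.path(out, "patterns.csv"), row.names = FALSE)
    add(file.path(out, "patterns.csv"))
    if (nrow(found) > 0) {
      pat <- spatial_pattern(M, unlist(found[1, c("di1", "di2", "di3")]),
                             outcome = cohort$observations$outcome,
                             septic_status = cohort$observations$septic_status,
                             nl = named_ratios(cohort)$NL,
                             window = pc$window %||% 5,
                             angle_threshold = pc$angle_threshold %||% 60,
                             thinness_threshold = pc$thinness_threshold %||% 0.9)
      export_3d(M, pat$triplet, labels = pat$assignment$labels,
                outcome = cohort$observations$outcome,
                path = file.path(out, "subsets_3d.csv"))
      add(file.path(out, "subsets_3d.csv"))
      jsonlite::write_json(list(triplet = pat$triplet, thinness = pat$thinness,
                                inflections = pat$inflections,
                                subsets = pat$assignment$summary),
                           file.path(out, "pattern.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
      add(file.path(out, "pattern.json"))
    } else say("no triplet exceeded the thinness threshold")
  } else if (command == "stage") {
    cohort <- load_run_cohort(out, config)
    sc <- config$stage %||% list()
    fit <- immunostage(cohort, q_low = sc$q_low %||% 0.10,
                       q_high = sc$q_high %||% 0.75)
    say("resolved cutpoints:")
    if (verbose) print(fit$rules)
    st <- data.frame(key = fit$keys, stage = as.character(fit$stages),
                     attr(fit$stages, "provenance"), stringsAsFactors = FALSE)
    utils::write.csv(st, file.path(out, "stages.csv"), row.names = FALSE)
    add(file.path(out, "stages.csv"))
    jsonlite::write_json(list(cutpoints = as.data.frame(coef(fit)),
                              table = fit$outcome_table$table),
                         file.path(out, "stage_outcome.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    add(file.path(out, "stage_outcome.json"))
    tpath <- file.path(out, "truth.csv")
    if (file.exists(tpath)) {
      # synthetic runs: also tabulate against the generator's ground truth,
      # where the constructive mortality extremes hold exactly
      truth <- utils::read.csv(tpath)
      ok <- paste(cohort$observations$patient_id, cohort$observations$day)
      truth <- truth[match(ok, paste(truth$patient_id, truth$day)), ]
      tot <- stage_outcome_table(factor(truth$stage, levels = stage_levels()),
                                 cohort$observations$outcome)
      jsonlite::write_json(list(table = tot$table),
                           file.path(out, "stage_outcome_truth.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      add(file.path(out, "stage_outcome_truth.json"))
    }
  } else if (command == "trajectory") {
    cohort <- load_run_cohort(out, config)
    M <- load_run_matrix(out)
    spath <- file.path(out, "stages.csv")
    if (!file.exists(spath)) stopf("no stages: run 'stage' first")
    stages <- utils::read.csv(spath)$stage
    found <- utils::read.csv(file.path(out, "patterns.csv"))
    if (nrow(found) == 0) stopf("no spatial pattern available for trajectories")
    pat <- spatial_pattern(M, unlist(found[1, c("di1", "di2", "di3")]),
                           outcome = cohort$observations$outcome)
    tc <- config$trajectory %||% list()
    rep_ <- cohort_trajectory_report(cohort, pat, stages,
                                     min_weeks = tc$min_weeks %||% 3,
                                     tol = tc$tol %||% 0.10)
    utils::write.csv(rep_, file.path(out, "trajectory_report.csv"),
                     row.names = FALSE)
    add(file.path(out, "trajectory_report.csv"))
  } else if (command == "report") {
    have <- list.files(out, pattern = "\\.(csv|json)$")
    have <- setdiff(have, "manifest.json")
    if (length(have) == 0) stopf("nothing to report: no prior artifacts in %s", out)
    cohort <- try(load_run_cohort(out, config), silent = TRUE)
    rep_ <- list(artifacts = have)
    if (!inherits(cohort, "try-error")) {
      rep_$mortality_all <- summarize_mortality(cohort, "all_observations")$table
      rep_$mortality_day1 <- summarize_mortality(cohort, "day1_only")$table
    }
    sj <- file.path(out, "stage_outcome.json")
    if (file.exists(sj)) rep_$stage_outcome <- jsonlite::read_json(sj)
    jsonlite::write_json(rep_, file.path(out, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    add(file.path(out, "report.json"))
  }
  write_manifest(out, command, config, seed, art)
  invisible(art)
}

#' Export a DI triplet as 3D plot data
#'
#' Writes (or returns) the coordinates of a triplet of indicators together
#' with subset, stage and outcome labels, ready for any 3D plotting tool.
#'
#' @param di_matrix numeric matrix, observations x indicators.
#' @param triplet three column names of `di_matrix`.
#' @param labels optional subset labels per observation; missing entries
#'   are exported as "other" with a warning.
#' @param stages,outcome optional per-observation annotations.
#' @param path optional CSV output path.
#' @return data.frame with columns x, y, z, subset, stage, outcome.
#' @export
export_3d <- function(di_matrix, triplet, labels = NULL, stages = NULL,
                      outcome = NULL, path = NULL) {
  di_matrix <- as.matrix(di_matrix)
  if (nrow(di_matrix) == 0 || ncol(di_matrix) == 0)
    stopf("export_3d: empty DI matrix")
  if (!all(triplet %in% colnames(di_matrix)))
    stopf("export_3d: triplet not present in matrix: %s",
          paste(setdiff(triplet, colnames(di_matrix)), collapse = ", "))
  n <- nrow(di_matrix)
  fill <- function(x) {
    if (is.null(x)) return(rep("other", n))
    x <- as.character(x)
    if (anyNA(x)) {
      warnf("export_3d: %d observation(s) without a label exported as 'other'",
            sum(is.na(x)))
      x[is.na(x)] <- "other"
    }
    x
  }
  out <- data.frame(x = di_matrix[, triplet[1]], y = di_matrix[, triplet[2]],
                    z = di_matrix[, triplet[3]], subset = fill(labels),
                    stage = fill(stages), outcome = fill(outcome),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
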