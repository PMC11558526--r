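# Fixtures are built in code; nothing is read from disk.

# minimal valid observation rows (defaults satisfy every invariant)
obs_row <- function(patient_id = "p1", day = 1, lymph_pct = 30, neut_pct = 60,
                    mono_pct = 6, eos_pct = 2, baso_pct = 1,
                    wbc_count = 9000, outcome = "survived",
                    culture = "not_done", ...) {
  data.frame(patient_id = patient_id, day = day, lymph_pct = lymph_pct,
             neut_pct = neut_pct, mono_pct = mono_pct, eos_pct = eos_pct,
             baso_pct = baso_pct, wbc_count = wbc_count, outcome = outcome,
             culture = culture, ..., stringsAsFactors = FALSE)
}

# random valid observations with independent count and percentage channels
random_obs <- function(n, seed = 1) {
  set.seed(seed)
  L <- runif(n, 5, 50); N <- runif(n, 30, 80); M <- runif(n, 1, 15)
  s <- pmax(1, (L + N + M) / 92)   # keep the differential under 100
  wbc <- round(runif(n, 4000, 20000))
  data.frame(patient_id = paste0("r", seq_len(n)), day = 1,
             lymph_pct = L / s, neut_pct = N / s, mono_pct = M / s,
             eos_pct = runif(n, 0.5, 4), baso_pct = runif(n, 0.2, 1.5),
             wbc_count = wbc,
             lymph_count = round(runif(n, 500, 5000)),
             neut_count = round(runif(n, 2000, 15000)),
             mono_count = round(runif(n, 100, 1500)),
             outcome = "survived", stringsAsFactors = FALSE)
}

# cohort with prescribed group sizes and death counts, one observation per
# patient per day in `days`
counts_cohort <- function(n_septic, septic_deaths, n_non_septic,
                          non_septic_deaths, days = 1) {
  mk <- function(n, deaths, culture, prefix) {
    if (n == 0) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(i)
      obs_row(patient_id = paste0(prefix, i), day = days,
              outcome = if (i <= deaths) "died" else "survived",
              culture = culture)))
  }
  sepsis_cohort(rbind(mk(n_septic, septic_deaths, "positive", "s"),
                      mk(n_non_septic, non_septic_deaths, "negative", "ns")))
}

# 3D point set tracing a right-angle L (two straight arms), exact geometry
l_shape <- function(n_arm = 12, jitter = 0, seed = 1) {
  set.seed(seed)
  arm1 <- cbind(seq(0, 1, length.out = n_arm), 0, 0)
  arm2 <- cbind(1, seq(0, 1, length.out = n_arm + 1)[-1], 0)
  pts <- rbind(arm1, arm2)
  if (jitter > 0) pts <- pts + matrix(rnorm(length(pts), 0, jitter), ncol = 3)
  pts
}

# DI matrix with one planted thin (collinear) triplet among noise columns
planted_matrix <- function(n = 40, n_noise = 3, seed = 1) {
  set.seed(seed)
  t <- sort(runif(n))
  planted <- cbind(t, 2 * t, -t) +
    matrix(rnorm(3 * n, 0, 0.005), ncol = 3)
  noise <- matrix(rnorm(n * n_noise), ncol = n_noise)
  m <- cbind(planted, noise)
  colnames(m) <- c("pl1", "pl2", "pl3", paste0("nz", seq_len(n_noise)))
  list(m = m, t = t)
}
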