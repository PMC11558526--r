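test_that("reading and writing a cohort file round-trips all retained fields", {
  df <- rbind(obs_row("a", 1), obs_row("a", 2), obs_row("a", 3),
              obs_row("b", 1, culture = "positive"),
              obs_row("b", 2, lymph_pct = 22),
              obs_row("b", 3))
  df$outcome[df$patient_id == "b"] <- "died"
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(df, f1, row.names = FALSE)
  cohort <- read_cohort(f1)
  expect_equal(nrow(cohort$patients), 2)
  expect_equal(nrow(cohort$observations), 6)
  expect_equal(cohort$patients$septic_status,
               c("not_assigned", "septic"))
  write_cohort(cohort, f2)
  again <- read_cohort(f2)
  expect_identical(again$observations, cohort$observations)
})

test_that("rows with zero percentages are rejected with a reason, not dropped silently", {
  df <- rbind(obs_row("a", 1), obs_row("a", 2, mono_pct = 0), obs_row("b", 1))
  cohort <- sepsis_cohort(df)
  expect_equal(nrow(cohort$observations), 2)
  expect_equal(cohort$rejects$reject_reason, "zero percentage")
  expect_equal(cohort$rejects$day, 2)
})

test_that("an outcome that differs within one patient is an error", {
  df <- rbind(obs_row("a", 1, outcome = "survived"),
              obs_row("a", 2, outcome = "died"))
  expect_error(sepsis_cohort(df), "outcome differs")
})

test_that("missing required columns are reported by name", {
  f <- tempfile(fileext = ".csv")
  write.csv(obs_row()[, setdiff(names(obs_row()), "wbc_count")], f,
            row.names = FALSE)
  expect_error(read_cohort(f), "wbc_count")
})

test_that("a column-mapping config renames file columns to the canonical schema", {
  df <- obs_row()
  names(df)[names(df) == "lymph_pct"] <- "LYMPH%"
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  cohort <- read_cohort(f, config = list(columns = list(lymph_pct = "LYMPH.")))
  expect_equal(cohort$observations$lymph_pct, 30)
})

test_that("SIRS criteria count follows the four admission thresholds", {
  expect_identical(sirs_count(39.0, 100, 25, NA, 15000), 4L)
  expect_identical(sirs_count(37.0, 80, 15, 40, 8000), 0L)
  # temperature + respiratory; low PaCO2 is redundant with the rate
  expect_identical(sirs_count(38.5, 80, 25, 30, 8000), 2L)
  expect_identical(sirs_count(NA, NA, NA, NA, NA), NA_integer_)
  # vectorized
  expect_identical(sirs_count(c(39, 37), c(100, 80), c(25, 15),
                              c(NA, 40), c(15000, 8000)), c(4L, 0L))
})

test_that("inclusion keeps SIRS >= 2 at admission and reports every exclusion", {
  df <- rbind(
    obs_row("in1", 1, temperature_c = 39, heart_rate_bpm = 100,
            resp_rate_bpm = 25, wbc_count = 15000),
    obs_row("in1", 4, temperature_c = 37, heart_rate_bpm = 80,
            resp_rate_bpm = 15, wbc_count = 9000),
    obs_row("out1", 1, temperature_c = 37, heart_rate_bpm = 95,
            resp_rate_bpm = 15, wbc_count = 9000),
    obs_row("out2", 3, temperature_c = 39, heart_rate_bpm = 100,
            resp_rate_bpm = 25, wbc_count = 15000))
  cohort <- sepsis_cohort(df)
  res <- apply_inclusion(cohort)
  expect_equal(res$cohort$patients$patient_id, "in1")
  expect_setequal(unique(res$exclusions$patient_id), c("out1", "out2"))
  expect_true("no admission sample" %in%
                res$exclusions$reason[res$exclusions$patient_id == "out2"])
  expect_true(any(grepl("SIRS", res$exclusions$reason) |
                    grepl("criteria", res$exclusions$reason)))
  # accounting: exclusion rows + included observations = input observations
  expect_equal(nrow(res$exclusions) + nrow(res$cohort$observations),
               nrow(cohort$observations))
  # idempotence
  twice <- apply_inclusion(res$cohort)
  expect_identical(twice$cohort$observations, res$cohort$observations)
  expect_equal(nrow(twice$exclusions), 0)
})

test_that("inclusion of an empty cohort is a degenerate no-op", {
  empty <- sepsis_cohort(obs_row()[0, ])
  res <- apply_inclusion(empty)
  expect_equal(nrow(res$cohort$observations), 0)
  expect_equal(nrow(res$exclusions), 0)
})

test_that("mortality percentages match the printed one-decimal half-up style", {
  expect_equal(mortality_pct(1090, 3605), 30.2)
  expect_equal(mortality_pct(81, 286), 28.3)
  expect_equal(mortality_pct(3, 43), 7.0)
  expect_equal(mortality_pct(0, 10), 0.0)
  expect_true(is.na(mortality_pct(0, 0)))
  # half-up at the boundary: 121/400 = 30.25% -> 30.3
  expect_equal(mortality_pct(121, 400), 30.3)
})

test_that("mortality summaries count the stated unit per scope", {
  cohort <- counts_cohort(20, 6, 10, 1)
  s1 <- summarize_mortality(cohort, "day1_only")
  tab <- s1$table
  expect_equal(tab$total[tab$group == "septic"], 20)
  expect_equal(tab$mortality_pct[tab$group == "septic"], 30.0)
  expect_equal(tab$mortality_pct[tab$group == "non_septic"], 10.0)
  expect_true(is.na(tab$mortality_pct[tab$group == "not_assigned"]))
  # observation scope counts every longitudinal row
  df <- rbind(obs_row("a", 1, culture = "positive", outcome = "died"),
              obs_row("a", 2, culture = "positive", outcome = "died"),
              obs_row("b", 1, culture = "positive"))
  s2 <- summarize_mortality(sepsis_cohort(df), "all_observations")
  expect_equal(s2$table$total[s2$table$group == "septic"], 3)
  expect_equal(s2$table$deaths[s2$table$group == "septic"], 2)
})

test_that("summary percentages equal the rounded formula on random cohorts", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:60, 1); d <- sample(0:n, 1)
    s <- summarize_mortality(counts_cohort(n, d, 0, 0), "day1_only")
    got <- s$table$mortality_pct[s$table$group == "septic"]
    expect_equal(got, floor(1000 * d / n + 0.5) / 10)
  }
})
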