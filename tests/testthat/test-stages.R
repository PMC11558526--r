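# marker frame whose quantiles land at known values, for crafting rule inputs
flat_markers <- function(n = 101) {
  data.frame(week = rep(1:2, length.out = n),
             NL = seq(0, 10, length.out = n),
             NL_over_MN = seq(0, 100, length.out = n),
             MN = seq(0, 1, length.out = n),
             urea = seq(0, 200, length.out = n),
             creatinine = seq(0, 5, length.out = n))
}

test_that("cutpoints are the stated cohort quantiles", {
  set.seed(1)
  mk <- flat_markers()
  mk$NL <- runif(101)
  rules <- fit_cutpoints(mk)
  expect_equal(rules$cutpoints["NL", "high"],
               quantile(mk$NL, 0.75, names = FALSE))
  expect_equal(rules$cutpoints["NL", "low"],
               quantile(mk$NL, 0.10, names = FALSE))
  expect_equal(unname(rules$cutpoints["urea", ]), c(20, 150))
  # constant marker: degenerate flag
  mk$MN <- 1
  expect_true(fit_cutpoints(mk)$degenerate[["MN"]])
  expect_error(fit_cutpoints(flat_markers(19)), ">= 20")
  mk2 <- flat_markers(); mk2$creatinine <- NA
  expect_error(fit_cutpoints(mk2), "creatinine")
  expect_error(fit_cutpoints(flat_markers(), q_low = 0.8, q_high = 0.2),
               "q_low")
})

test_that("the stage rules fire in the documented precedence with week constraints", {
  rules <- fit_cutpoints(flat_markers())
  cp <- rules$cutpoints
  row <- function(week, NL, NLMN, MN, urea, creat)
    data.frame(week = week, NL = NL, NL_over_MN = NLMN, MN = MN,
               urea = urea, creatinine = creat)
  cls <- function(...) as.character(classify_stage(row(...), rules))

  # week 1, N/L and urea near zero, high M/N -> early immunocompetence
  expect_equal(cls(1, cp["NL", "low"] * 0.5, 50, cp["MN", "high"] * 1.2,
                   cp["urea", "low"] * 0.5, 2),
               "early_immunocompetence")
  # week 3 with jointly elevated renal markers -> late suppression
  expect_equal(cls(3, 5, 50, 0.5, cp["urea", "high"] * 1.2,
                   cp["creatinine", "high"] * 1.2),
               "late_suppression")
  # the same renal elevation in week 1 cannot be suppression
  lab1 <- cls(1, 5, 50, 0.5, cp["urea", "high"] * 1.2,
              cp["creatinine", "high"] * 1.2)
  expect_false(lab1 %in% c("late_suppression", "intermediary_suppression"))
  # week >= 2 with N/L and [N/L]/[M/N] both high, renal normal -> intermediary
  expect_equal(cls(2, cp["NL", "high"] * 1.2, cp["NL_over_MN", "high"] * 1.2,
                   0.1, 50, 1),
               "intermediary_suppression")
  # high N/L with [N/L]/[M/N] approaching zero -> early inflammation (any week)
  expect_equal(cls(1, cp["NL", "high"] * 1.2, cp["NL_over_MN", "low"] * 0.5,
                   0.1, 50, 1),
               "early_inflammation")
  # renal dominance: jointly high renal markers win over the intermediary rule
  expect_equal(cls(2, cp["NL", "high"] * 1.2, cp["NL_over_MN", "high"] * 1.2,
                   0.1, cp["urea", "high"] * 1.2, cp["creatinine", "high"] * 1.2),
               "late_suppression")
})

test_that("missing renal markers make those rules unassessable and fall through", {
  rules <- fit_cutpoints(flat_markers())
  cp <- rules$cutpoints
  st <- classify_stage(data.frame(week = 3, NL = 5, NL_over_MN = 50, MN = 0.5,
                                  urea = NA, creatinine = NA), rules)
  expect_equal(as.character(st), "other")
  expect_true(attr(st, "provenance")$renal_unassessable)
})

test_that("every observation gets exactly one label and week constraints always hold", {
  rules <- fit_cutpoints(flat_markers())
  set.seed(12)
  nd <- data.frame(week = sample(1:5, 500, TRUE),
                   NL = rlnorm(500, 1, 1),
                   NL_over_MN = rlnorm(500, 3, 2),
                   MN = rlnorm(500, -2, 1),
                   urea = ifelse(runif(500) < 0.1, NA, rlnorm(500, 3.5, 0.6)),
                   creatinine = ifelse(runif(500) < 0.1, NA, rlnorm(500, 0, 0.5)))
  st <- classify_stage(nd, rules)
  expect_equal(length(st), 500)
  expect_false(anyNA(st))
  expect_true(all(as.character(st) %in% stage_levels()))
  supp <- as.character(st) %in% c("intermediary_suppression", "late_suppression")
  expect_false(any(supp & nd$week == 1))
  expect_false(any(as.character(st) == "early_immunocompetence" & nd$week > 1))
})

test_that("raising renal markers above the high cutpoints never leaves late suppression", {
  rules <- fit_cutpoints(flat_markers())
  cp <- rules$cutpoints
  set.seed(9)
  nd <- data.frame(week = sample(2:5, 100, TRUE),
                   NL = rlnorm(100, 1, 1), NL_over_MN = rlnorm(100, 3, 2),
                   MN = rlnorm(100, -2, 1),
                   urea = runif(100, cp["urea", "high"], cp["urea", "high"] * 3),
                   creatinine = runif(100, cp["creatinine", "high"],
                                      cp["creatinine", "high"] * 3))
  expect_true(all(classify_stage(nd, rules) == "late_suppression"))
})

test_that("the fitted model recovers generated stage memberships on a default cohort", {
  sim <- simulate_cohort(cohort_config(n_patients = 120, n_septic = 104,
                                       seed = 23))
  fit <- immunostage(sim$cohort)
  expect_gte(mean(as.character(fit$stages) == sim$truth$stage), 0.9)
  # model interface
  expect_s3_class(fit, "immunostage")
  expect_equal(dim(coef(fit)), c(5, 2))
  expect_equal(length(fitted(fit)), nrow(sim$cohort$observations))
  expect_identical(predict(fit), fitted(fit))
  pred <- predict(fit, newdata = sim$cohort$observations[1:10, ])
  expect_identical(as.character(pred), as.character(fit$stages[1:10]))
})

test_that("the stage-outcome table reports counts, percentages and association", {
  stages <- factor(c(rep("late_suppression", 4), rep("other", 6)),
                   levels = stage_levels())
  outcome <- c(rep("died", 4), rep("survived", 5), "died")
  tab <- stage_outcome_table(stages, outcome)$table
  expect_equal(tab$mortality_pct[tab$stage == "late_suppression"], 100)
  expect_true(is.na(tab$mortality_pct[tab$stage == "early_inflammation"]))
  # single occupied stage
  tab1 <- stage_outcome_table(factor(rep("other", 5), stage_levels()),
                              rep("survived", 5))
  expect_equal(sum(tab1$table$n > 0), 1)
  expect_null(tab1$association)
  expect_error(stage_outcome_table(factor(character(0)), character(0)),
               "empty")
})
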