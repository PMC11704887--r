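test_that("item points follow the frequency scale", {
  expect_identical(
    score_leq_item(c("daily", "weekly", "twice_monthly", "monthly",
                     "less_than_monthly", "never")),
    c(5L, 4L, 3L, 2L, 1L, 0L)
  )
  expect_identical(score_leq_item(c(0L, 5L, NA)), c(0L, 5L, NA))
  expect_true(is.na(score_leq_item(NA_character_)))
  expect_error(score_leq_item("sometimes"), "sometimes")
  expect_error(score_leq_item(7), "7")
})

test_that("stage subscores sum item points and propagate missingness", {
  expect_identical(leq_stage_subscore(rep("daily", 6)), 30L)
  expect_identical(leq_stage_subscore(rep("never", 6)), 0L)
  expect_identical(
    leq_stage_subscore(c("daily", "weekly", "monthly", "never", "never",
                         "less_than_monthly")),
    12L
  )
  named <- setNames(rep("daily", 6), leq_activities)
  expect_identical(leq_stage_subscore(named), 30L)
  expect_true(is.na(leq_stage_subscore(c("daily", NA, rep("never", 4)))))
  expect_error(leq_stage_subscore(rep("daily", 5)), "six")
  expect_error(
    leq_stage_subscore(setNames(rep("daily", 6),
                                c(leq_activities[-1], "travel"))),
    "Activity"
  )
})

test_that("EE score sums the two stage subscores with missing propagation", {
  full <- tibble::as_tibble(setNames(as.list(rep(5L, 12)), leq_cols))
  scored <- score_leq(full)
  expect_identical(scored$early_subscore, 30L)
  expect_identical(scored$mid_subscore, 30L)
  expect_identical(scored$ee_score, 60L)

  mixed <- full
  mixed[1, leq_cols[1:6]] <- as.list(c(5L, 4L, 2L, 0L, 0L, 1L))   # early = 12
  mixed[1, leq_cols[7:12]] <- as.list(c(5L, 5L, 4L, 4L, 3L, 1L))  # mid = 22
  expect_identical(score_leq(mixed)$ee_score, 34L)

  gap <- full
  gap[1, leq_cols[2]] <- NA_integer_
  s <- score_leq(gap)
  expect_true(is.na(s$early_subscore))
  expect_identical(s$mid_subscore, 30L)
  expect_true(is.na(s$ee_score))
})

test_that("scoring is monotone, bounded and travel-invariant on random profiles", {
  prof <- random_profiles(1000, seed = 101)
  base <- score_leq(prof)
  expect_true(all(base$ee_score >= 0 & base$ee_score <= 60))
  expect_true(all(base$early_subscore >= 0 & base$early_subscore <= 30))
  expect_true(all(base$mid_subscore >= 0 & base$mid_subscore <= 30))

  set.seed(102)
  bump_col <- sample(leq_cols, 1000, replace = TRUE)
  bumped <- prof
  for (cl in unique(bump_col)) {
    rows <- which(bump_col == cl & prof[[cl]] < 5L)
    v <- bumped[[cl]]
    v[rows] <- v[rows] + 1L
    bumped[[cl]] <- v
  }
  expect_true(all(score_leq(bumped)$ee_score >= base$ee_score))

  with_travel <- prof
  with_travel$leq_travel_early <- sample(0:5, 1000, replace = TRUE)
  with_travel$leq_travel_mid <- sample(0:5, 1000, replace = TRUE)
  expect_identical(score_leq(with_travel)$ee_score, base$ee_score)
})
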