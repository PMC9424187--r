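test_that("social participation counts any non-none frequency", {
  expect_identical(code_social_participation("none", "none", "none"), 0L)
  expect_identical(
    code_social_participation("lt_monthly", "none", "weekly_plus"), 2L)
  expect_identical(
    code_social_participation("weekly_plus", "weekly_plus", "weekly_plus"),
    3L)
  # vectorised, and "less than once a month" already counts
  expect_identical(
    code_social_participation(c("lt_monthly", "1_3_monthly", "none"),
                              c("none", "none", "none"),
                              c("none", "weekly_plus", "none")),
    c(1L, 2L, 0L))
})

test_that("missing participation information is never coerced to none", {
  expect_identical(code_social_participation(NA, "none", "weekly_plus"),
                   NA_integer_)
  expect_error(
    code_social_participation(NA, "none", "none", id = "X42", strict = TRUE),
    "X42")
  expect_error(code_social_participation("sometimes", "none", "none"),
               "invalid")
})

test_that("depression screen scores exactly as the instrument prescribes", {
  # items 1, 2, 4 score a yes; items 3, 5 score a no
  all_yes <- code_depression("yes", "yes", "yes", "yes", "yes")
  expect_identical(all_yes$score, 3L)
  expect_true(all_yes$depressed)
  all_no <- code_depression("no", "no", "no", "no", "no")
  expect_identical(all_no$score, 2L)
  expect_true(all_no$depressed)
  zero <- code_depression("no", "no", "yes", "no", "yes")
  expect_identical(zero$score, 0L)
  expect_false(zero$depressed)
  top <- code_depression("yes", "yes", "no", "yes", "no")
  expect_identical(top$score, 5L)
})

test_that("depression classification is score >= 2 over all item patterns", {
  g <- expand.grid(rep(list(c("yes", "no")), 5), stringsAsFactors = FALSE)
  res <- code_depression(g[[1]], g[[2]], g[[3]], g[[4]], g[[5]])
  manual <- (g[[1]] == "yes") + (g[[2]] == "yes") + (g[[3]] == "no") +
    (g[[4]] == "yes") + (g[[5]] == "no")
  expect_identical(res$score, as.integer(manual))
  expect_identical(res$depressed, manual >= 2)
  expect_true(is.na(code_depression("yes", NA, "no", "no", "no")$depressed))
})

test_that("NCD risk counting uses the exact BMI boundaries", {
  expect_identical(
    code_ncd_risk("never_former", 22.0, "ge_half_hour")$count, 0L)
  expect_identical(code_ncd_risk("current", 26.0, "lt_half_hour")$count, 3L)
  # 18.5 is not < 18.5 and not >= 25.0
  expect_identical(
    code_ncd_risk("never_former", 18.5, "ge_half_hour")$count, 0L)
  expect_identical(
    code_ncd_risk("never_former", 18.4999, "ge_half_hour")$count, 1L)
  expect_identical(
    code_ncd_risk("never_former", 25.0, "ge_half_hour")$count, 1L)
  res <- code_ncd_risk(c("current", "never_former", NA),
                       c(23, 30, 23),
                       c("ge_half_hour", "ge_half_hour", "ge_half_hour"))
  expect_identical(res$count, c(1L, 1L, NA))
  expect_identical(as.character(res$stratum),
                   c("one risk factor", "one risk factor", NA))
  expect_identical(
    as.character(code_ncd_risk("current", 30, "lt_half_hour")$stratum),
    "two or three risk factors")
})

test_that("coding is deterministic across repeated calls", {
  p <- draw_baseline(single_group_config(200, seed = 5, group = 2L))
  a <- code_social_participation(p$vol_freq, p$hobby_freq, p$neigh_freq)
  b <- code_social_participation(p$vol_freq, p$hobby_freq, p$neigh_freq)
  expect_identical(a, b)
  expect_true(all(a == 2L))
})
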