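test_that("a single participant occupies 100% of their cell", {
  p <- make_participants("A", sex = "male", vol = "weekly_plus")
  w <- data.frame(id = "A", t_months = c(0L, 132L), state = "nd")
  tab <- outcome_distribution_table(panel_dataset(p, w))
  row <- tab[tab$sex == "male" & tab$group == "1" &
               tab$status == "nondisabled", ]
  expect_identical(row$n, 1L)
  expect_equal(row$pct, 100)
})

test_that("final status precedence is death > emigration > disabled", {
  p <- make_participants(c("A", "B", "C"), vol = "none")
  w <- data.frame(id = c("A", "A", "B", "C", "C"),
                  t_months = c(0L, 12L, 0L, 0L, 24L),
                  state = c("nd", "dis", "nd", "nd", "dis"))
  e <- data.frame(id = c("A", "B", "B"),
                  kind = c("death", "emigration", "disability_cert"),
                  t_months = c(60L, 36L, 36L))
  tab <- outcome_distribution_table(panel_dataset(p, w, e))
  st <- function(id) {
    s <- tab[tab$sex == "male" & tab$group == "0" & tab$n > 0, ]
    s$status
  }
  got <- tab[tab$sex == "male" & tab$group == "0" & tab$n > 0,
             c("status", "n")]
  expect_setequal(got$status, c("dead", "emigrated", "disabled"))
  # a disability record later than the last nd wave makes the status disabled
  expect_identical(got$n[got$status == "disabled"], 1L)
})

test_that("percentages are of the sex-specific total and sum to 100", {
  ds <- generate_dataset(simulation_config(n = 2000, seed = 3))
  tab <- outcome_distribution_table(ds)
  for (s in c("male", "female")) {
    nongrp <- tab[tab$sex == s & tab$group != "all", ]
    expect_equal(sum(nongrp$pct), 100, tolerance = 1e-9)
    allrows <- tab[tab$sex == s & tab$group == "all", ]
    expect_equal(sum(allrows$pct), 100, tolerance = 1e-9)
  }
})

test_that("outcome table reproduces a reconstructed count table", {
  counts <- data.frame(sex = rep(c("male", "female"), each = 4),
                       group = rep(c(0, 2), 4),
                       status = c("nondisabled", "disabled", "dead",
                                  "emigrated"),
                       n = c(5, 3, 2, 1, 7, 4, 2, 2))
  ds <- panel_from_outcome_counts(counts)
  tab <- outcome_distribution_table(ds)
  for (i in seq_len(nrow(counts))) {
    row <- tab[tab$sex == counts$sex[i] &
                 tab$group == as.character(counts$group[i]) &
                 tab$status == counts$status[i], ]
    expect_identical(row$n, as.integer(counts$n[i]))
  }
})

test_that("baseline table matches the generating marginals", {
  cfg <- single_group_config(20000, seed = 17, group = 0L)
  ds <- generate_dataset(cfg)
  tab <- baseline_characteristics_table(ds)
  val <- function(ch) tab[tab$characteristic == ch, "group_0"]
  # truncation to [65, 100] lifts the mean above the nominal 75.1
  mu <- 75.1; sdv <- 6.5
  a <- (65 - mu) / sdv; b <- (100 - mu) / sdv
  z <- pnorm(b) - pnorm(a)
  tmean <- mu + sdv * (dnorm(a) - dnorm(b)) / z
  expect_equal(val("age_mean"), tmean, tolerance = 4 * sdv / sqrt(20000))
  expect_equal(val("men_pct"), 100)
  expect_equal(val("depression_pct"), 40.2, tolerance = 1.5)
  expect_equal(val("current_smoker_pct"), 13.1, tolerance = 1.5)
  expect_equal(val("walking_lt_half_pct"), 46.1, tolerance = 1.5)
  expect_equal(val("bmi_mean"), 23.4, tolerance = 0.1)
})

test_that("an empty group yields missing markers without error", {
  p <- make_participants("A", vol = "none")
  w <- data.frame(id = "A", t_months = 0L, state = "nd")
  ds <- panel_dataset(p, w)
  group_of <- function(p) factor("g0", levels = c("g0", "g1"))
  tab <- baseline_characteristics_table(ds, group_of = group_of)
  expect_true(all(is.na(tab$group_g1)))
  expect_identical(tab[tab$characteristic == "n", "group_g0"], 1)
  out <- outcome_distribution_table(ds, group_of = group_of)
  expect_true(all(out$n[out$group == "g1"] == 0))
})
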