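test_that("generation is reproducible given the config and seed", {
  cfg <- simulation_config(n = 300, seed = 99)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$participants, d2$participants)
  expect_identical(d1$waves, d2$waves)
  expect_identical(d1$events, d2$events)
  d3 <- generate_dataset(simulation_config(n = 300, seed = 100))
  expect_false(identical(d2$waves, d3$waves))
  # same schema either way
  expect_identical(names(d2$waves), names(d3$waves))
})

test_that("every simulated participant enters non-disabled", {
  ds <- generate_dataset(simulation_config(n = 400, seed = 8))
  base <- ds$waves[ds$waves$t_months == 0L, ]
  expect_identical(nrow(base), 400L)
  expect_true(all(base$state == "nd"))
})

test_that("degenerate group probabilities pin the coded exposure", {
  ds <- generate_dataset(single_group_config(150, seed = 4, group = 0L))
  expect_true(all(participant_exposure(ds) == 0L))
  ds3 <- generate_dataset(single_group_config(150, seed = 4, group = 3L))
  expect_true(all(participant_exposure(ds3) == 3L))
})

test_that("an absent-transition chain never leaves the entry state", {
  set.seed(1)
  traj <- simulate_trajectory(transition_params(), baseline_age = 70)
  expect_identical(length(unclass(traj)), 133L)
  expect_true(all(unclass(traj) == 1L))
})

test_that("one-step empirical frequencies match the step matrix row", {
  cfg <- single_group_config(
    200000, seed = 21, group = 0L,
    age_dist_by_group = cbind(mean = rep(75, 4), sd = rep(1e-7, 4)),
    followup_months = 1L, wave_interval_months = 1L,
    emigration_monthly_prob = 0)
  ds <- generate_dataset(cfg)
  P <- step_matrix(default_true_params("male", 0L), 75)
  n <- 200000
  w1 <- ds$waves[ds$waves$t_months == 1L, ]
  deaths <- sum(ds$events$kind == "death")
  p_hat <- c(nd = sum(w1$state == "nd") / n,
             dis = sum(w1$state == "dis") / n,
             dead = deaths / n)
  for (j in 1:3) {
    tol <- 4 * sqrt(P[1, j] * (1 - P[1, j]) / n) + 1e-9
    expect_lt(abs(p_hat[j] - P[1, j]), tol)
  }
})

test_that("recovery shows up in trajectories when allowed", {
  th <- transition_params(a_nd_dis = -2, b_nd_dis = 0,
                          a_dis_nd = -1, b_dis_nd = 0,
                          a_nd_dead = -6, b_nd_dead = 0,
                          a_dis_dead = -6, b_dis_dead = 0)
  set.seed(5)
  saw_recovery <- FALSE
  for (i in 1:50) {
    s <- unclass(simulate_trajectory(th, 70, months = 60))
    if (any(s[-1] == 1L & s[-length(s)] == 2L)) saw_recovery <- TRUE
  }
  expect_true(saw_recovery)
})

test_that("observation records waves while alive and events exactly dated", {
  cfg <- simulation_config(n = 10, seed = 1, emigration_monthly_prob = 0)
  # death at month 30: waves at 0, 12, 24 and a dated death event
  s <- c(rep(1L, 28), 2L, 2L, rep(3L, 103))
  traj <- structure(s, class = "latent_trajectory", baseline_age = 70)
  ob <- observe(traj, cfg, id = "Z1")
  expect_identical(ob$waves$t_months, c(0L, 12L, 24L))
  expect_identical(ob$waves$state, c("nd", "nd", "nd"))
  d <- ob$events[ob$events$kind == "death", ]
  expect_identical(d$t_months, 30L)
  cert <- ob$events[ob$events$kind == "disability_cert", ]
  expect_identical(cert$t_months, 28L)  # first month in the disabled state
})

test_that("emigration censors all later records", {
  cfg <- simulation_config(n = 10, seed = 1, emigration_monthly_prob = 0.5)
  traj <- structure(rep(1L, 133), class = "latent_trajectory",
                    baseline_age = 70)
  set.seed(77)
  e_month <- rgeom(1, 0.5) + 1
  set.seed(77)
  ob <- observe(traj, cfg, id = "Z2")
  expect_true(all(ob$waves$t_months < e_month))
  em <- ob$events[ob$events$kind == "emigration", ]
  expect_identical(em$t_months, as.integer(e_month))
})

test_that("default emigration rate loses about 3% of the cohort", {
  ds <- generate_dataset(simulation_config(n = 30000, seed = 12))
  frac <- mean(ds$participants$id %in%
                 ds$events$id[ds$events$kind == "emigration"])
  expect_gt(frac, 0.025)
  expect_lt(frac, 0.038)
})

test_that("with flat age slopes annual fractions follow the matrix power", {
  th <- transition_params(a_nd_dis = -4.5, b_nd_dis = 0,
                          a_dis_nd = -4.0, b_dis_nd = 0,
                          a_nd_dead = -5.5, b_nd_dead = 0,
                          a_dis_dead = -4.5, b_dis_dead = 0)
  cfg <- single_group_config(
    50000, seed = 31, group = 0L,
    age_dist_by_group = cbind(mean = rep(75, 4), sd = rep(1e-7, 4)),
    followup_months = 12L, emigration_monthly_prob = 0,
    true_params = list(male = rep(list(th), 4), female = rep(list(th), 4)))
  ds <- generate_dataset(cfg)
  P12 <- mat_pow(step_matrix(th, 75), 12)
  n <- 50000
  w12 <- ds$waves[ds$waves$t_months == 12L, ]
  p_hat <- c(sum(w12$state == "nd"), sum(w12$state == "dis"),
             sum(ds$events$kind == "death")) / n
  for (j in 1:3)
    expect_lt(abs(p_hat[j] - P12[1, j]),
              4 * sqrt(P12[1, j] * (1 - P12[1, j]) / n))
})

test_that("invalid configs are rejected with the violated invariant", {
  expect_error(simulation_config(group_probs_by_sex = list(
    male = c(0.5, 0.5, 0.5, 0.5), female = c(0.25, 0.25, 0.25, 0.25))),
    "summing to 1")
  expect_error(simulation_config(step_h = 1 / 5), "dividing")
  expect_error(simulation_config(emigration_monthly_prob = 1.2),
               "emigration")
  expect_error(simulation_config(n = -1), "n must be")
})

test_that("n = 0 gives an empty dataset with intact schema", {
  ds <- generate_dataset(simulation_config(n = 0, seed = 1))
  expect_identical(nrow(ds$participants), 0L)
  expect_identical(nrow(ds$waves), 0L)
  expect_true("vol_freq" %in% names(ds$participants))
})
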