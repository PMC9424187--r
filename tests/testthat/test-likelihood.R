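theta_test <- transition_params(
  a_nd_dis = -4.2, b_nd_dis = 0.02, a_dis_nd = -2.5, b_dis_nd = -0.01,
  a_nd_dead = -5.0, b_nd_dead = 0.03, a_dis_dead = -3.6, b_dis_dead = 0.02)

test_that("a 12-step interval equals the matrix-power entry", {
  flat <- transition_params(a_nd_dis = -4, a_dis_nd = -3,
                            a_nd_dead = -5, a_dis_dead = -3.5)
  P12 <- mat_pow(step_matrix(flat, 70), 12)
  for (s0 in 1:2) for (s1 in 1:2) {
    ds <- pair_panel(70, 0L, c("nd", "dis")[s0], 12L, c("nd", "dis")[s1])
    expect_equal(interval_log_likelihood(flat, ds), log(P12[s0, s1]),
                 tolerance = 1e-12)
  }
})

test_that("matrix-product likelihood equals exhaustive path enumeration", {
  for (g in 1:3) for (s0 in 1:2) {
    for (s1 in 1:2) {
      ds <- pair_panel(72, 6L, c("nd", "dis")[s0], 6L + g,
                       c("nd", "dis")[s1])
      expected <- enum_interval_prob(theta_test, 72 + 6 / 12, g, s0, s1)
      expect_equal(interval_log_likelihood(theta_test, ds), log(expected),
                   tolerance = 1e-12)
    }
    # exactly dated death g steps after the last wave
    ds <- pair_panel(72, 6L, c("nd", "dis")[s0], death_at = 6L + g)
    expected <- enum_death_prob(theta_test, 72 + 6 / 12, g, s0)
    expect_equal(interval_log_likelihood(theta_test, ds), log(expected),
                 tolerance = 1e-12)
  }
})

test_that("probability-one paths give log-likelihood zero", {
  p <- make_participants(c("A", "B"), vol = "none")
  w <- data.frame(id = rep(c("A", "B"), each = 3),
                  t_months = rep(c(0L, 12L, 24L), 2), state = "nd")
  ds <- panel_dataset(p, w)
  expect_identical(interval_log_likelihood(transition_params(), ds), 0)
})

test_that("an impossible observed path yields -Inf with a diagnostic", {
  ds <- pair_panel(70, 0L, "nd", 12L, "dis")
  expect_warning(
    ll <- interval_log_likelihood(transition_params(), ds),
    "probability zero")
  expect_identical(ll, -Inf)
})

test_that("emigration contributes nothing beyond the last wave", {
  ds1 <- pair_panel(70, 0L, "nd", 12L, "nd")
  p <- ds1$participants
  w <- ds1$waves
  e <- data.frame(id = "P1", kind = "emigration", t_months = 18L)
  ds2 <- panel_dataset(p, w, e)
  expect_equal(interval_log_likelihood(theta_test, ds1),
               interval_log_likelihood(theta_test, ds2))
})

test_that("doubling the dataset doubles the likelihood and halves vcov", {
  cfg <- single_group_config(1500, seed = 13)
  ds <- generate_dataset(cfg)
  ds2 <- ds
  clone <- ds$participants
  clone$id <- paste0("D", clone$id)
  w2 <- ds$waves; w2$id <- paste0("D", w2$id)
  e2 <- ds$events; e2$id <- paste0("D", e2$id)
  ds2$participants <- rbind(ds$participants, clone)
  ds2$waves <- rbind(ds$waves, w2)
  ds2$events <- rbind(ds$events, e2)
  f1 <- fit_transitions(ds, sex = "male", group = 0)
  f2 <- fit_transitions(ds2, sex = "male", group = 0)
  expect_equal(as.numeric(f2$params), as.numeric(f1$params),
               tolerance = 5e-3)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
  v1 <- diag(f1$vcov)[f1$free]
  v2 <- diag(f2$vcov)[f2$free]
  expect_equal(unname(v2 / v1), rep(0.5, length(v1)), tolerance = 0.05)
})

test_that("the optimiser never degrades the initial log-likelihood", {
  cfg <- single_group_config(800, seed = 19)
  ds <- generate_dataset(cfg)
  fit <- fit_transitions(ds, sex = "male", group = 0)
  init <- transition_params(a_nd_dis = -4, a_dis_nd = -4,
                            a_nd_dead = -4, a_dis_dead = -4)
  ll0 <- interval_log_likelihood(init, ds, sex = "male", group = 0)
  expect_gte(fit$loglik, ll0)
})
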