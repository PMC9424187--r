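test_that("occupancy of an absent-transition chain stays at the identity", {
  occ <- occupancy_curve(transition_params(), 65, 70)
  for (t in c(1, 30, 61))
    expect_equal(occ[t, , ], diag(3), tolerance = 1e-14,
                 ignore_attr = TRUE)
})

test_that("flat-slope occupancy equals the matrix power", {
  th <- transition_params(a_nd_dis = -4, a_dis_nd = -3,
                          a_nd_dead = -5, a_dis_dead = -3.5)
  occ <- occupancy_curve(th, 65, 75)
  P <- step_matrix(th, 65)
  expect_equal(occ[1, , ], diag(3), ignore_attr = TRUE)
  for (k in c(1, 7, 120))
    expect_equal(occ[k + 1, , ], mat_pow(P, k), tolerance = 1e-12,
                 ignore_attr = TRUE)
})

test_that("occupancy rows remain stochastic along the whole curve", {
  occ <- occupancy_curve(default_true_params("female", 2), 65, 115)
  sums <- apply(occ, 1, rowSums)
  expect_lt(max(abs(sums - 1)), 1e-10)
})

test_that("a constant-hazard chain matches the geometric closed form", {
  p <- 0.01
  th <- transition_params(a_nd_dead = qlogis(p), b_nd_dead = 0)
  # closure truncation is material here by construction; the closed form
  # below truncates at the identical horizon
  lt <- suppressWarnings(expectancies(th, x0 = 65, x_max = 115, h = 1 / 12))
  T_ <- 600L
  q <- 1 - step_matrix(th, 65)[1, 3]
  closed <- (1 / 12) * (0.5 + sum(q^(1:(T_ - 1))) + 0.5 * q^T_)
  expect_equal(lt$tle, closed, tolerance = 1e-10)
  expect_equal(lt$dfle, closed, tolerance = 1e-10)
  # with a horizon long enough for survival to die out, the sum approaches
  # the headline value h * (1/2 + (1 - p)/p)
  ltT <- expectancies(th, x0 = 65, x_max = 165, h = 1 / 12)
  expect_equal(ltT$tle, 8.2917, tolerance = 2e-5)
})

test_that("zero hazards give the full truncated horizon", {
  lt <- suppressWarnings(expectancies(transition_params(), 65, 115))
  expect_equal(lt$tle, 50)
  expect_equal(lt$dfle, 50)
  expect_equal(lt$duration_disabled, 0)
})

test_that("the expectancy triple is additive to machine precision", {
  for (s in c("male", "female")) for (g in c(0L, 3L)) {
    lt <- expectancies(default_true_params(s, g))
    expect_identical(lt$tle, lt$dfle + lt$duration_disabled)
    expect_true(lt$dfle >= 0 && lt$tle <= 50)
  }
})

test_that("raising both death intercepts strictly lowers DFLE and TLE", {
  base <- default_true_params("male", 1)
  lt0 <- expectancies(base)
  worse <- as.numeric(base)
  names(worse) <- names(base)
  worse["a_nd_dead"] <- worse["a_nd_dead"] + 0.5
  worse["a_dis_dead"] <- worse["a_dis_dead"] + 0.5
  lt1 <- expectancies(as_transition_params(worse))
  expect_lt(lt1$tle, lt0$tle)
  expect_lt(lt1$dfle, lt0$dfle)
})

test_that("halving the step changes DFLE by less than 0.02 years", {
  for (s in c("male", "female")) {
    th <- default_true_params(s, 0)
    d12 <- expectancies(th, h = 1 / 12)$dfle
    d24 <- expectancies(th, h = 1 / 24)$dfle
    expect_lt(abs(d12 - d24), 0.02)
  }
})

test_that("results are insensitive to the closure age when survival is negligible", {
  th <- default_true_params("male", 0)
  lt110 <- expectancies(th, x_max = 110)
  expect_lt(lt110$survival_at_closure, 1e-4)
  lt115 <- expectancies(th, x_max = 115)
  expect_lt(abs(lt115$dfle - lt110$dfle), 0.01)
  expect_lt(abs(lt115$tle - lt110$tle), 0.01)
})

test_that("material closure truncation raises a warning", {
  soft <- transition_params(a_nd_dead = qlogis(0.002), b_nd_dead = 0)
  expect_warning(expectancies(soft, x_max = 115), "closure")
})

make_fit <- function(params, vcov = matrix(0, 8, 8)) {
  dimnames(vcov) <- list(names(params), names(params))
  structure(list(params = params, loglik = 0, vcov = vcov,
                 free = setNames(rep(TRUE, 8), names(params)),
                 converged = TRUE, n_obs_pairs = 1L, n_subjects = 1L,
                 support = NULL, sex = "male", group = 0),
            class = "transition_fit")
}

test_that("a zero covariance collapses the bootstrap CI to the point", {
  fit <- make_fit(default_true_params("male", 0))
  lt <- bootstrap_ci(fit, B = 50, seed = 3)
  expect_equal(unname(lt$ci["dfle", "lo"]), lt$dfle)
  expect_equal(unname(lt$ci["dfle", "hi"]), lt$dfle)
})

test_that("B = 1 gives the degenerate single-draw interval", {
  vc <- diag(c(0.01, 1e-6, 0.01, 1e-6, 0.01, 1e-6, 0.01, 1e-6))
  fit <- make_fit(default_true_params("male", 0), vc)
  lt <- bootstrap_ci(fit, B = 1, seed = 4)
  expect_equal(unname(lt$ci["dfle", "lo"]), unname(lt$ci["dfle", "hi"]))
  expect_identical(nrow(lt$draws), 1L)
})

test_that("bootstrap intervals are reproducible given the seed", {
  vc <- diag(c(0.02, 2e-6, 0.05, 5e-6, 0.01, 1e-6, 0.04, 4e-6))
  fit <- make_fit(default_true_params("female", 1), vc)
  a <- bootstrap_ci(fit, B = 200, seed = 9)
  b <- bootstrap_ci(fit, B = 200, seed = 9)
  expect_identical(a$ci, b$ci)
})

test_that("microsimulation of an absent-transition chain is exact", {
  ms <- microsim_expectancy(transition_params(), 65, 115, N = 10, seed = 1)
  expect_equal(ms$dfle, 50)
  expect_equal(ms$duration_disabled, 0)
  expect_identical(unname(ms$se["dfle"]), 0)
})

test_that("microsimulation is reproducible and agrees with the matrix form", {
  th <- default_true_params("male", 2)
  m1 <- microsim_expectancy(th, N = 20000, seed = 6)
  m2 <- microsim_expectancy(th, N = 20000, seed = 6)
  expect_identical(m1$dfle, m2$dfle)
  lt <- expectancies(th)
  expect_lt(abs(m1$dfle - lt$dfle), 4 * m1$se["dfle"])
  expect_lt(abs(m1$tle - lt$tle), 4 * m1$se["tle"])
})
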