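#' State-occupancy curve of the fitted Markov chain
#'
#' Computes the matrices `M_t = P(x0) P(x0 + h) ... P(x0 + (t-1) h)`,
#' whose (i, j) entry is the probability of being in state j at age
#' `x0 + t h` given state i at `x0`.  `M_0` is the identity.
#'
#' @param params a `transition_params`.
#' @param x0 index age in years.
#' @param x_max closure age in years (everyone is treated as transferred to
#'   dead beyond it).
#' @param h step length in years (default the parameters' native step).
#' @return array of dimension `(T + 1, 3, 3)` with `T = (x_max - x0) / h`;
#'   dimnames name the states.
#' @export
occupancy_curve <- function(params, x0 = 65, x_max = 115, h = NULL) {
  stopifnot(inherits(params, "transition_params"), x0 < x_max)
  if (is.null(h)) h <- attr(params, "step")
  T_ <- as.integer(round((x_max - x0) / h))
  ages <- x0 + (seq_len(T_) - 1L) * h
  pr <- .step_probs(unclass(params), ages,
                    scale = h / attr(params, "step"))
  out <- array(0, dim = c(T_ + 1L, 3L, 3L),
               dimnames = list(NULL, .STATES, .STATES))
  M <- diag(3)
  out[1L, , ] <- M
  for (t_i in seq_len(T_)) {
    P <- rbind(c(pr$p11[t_i], pr$p12[t_i], pr$p13[t_i]),
               c(pr$p21[t_i], pr$p22[t_i], pr$p23[t_i]),
               c(0, 0, 1))
    M <- M %*% P
    out[t_i + 1L, , ] <- M
  }
  out
}

#' Life-table expectancies from the transition model
#'
#' Integrates the state-occupancy curve over age with trapezoid weights
#' (half weight at the index and closure ages, the standard half-interval
#' life-table convention): the expected years in living state j are
#' `h * sum_t w_t M_t[start, j]`.  DFLE is the expectation for the
#' non-disabled state, duration with disability that for the disabled
#' state, and TLE their sum (exactly, by construction).
#'
#' @inheritParams occupancy_curve
#' @param conditioning `"nd_at_x0"` (default: expectancies for a person
#'   non-disabled at the index age, matching a disability-free entry
#'   cohort) or `"prevalence_weighted"` (mix the non-disabled and disabled
#'   rows by `init_dist`).
#' @param init_dist length-2 probability vector over (non-disabled,
#'   disabled) used when `conditioning = "prevalence_weighted"`.
#' @param keep_occupancy store the occupancy array in the result.
#' @return object of class `life_table_result` with elements `dfle`,
#'   `duration_disabled`, `tle` (years), `x0`, `x_max`, `h`,
#'   `conditioning`, `survival_at_closure`, and optionally `occupancy`.
#'   A warning is raised when survival at the closure age exceeds 1e-4
#'   (truncation would then be material).
#' @export
expectancies <- function(params, x0 = 65, x_max = 115, h = NULL,
                         conditioning = c("nd_at_x0", "prevalence_weighted"),
                         init_dist = NULL, keep_occupancy = FALSE) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(params, "transition_params"), x0 < x_max)
  if (is.null(h)) h <- attr(params, "step")
  init <- if (conditioning == "nd_at_x0") c(1, 0) else {
    if (is.null(init_dist) || length(init_dist) != 2 ||
        abs(sum(init_dist) - 1) > 1e-8)
      stop("prevalence_weighted conditioning needs init_dist, a length-2 ",
           "probability vector over (nd, dis)")
    as.numeric(init_dist)
  }
  e <- .expect_many(matrix(unclass(params), nrow = 1L), x0, x_max, h,
                    scale = h / attr(params, "step"), init = init)
  occ <- if (keep_occupancy) occupancy_curve(params, x0, x_max, h) else NULL
  if (e$surv > 1e-4)
    warning(sprintf(
      "survival at the closure age %.0f is %.2g (> 1e-4); closure-age
truncation is material, consider raising x_max", x_max, e$surv))
  structure(list(dfle = e$e_nd, duration_disabled = e$e_dis,
                 tle = e$e_nd + e$e_dis,
                 x0 = x0, x_max = x_max, h = h,
                 conditioning = conditioning,
                 survival_at_closure = e$surv,
                 occupancy = occ, ci = NULL),
            class = "life_table_result")
}

# Trapezoid expectancies for a matrix of parameter vectors (rows), shared
# age grid; vectorised across rows so the bootstrap is one pass.
.expect_many <- function(thetas, x0, x_max, h, scale = 1, init = c(1, 0)) {
  T_ <- as.integer(round((x_max - x0) / h))
  B <- nrow(thetas)
  v1 <- rep(init[1L], B); v2 <- rep(init[2L], B)
  acc1 <- 0.5 * v1; acc2 <- 0.5 * v2
  a1 <- thetas[, 1L]; b1 <- thetas[, 2L]
  a2 <- thetas[, 3L]; b2 <- thetas[, 4L]
  a3 <- thetas[, 5L]; b3 <- thetas[, 6L]
  a4 <- thetas[, 7L]; b4 <- thetas[, 8L]
  for (t_i in 0:(T_ - 1L)) {
    x <- x0 + t_i * h
    l12 <- a1 + b1 * x; l13 <- a3 + b3 * x
    m <- pmax(0, l12, l13)
    z0 <- exp(-m); z12 <- exp(l12 - m); z13 <- exp(l13 - m)
    z12[l12 < -35] <- 0; z13[l13 < -35] <- 0
    s <- z0 + z12 + z13
    p12 <- scale * z12 / s; p13 <- scale * z13 / s
    p11 <- pmax(1 - p12 - p13, 0)
    l21 <- a2 + b2 * x; l23 <- a4 + b4 * x
    m <- pmax(0, l21, l23)
    z0 <- exp(-m); z21 <- exp(l21 - m); z23 <- exp(l23 - m)
    z21[l21 < -35] <- 0; z23[l23 < -35] <- 0
    s <- z0 + z21 + z23
    p21 <- scale * z21 / s; p23 <- scale * z23 / s
    p22 <- pmax(1 - p21 - p23, 0)
    w1 <- v1 * p11 + v2 * p21
    w2 <- v1 * p12 + v2 * p22
    v1 <- w1; v2 <- w2
    w <- if (t_i == T_ - 1L) 0.5 else 1
    acc1 <- acc1 + w * v1
    acc2 <- acc2 + w * v2
  }
  list(e_nd = h * acc1, e_dis = h * acc2, surv = v1 + v2)
}

#' @export
print.life_table_result <- function(x, ...) {
  cat(sprintf(
    "life table at age %.0f (closure %.0f, step %.4g yr, %s):\n",
    x$x0, x$x_max, x$h, x$conditioning))
  fmt <- function(v, ci) {
    if (is.null(x$ci)) sprintf("%6.2f yr", v)
    else sprintf("%6.2f yr (95%% CI %.2f-%.2f)", v, ci[1L], ci[2L])
  }
  cat("  DFLE:                    ", fmt(x$dfle, x$ci["dfle", ]), "\n")
  cat("  duration with disability:",
      fmt(x$duration_disabled, x$ci["duration_disabled", ]), "\n")
  cat("  TLE:                     ", fmt(x$tle, x$ci["tle", ]), "\n")
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for life-table quantities
#'
#' Draws `B` parameter vectors from the multivariate normal approximation
#' to the sampling distribution of the estimates (mean the MLE, covariance
#' the inverse observed information), recomputes the expectancies for each
#' draw, and reports percentile intervals.  Percentile rather than
#' normal-theory intervals are used because the expectancies are nonlinear
#' functionals of the parameters.
#'
#' @param fit a converged `transition_fit`.
#' @param B number of bootstrap draws (default 1000).  `B = 1` gives a
#'   degenerate interval equal to the single draw — legal but useless.
#' @param seed optional integer seed for reproducibility.
#' @param level confidence level (default 0.95).
#' @param x0,x_max,h,conditioning,init_dist passed to [expectancies()].
#' @return a `life_table_result` whose `ci` element is a matrix with rows
#'   `dfle`, `duration_disabled`, `tle` and columns `lo`, `hi`, plus a
#'   `draws` matrix (B x 3) of the bootstrap replicates.
#' @export
bootstrap_ci <- function(fit, B = 1000L, seed = NULL, level = 0.95,
                         x0 = 65, x_max = 115, h = 1 / 12,
                         conditioning = c("nd_at_x0", "prevalence_weighted"),
                         init_dist = NULL) {
  stopifnot(inherits(fit, "transition_fit"))
  conditioning <- match.arg(conditioning)
  if (!isTRUE(fit$converged))
    stop("refusing to bootstrap a non-converged fit")
  if (!is.null(seed)) set.seed(seed)
  point <- expectancies(fit$params, x0, x_max, h,
                        conditioning = conditioning, init_dist = init_dist)
  free <- fit$free
  theta_hat <- as.numeric(fit$params)
  Sigma <- fit$vcov[free, free, drop = FALSE]
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
    repaired <- ev$vectors %*% diag(pmax(ev$values, 0),
                                    length(ev$values)) %*% t(ev$vectors)
    dist <- sqrt(sum((repaired - Sigma)^2)) /
      max(sqrt(sum(Sigma^2)), .Machine$double.eps)
    if (dist > 0.1)
      stop("covariance matrix is far from positive semi-definite ",
           "(relative repair distance ", signif(dist, 3), ")")
    warning("covariance not positive semi-definite; repaired by ",
            "eigenvalue clipping (relative distance ", signif(dist, 3), ")")
    Sigma <- repaired
  }
  draws_free <- if (sum(free) == 0L || all(Sigma == 0)) {
    matrix(rep(theta_hat[free], each = B), nrow = B)
  } else {
    MASS::mvrnorm(B, mu = theta_hat[free], Sigma = Sigma)
  }
  if (B == 1L) draws_free <- matrix(draws_free, nrow = 1L)
  thetas <- matrix(rep(theta_hat, each = B), nrow = B)
  thetas[, free] <- draws_free
  init <- if (conditioning == "nd_at_x0") c(1, 0) else as.numeric(init_dist)
  e <- .expect_many(thetas, x0, x_max, h,
                    scale = h / attr(fit$params, "step"), init = init)
  draws <- cbind(dfle = e$e_nd, duration_disabled = e$e_dis,
                 tle = e$e_nd + e$e_dis)
  alpha <- (1 - level) / 2
  ci <- t(apply(draws, 2L, quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lo", "hi")
  point$ci <- ci
  point$draws <- draws
  point$B <- B
  point
}

#' Microsimulation estimate of the life-table expectancies
#'
#' Simulates `N` individual trajectories from the step matrices, starting
#' non-disabled at the index age, and averages time spent in each living
#' state using the same trapezoid convention as [expectancies()].  The two
#' estimators target the same integral, so this is an independent
#' Monte-Carlo oracle for the matrix-product life-table math.
#'
#' @inheritParams occupancy_curve
#' @param N number of simulated trajectories.
#' @param seed optional integer seed.
#' @return list with `dfle`, `duration_disabled`, `tle` (years) and `se`,
#'   a named vector of Monte-Carlo standard errors (sample SD / sqrt(N)).
#' @export
microsim_expectancy <- function(params, x0 = 65, x_max = 115, h = NULL,
                                N = 1e5, seed = NULL) {
  stopifnot(inherits(params, "transition_params"), N >= 1)
  if (is.null(h)) h <- attr(params, "step")
  if (!is.null(seed)) set.seed(seed)
  T_ <- as.integer(round((x_max - x0) / h))
  scale <- h / attr(params, "step")
  th <- unclass(params)
  state <- rep(1L, N)
  acc_nd <- rep(0.5, N)  # trapezoid weight at t = 0, everyone nd
  acc_dis <- numeric(N)
  for (t_i in 0:(T_ - 1L)) {
    x <- x0 + t_i * h
    pr <- .step_probs(th, x, scale = scale)
    u <- runif(N)
    alive1 <- state == 1L
    alive2 <- state == 2L
    ns <- state
    # nd row: thresholds stay | -> dis | -> dead
    ns[alive1 & u >= pr$p11 & u < pr$p11 + pr$p12] <- 2L
    ns[alive1 & u >= pr$p11 + pr$p12] <- 3L
    # dis row: thresholds -> nd | stay | -> dead
    ns[alive2 & u < pr$p21] <- 1L
    ns[alive2 & u >= pr$p21 + pr$p22] <- 3L
    state <- ns
    w <- if (t_i == T_ - 1L) 0.5 else 1
    acc_nd <- acc_nd + w * (state == 1L)
    acc_dis <- acc_dis + w * (state == 2L)
  }
  t_nd <- h * acc_nd
  t_dis <- h * acc_dis
  t_tot <- t_nd + t_dis
  se <- c(dfle = sd(t_nd), duration_disabled = sd(t_dis),
          tle = sd(t_tot)) / sqrt(N)
  list(dfle = mean(t_nd), duration_disabled = mean(t_dis),
       tle = mean(t_tot), se = se, N = N)
}

#' Plot state occupancy over age
#'
#' @param x a `life_table_result` computed with `keep_occupancy = TRUE`,
#'   or a `transition_params`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @importFrom graphics matplot legend
#' @export
plot_occupancy <- function(x, ...) {
  if (inherits(x, "transition_params"))
    x <- expectancies(x, keep_occupancy = TRUE)
  if (is.null(x$occupancy))
    stop("no occupancy stored; recompute with keep_occupancy = TRUE")
  ages <- x$x0 + (seq_len(dim(x$occupancy)[1L]) - 1L) * x$h
  occ <- x$occupancy[, 1L, ]  # conditional on nd at x0
  matplot(ages, occ, type = "l", lty = 1, lwd = 2,
          col = c("#2166ac", "#b2182b", "grey40"),
          xlab = "age (years)", ylab = "occupancy probability", ...)
  legend("right", legend = c("non-disabled", "disabled", "dead"),
         col = c("#2166ac", "#b2182b", "grey40"), lwd = 2, bty = "n")
  invisible(x)
}
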