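#' Transition-model parameters
#'
#' Holds the eight scalars of the age-parameterised multinomial-logit step
#' model: an intercept `a` and an age slope `b` (logit units, age in years)
#' for each of the four transitions of the illness-death-with-recovery
#' scheme: non-disabled to disabled (incidence), disabled to non-disabled
#' (recovery), non-disabled to dead, and disabled to dead.  Probabilities
#' refer to one elementary step, one month (`step = 1/12` year) by default.
#'
#' An intercept of `-50` is the sentinel for a structurally absent
#' transition (its per-step probability is numerically zero).
#'
#' @param a_nd_dis,b_nd_dis incidence intercept and slope.
#' @param a_dis_nd,b_dis_nd recovery intercept and slope.
#' @param a_nd_dead,b_nd_dead mortality from the non-disabled state.
#' @param a_dis_dead,b_dis_dead mortality from the disabled state.
#' @param step elementary step length in years (default 1/12).
#' @return named numeric vector of class `transition_params`.
#' @examples
#' tp <- transition_params(a_nd_dis = -15, b_nd_dis = 0.105,
#'                         a_nd_dead = -13.5, b_nd_dead = 0.1)
#' step_matrix(tp, age = 75)
#' @export
transition_params <- function(a_nd_dis = -50, b_nd_dis = 0,
                              a_dis_nd = -50, b_dis_nd = 0,
                              a_nd_dead = -50, b_nd_dead = 0,
                              a_dis_dead = -50, b_dis_dead = 0,
                              step = 1 / 12) {
  x <- c(a_nd_dis = a_nd_dis, b_nd_dis = b_nd_dis,
         a_dis_nd = a_dis_nd, b_dis_nd = b_dis_nd,
         a_nd_dead = a_nd_dead, b_nd_dead = b_nd_dead,
         a_dis_dead = a_dis_dead, b_dis_dead = b_dis_dead)
  if (!all(is.finite(x)))
    stop("transition parameters must be finite (use -50 for an absent ",
         "transition)")
  structure(x, class = "transition_params", step = step)
}

#' Coerce a named numeric vector to transition parameters
#'
#' @param x named numeric vector containing the eight parameter names.
#' @param step elementary step length in years.
#' @return a `transition_params`.
#' @export
as_transition_params <- function(x, step = 1 / 12) {
  miss <- setdiff(.PARAM_NAMES, names(x))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  do.call(transition_params, c(as.list(x[.PARAM_NAMES]), list(step = step)))
}

#' @export
print.transition_params <- function(x, ...) {
  cat("transition_params (step =", format(attr(x, "step")), "years):\n")
  lab <- c("nd -> dis", "dis -> nd", "nd -> dead", "dis -> dead")
  for (k in 1:4)
    cat(sprintf("  %-11s a = %9.4f   b = %8.5f\n",
                lab[k], x[2 * k - 1], x[2 * k]))
  invisible(x)
}

# per-step transition probabilities of the two transient rows at the given
# ages (vectorised, log-sum-exp stabilised).  `scale` rescales off-diagonal
# probabilities for a step length differing from the parameters' native
# step (first-order intensity approximation).
.step_probs <- function(theta, ages, scale = 1, zero_cut = -35) {
  row_probs <- function(a1, b1, a2, b2) {
    l1 <- a1 + b1 * ages
    l2 <- a2 + b2 * ages
    m <- pmax(0, l1, l2)
    z1 <- exp(l1 - m); z2 <- exp(l2 - m)
    # logits below the cut are structural zeros (the absent-transition
    # sentinel), so impossible observed paths get likelihood exactly 0;
    # the fitter disables the cut so that a sparse transition dropped to
    # the sentinel leaves its few observed occurrences merely improbable
    z1[l1 < zero_cut] <- 0
    z2[l2 < zero_cut] <- 0
    s <- exp(-m) + z1 + z2
    list(p1 = z1 / s, p2 = z2 / s)
  }
  nd <- row_probs(theta[1L], theta[2L], theta[5L], theta[6L])
  di <- row_probs(theta[3L], theta[4L], theta[7L], theta[8L])
  p12 <- nd$p1 * scale; p13 <- nd$p2 * scale
  p21 <- di$p1 * scale; p23 <- di$p2 * scale
  list(p11 = pmax(1 - p12 - p13, 0), p12 = p12, p13 = p13,
       p21 = p21, p22 = pmax(1 - p21 - p23, 0), p23 = p23)
}

#' Per-step transition probability matrix at a given age
#'
#' For a transient origin state i, the probability of moving to j != i over
#' one elementary step at age x is
#' `exp(a_ij + b_ij * x) / (1 + sum_k exp(a_ik + b_ik * x))`, and the
#' retention probability is the complementary `1 / (1 + sum_k ...)`.  The
#' dead row is exactly absorbing.
#'
#' @param params a `transition_params`.
#' @param age age in years at the start of the step, in \[65, 115\].
#' @param h step length in years; defaults to the parameters' native step.
#'   Other step lengths rescale the off-diagonal probabilities
#'   proportionally (intensity approximation), which is first-order exact
#'   for small probabilities.
#' @return 3x3 row-stochastic matrix with rows/columns `nd`, `dis`, `dead`.
#' @export
step_matrix <- function(params, age, h = NULL) {
  stopifnot(inherits(params, "transition_params"), length(age) == 1)
  if (age < 65 || age > 115)
    stop("age must be in [65, 115], got ", age)
  if (is.null(h)) h <- attr(params, "step")
  pr <- .step_probs(unclass(params), age, scale = h / attr(params, "step"))
  m <- rbind(c(pr$p11, pr$p12, pr$p13),
             c(pr$p21, pr$p22, pr$p23),
             c(0, 0, 1))
  dimnames(m) <- list(.STATES, .STATES)
  if (!all(is.finite(m)) || any(m < 0))
    stop("non-finite or negative step probabilities at age ", age,
         " (params: ", paste(signif(unclass(params), 4), collapse = ", "),
         ")")
  m
}

# ---- interval likelihood ----------------------------------------------------

# Decompose a dataset subset into aggregated likelihood intervals.
# Columns: x (age at interval start, whole months), g (number of monthly
# steps), from (1 = nd, 2 = dis), to (1/2, or 3 for an exactly dated death),
# dead (logical), n (multiplicity).
.panel_intervals <- function(dataset, ids = NULL) {
  p <- dataset$participants
  if (!is.null(ids)) p <- p[p$id %in% ids, , drop = FALSE]
  agem <- setNames(as.integer(round(p$age * 12)), p$id)
  w <- dataset$waves[dataset$waves$id %in% p$id, , drop = FALSE]
  empty <- data.frame(x = integer(), g = integer(), from = integer(),
                      to = integer(), dead = logical(), n = integer())
  if (!nrow(w)) return(empty)
  w <- w[order(w$id, w$t_months), , drop = FALSE]
  st <- ifelse(w$state == "nd", 1L, 2L)
  nw <- nrow(w)
  x <- integer(0); g <- integer(0); from <- integer(0); to <- integer(0)
  if (nw > 1) {
    same <- w$id[-1L] == w$id[-nw]
    x <- (agem[w$id[-nw]] + w$t_months[-nw])[same]
    g <- (w$t_months[-1L] - w$t_months[-nw])[same]
    from <- st[-nw][same]
    to <- st[-1L][same]
  }
  dead <- rep(FALSE, length(x))
  d <- dataset$events[dataset$events$kind == "death" &
                        dataset$events$id %in% p$id, , drop = FALSE]
  if (nrow(d)) {
    last_i <- which(!duplicated(w$id, fromLast = TRUE))
    mi <- match(d$id, w$id[last_i])
    if (anyNA(mi)) {
      warning("death event(s) without any wave observation skipped: ",
              paste(head(d$id[is.na(mi)], 3), collapse = ", "))
      d <- d[!is.na(mi), , drop = FALSE]; mi <- mi[!is.na(mi)]
    }
    lt <- w$t_months[last_i][mi]
    x <- c(x, agem[d$id] + lt)
    g <- c(g, d$t_months - lt)
    from <- c(from, st[last_i][mi])
    to <- c(to, rep(3L, nrow(d)))
    dead <- c(dead, rep(TRUE, nrow(d)))
  }
  if (!length(x)) return(empty)
  stopifnot(all(g >= 1L))
  key <- ((as.numeric(x) * 256 + g) * 4 + from) * 8 + to
  o <- order(key)
  r <- rle(key[o])
  first <- o[cumsum(r$lengths)]
  data.frame(x = x[first], g = g[first], from = from[first], to = to[first],
             dead = dead[first], n = r$lengths)
}

# Precompute the index structure reused across likelihood evaluations.
.prep_intervals <- function(iv) {
  if (!nrow(iv))
    return(list(iv = iv, empty = TRUE))
  S <- sort(unique(iv$x))
  list(iv = iv, empty = FALSE, S = S, si = match(iv$x, S),
       m0 = min(S), m1 = max(iv$x + iv$g) - 1L, gmax = max(iv$g),
       alive_by_g = split(which(!iv$dead), iv$g[!iv$dead]),
       dead_by_g = split(which(iv$dead), iv$g[iv$dead]))
}

# Core log-likelihood over prepped intervals.  Maintains, for every distinct
# interval-start age, the running product of monthly 2x2 transient blocks;
# an exactly dated death at step g multiplies the (g-1)-step product by the
# relevant death probabilities of the final month.
.loglik_prepped <- function(theta, prep, zero_cut = -35) {
  if (prep$empty) return(0)
  ages <- (prep$m0:prep$m1) / 12
  pr <- .step_probs(theta, ages, zero_cut = zero_cut)
  if (!all(is.finite(pr$p11)) || !all(is.finite(pr$p22))) return(-Inf)
  iv <- prep$iv
  S <- prep$S; si <- prep$si
  ns <- length(S)
  T11 <- rep(1, ns); T12 <- numeric(ns)
  T21 <- numeric(ns); T22 <- rep(1, ns)
  ll <- 0
  base <- S - prep$m0 + 1L
  for (u in seq_len(prep$gmax)) {
    mi <- base + (u - 1L)
    ug <- as.character(u)
    rows <- prep$dead_by_g[[ug]]
    if (length(rows)) {
      j <- si[rows]; mj <- mi[j]
      f1 <- iv$from[rows] == 1L
      v <- ifelse(f1,
                  T11[j] * pr$p13[mj] + T12[j] * pr$p23[mj],
                  T21[j] * pr$p13[mj] + T22[j] * pr$p23[mj])
      if (any(v <= 0)) return(-Inf)
      ll <- ll + sum(iv$n[rows] * log(v))
    }
    b11 <- pr$p11[mi]; b12 <- pr$p12[mi]
    b21 <- pr$p21[mi]; b22 <- pr$p22[mi]
    t11 <- T11 * b11 + T12 * b21
    t12 <- T11 * b12 + T12 * b22
    t21 <- T21 * b11 + T22 * b21
    t22 <- T21 * b12 + T22 * b22
    T11 <- t11; T12 <- t12; T21 <- t21; T22 <- t22
    rows <- prep$alive_by_g[[ug]]
    if (length(rows)) {
      j <- si[rows]
      f1 <- iv$from[rows] == 1L
      t1 <- iv$to[rows] == 1L
      v <- ifelse(f1, ifelse(t1, T11[j], T12[j]),
                  ifelse(t1, T21[j], T22[j]))
      if (any(v <= 0)) return(-Inf)
      ll <- ll + sum(iv$n[rows] * log(v))
    }
  }
  ll
}

#' Interval-censored panel log-likelihood
#'
#' The log-likelihood of a panel under the multinomial-logit step model.
#' Each pair of consecutive wave observations contributes the log of the
#' (state-at-start, state-at-end) entry of the product of the monthly step
#' matrices spanning the interval, so the unobserved path between waves is
#' integrated out.  A death dated to month m after a last wave in state s
#' contributes the log of the probability of reaching either living state
#' by month m-1 and then dying in the final month.  Emigration contributes
#' nothing beyond the last observed wave (non-informative right censoring).
#'
#' @param params a `transition_params` (monthly step).
#' @param dataset a validated `panel_dataset` with month-resolution times.
#' @param sex,group optional subgroup filter: participants with this sex
#'   and this coded exposure group only.
#' @param group_of optional function `participants -> group labels`
#'   overriding the default exposure coding.
#' @return scalar log-likelihood; `-Inf` (with a warning naming the first
#'   offending interval) if any observed path has probability zero.
#' @export
interval_log_likelihood <- function(params, dataset, sex = NULL,
                                    group = NULL, group_of = NULL) {
  stopifnot(inherits(params, "transition_params"),
            inherits(dataset, "panel_dataset"))
  ids <- .subgroup_ids(dataset, sex, group, group_of)
  prep <- .prep_intervals(.panel_intervals(dataset, ids))
  ll <- .loglik_prepped(unclass(params), prep)
  if (identical(ll, -Inf))
    warning("an observed path has probability zero under these parameters")
  ll
}

.subgroup_ids <- function(dataset, sex = NULL, group = NULL,
                          group_of = NULL) {
  p <- dataset$participants
  keep <- rep(TRUE, nrow(p))
  if (!is.null(sex)) keep <- keep & p$sex == sex
  if (!is.null(group)) {
    g <- if (is.null(group_of)) participant_exposure(dataset) else group_of(p)
    keep <- keep & !is.na(g) & as.character(g) == as.character(group)
  }
  p$id[keep]
}

# ---- maximum likelihood fit -------------------------------------------------

#' Fit the transition model to a panel subgroup by maximum likelihood
#'
#' Maximises the interval-censored likelihood over the intercept/slope
#' pairs of the four transitions by quasi-Newton (BFGS) iteration.  A
#' transition with fewer than `min_support` directly observed occurrences
#' (wave pairs showing the move, or deaths from the relevant last-observed
#' state) is dropped to the absent-transition sentinel and not estimated.
#' For numerical conditioning the optimiser works with age centred at
#' `age_center`; results are reported on the original scale (the transform
#' is linear, so this is exact).
#'
#' @param dataset a `panel_dataset`.
#' @param sex,group,group_of subgroup selection as in
#'   [interval_log_likelihood()].
#' @param init initial values `c(intercept, slope)` for every fitted
#'   transition (default `c(-4, 0)`: rare transitions, no age trend).
#' @param min_support minimum number of directly observed transitions of a
#'   type for it to be fitted (default 1).
#' @param age_center centring age in years used internally (default 80).
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 500, reltol = 1e-8)`.
#' @return object of class `transition_fit`: list with `params`
#'   (`transition_params`), `loglik`, `vcov` (8x8, inverse observed
#'   information, zero rows/columns for dropped transitions), `free`
#'   (logical 8-vector), `converged`, `n_obs_pairs`, `n_subjects`,
#'   `support` (per-transition observed counts), `sex`, `group`.
#' @export
fit_transitions <- function(dataset, sex = NULL, group = NULL,
                            group_of = NULL, init = c(-4, 0),
                            min_support = 1L, age_center = 80,
                            control = list(maxit = 500, reltol = 1e-8)) {
  stopifnot(inherits(dataset, "panel_dataset"))
  ids <- .subgroup_ids(dataset, sex, group, group_of)
  if (!length(ids))
    return(.failed_fit(sex, group, reason = "empty subgroup"))
  iv <- .panel_intervals(dataset, ids)
  if (!nrow(iv))
    return(.failed_fit(sex, group, reason = "no observation pairs"))
  support <- c(
    nd_dis = sum(iv$n[!iv$dead & iv$from == 1L & iv$to == 2L]),
    dis_nd = sum(iv$n[!iv$dead & iv$from == 2L & iv$to == 1L]),
    nd_dead = sum(iv$n[iv$dead & iv$from == 1L]),
    dis_dead = sum(iv$n[iv$dead & iv$from == 2L]))
  fitted_tr <- support >= min_support
  if (!any(fitted_tr))
    return(.failed_fit(sex, group, reason = "no supported transitions"))
  free <- rep(fitted_tr, each = 2L)  # (a, b) per transition
  names(free) <- .PARAM_NAMES
  prep <- .prep_intervals(iv)
  # internal parameterisation: intercept at age_center, slope per year
  theta_of <- function(par) {
    th <- rep(c(.ABSENT, 0), 4L)
    th[free] <- par
    a_i <- seq(1L, 8L, 2L)
    th[a_i] <- th[a_i] - th[a_i + 1L] * age_center
    th
  }
  negll <- function(par) {
    ll <- .loglik_prepped(theta_of(par), prep, zero_cut = -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- rep(c(init[1L], init[2L]), sum(fitted_tr))
  opt <- optim(par0, negll, method = "BFGS", control = control,
               hessian = TRUE)
  theta <- theta_of(opt$par)
  names(theta) <- .PARAM_NAMES
  # back-transform the covariance: a = a_c - b * age_center
  vc_free <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("observed information singular; using a pseudo-inverse")
    MASS::ginv(opt$hessian)
  })
  vc_free <- (vc_free + t(vc_free)) / 2
  k <- sum(fitted_tr)
  J <- diag(2 * k)
  for (t_i in seq_len(k)) J[2 * t_i - 1L, 2 * t_i] <- -age_center
  vc_free <- J %*% vc_free %*% t(J)
  vcov <- matrix(0, 8L, 8L, dimnames = list(.PARAM_NAMES, .PARAM_NAMES))
  vcov[free, free] <- vc_free
  structure(list(
    params = as_transition_params(theta),
    loglik = -opt$value,
    vcov = vcov,
    free = free,
    converged = opt$convergence == 0L,
    n_obs_pairs = sum(iv$n),
    n_subjects = length(ids),
    support = support,
    sex = sex, group = group,
    optim = list(counts = opt$counts, convergence = opt$convergence,
                 message = opt$message)),
    class = "transition_fit")
}

.failed_fit <- function(sex, group, reason) {
  structure(list(params = transition_params(), loglik = NA_real_,
                 vcov = matrix(0, 8L, 8L,
                               dimnames = list(.PARAM_NAMES, .PARAM_NAMES)),
                 free = setNames(rep(FALSE, 8L), .PARAM_NAMES),
                 converged = FALSE, n_obs_pairs = 0L, n_subjects = 0L,
                 support = c(nd_dis = 0L, dis_nd = 0L, nd_dead = 0L,
                             dis_dead = 0L),
                 sex = sex, group = group, reason = reason),
            class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat("transition_fit",
      if (!is.null(x$sex)) paste0("[sex=", x$sex, "]"),
      if (!is.null(x$group)) paste0("[group=", x$group, "]"), "\n")
  if (!is.null(x$reason)) {
    cat("  not fitted:", x$reason, "\n")
    return(invisible(x))
  }
  cat("  subjects:", x$n_subjects, " observation pairs:", x$n_obs_pairs,
      "\n  log-likelihood:", format(x$loglik),
      " converged:", x$converged, "\n")
  se <- sqrt(pmax(diag(x$vcov), 0))
  est <- cbind(estimate = as.numeric(x$params), se = se)
  rownames(est) <- .PARAM_NAMES
  print(round(est[x$free, , drop = FALSE], 5))
  dropped <- unique(sub("^[ab]_", "", .PARAM_NAMES[!x$free]))
  if (length(dropped))
    cat("  dropped (insufficient support):",
        paste(dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Wald confidence intervals for fitted transition parameters
#'
#' @param fit a converged `transition_fit`.
#' @param level confidence level (default 0.95).
#' @return matrix with columns `estimate`, `lo`, `hi` for the fitted
#'   parameters.
#' @export
wald_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "transition_fit"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- as.numeric(fit$params)[fit$free]
  se <- sqrt(pmax(diag(fit$vcov)[fit$free], 0))
  cbind(estimate = est, lo = est - z * se, hi = est + z * se)
}

#' Serialise a transition fit to JSON
#'
#' @param fit a `transition_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "transition_fit"))
  obj <- list(sex = fit$sex, group = fit$group,
              params = as.list(setNames(as.numeric(fit$params),
                                        .PARAM_NAMES)),
              free = as.list(setNames(fit$free, .PARAM_NAMES)),
              loglik = fit$loglik, converged = fit$converged,
              n_obs_pairs = fit$n_obs_pairs, n_subjects = fit$n_subjects,
              vcov = fit$vcov)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transition fit from JSON
#'
#' @param path file written by [write_fit_json()].
#' @return a `transition_fit`.
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vc <- matrix(unlist(obj$vcov), 8L, 8L,
               dimnames = list(.PARAM_NAMES, .PARAM_NAMES))
  structure(list(params = as_transition_params(unlist(obj$params)),
                 loglik = obj$loglik, vcov = vc,
                 free = setNames(unlist(obj$free), .PARAM_NAMES),
                 converged = obj$converged,
                 n_obs_pairs = obj$n_obs_pairs,
                 n_subjects = obj$n_subjects,
                 support = NULL, sex = obj$sex, group = obj$group),
            class = "transition_fit")
}
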