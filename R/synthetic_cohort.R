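# Frozen generator defaults.  Age slopes are Gompertz-like (log-odds of
# death/disability rising ~0.10-0.14 per year of age); intercepts were
# calibrated with calibrate_intercepts() so that the implied DFLE and
# duration with disability at age 65 match, per sex and participation
# group, the values reported for a large Japanese community cohort of
# older adults (men: DFLE 17.8/20.9/21.5/22.7 y, duration ~1 y; women:
# 21.8/25.1/25.3/26.7 y, duration ~4-4.7 y).
.DEFAULT_THETA <- list(
  male = list(
    c(-14.928901, 0.105, -4.5, 0, -13.468468, 0.100, -12.668468, 0.100),
    c(-15.270479, 0.105, -4.5, 0, -13.869282, 0.100, -13.069282, 0.100),
    c(-15.351434, 0.105, -4.5, 0, -13.940815, 0.100, -13.140815, 0.100),
    c(-15.510271, 0.105, -4.5, 0, -14.082107, 0.100, -13.282107, 0.100)),
  female = list(
    c(-16.282956, 0.130, -4.5, 0, -17.718902, 0.140, -17.418902, 0.140),
    c(-16.612559, 0.130, -4.5, 0, -18.332083, 0.140, -18.032083, 0.140),
    c(-16.725536, 0.130, -4.5, 0, -18.280419, 0.140, -17.980419, 0.140),
    c(-16.958322, 0.130, -4.5, 0, -18.450804, 0.140, -18.150804, 0.140)))

#' Default true transition parameters per sex and exposure group
#'
#' The generator's built-in truth: monthly multinomial-logit parameters for
#' each sex and number of social participations (0-3), calibrated so that
#' the implied disability-free and total life expectancy at 65 reproduce
#' values typical of Japanese community-dwelling older adults, with a
#' roughly 5-year DFLE gradient between the no-activity and three-activity
#' groups in both sexes.
#'
#' @param sex `"male"` or `"female"`.
#' @param group number of social participations, 0-3.
#' @return a `transition_params`.
#' @export
default_true_params <- function(sex = c("male", "female"), group = 0L) {
  sex <- match.arg(sex)
  stopifnot(group %in% 0:3)
  th <- .DEFAULT_THETA[[sex]][[group + 1L]]
  as_transition_params(setNames(th, .PARAM_NAMES))
}

#' Calibrate incidence and mortality intercepts to target expectancies
#'
#' Finds the non-disabled-to-disabled and non-disabled-to-dead intercepts
#' for which the model's DFLE and duration with disability at the index
#' age equal given targets, holding the age slopes, the recovery
#' parameters, and the disabled-mortality excess fixed.  This is how the
#' frozen defaults of [default_true_params()] were produced.
#'
#' @param dfle,duration target years at the index age.
#' @param b_nd_dis,b_mort age slopes (logit/year) for incidence and for
#'   both mortality transitions.
#' @param a_dis_nd,b_dis_nd recovery parameters (held fixed).
#' @param excess additive excess of the disabled-mortality intercept over
#'   the non-disabled one (logit units).
#' @param x0,x_max index and closure ages.
#' @return a `transition_params`; attribute `"residual"` carries the
#'   root-finding residual in years.
#' @export
calibrate_intercepts <- function(dfle, duration, b_nd_dis = 0.105,
                                 b_mort = 0.100, a_dis_nd = -4.5,
                                 b_dis_nd = 0, excess = 0.8,
                                 x0 = 65, x_max = 115) {
  obj <- function(p) {
    th <- c(p[1L], b_nd_dis, a_dis_nd, b_dis_nd, p[2L], b_mort,
            p[2L] + excess, b_mort)
    e <- .expect_many(matrix(th, nrow = 1L), x0, x_max, 1 / 12)
    (e$e_nd - dfle)^2 + (e$e_dis - duration)^2
  }
  best <- NULL
  for (st in list(c(-6.5, -7.5), c(-8, -9), c(-9, -10.5)))
    for (i in 1:2) {
      o <- optim(if (i == 1) st else best$par, obj,
                 control = list(maxit = 5000, reltol = 1e-15))
      if (is.null(best) || o$value < best$value) best <- o
    }
  th <- transition_params(
    a_nd_dis = best$par[1L], b_nd_dis = b_nd_dis,
    a_dis_nd = a_dis_nd, b_dis_nd = b_dis_nd,
    a_nd_dead = best$par[2L], b_nd_dead = b_mort,
    a_dis_dead = best$par[2L] + excess, b_dis_dead = b_mort)
  attr(th, "residual") <- sqrt(best$value)
  th
}

#' Specify the synthetic-cohort generative model
#'
#' All defaults emulate the structure of an 11-year annual-wave disability
#' follow-up of community-dwelling Japanese adults aged 65+: four
#' social-participation groups with published baseline covariate marginals,
#' monthly latent Markov transitions with age-increasing hazards
#' ([default_true_params()]), annual observation waves, month-precision
#' death dates, and independent monthly emigration calibrated so that
#' about 3.1% of the cohort emigrates during follow-up.
#'
#' @param n number of participants (default 11,982, a realistic cohort
#'   size for this design).
#' @param seed integer seed; [generate_dataset()] is reproducible given
#'   the config.
#' @param sex_prob probability of male (default 0.46).
#' @param group_probs_by_sex list with `male` and `female` 4-vectors of
#'   group membership probabilities (defaults reflect that frequent
#'   participants are more often male).
#' @param age_dist_by_group 4x2 matrix of (mean, SD) baseline age in years
#'   per group, truncated to \[65, 100\] and rounded to the month; the
#'   default declines from 75.1 (6.5) to 72.1 (4.9) across groups.
#' @param covariate_model list of per-group covariate marginals:
#'   `smoking_current`, `walking_lt_half`, `depression`, `bmi_mean`,
#'   `bmi_sd`, `hx` (5x4 matrix of disease-history probabilities), and
#'   `missing` rates for smoking/bmi/walking/dss items.
#' @param true_params list `male`/`female` of four `transition_params`
#'   (groups 0-3).
#' @param step_h elementary step in years (default 1/12).
#' @param followup_months total follow-up (default 132).
#' @param wave_interval_months wave spacing (default 12); must be a
#'   multiple of the step.
#' @param emigration_monthly_prob per-month emigration probability
#'   (default 2.6e-4).
#' @param p_missing_social probability that a participant's
#'   social-participation information is unavailable (one activity item
#'   set missing).
#' @param p_no_consent,p_prevalent,p_pre_exit rates of the exclusion-flag
#'   conditions, for exercising the cascade (defaults 0: the generator
#'   emulates the analysed, post-exclusion cohort).
#' @param covariate_hazard_hook optional function
#'   `participants -> numeric offset` returning a per-participant additive
#'   shift of the incidence and mortality logit intercepts; lets tests
#'   inject covariate-dependent hazards to probe confounding.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n = 11982L, seed = 1L, sex_prob = 0.46,
    group_probs_by_sex = list(male = c(0.328, 0.200, 0.193, 0.279),
                              female = c(0.438, 0.235, 0.158, 0.169)),
    age_dist_by_group = cbind(mean = c(75.1, 73.1, 72.7, 72.1),
                              sd = c(6.5, 5.7, 5.5, 4.9)),
    covariate_model = list(
      smoking_current = c(0.131, 0.131, 0.136, 0.142),
      walking_lt_half = c(0.461, 0.337, 0.307, 0.245),
      depression = c(0.402, 0.260, 0.204, 0.140),
      bmi_mean = c(23.4, 23.5, 23.6, 23.9),
      bmi_sd = c(3.7, 3.3, 3.1, 3.0),
      hx = rbind(htn = c(0.450, 0.449, 0.419, 0.411),
                 dm = c(0.126, 0.119, 0.110, 0.120),
                 stroke = c(0.038, 0.024, 0.021, 0.020),
                 mi = c(0.056, 0.046, 0.055, 0.040),
                 cancer = c(0.097, 0.086, 0.091, 0.086)),
      missing = c(smoking = 0, bmi = 0, walking = 0, dss = 0)),
    true_params = NULL,
    step_h = 1 / 12, followup_months = 132L, wave_interval_months = 12L,
    emigration_monthly_prob = 2.6e-4,
    p_missing_social = 0, p_no_consent = 0, p_prevalent = 0,
    p_pre_exit = 0, covariate_hazard_hook = NULL) {
  if (is.null(true_params))
    true_params <- list(
      male = lapply(0:3, function(g) default_true_params("male", g)),
      female = lapply(0:3, function(g) default_true_params("female", g)))
  cfg <- structure(as.list(environment()), class = "simulation_config")
  .validate_simulation_config(cfg)
  cfg
}

.validate_simulation_config <- function(cfg) {
  bad <- function(msg) stop("invalid simulation_config: ", msg)
  if (cfg$n < 0) bad("n must be >= 0")
  if (cfg$sex_prob < 0 || cfg$sex_prob > 1) bad("sex_prob not a probability")
  for (s in c("male", "female")) {
    gp <- cfg$group_probs_by_sex[[s]]
    if (length(gp) != 4 || any(gp < 0) || abs(sum(gp) - 1) > 1e-8)
      bad(paste0("group_probs_by_sex$", s,
                 " must be a 4-vector summing to 1"))
    if (length(cfg$true_params[[s]]) != 4 ||
        !all(vapply(cfg$true_params[[s]], inherits, logical(1),
                    "transition_params")))
      bad(paste0("true_params$", s,
                 " must be four transition_params objects"))
  }
  if (any(cfg$age_dist_by_group[, 2] <= 0)) bad("age SDs must be > 0")
  if (cfg$step_h <= 0) bad("step_h must be > 0")
  months_per_step <- cfg$step_h * 12
  if (abs(months_per_step - round(months_per_step)) > 1e-9 ||
      cfg$wave_interval_months %% round(months_per_step) != 0)
    bad("step_h x 12 must be an integer dividing wave_interval_months")
  if (cfg$emigration_monthly_prob < 0 || cfg$emigration_monthly_prob >= 1)
    bad("emigration_monthly_prob not in [0, 1)")
  cm <- cfg$covariate_model
  for (nm in c("smoking_current", "walking_lt_half", "depression"))
    if (any(cm[[nm]] < 0 | cm[[nm]] > 1))
      bad(paste(nm, "entries must be probabilities"))
  if (any(cm$bmi_sd <= 0)) bad("bmi_sd must be > 0")
  invisible(cfg)
}

# per-item yes probability giving a target P(score >= 2) under independent
# items (score ~ Binomial(5, p))
.dss_item_prob <- function(target) {
  if (target <= 0) return(0)
  uniroot(function(p) 1 - pbinom(1, 5, p) - target,
          c(1e-9, 0.999), tol = 1e-12)$root
}

#' @importFrom stats pbinom rgeom
NULL

#' Draw baseline participants from the generative model
#'
#' Assigns sex, exposure group, baseline age (truncated normal per group,
#' rounded to whole months), activity frequencies consistent with the
#' assigned group (a group-g participant has exactly g categories with
#' non-`"none"` frequency, uniformly spread over the three non-none
#' levels), and the remaining covariates from the per-group marginals.
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param config a `simulation_config`.
#' @return participants data frame (see [panel_dataset()]); the assigned
#'   group is recoverable as [participant_exposure()] except where social
#'   information was made missing.
#' @export
draw_baseline <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  if (n == 0)
    return(.empty_participants())
  sex <- ifelse(runif(n) < config$sex_prob, "male", "female")
  grp <- integer(n)
  for (s in c("male", "female")) {
    i <- sex == s
    grp[i] <- sample(0:3, sum(i), replace = TRUE,
                     prob = config$group_probs_by_sex[[s]])
  }
  mu <- config$age_dist_by_group[grp + 1L, 1L]
  sdv <- config$age_dist_by_group[grp + 1L, 2L]
  lo <- pnorm(65, mu, sdv); hi <- pnorm(100, mu, sdv)
  age <- qnorm(lo + runif(n) * (hi - lo), mu, sdv)
  age <- round(age * 12) / 12
  # which categories are active: the grp[i] largest of three uniform draws
  r1 <- runif(n); r2 <- runif(n); r3 <- runif(n)
  rk1 <- 1L + (r1 < r2) + (r1 < r3)
  rk2 <- 1L + (r2 < r1) + (r2 < r3)
  rk3 <- 1L + (r3 < r1) + (r3 < r2)
  lev <- function(active) ifelse(active,
                                 .FREQ_LEVELS[1L + sample.int(3, n,
                                                              replace = TRUE)],
                                 "none")
  vol <- lev(rk1 <= grp); hob <- lev(rk2 <= grp); nei <- lev(rk3 <= grp)
  if (config$p_missing_social > 0) {
    hit <- runif(n) < config$p_missing_social
    which_item <- sample.int(3, n, replace = TRUE)
    vol[hit & which_item == 1L] <- NA
    hob[hit & which_item == 2L] <- NA
    nei[hit & which_item == 3L] <- NA
  }
  cm <- config$covariate_model
  gi <- grp + 1L
  smoking <- ifelse(runif(n) < cm$smoking_current[gi], "current",
                    "never_former")
  walking <- ifelse(runif(n) < cm$walking_lt_half[gi], "lt_half_hour",
                    "ge_half_hour")
  bmi <- round(pmin(pmax(rnorm(n, cm$bmi_mean[gi], cm$bmi_sd[gi]), 12), 55),
               1)
  p_item <- vapply(cm$depression, .dss_item_prob, numeric(1))[gi]
  scored <- matrix(runif(5 * n) < p_item, n, 5L)
  yes_if_scored <- c(TRUE, TRUE, FALSE, TRUE, FALSE)  # items 3/5 reversed
  dss <- matrix("no", n, 5L)
  for (j in 1:5)
    dss[, j] <- ifelse(xor(scored[, j], !yes_if_scored[j]), "yes", "no")
  ms <- cm$missing
  if (ms["smoking"] > 0) smoking[runif(n) < ms["smoking"]] <- NA
  if (ms["bmi"] > 0) bmi[runif(n) < ms["bmi"]] <- NA
  if (ms["walking"] > 0) walking[runif(n) < ms["walking"]] <- NA
  if (ms["dss"] > 0) dss[runif(n) < ms["dss"], 1L] <- NA
  hx <- matrix(runif(5 * n) < t(cm$hx)[gi, ], n, 5L)
  data.frame(
    id = sprintf("S%06d", seq_len(n)), sex = sex, age = age,
    vol_freq = vol, hobby_freq = hob, neigh_freq = nei,
    smoking = smoking, bmi = bmi, walking = walking,
    dss1 = dss[, 1L], dss2 = dss[, 2L], dss3 = dss[, 3L],
    dss4 = dss[, 4L], dss5 = dss[, 5L],
    hx_htn = hx[, 1L], hx_dm = hx[, 2L], hx_stroke = hx[, 3L],
    hx_mi = hx[, 4L], hx_cancer = hx[, 5L],
    consent = !(runif(n) < config$p_no_consent),
    prevalent_disability = runif(n) < config$p_prevalent,
    pre_baseline_exit = runif(n) < config$p_pre_exit,
    stringsAsFactors = FALSE)
}

# Vectorised monthly latent chains for a block of subjects sharing theta.
# base_age_months: integer vector; offset: per-subject logit shift of the
# incidence and mortality intercepts.  Returns n x (months + 1) matrix of
# state codes; everyone starts non-disabled; dead is absorbing.
.simulate_states <- function(theta, base_age_months, months, offset = 0) {
  n <- length(base_age_months)
  S <- matrix(1L, n, months + 1L)
  state <- rep(1L, n)
  off <- rep_len(offset, n)
  for (t_i in 0:(months - 1L)) {
    ages <- (base_age_months + t_i) / 12
    l12 <- theta[1L] + off + theta[2L] * ages
    l13 <- theta[5L] + off + theta[6L] * ages
    m <- pmax(0, l12, l13)
    z0 <- exp(-m); z12 <- exp(l12 - m); z13 <- exp(l13 - m)
    z12[l12 < -35] <- 0; z13[l13 < -35] <- 0
    s <- z0 + z12 + z13
    p11 <- z0 / s; p12 <- z12 / s
    l21 <- theta[3L] + theta[4L] * ages
    l23 <- theta[7L] + off + theta[8L] * ages
    m <- pmax(0, l21, l23)
    z0 <- exp(-m); z21 <- exp(l21 - m); z23 <- exp(l23 - m)
    z21[l21 < -35] <- 0; z23[l23 < -35] <- 0
    s <- z0 + z21 + z23
    p21 <- z21 / s; p22 <- z0 / s
    u <- runif(n)
    a1 <- state == 1L; a2 <- state == 2L
    ns <- state
    ns[a1 & u >= p11 & u < p11 + p12] <- 2L
    ns[a1 & u >= p11 + p12] <- 3L
    ns[a2 & u < p21] <- 1L
    ns[a2 & u >= p21 + p22] <- 3L
    state <- ns
    S[, t_i + 2L] <- state
  }
  S
}

#' Simulate one latent monthly trajectory
#'
#' Starting non-disabled, draws the next state each month from the row of
#' the current state in the step matrix at the current age, until death or
#' the end of follow-up.  Uses the current RNG state.
#'
#' @param true_params a `transition_params`.
#' @param baseline_age age in years at entry (rounded to the month).
#' @param months follow-up length in months (default 132).
#' @return object of class `latent_trajectory`: integer vector of state
#'   codes (1 nd, 2 dis, 3 dead) of length `months + 1`, with attribute
#'   `baseline_age`.
#' @export
simulate_trajectory <- function(true_params, baseline_age, months = 132L) {
  stopifnot(inherits(true_params, "transition_params"))
  S <- .simulate_states(unclass(true_params),
                        as.integer(round(baseline_age * 12)), months)
  structure(drop(S), class = "latent_trajectory",
            baseline_age = round(baseline_age * 12) / 12)
}

# waves/events from a block of latent trajectories (rows of S); emig is the
# per-subject emigration month (Inf = never).  Death dominates emigration
# in a shared month.
.observe_block <- function(S, ids, emig, followup, wave_interval) {
  n <- nrow(S)
  dead <- S == 3L
  any_dead <- rowSums(dead) > 0
  dm <- rep(Inf, n)
  dm[any_dead] <- max.col(dead[any_dead, , drop = FALSE], "first") - 1
  dis <- S == 2L
  any_dis <- rowSums(dis) > 0
  fd <- rep(Inf, n)
  fd[any_dis] <- max.col(dis[any_dis, , drop = FALSE], "first") - 1
  tw <- seq(0L, followup, by = wave_interval)
  waves <- do.call(rbind, lapply(tw, function(t_i) {
    i <- which(dm > t_i & emig > t_i)
    if (!length(i)) return(NULL)
    data.frame(id = ids[i], t_months = t_i,
               state = ifelse(S[i, t_i + 1L] == 2L, "dis", "nd"))
  }))
  keep_death <- dm <= followup & emig >= dm
  keep_emig <- emig <= followup & emig < dm
  keep_cert <- fd <= followup & fd < emig
  events <- rbind(
    if (any(keep_cert))
      data.frame(id = ids[keep_cert], kind = "disability_cert",
                 t_months = as.integer(fd[keep_cert])),
    if (any(keep_death))
      data.frame(id = ids[keep_death], kind = "death",
                 t_months = as.integer(dm[keep_death])),
    if (any(keep_emig))
      data.frame(id = ids[keep_emig], kind = "emigration",
                 t_months = as.integer(emig[keep_emig])))
  if (is.null(waves))
    waves <- data.frame(id = character(), t_months = integer(),
                        state = character())
  if (is.null(events))
    events <- data.frame(id = character(), kind = character(),
                         t_months = integer())
  list(waves = waves, events = events)
}

#' Observe a latent trajectory through the study's measurement process
#'
#' Records the state at every wave (t = 0, 12, 24, ... by default) while
#' the subject is alive and not emigrated, the death month exactly, and
#' the first entry into the disabled state as a certification event.
#' Independent monthly emigration (drawn here) censors all later records;
#' death dominates emigration in a shared month.
#'
#' @param trajectory a `latent_trajectory`.
#' @param config a `simulation_config` (schedule and emigration rate).
#' @param id participant id to stamp on the records.
#' @return list with `waves` and `events` data frames.
#' @export
observe <- function(trajectory, config, id = "T1") {
  stopifnot(inherits(trajectory, "latent_trajectory"),
            inherits(config, "simulation_config"))
  p <- config$emigration_monthly_prob
  emig <- if (p > 0) rgeom(1L, p) + 1 else Inf
  .observe_block(matrix(trajectory, nrow = 1L), id, emig,
                 config$followup_months, config$wave_interval_months)
}

#' Generate a complete synthetic panel dataset
#'
#' Seeds the RNG from the config, draws the baseline cohort, simulates the
#' latent monthly trajectories per sex and group under the configured true
#' parameters, and pushes them through the observation process.  Byte-for-
#' byte reproducible given the same config.
#'
#' @param config a `simulation_config`.
#' @return a validated `panel_dataset`; `provenance` records the config
#'   hash, size and seed.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .validate_simulation_config(config)
  set.seed(config$seed)
  if (config$n == 0)
    return(panel_dataset(.empty_participants(),
                         provenance = "synthetic cohort, n = 0",
                         max_t = config$followup_months))
  p <- draw_baseline(config)
  grp <- suppressWarnings(
    code_social_participation(p$vol_freq, p$hobby_freq, p$neigh_freq))
  # subjects with a missing activity item still follow their latent group;
  # recover it from the non-missing items plus the masked one
  if (anyNA(grp)) {
    m <- cbind(p$vol_freq, p$hobby_freq, p$neigh_freq)
    grp[is.na(grp)] <- rowSums(m[is.na(grp), , drop = FALSE] != "none",
                               na.rm = TRUE)
  }
  agem <- as.integer(round(p$age * 12))
  emig <- if (config$emigration_monthly_prob > 0)
    rgeom(config$n, config$emigration_monthly_prob) + 1 else rep(Inf, config$n)
  off <- if (is.null(config$covariate_hazard_hook)) numeric(config$n)
  else config$covariate_hazard_hook(p)
  waves <- list(); events <- list(); k <- 0L
  for (s in c("male", "female")) for (g in 0:3) {
    i <- which(p$sex == s & grp == g)
    if (!length(i)) next
    th <- unclass(config$true_params[[s]][[g + 1L]])
    S <- .simulate_states(th, agem[i], config$followup_months, off[i])
    ob <- .observe_block(S, p$id[i], emig[i], config$followup_months,
                         config$wave_interval_months)
    k <- k + 1L
    waves[[k]] <- ob$waves; events[[k]] <- ob$events
  }
  w <- do.call(rbind, waves)
  e <- do.call(rbind, events)
  w <- w[order(w$id, w$t_months), , drop = FALSE]
  e <- e[order(e$id, e$t_months, e$kind), , drop = FALSE]
  rownames(w) <- rownames(e) <- NULL
  panel_dataset(
    p, w, e,
    provenance = c(
      sprintf("synthetic cohort: n = %d, seed = %d", config$n, config$seed),
      sprintf("config hash: %s", .config_hash(config))),
    max_t = config$followup_months)
}

.empty_participants <- function() {
  data.frame(id = character(), sex = character(), age = numeric(),
             vol_freq = character(), hobby_freq = character(),
             neigh_freq = character(), smoking = character(),
             bmi = numeric(), walking = character(),
             dss1 = character(), dss2 = character(), dss3 = character(),
             dss4 = character(), dss5 = character(),
             hx_htn = logical(), hx_dm = logical(), hx_stroke = logical(),
             hx_mi = logical(), hx_cancer = logical(),
             consent = logical(), prevalent_disability = logical(),
             pre_baseline_exit = logical(), stringsAsFactors = FALSE)
}

.config_hash <- function(config) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  # strip closures (environments make serialisation unstable)
  config$covariate_hazard_hook <- NULL
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' @importFrom stats pnorm qnorm
NULL
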