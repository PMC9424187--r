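# shared fixtures and independent oracles, all built in code

# one-sex, one-group generator shortcut
single_group_config <- function(n, seed, sex = "male", group = 0L, ...) {
  gp <- numeric(4); gp[group + 1L] <- 1
  simulation_config(n = n, seed = seed,
                    sex_prob = if (sex == "male") 1 else 0,
                    group_probs_by_sex = list(male = gp, female = gp), ...)
}

# minimal complete participant rows
make_participants <- function(id, sex = "male", age = 72,
                              vol = "none", hobby = "none", neigh = "none",
                              smoking = "never_former", bmi = 23,
                              walking = "ge_half_hour", dss = "no",
                              consent = TRUE, prevalent = FALSE,
                              pre_exit = FALSE) {
  n <- length(id)
  data.frame(id = id, sex = rep_len(sex, n), age = rep_len(age, n),
             vol_freq = rep_len(vol, n), hobby_freq = rep_len(hobby, n),
             neigh_freq = rep_len(neigh, n),
             smoking = rep_len(smoking, n), bmi = rep_len(bmi, n),
             walking = rep_len(walking, n),
             dss1 = rep_len(dss, n), dss2 = rep_len(dss, n),
             dss3 = rep_len(ifelse(dss == "no", "yes", "no"), n),
             dss4 = rep_len(dss, n),
             dss5 = rep_len(ifelse(dss == "no", "yes", "no"), n),
             hx_htn = FALSE, hx_dm = FALSE, hx_stroke = FALSE,
             hx_mi = FALSE, hx_cancer = FALSE,
             consent = rep_len(consent, n),
             prevalent_disability = rep_len(prevalent, n),
             pre_baseline_exit = rep_len(pre_exit, n),
             stringsAsFactors = FALSE)
}

# a panel holding exactly one observation interval (or one dated death)
pair_panel <- function(age, t0, s0, t1, s1 = NULL, death_at = NULL) {
  p <- make_participants("P1", age = age)
  waves <- data.frame(id = "P1", t_months = t0, state = s0)
  events <- NULL
  if (!is.null(s1))
    waves <- rbind(waves, data.frame(id = "P1", t_months = t1, state = s1))
  if (!is.null(death_at))
    events <- data.frame(id = "P1", kind = "death", t_months = death_at)
  panel_dataset(p, waves, events)
}

# independent oracle: interval probability by explicit path enumeration
# over all intermediate states (exponential in g; used for g <= 3)
enum_interval_prob <- function(params, age_years, g, from, to) {
  if (g == 0) return(as.numeric(from == to))
  P <- step_matrix(params, age_years)
  sum(vapply(1:3, function(k)
    P[from, k] * enum_interval_prob(params, age_years + 1 / 12, g - 1, k, to),
    numeric(1)))
}

enum_death_prob <- function(params, age_years, g, from) {
  # reach a living state by step g - 1, then die in the final month
  Plast <- step_matrix(params, age_years + (g - 1) / 12)
  sum(vapply(1:2, function(l)
    enum_interval_prob(params, age_years, g - 1, from, l) * Plast[l, 3],
    numeric(1)))
}

# matrix power of a constant step matrix
mat_pow <- function(M, k) Reduce(`%*%`, replicate(k, M, simplify = FALSE))

# end-of-follow-up outcome counts of a published community cohort
# (sex x participation group x final status)
outcome_counts_2017 <- function() {
  rbind(
    expand_counts("male", "nondisabled", c(702, 615, 622, 1000)),
    expand_counts("male", "disabled", c(125, 68, 63, 80)),
    expand_counts("male", "dead", c(933, 393, 344, 421)),
    expand_counts("male", "emigrated", c(48, 30, 32, 32)),
    expand_counts("female", "nondisabled", c(1444, 1034, 737, 846)),
    expand_counts("female", "disabled", c(394, 177, 101, 79)),
    expand_counts("female", "dead", c(884, 264, 159, 128)),
    expand_counts("female", "emigrated", c(111, 49, 26, 41)))
}

expand_counts <- function(sex, status, n) {
  data.frame(sex = sex, group = 0:3, status = status, n = n,
             stringsAsFactors = FALSE)
}

# raw cohort matching the published exclusion flowchart: 23,091 responders,
# of whom 6,333 without consent, then 1,979 with prevalent disability,
# then 5 pre-baseline exits, then 2,792 with missing social information
cascade_raw_cohort <- function() {
  n <- 23091
  p <- make_participants(sprintf("R%05d", seq_len(n)), vol = "weekly_plus")
  i <- 0
  p$consent[i + seq_len(6333)] <- FALSE; i <- i + 6333
  p$prevalent_disability[i + seq_len(1979)] <- TRUE; i <- i + 1979
  p$pre_baseline_exit[i + seq_len(5)] <- TRUE; i <- i + 5
  p$vol_freq[i + seq_len(2792)] <- NA
  panel_dataset(p)
}

round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d
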