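#' Construct and validate a panel dataset
#'
#' Bundles baseline participant records, annual wave observations and dated
#' terminal events into a single validated object, the input of the
#' transition-model likelihood.
#'
#' @param participants data frame with one row per participant.  Required
#'   columns: `id` (unique character key), `sex` (`"male"`/`"female"`),
#'   `age` (baseline age in years, >= 65), `vol_freq`, `hobby_freq`,
#'   `neigh_freq` (participation frequency of the three community-activity
#'   categories: `"none"`, `"lt_monthly"`, `"1_3_monthly"`, `"weekly_plus"`,
#'   or `NA` when unknown), `smoking` (`"never_former"`/`"current"`/`NA`),
#'   `bmi` (kg/m2, in (10, 60) or `NA`), `walking`
#'   (`"ge_half_hour"`/`"lt_half_hour"`/`NA`), `dss1`..`dss5`
#'   (`"yes"`/`"no"`/`NA`, the five depression-screen items), `hx_htn`,
#'   `hx_dm`, `hx_stroke`, `hx_mi`, `hx_cancer` (logical disease history),
#'   `consent`, `prevalent_disability`, `pre_baseline_exit` (logical flags
#'   consumed by [apply_exclusion_cascade()]).
#' @param waves data frame with columns `id`, `t_months` (integer months
#'   since follow-up start, 0..`max_t`), `state` (`"nd"`/`"dis"`).
#' @param events data frame with columns `id`, `kind`
#'   (`"disability_cert"`/`"death"`/`"emigration"`), `t_months`.
#' @param provenance character vector; free-text audit log carried along.
#' @param max_t latest admissible `t_months` (default 132, an 11-year
#'   follow-up observed at most monthly).
#'
#' @details Baseline ages are canonicalised to whole months
#'   (`round(age * 12) / 12`), the resolution of the elementary time step.
#'   Validation enforces: unique participant ids; every wave/event id known;
#'   per-id wave times strictly increasing; at most one death and one
#'   emigration per id; no wave at or after the death month; all
#'   `t_months` in `[0, max_t]`.
#'
#' @return An object of class `panel_dataset`: a list with elements
#'   `participants`, `waves`, `events`, `provenance`.
#' @seealso [read_panel_csv()], [generate_dataset()]
#' @export
panel_dataset <- function(participants, waves = NULL, events = NULL,
                          provenance = character(), max_t = 132L) {
  if (is.null(waves))
    waves <- data.frame(id = character(), t_months = integer(),
                        state = character())
  if (is.null(events))
    events <- data.frame(id = character(), kind = character(),
                         t_months = integer())
  participants <- as.data.frame(participants)
  waves <- as.data.frame(waves)
  events <- as.data.frame(events)
  participants$id <- as.character(participants$id)
  if (nrow(waves)) waves$id <- as.character(waves$id)
  if (nrow(events)) events$id <- as.character(events$id)
  participants$age <- round(participants$age * 12) / 12
  x <- structure(list(participants = participants, waves = waves,
                      events = events, provenance = as.character(provenance)),
                 class = "panel_dataset", max_t = as.integer(max_t))
  validate_panel_dataset(x)
  x
}

#' Validate a panel dataset
#'
#' @param x a `panel_dataset`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_panel_dataset <- function(x) {
  stopifnot(inherits(x, "panel_dataset"))
  p <- x$participants; w <- x$waves; e <- x$events
  max_t <- attr(x, "max_t")
  if (anyDuplicated(p$id))
    stop("duplicate participant ids: ",
         paste(unique(p$id[duplicated(p$id)])[1:5], collapse = ", "))
  if (nrow(p) && any(bad <- !is.na(p$age) & p$age < 65))
    stop("baseline age below 65 for id(s): ",
         paste(head(p$id[bad], 5), collapse = ", "))
  if (nrow(p) && any(bad <- !is.na(p$bmi) & (p$bmi <= 10 | p$bmi >= 60)))
    stop("BMI outside (10, 60) for id(s): ",
         paste(head(p$id[bad], 5), collapse = ", "))
  for (nm in c("vol_freq", "hobby_freq", "neigh_freq")) {
    v <- p[[nm]]
    if (!is.null(v) && any(bad <- !is.na(v) & !v %in% .FREQ_LEVELS))
      stop("invalid ", nm, " value(s): ",
           paste(unique(v[bad])[1:5], collapse = ", "))
  }
  if (nrow(w)) {
    if (any(bad <- !w$id %in% p$id))
      stop("wave rows reference unknown id(s): ",
           paste(unique(w$id[bad])[1:5], collapse = ", "))
    if (any(bad <- w$t_months < 0 | w$t_months > max_t))
      stop("wave t_months outside [0, ", max_t, "] for id(s): ",
           paste(unique(w$id[bad])[1:5], collapse = ", "))
    if (any(bad <- !w$state %in% c("nd", "dis")))
      stop("invalid wave state(s): ",
           paste(unique(w$state[bad])[1:5], collapse = ", "))
    o <- order(w$id, w$t_months)
    ws <- w[o, ]
    same <- ws$id[-1L] == ws$id[-nrow(ws)]
    if (any(same & diff(ws$t_months) <= 0))
      stop("wave t_months not strictly increasing for id(s): ",
           paste(unique(ws$id[-1L][same & diff(ws$t_months) <= 0])[1:3],
                 collapse = ", "))
  }
  if (nrow(e)) {
    if (any(bad <- !e$id %in% p$id))
      stop("event rows reference unknown id(s): ",
           paste(unique(e$id[bad])[1:5], collapse = ", "))
    if (any(bad <- !e$kind %in% c("disability_cert", "death", "emigration")))
      stop("invalid event kind(s): ",
           paste(unique(e$kind[bad])[1:5], collapse = ", "))
    if (any(bad <- e$t_months < 0 | e$t_months > max_t))
      stop("event t_months outside [0, ", max_t, "]")
    for (k in c("death", "emigration")) {
      ids <- e$id[e$kind == k]
      if (anyDuplicated(ids))
        stop("more than one ", k, " event for id(s): ",
             paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
    }
    d <- e[e$kind == "death", ]
    if (nrow(d) && nrow(w)) {
      dt <- setNames(d$t_months, d$id)
      m <- dt[w$id]
      if (any(bad <- !is.na(m) & w$t_months >= m))
        stop("observation at or after death month for id(s): ",
             paste(unique(w$id[bad])[1:3], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", nrow(x$participants), "participants,",
      nrow(x$waves), "waves,", nrow(x$events), "events\n")
  if (length(x$provenance))
    cat("provenance:\n", paste(" ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Subset a panel dataset by participant id
#'
#' Keeps the given participants and their waves/events only.
#'
#' @param x a `panel_dataset`.
#' @param ids character vector of participant ids to keep.
#' @param note optional provenance line describing the subset.
#' @return a `panel_dataset`.
#' @export
subset_panel <- function(x, ids, note = NULL) {
  stopifnot(inherits(x, "panel_dataset"))
  out <- x
  out$participants <- x$participants[x$participants$id %in% ids, , drop = FALSE]
  out$waves <- x$waves[x$waves$id %in% ids, , drop = FALSE]
  out$events <- x$events[x$events$id %in% ids, , drop = FALSE]
  if (!is.null(note)) out$provenance <- c(out$provenance, note)
  out
}

# ---- deterministic coding rules ---------------------------------------------

#' Count social-participation activities
#'
#' An activity category (volunteering, hobby activities, neighbourhood
#' associations) is counted as participation whenever its reported frequency
#' is anything other than `"none"` — i.e. "less than once a month" or more
#' already counts.
#'
#' @param vol,hobby,neigh frequency of each category:
#'   `"none"`, `"lt_monthly"`, `"1_3_monthly"`, `"weekly_plus"`, or `NA`.
#' @param id optional participant ids used in error messages.
#' @param strict if `TRUE`, a missing frequency is a coding error naming the
#'   participant; if `FALSE` (default) it yields `NA`, and callers are
#'   expected to exclude such participants (the exposure-missing rule of the
#'   exclusion cascade).
#' @return integer vector of counts 0–3 (`NA` where any item is missing).
#' @examples
#' code_social_participation("none", "none", "none")            # 0
#' code_social_participation("lt_monthly", "none", "weekly_plus") # 2
#' @export
code_social_participation <- function(vol, hobby, neigh, id = NULL,
                                      strict = FALSE) {
  m <- cbind(as.character(vol), as.character(hobby), as.character(neigh))
  bad <- !is.na(m) & !m %in% .FREQ_LEVELS
  if (any(bad))
    stop("invalid activity frequency value(s): ",
         paste(unique(m[bad])[1:5], collapse = ", "))
  miss <- rowSums(is.na(m)) > 0
  if (strict && any(miss)) {
    who <- if (is.null(id)) paste("row", which(miss)[1:5]) else
      head(id[miss], 5)
    stop("missing activity frequency for participant(s): ",
         paste(who, collapse = ", "))
  }
  out <- rowSums(m != "none")
  out[miss] <- NA_integer_
  as.integer(out)
}

#' Score the five-item depression screen
#'
#' Items 1, 2 and 4 score one point for a "yes"; items 3 and 5 score one
#' point for a "no".  A total score of 2 or more classifies the participant
#' as having depression.  Note that the scoring direction is exactly as the
#' instrument prescribes even where it looks counterintuitive (a "yes" to
#' item 1, "Is your life pretty full?", scores toward depression).
#'
#' @param d1,d2,d3,d4,d5 responses, `"yes"`/`"no"`/`NA`.
#' @return data frame with integer `score` (0–5) and logical `depressed`
#'   (`NA` propagates when any item is missing).
#' @examples
#' code_depression("yes", "yes", "yes", "yes", "yes")  # score 3, depressed
#' code_depression("no", "no", "no", "no", "no")       # score 2, depressed
#' @export
code_depression <- function(d1, d2, d3, d4, d5) {
  m <- cbind(as.character(d1), as.character(d2), as.character(d3),
             as.character(d4), as.character(d5))
  bad <- !is.na(m) & !m %in% c("yes", "no")
  if (any(bad))
    stop("depression-screen items must be yes/no/NA, got: ",
         paste(unique(m[bad])[1:5], collapse = ", "))
  pts <- matrix(NA_integer_, nrow(m), 5L)
  for (j in c(1L, 2L, 4L)) pts[, j] <- as.integer(m[, j] == "yes")
  for (j in c(3L, 5L)) pts[, j] <- as.integer(m[, j] == "no")
  score <- as.integer(rowSums(pts))
  data.frame(score = score, depressed = score >= 2L)
}

#' Count non-communicable-disease risk factors
#'
#' The three risks are: current smoking, BMI below 18.5 or at/above 25.0
#' kg/m2 (boundaries strict and inclusive respectively), and walking less
#' than half an hour per day.
#'
#' @param smoking `"never_former"`/`"current"`/`NA`.
#' @param bmi kg/m2 or `NA`.
#' @param walking `"ge_half_hour"`/`"lt_half_hour"`/`NA`.
#' @return data frame with integer `count` (0–3) and factor `stratum` with
#'   levels `"no risk factor"`, `"one risk factor"`,
#'   `"two or three risk factors"` (`NA` when any input is missing).
#' @examples
#' code_ncd_risk("current", 26.0, "lt_half_hour")       # count 3
#' code_ncd_risk("never_former", 18.5, "ge_half_hour")  # count 0 (boundary)
#' @export
code_ncd_risk <- function(smoking, bmi, walking) {
  smoking <- as.character(smoking); walking <- as.character(walking)
  if (any(bad <- !is.na(smoking) & !smoking %in% c("never_former", "current")))
    stop("invalid smoking value(s): ",
         paste(unique(smoking[bad])[1:5], collapse = ", "))
  if (any(bad <- !is.na(walking) &
            !walking %in% c("ge_half_hour", "lt_half_hour")))
    stop("invalid walking value(s): ",
         paste(unique(walking[bad])[1:5], collapse = ", "))
  count <- as.integer((smoking == "current") +
                        (bmi < 18.5 | bmi >= 25.0) +
                        (walking == "lt_half_hour"))
  lev <- c("no risk factor", "one risk factor", "two or three risk factors")
  stratum <- factor(lev[pmin(count, 2L) + 1L], levels = lev)
  data.frame(count = count, stratum = stratum)
}

#' Coded exposure (number of social participations) per participant
#'
#' @param x a `panel_dataset` or a participants data frame.
#' @return integer vector aligned with the participant rows (`NA` when
#'   exposure information is missing).
#' @export
participant_exposure <- function(x) {
  p <- if (inherits(x, "panel_dataset")) x$participants else x
  code_social_participation(p$vol_freq, p$hobby_freq, p$neigh_freq, id = p$id)
}

# ---- exclusion cascade ------------------------------------------------------

#' Apply the baseline exclusion cascade
#'
#' Rules are applied sequentially, in this fixed order, each to the
#' participants remaining after the previous rule:
#' \enumerate{
#'   \item no written consent for review of care-insurance records,
#'   \item disability already certified before the follow-up start,
#'   \item death or emigration before the follow-up start,
#'   \item information about social participation unavailable (any of the
#'     three activity-frequency items missing).
#' }
#' Because the cascade is sequential, each rule's removal count excludes
#' participants already removed upstream — the counts are not marginal
#' totals.
#'
#' @param raw a `panel_dataset` whose participants carry the `consent`,
#'   `prevalent_disability` and `pre_baseline_exit` flags.
#' @return list with elements `dataset` (the filtered `panel_dataset`) and
#'   `accounting` (class `exclusion_accounting`: `n_initial`, `n_final`,
#'   and a data frame of `(rule, n_removed)` in application order).
#' @export
apply_exclusion_cascade <- function(raw) {
  stopifnot(inherits(raw, "panel_dataset"))
  p <- raw$participants
  n_initial <- nrow(p)
  rules <- list(
    no_consent = function(p) !isTRUE_vec(p$consent),
    prevalent_disability = function(p) isTRUE_vec(p$prevalent_disability),
    pre_baseline_exit = function(p) isTRUE_vec(p$pre_baseline_exit),
    missing_social_participation = function(p)
      is.na(code_social_participation(p$vol_freq, p$hobby_freq, p$neigh_freq))
  )
  removed <- integer(length(rules))
  names(removed) <- names(rules)
  for (i in seq_along(rules)) {
    drop <- rules[[i]](p)
    removed[i] <- sum(drop)
    p <- p[!drop, , drop = FALSE]
  }
  acc <- structure(
    list(n_initial = n_initial, n_final = nrow(p),
         rules = data.frame(rule = names(removed), n_removed = unname(removed))),
    class = "exclusion_accounting")
  stopifnot(acc$n_final == acc$n_initial - sum(acc$rules$n_removed))
  ds <- subset_panel(raw, p$id,
                     note = sprintf(
                       "exclusion cascade: %d -> %d (%s)", n_initial, nrow(p),
                       paste(names(removed), removed, sep = "=",
                             collapse = ", ")))
  list(dataset = ds, accounting = acc)
}

# all(x) treating NA as FALSE, elementwise
isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.exclusion_accounting <- function(x, ...) {
  cat("exclusion cascade:", x$n_initial, "->", x$n_final, "\n")
  for (i in seq_len(nrow(x$rules)))
    cat(sprintf("  - %-30s %6d removed\n",
                x$rules$rule[i], x$rules$n_removed[i]))
  invisible(x)
}

# ---- CSV I/O ---------------------------------------------------------------

#' Read a panel dataset from CSV files
#'
#' Expects `participants.csv`, `waves.csv` and `events.csv` (UTF-8, header
#' row) following the documented schema; see [panel_dataset()] for columns.
#' Malformed rows are reported with their line numbers; duplicate
#' participant ids are fatal.
#'
#' @param dir directory containing the three files, or `NULL` if paths are
#'   given explicitly.
#' @param participants,waves,events explicit file paths (override `dir`).
#' @param max_t passed to [panel_dataset()].
#' @return a validated `panel_dataset`.
#' @export
read_panel_csv <- function(dir = NULL, participants = NULL, waves = NULL,
                           events = NULL, max_t = 132L) {
  if (!is.null(dir)) {
    if (is.null(participants)) participants <- file.path(dir, "participants.csv")
    if (is.null(waves)) waves <- file.path(dir, "waves.csv")
    if (is.null(events)) events <- file.path(dir, "events.csv")
  }
  p <- read.csv(participants, stringsAsFactors = FALSE)
  w <- read.csv(waves, stringsAsFactors = FALSE)
  e <- read.csv(events, stringsAsFactors = FALSE)
  .check_columns(p, c("id", "sex", "age", "vol_freq", "hobby_freq",
                      "neigh_freq"), participants)
  .check_columns(w, c("id", "t_months", "state"), waves)
  .check_columns(e, c("id", "kind", "t_months"), events)
  for (col in c("t_months")) {
    bad <- which(is.na(suppressWarnings(as.integer(w[[col]]))))
    if (length(bad))
      stop(waves, ": malformed ", col, " at line(s) ",
           paste(bad + 1L, collapse = ", "))  # +1 for the header row
  }
  bad <- which(!w$state %in% c("nd", "dis"))
  if (length(bad))
    stop(waves, ": invalid state at line(s) ",
         paste(head(bad, 5) + 1L, collapse = ", "))
  bad <- which(w$t_months < 0 | w$t_months > max_t)
  if (length(bad))
    stop(waves, ": t_months outside [0, ", max_t, "] at line(s) ",
         paste(head(bad, 5) + 1L, collapse = ", "))
  bad <- which(!e$kind %in% c("disability_cert", "death", "emigration"))
  if (length(bad))
    stop(events, ": invalid kind at line(s) ",
         paste(head(bad, 5) + 1L, collapse = ", "))
  if (anyDuplicated(p$id))
    stop(participants, ": duplicate participant id(s): ",
         paste(unique(p$id[duplicated(p$id)])[1:5], collapse = ", "))
  for (col in c("hx_htn", "hx_dm", "hx_stroke", "hx_mi", "hx_cancer",
                "consent", "prevalent_disability", "pre_baseline_exit"))
    if (!is.null(p[[col]])) p[[col]] <- as.logical(p[[col]])
  panel_dataset(p, w, e,
                provenance = sprintf("read from %s", participants),
                max_t = max_t)
}

.check_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
}

#' Write a panel dataset to CSV files
#'
#' Writes `participants.csv`, `waves.csv`, `events.csv` in canonical order
#' (participants by id; waves by id then time; events by id, time, kind) so
#' that writing and re-reading a dataset is the identity.
#'
#' @param dataset a `panel_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_panel_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "panel_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- dataset$participants[order(dataset$participants$id), , drop = FALSE]
  p$age <- round(p$age, 6)  # whole months survive a 6-dp decimal round trip
  w <- dataset$waves[order(dataset$waves$id, dataset$waves$t_months), ,
                     drop = FALSE]
  e <- dataset$events[order(dataset$events$id, dataset$events$t_months,
                            dataset$events$kind), , drop = FALSE]
  write.csv(p, file.path(dir, "participants.csv"), row.names = FALSE)
  write.csv(w, file.path(dir, "waves.csv"), row.names = FALSE)
  write.csv(e, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

# ---- descriptive tables -----------------------------------------------------

# final observed status of each participant at the horizon, with precedence
# death > emigration > disabled > non-disabled on shared months
.final_status <- function(dataset, horizon = 132L) {
  p <- dataset$participants
  status <- rep("nondisabled", nrow(p))
  names(status) <- p$id
  w <- dataset$waves[dataset$waves$t_months <= horizon, , drop = FALSE]
  cert <- dataset$events[dataset$events$kind == "disability_cert" &
                           dataset$events$t_months <= horizon, , drop = FALSE]
  rec <- data.frame(id = c(w$id, cert$id),
                    t = c(w$t_months, cert$t_months),
                    dis = c(w$state == "dis", rep(TRUE, nrow(cert))))
  if (nrow(rec)) {
    # latest record wins; a disabled record wins a tie at the same month
    o <- order(rec$id, rec$t, rec$dis)
    rec <- rec[o, ]
    last <- rec[!duplicated(rec$id, fromLast = TRUE), ]
    status[last$id[last$dis]] <- "disabled"
    status[last$id[!last$dis]] <- "nondisabled"
  }
  em <- dataset$events[dataset$events$kind == "emigration" &
                         dataset$events$t_months <= horizon, , drop = FALSE]
  status[em$id] <- "emigrated"
  d <- dataset$events[dataset$events$kind == "death" &
                        dataset$events$t_months <= horizon, , drop = FALSE]
  status[d$id] <- "dead"
  status
}

#' Outcome distribution at the end of follow-up
#'
#' Tabulates counts and percentages of final status (non-disabled, disabled,
#' dead, emigrated) by sex and exposure group, the usual end-of-follow-up
#' descriptive table.  Percentages are of the sex-specific total, so they
#' sum to 100 within each sex across all groups and statuses.
#'
#' @param dataset a `panel_dataset`.
#' @param group_of optional function `participants -> group labels`; the
#'   default groups by the coded number of social participations
#'   ([participant_exposure()]).  Participants with a missing group are
#'   dropped from the table.
#' @param horizon months since follow-up start at which status is read
#'   (default 132).
#' @return data frame with columns `sex`, `group` (including an `"all"`
#'   margin), `status`, `n`, `pct`.  `pct` is kept at full precision;
#'   round at display time.
#' @export
outcome_distribution_table <- function(dataset, group_of = NULL,
                                       horizon = 132L) {
  stopifnot(inherits(dataset, "panel_dataset"))
  if (horizon > attr(dataset, "max_t"))
    stop("horizon beyond the dataset's follow-up")
  p <- dataset$participants
  grp <- if (is.null(group_of)) participant_exposure(dataset) else group_of(p)
  status <- .final_status(dataset, horizon)[p$id]
  keep <- !is.na(grp)
  p <- p[keep, , drop = FALSE]; grp <- grp[keep]; status <- status[keep]
  statuses <- c("nondisabled", "disabled", "dead", "emigrated")
  glev <- if (is.factor(grp)) levels(grp) else sort(unique(grp))
  out <- expand.grid(sex = c("male", "female"),
                     group = c(as.character(glev), "all"),
                     status = statuses, stringsAsFactors = FALSE)
  out$n <- mapply(function(s, g, st) {
    in_g <- if (g == "all") TRUE else as.character(grp) == g
    sum(p$sex == s & in_g & status == st)
  }, out$sex, out$group, out$status)
  sex_tot <- vapply(c(male = "male", female = "female"),
                    function(s) sum(p$sex == s), numeric(1))
  out$pct <- 100 * out$n / sex_tot[out$sex]
  out$pct[sex_tot[out$sex] == 0] <- NA_real_
  out[order(match(out$sex, c("male", "female")),
            match(out$group, c(as.character(glev), "all")),
            match(out$status, statuses)), , drop = FALSE]
}

#' Baseline characteristics by exposure group
#'
#' Means (SD) and percentages of the baseline covariates per exposure
#' group: n, age, % men, BMI, % current smokers, % walking under half an
#' hour a day, % depression, and disease-history percentages.  Each summary
#' uses the participants non-missing on that covariate; an empty group
#' yields a column of `NA` without error.
#'
#' @inheritParams outcome_distribution_table
#' @return data frame with one row per characteristic and one column per
#'   group; values at full precision.
#' @export
baseline_characteristics_table <- function(dataset, group_of = NULL) {
  stopifnot(inherits(dataset, "panel_dataset"))
  p <- dataset$participants
  grp <- if (is.null(group_of)) participant_exposure(dataset) else group_of(p)
  keep <- !is.na(grp)
  glev <- if (is.factor(grp)) levels(grp) else sort(unique(grp[keep]))
  p <- p[keep, , drop = FALSE]; grp <- as.character(grp[keep])
  glev <- as.character(glev)
  dep <- code_depression(p$dss1, p$dss2, p$dss3, p$dss4, p$dss5)$depressed
  pct <- function(x) if (all(is.na(x))) NA_real_ else
    100 * mean(x, na.rm = TRUE)
  mn <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  s  <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE)
  one_group <- function(g) {
    i <- grp == g
    if (!any(i)) return(rep(NA_real_, 14))
    q <- p[i, , drop = FALSE]
    c(n = sum(i),
      age_mean = mn(q$age), age_sd = s(q$age),
      men_pct = pct(q$sex == "male"),
      bmi_mean = mn(q$bmi), bmi_sd = s(q$bmi),
      current_smoker_pct = pct(q$smoking == "current"),
      walking_lt_half_pct = pct(q$walking == "lt_half_hour"),
      depression_pct = pct(dep[i]),
      hx_htn_pct = pct(q$hx_htn), hx_dm_pct = pct(q$hx_dm),
      hx_stroke_pct = pct(q$hx_stroke), hx_mi_pct = pct(q$hx_mi),
      hx_cancer_pct = pct(q$hx_cancer))
  }
  cols <- lapply(glev, one_group)
  out <- as.data.frame(cols)
  names(out) <- paste0("group_", glev)
  rn <- c("n", "age_mean", "age_sd", "men_pct", "bmi_mean", "bmi_sd",
          "current_smoker_pct", "walking_lt_half_pct", "depression_pct",
          "hx_htn_pct", "hx_dm_pct", "hx_stroke_pct", "hx_mi_pct",
          "hx_cancer_pct")
  data.frame(characteristic = rn, out, row.names = NULL)
}

#' Build a panel dataset from an outcome count table
#'
#' Reconstructs a minimal panel consistent with a published end-of-follow-up
#' distribution: for each (sex, group, status) cell it creates the stated
#' number of participants whose records realise that final status.  Useful
#' for checking table arithmetic against printed counts.
#'
#' @param counts data frame with columns `sex` (`"male"`/`"female"`),
#'   `group` (0–3), `status` (`"nondisabled"`/`"disabled"`/`"dead"`/
#'   `"emigrated"`), `n`.
#' @param horizon follow-up end in months (default 132).
#' @return a `panel_dataset` whose [outcome_distribution_table()] reproduces
#'   `counts`.
#' @export
panel_from_outcome_counts <- function(counts, horizon = 132L) {
  stopifnot(all(c("sex", "group", "status", "n") %in% names(counts)))
  counts <- counts[counts$n > 0, , drop = FALSE]
  n_tot <- sum(counts$n)
  id <- sprintf("C%06d", seq_len(n_tot))
  sex <- rep(counts$sex, counts$n)
  grp <- rep(counts$group, counts$n)
  status <- rep(counts$status, counts$n)
  freq <- function(active) ifelse(active, "weekly_plus", "none")
  p <- data.frame(
    id = id, sex = sex, age = 72,
    vol_freq = freq(grp >= 1), hobby_freq = freq(grp >= 2),
    neigh_freq = freq(grp >= 3),
    smoking = "never_former", bmi = 23, walking = "ge_half_hour",
    dss1 = "no", dss2 = "no", dss3 = "yes", dss4 = "no", dss5 = "yes",
    hx_htn = FALSE, hx_dm = FALSE, hx_stroke = FALSE, hx_mi = FALSE,
    hx_cancer = FALSE, consent = TRUE, prevalent_disability = FALSE,
    pre_baseline_exit = FALSE, stringsAsFactors = FALSE)
  waves <- data.frame(id = id, t_months = 0L, state = "nd")
  late <- status %in% c("nondisabled", "disabled")
  waves <- rbind(waves,
                 data.frame(id = id[late], t_months = as.integer(horizon),
                            state = ifelse(status[late] == "disabled",
                                           "dis", "nd")))
  mid <- as.integer(horizon %/% 2)
  events <- rbind(
    data.frame(id = id[status == "dead"], kind = "death", t_months = mid),
    data.frame(id = id[status == "emigrated"], kind = "emigration",
               t_months = mid))
  panel_dataset(p, waves, events,
                provenance = "reconstructed from an outcome count table",
                max_t = as.integer(horizon))
}
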