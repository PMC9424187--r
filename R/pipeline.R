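#' Configure a full analysis run
#'
#' @param input either a `panel_dataset`, a directory of panel CSVs, or a
#'   `simulation_config` (the cohort is then generated).
#' @param index_age,x_max,h life-table grid (years); defaults 65, 115,
#'   1/12.
#' @param B bootstrap draws per cell (0 disables confidence intervals).
#' @param seed integer seed governing the bootstrap (and generation when
#'   `input` is a `simulation_config` without its own seed).
#' @param min_support minimum directly observed transitions for a
#'   transition to be fitted in a cell (default 10; sparser cells drop the
#'   transition with a logged sentinel).
#' @param stratifiers which of the five stratified analyses
#'   [run_full_study()] performs.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(input, index_age = 65, x_max = 115, h = 1 / 12,
                            B = 1000L, seed = 1L, min_support = 10L,
                            stratifiers = c("smoking", "bmi", "walking",
                                            "depression", "ncd_risk")) {
  stopifnot(index_age < x_max, B >= 0)
  stratifiers <- match.arg(stratifiers, several.ok = TRUE)
  structure(list(input = input, index_age = index_age, x_max = x_max,
                 h = h, B = as.integer(B), seed = as.integer(seed),
                 min_support = as.integer(min_support),
                 stratifiers = stratifiers),
            class = "analysis_config")
}

.resolve_input <- function(config) {
  input <- config$input
  if (inherits(input, "panel_dataset")) return(input)
  if (inherits(input, "simulation_config")) return(generate_dataset(input))
  if (is.character(input) && dir.exists(input)) return(read_panel_csv(input))
  stop("analysis input must be a panel_dataset, a simulation_config, or a ",
       "directory of panel CSVs")
}

# Fit + expectancies + optional bootstrap for one cell; returns a one-row
# data frame.  A failed or empty cell is flagged, never fatal.
.dfle_cell <- function(dataset, sex, group, group_of, config, cell_seed) {
  na_row <- function(fit, n) data.frame(
    sex = sex, group = as.character(group), n = n,
    converged = FALSE, dfle = NA_real_, dfle_lo = NA_real_,
    dfle_hi = NA_real_, duration = NA_real_, duration_lo = NA_real_,
    duration_hi = NA_real_, tle = NA_real_, tle_lo = NA_real_,
    tle_hi = NA_real_, stringsAsFactors = FALSE)
  # cell-level numerical warnings (singular information in sparse cells,
  # material closure truncation of a poor fit) are summarised by the
  # converged flag and NA intervals rather than surfaced one by one
  fit <- tryCatch(
    suppressWarnings(
      fit_transitions(dataset, sex = sex, group = group,
                      group_of = group_of,
                      min_support = config$min_support)),
    error = function(e) NULL)
  if (is.null(fit) || !isTRUE(fit$converged))
    return(na_row(fit, if (is.null(fit)) 0L else fit$n_subjects))
  na_ci <- matrix(NA_real_, 3, 2,
                  dimnames = list(c("dfle", "duration_disabled", "tle"),
                                  c("lo", "hi")))
  if (config$B > 0) {
    lt <- tryCatch(
      suppressWarnings(
        bootstrap_ci(fit, B = config$B, seed = cell_seed,
                     x0 = config$index_age, x_max = config$x_max,
                     h = config$h)),
      error = function(e) NULL)
    if (is.null(lt)) {
      lt <- suppressWarnings(
        expectancies(fit$params, x0 = config$index_age,
                     x_max = config$x_max, h = config$h))
      ci <- na_ci
    } else ci <- lt$ci
  } else {
    lt <- suppressWarnings(
      expectancies(fit$params, x0 = config$index_age,
                   x_max = config$x_max, h = config$h))
    ci <- na_ci
  }
  data.frame(
    sex = sex, group = as.character(group), n = fit$n_subjects,
    converged = TRUE,
    dfle = lt$dfle, dfle_lo = ci["dfle", "lo"], dfle_hi = ci["dfle", "hi"],
    duration = lt$duration_disabled,
    duration_lo = ci["duration_disabled", "lo"],
    duration_hi = ci["duration_disabled", "hi"],
    tle = lt$tle, tle_lo = ci["tle", "lo"], tle_hi = ci["tle", "hi"],
    stringsAsFactors = FALSE)
}

#' DFLE table by sex and number of social participations
#'
#' Fits the transition model separately in each of the 8 sex-by-group
#' cells (stratified maximum likelihood, the grouping itself being the
#' exposure contrast), computes the life-table triple at the index age,
#' and attaches percentile-bootstrap confidence intervals.
#'
#' @param dataset a `panel_dataset`.
#' @param config an `analysis_config`.
#' @return data frame with one row per sex x group and columns
#'   `n`, `converged`, `dfle`, `duration`, `tle` and their `_lo`/`_hi`
#'   bounds (`NA` when `B = 0` or the cell failed).
#' @export
run_count_exposure_analysis <- function(dataset, config) {
  stopifnot(inherits(dataset, "panel_dataset"),
            inherits(config, "analysis_config"))
  rows <- list(); k <- 0L
  for (s in c("male", "female")) for (g in 0:3) {
    k <- k + 1L
    rows[[k]] <- .dfle_cell(dataset, s, g, NULL, config,
                            cell_seed = config$seed + 101L * k)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DFLE table by activity type and participation frequency
#'
#' Re-groups the cohort, separately for each activity category
#' (volunteering, hobby activities, neighbourhood associations), by the
#' four-level participation frequency, and runs the same per-cell
#' machinery: 2 sexes x 3 activities x 4 frequency levels.
#'
#' @inheritParams run_count_exposure_analysis
#' @return data frame as in [run_count_exposure_analysis()] with an extra
#'   leading `activity` column; `group` holds the frequency level.
#' @export
run_frequency_exposure_analysis <- function(dataset, config) {
  stopifnot(inherits(dataset, "panel_dataset"),
            inherits(config, "analysis_config"))
  acts <- c(volunteering = "vol_freq", hobby = "hobby_freq",
            neighborhood = "neigh_freq")
  rows <- list(); k <- 0L
  for (a in names(acts)) {
    col <- acts[[a]]
    group_of <- local({
      col <- col
      function(p) factor(p[[col]], levels = .FREQ_LEVELS)
    })
    for (s in c("male", "female")) for (f in .FREQ_LEVELS) {
      k <- k + 1L
      cell <- .dfle_cell(dataset, s, f, group_of, config,
                         cell_seed = config$seed + 977L * k)
      cell <- cbind(activity = a, cell)
      rows[[k]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# stratum labels per participant for each of the five stratifiers;
# NA = stratifier missing for that participant
.stratum_of <- function(p, stratifier) {
  switch(
    stratifier,
    smoking = ifelse(is.na(p$smoking), NA,
                     ifelse(p$smoking == "current", "current",
                            "never/former")),
    bmi = ifelse(is.na(p$bmi), NA,
                 ifelse(p$bmi < 18.5 | p$bmi >= 25.0,
                        "BMI <18.5 or >=25.0", "BMI 18.5 to <25")),
    walking = ifelse(is.na(p$walking), NA,
                     ifelse(p$walking == "lt_half_hour",
                            "walking <0.5 h/d", "walking >=0.5 h/d")),
    depression = {
      d <- code_depression(p$dss1, p$dss2, p$dss3, p$dss4, p$dss5)$depressed
      ifelse(is.na(d), NA, ifelse(d, "depression", "free of depression"))
    },
    ncd_risk = as.character(code_ncd_risk(p$smoking, p$bmi,
                                          p$walking)$stratum),
    stop("unknown stratifier: ", stratifier))
}

#' Stratified DFLE analysis
#'
#' Refits the transition models within each stratum of one of the five
#' stratifiers (smoking status, BMI category, walking time, depression,
#' number of non-communicable-disease risks) crossed with sex and exposure
#' group.  Stratification is the confounding control here: the transition
#' model itself carries no covariates.  Participants missing the
#' stratifier are dropped from this run only, with the count logged in the
#' result's `dropped_missing` attribute.
#'
#' @inheritParams run_count_exposure_analysis
#' @param stratifier one of `"smoking"`, `"bmi"`, `"walking"`,
#'   `"depression"`, `"ncd_risk"`.
#' @return data frame as in [run_count_exposure_analysis()] with a leading
#'   `stratum` column; attribute `dropped_missing` records how many
#'   participants lacked the stratifier.
#' @export
run_stratified_analysis <- function(dataset, stratifier, config) {
  stopifnot(inherits(dataset, "panel_dataset"),
            inherits(config, "analysis_config"))
  p <- dataset$participants
  strat <- .stratum_of(p, stratifier)
  n_missing <- sum(is.na(strat))
  if (n_missing)
    message(stratifier, ": dropping ", n_missing,
            " participant(s) with missing stratifier")
  rows <- list(); k <- 0L
  for (lev in sort(unique(strat[!is.na(strat)]))) {
    sub <- subset_panel(dataset, p$id[!is.na(strat) & strat == lev],
                        note = sprintf("stratum %s = %s", stratifier, lev))
    tab <- run_count_exposure_analysis(sub, config)
    rows[[k <- k + 1L]] <- cbind(stratum = lev, tab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped_missing") <- n_missing
  out
}

#' Run the complete study replica
#'
#' Exclusion cascade, baseline and outcome tables, the DFLE analysis by
#' number of social participations, the analysis by per-activity
#' frequency, and the configured stratified analyses, bundled with run
#' metadata.
#'
#' @param config an `analysis_config`.
#' @return list of class `study_report`: `accounting`, `baseline_table`,
#'   `outcome_table`, `dfle_by_count`, `dfle_by_frequency`,
#'   `dfle_stratified` (named list), `meta`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  raw <- .resolve_input(config)
  casc <- apply_exclusion_cascade(raw)
  ds <- casc$dataset
  strat <- lapply(setNames(nm = config$stratifiers), function(s)
    run_stratified_analysis(ds, s, config))
  structure(list(
    accounting = casc$accounting,
    baseline_table = baseline_characteristics_table(ds),
    outcome_table = outcome_distribution_table(
      ds, horizon = attr(ds, "max_t")),
    dfle_by_count = run_count_exposure_analysis(ds, config),
    dfle_by_frequency = run_frequency_exposure_analysis(ds, config),
    dfle_stratified = strat,
    meta = list(
      n_analyzed = nrow(ds$participants),
      seed = config$seed, B = config$B,
      index_age = config$index_age, x_max = config$x_max, h = config$h,
      provenance = ds$provenance,
      package_version = as.character(utils::packageVersion("healthspan")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (n analysed =", x$meta$n_analyzed, ")\n")
  print(x$accounting)
  cat("\nDFLE by number of social participations:\n")
  tab <- x$dfle_by_count
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], 1)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Render a study report to CSV and JSON files
#'
#' Writes each table as CSV and the whole report (tables plus metadata) as
#' a single JSON document.  Rendered tables round years to 0.1 and
#' percentages to one decimal (half-up); the returned report object keeps
#' full precision.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
render_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  disp <- function(df, d = 1) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
    df[num] <- lapply(df[num], round_half_up, d = d)
    df
  }
  write.csv(cbind(rule = c("initial", report$accounting$rules$rule, "final"),
                  n = c(report$accounting$n_initial,
                        -report$accounting$rules$n_removed,
                        report$accounting$n_final)),
            file.path(dir, "exclusion_accounting.csv"), row.names = FALSE)
  write.csv(disp(report$baseline_table),
            file.path(dir, "baseline_characteristics.csv"),
            row.names = FALSE)
  write.csv(disp(report$outcome_table),
            file.path(dir, "outcome_distribution.csv"), row.names = FALSE)
  write.csv(disp(report$dfle_by_count),
            file.path(dir, "dfle_by_count.csv"), row.names = FALSE)
  write.csv(disp(report$dfle_by_frequency),
            file.path(dir, "dfle_by_frequency.csv"), row.names = FALSE)
  for (s in names(report$dfle_stratified))
    write.csv(disp(report$dfle_stratified[[s]]),
              file.path(dir, sprintf("dfle_stratified_%s.csv", s)),
              row.names = FALSE)
  payload <- report
  payload$accounting <- list(n_initial = report$accounting$n_initial,
                             n_final = report$accounting$n_final,
                             rules = report$accounting$rules)
  class(payload) <- NULL
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(dir)
}
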