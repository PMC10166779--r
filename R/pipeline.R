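# End-to-end orchestration: validate -> score -> incidence -> survival ->
# mortality / onset / deaths, with a long-format CSV output bundle and a
# run log.  All outputs are deterministic given the inputs and config.

#' Configure a pipeline run
#'
#' @param carriers,events Paths to `carriers.csv` / `events.csv`
#'   (`events` may be `NULL`), or pass a `cohort` instead.
#' @param cohort A `lynch_cohort`, alternative to the CSV paths.
#' @param out_dir Output directory for the CSV bundle; `NULL` to skip
#'   writing.
#' @param organ_sets List of organ sets to analyse; default every core
#'   Lynch-syndrome organ individually plus the colorectal, gynaecological
#'   and all-LS-cancer groups.
#' @param by Stratification columns, default `c("gene", "sex")`.
#' @param grid Age-band grid, default [age_bands()] (25-75 by 5).
#' @param age_cap Diagnosis age cap for post-cancer survival (default 65).
#' @param horizon Survival readout horizon in years (default 10).
#' @param on_invalid Validation mode, `"stop"` or `"skip"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(carriers = NULL, events = NULL, cohort = NULL,
                            out_dir = NULL, organ_sets = NULL,
                            by = c("gene", "sex"), grid = age_bands(),
                            age_cap = 65, horizon = 10,
                            on_invalid = c("stop", "skip")) {
  if (is.null(cohort) && is.null(carriers)) {
    stop("supply either a cohort or a carriers CSV path")
  }
  stopifnot(horizon > 0, nrow(grid) >= 1)
  if (is.null(organ_sets)) {
    organ_sets <- c(as.list(ls_organs()), unname(organ_groups()))
  }
  structure(list(carriers = carriers, events = events, cohort = cohort,
                 out_dir = out_dir, organ_sets = organ_sets, by = by,
                 grid = grid, age_cap = age_cap, horizon = horizon,
                 on_invalid = match.arg(on_invalid)),
            class = "pipeline_config")
}

#' Run the full estimation pipeline
#'
#' Executes validate, score, incidence, survival, mortality, onset and death
#' tabulation, optionally writing the CSV bundle (`incidence_table.csv`,
#' `cumulative_incidence.csv`, `survival.csv`, `survival_readouts.csv`,
#' `mortality.csv`, `onset.csv`, `deaths.csv`) and a `run_log.txt` with the
#' cohort summary.  Mortality combines the stratified cumulative incidence
#' at 65 for each single organ with that organ's gene-pooled 10-year
#' survival.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of class `lynch_report` with elements
#'   `cohort`, `summary`, `incidence`, `cuminc`, `survival` (curves),
#'   `survival_readouts`, `mortality`, `onset`, `deaths`, `death_shares`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$cohort)) config$cohort else
    read_cohort(config$carriers, config$events)
  cohort <- validate_cohort(cohort, on_invalid = config$on_invalid)
  cohort <- score_prospective_events(cohort)
  summ <- cohort_summary(cohort)

  tab <- incidence_table(cohort, config$organ_sets, by = config$by,
                         grid = config$grid)
  curves <- cumulative_incidence(tab)
  g1 <- max(config$grid$upper)

  # gene-pooled survival per single organ with any prospective events
  single <- vapply(config$organ_sets, function(x) {
    length(as_organ_group(x)$members) == 1L
  }, logical(1))
  organs1 <- vapply(config$organ_sets[single], function(x) {
    as_organ_group(x)$members
  }, character(1))
  sv <- lapply(organs1, function(o) {
    survival_after_cancer(cohort, o, age_cap = config$age_cap,
                          horizon = config$horizon)
  })
  names(sv) <- organs1
  surv_curves <- do.call(rbind, c(lapply(sv, `[[`, "curve"),
                                  make.row.names = FALSE))
  surv_reads <- do.call(rbind, c(lapply(sv, `[[`, "readouts"),
                                 make.row.names = FALSE))
  if (any(is.na(surv_reads$s10))) {
    warning("empty post-cancer risk set for organ(s): ",
            paste(surv_reads$organ[is.na(surv_reads$s10)], collapse = ", "),
            "; survival readouts flagged NA")
  }

  # mortality at 75 per (organ, stratum): stratified Q65, pooled S10
  q65 <- curves[curves$age == 65 & curves$set %in% organs1, , drop = FALSE]
  s10 <- surv_reads$s10[match(q65$set, surv_reads$organ)]
  mort <- q65[c("set", config$by)]
  names(mort)[1] <- "organ"
  mort$q65 <- q65$Q
  mort$s10 <- s10
  mort$m75 <- ifelse(is.na(s10), NA_real_, q65$Q * (1 - s10))
  mort$m75_pct <- round_half_away(100 * mort$m75)

  onset <- median_onset(curves)
  deaths <- death_table(cohort)
  shares <- suppressWarnings(
    death_shares(deaths, groups = list(colorectal = c("colon", "rectum"),
                                       gynaecological = c("endometrium",
                                                          "ovary"))))

  report <- structure(list(cohort = cohort, summary = summ, incidence = tab,
                           cuminc = curves, survival = surv_curves,
                           survival_readouts = surv_reads, mortality = mort,
                           onset = onset, deaths = deaths,
                           death_shares = shares),
                      class = "lynch_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) {
      write.csv(as.data.frame(x), file.path(config$out_dir, f),
                row.names = FALSE)
    }
    wr(tab, "incidence_table.csv")
    wr(curves, "cumulative_incidence.csv")
    wr(surv_curves, "survival.csv")
    wr(surv_reads, "survival_readouts.csv")
    wr(mort, "mortality.csv")
    wr(onset, "onset.csv")
    wr(deaths, "deaths.csv")
    log <- c(
      paste0("lynchrisk ", as.character(utils::packageVersion("lynchrisk")),
             " / R ", R.version$major, ".", R.version$minor),
      sprintf("carriers: %d", summ$n_carriers),
      sprintf("by gene: %s", paste(names(summ$n_by_gene),
                                   as.integer(summ$n_by_gene),
                                   sep = "=", collapse = ", ")),
      sprintf("by sex: %s", paste(names(summ$n_by_sex),
                                  as.integer(summ$n_by_sex),
                                  sep = "=", collapse = ", ")),
      sprintf("observation years: %.2f", summ$observation_years),
      sprintf("mean follow-up: %.2f", summ$mean_follow_up),
      sprintf("prospective first cancers: %d (LS organs: %d)",
              summ$n_prospective_cancers, summ$n_ls_cancers),
      sprintf("age grid: %d-%d; survival age cap: %s; horizon: %s years",
              min(config$grid$lower), g1, config$age_cap, config$horizon)
    )
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(report)
}

#' @export
print.lynch_report <- function(x, ...) {
  cat("<lynch_report>\n")
  print(x$summary)
  cat("  incidence strata:", length(unique(x$incidence$set)),
      "organ sets\n")
  cat("  mortality rows:", nrow(x$mortality), "\n")
  invisible(x)
}
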