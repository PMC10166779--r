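# Crude overall survival after a first prospective cancer, estimated with
# the Nelson-Aalen cumulative hazard of death from any cause.
#
# The time origin is the age at diagnosis; the event is death from any cause
# (including synchronous and metachronous cancers); carriers alive at last
# observation are censored there.  Carriers with a later cancer in another
# organ remain in the risk set (crude, not cause-specific, survival).

# Nelson-Aalen fit on (time, status) with deaths processed before
# censorings at tied times, so a subject censored at t is still at risk for
# a death at t.
na_fit <- function(time, status, conf_level = 0.95) {
  stopifnot(length(time) == length(status), all(time >= 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  dt <- sort(unique(time[status == 1]))
  n_risk <- vapply(dt, function(t) sum(time >= t), numeric(1))
  d <- vapply(dt, function(t) sum(time == t & status == 1), numeric(1))
  H <- cumsum(d / n_risk)
  V <- cumsum(d / n_risk^2)
  f <- exp(z * sqrt(V) / H)
  data.frame(
    time = c(0, dt),
    n_risk = c(length(time), n_risk),
    n_event = c(0, d),
    H = c(0, H),
    var_H = c(0, V),
    surv = exp(-c(0, H)),
    ci_low = c(1, exp(-H * f)),
    ci_high = c(1, exp(-H / f))
  )
}

# Step-function lookup: last value at or before t (last value carried
# forward between death times).
na_step <- function(fit, t) {
  i <- findInterval(t, fit$time)
  list(surv = fit$surv[i], var_H = fit$var_H[i], H = fit$H[i])
}

#' Crude survival after a first prospective cancer
#'
#' Estimates overall (all-cause) survival after the first scored prospective
#' cancer in `organ` diagnosed before `age_cap`, using the Nelson-Aalen
#' cumulative death hazard: `S(t) = exp(-H(t))`.  Vital status is
#' categorised at last observation for all carriers.  The 95% interval uses
#' a log-normal interval on the hazard mapped through `exp(-.)`, matching
#' the incidence module.  Readouts `S5`/`S10` are the step-function values
#' at 5 and 10 years, with delta-method standard errors
#' (`se = S * sqrt(var H)`).
#'
#' @param cohort A `lynch_cohort`.
#' @param organ A single organ code.
#' @param age_cap Only diagnoses before this age enter the risk set
#'   (default 65 years).
#' @param by_gene If `TRUE`, fit one curve per gene; otherwise pool genes.
#' @param horizon Maximum readout time in years (default 10).
#' @param conf_level Confidence level for the curve (default 0.95).
#' @param adjust Optional function applied to the risk-set data frame
#'   (columns `carrier_id`, `gene`, `age_dx`, `time`, `status`) before
#'   estimation; extension hook for diagnosis-adjustment schemes such as
#'   corrections for surveillance overdiagnosis.  Default `NULL` (no
#'   adjustment).
#' @return A list of class `lynch_survival` with elements `curve` (long
#'   data frame: `organ`, `stratum`, `time`, `n_risk`, `n_event`, `H`,
#'   `var_H`, `surv`, `ci_low`, `ci_high`) and `readouts` (one row per
#'   stratum: `n`, `n_deaths`, `s5`, `s10`, `se_s5`, `se_s10`).  An empty
#'   risk set yields `NA` readouts and an empty curve.
#' @export
survival_after_cancer <- function(cohort, organ, age_cap = 65,
                                  by_gene = FALSE, horizon = 10,
                                  conf_level = 0.95, adjust = NULL) {
  cohort <- score_prospective_events(cohort)
  organ <- canon_vocab(organ, .ORGANS, "organ")
  stopifnot(length(organ) == 1L, horizon > 0)
  ca <- cohort$carriers
  ev <- cohort$events
  pro <- ev[ev$timing == "prospective" & ev$organ == organ &
              ev$age_dx < age_cap, , drop = FALSE]
  i <- match(pro$carrier_id, ca$carrier_id)
  rs <- data.frame(
    carrier_id = pro$carrier_id,
    gene = ca$gene[i],
    age_dx = pro$age_dx,
    time = ca$age_last_obs[i] - pro$age_dx,
    status = as.integer(ca$vital_status[i] == "dead")
  )
  if (!is.null(adjust)) rs <- adjust(rs)

  strata <- if (by_gene) split(rs, factor(rs$gene, levels = .GENES)) else
    list(all = rs)
  curves <- list()
  reads <- list()
  for (nm in names(strata)) {
    s <- strata[[nm]]
    if (nrow(s) == 0L) {
      reads[[nm]] <- data.frame(organ = organ, stratum = nm, n = 0L,
                                n_deaths = 0L, s5 = NA_real_, s10 = NA_real_,
                                se_s5 = NA_real_, se_s10 = NA_real_)
      next
    }
    fit <- na_fit(s$time, s$status, conf_level)
    curves[[nm]] <- cbind(organ = organ, stratum = nm, fit)
    r5 <- na_step(fit, min(5, horizon))
    r10 <- na_step(fit, horizon)
    reads[[nm]] <- data.frame(
      organ = organ, stratum = nm, n = nrow(s), n_deaths = sum(s$status),
      s5 = r5$surv, s10 = r10$surv,
      se_s5 = r5$surv * sqrt(r5$var_H), se_s10 = r10$surv * sqrt(r10$var_H)
    )
  }
  curve <- if (length(curves)) do.call(rbind, curves) else
    data.frame(organ = character(), stratum = character(), time = numeric(),
               n_risk = numeric(), n_event = numeric(), H = numeric(),
               var_H = numeric(), surv = numeric(), ci_low = numeric(),
               ci_high = numeric())
  rownames(curve) <- NULL
  readouts <- do.call(rbind, reads)
  rownames(readouts) <- NULL
  structure(list(curve = curve, readouts = readouts, organ = organ,
                 age_cap = age_cap, horizon = horizon),
            class = "lynch_survival")
}

#' @export
print.lynch_survival <- function(x, ...) {
  cat("<lynch_survival> after", x$organ, "cancer diagnosed before age",
      x$age_cap, "\n")
  print(x$readouts, row.names = FALSE)
  invisible(x)
}
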