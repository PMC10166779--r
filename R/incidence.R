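# Person-year attribution, annual incidence rates in five-year age bands,
# and Nelson-Aalen cumulative incidence with Poisson-based confidence
# intervals.
#
# Risk time is left-truncated at inclusion: a carrier contributes from
# max(age_inclusion, 25) to min(first scored event in the organ set,
# age_last_obs, 75), split exactly (fractional years) across half-open bands
# [lower, upper).  An event at exactly age 75 falls outside the grid and is
# not counted.

#' Five-year age-band grid
#'
#' The standard grid tiles `[25, 75)` in half-open five-year bands
#' `[25,30), [30,35), ..., [70,75)`.
#'
#' @param start,end Grid limits in years.
#' @param width Band width in years.
#' @return Data frame with columns `lower` and `upper`.
#' @export
age_bands <- function(start = 25, end = 75, width = 5) {
  stopifnot(end > start, width > 0)
  lower <- seq(start, end - width, by = width)
  data.frame(lower = lower, upper = lower + width)
}

#' Person-years at risk per age band
#'
#' Attributes each carrier's observation time for an organ set to the age
#' bands of `grid`.  Carriers ineligible for the set (previous or prevalent
#' cancer in a member organ) contribute all-zero rows.  The scored event, if
#' any, is credited to the band containing its age when it is the stopping
#' cause and occurs before the grid end.
#'
#' @param cohort A `lynch_cohort` (scored on the fly if needed).
#' @param organ_set An [organ_group()] or character vector of organ codes.
#' @param grid Age-band grid from [age_bands()].
#' @return Long data frame: `carrier_id`, `lower`, `upper`, `person_years`,
#'   `event` (0/1).
#' @export
#' @examples
#' ca <- data.frame(carrier_id = "a", gene = "MLH1", sex = "F",
#'                  age_inclusion = 40, age_last_obs = 52,
#'                  vital_status = "alive")
#' py <- person_years(as_lynch_cohort(ca), "colon")
#' py[py$person_years > 0, ]
person_years <- function(cohort, organ_set, grid = age_bands()) {
  cohort <- score_prospective_events(cohort)
  os <- as_organ_group(organ_set)
  ca <- cohort$carriers
  ev <- cohort$events
  n <- nrow(ca)
  nb <- nrow(grid)
  g0 <- min(grid$lower)
  g1 <- max(grid$upper)

  elig <- ca$carrier_id %in% eligible_carriers(cohort, os)
  pro <- ev[ev$timing == "prospective" & ev$organ %in% os$members, ,
            drop = FALSE]
  evage <- rep(Inf, n)
  if (nrow(pro)) {
    first <- tapply(pro$age_dx, pro$carrier_id, min)
    hit <- match(ca$carrier_id, names(first))
    evage[!is.na(hit)] <- unname(first[hit[!is.na(hit)]])
  }
  entry <- pmax(ca$age_inclusion, g0)
  stop_at <- pmin(evage, ca$age_last_obs, g1)
  entry[!elig] <- 0
  stop_at[!elig] <- 0

  lo <- matrix(grid$lower, n, nb, byrow = TRUE)
  hi <- matrix(grid$upper, n, nb, byrow = TRUE)
  em <- matrix(entry, n, nb)
  sm <- matrix(stop_at, n, nb)
  py <- pmax(0, pmin(sm, hi) - pmax(em, lo))
  dim(py) <- c(n, nb)

  has_event <- elig & is.finite(evage) & evage < g1
  evband <- findInterval(evage, c(grid$lower, g1))
  event <- matrix(0L, n, nb)
  idx <- which(has_event)
  event[cbind(idx, evband[idx])] <- 1L

  data.frame(
    carrier_id = rep(ca$carrier_id, each = nb),
    lower = rep(grid$lower, times = n),
    upper = rep(grid$upper, times = n),
    person_years = as.vector(t(py)),
    event = as.vector(t(event))
  )
}

#' Annual incidence rates in five-year cohorts
#'
#' Sums person-years and scored events per stratum (organ set crossed with
#' the `by` columns of the carrier table, typically gene and sex) and age
#' band, and computes the annual incidence rate AIR = events / person-years
#' (per person-year; `NA` where person-years are zero).
#'
#' @param cohort A `lynch_cohort`.
#' @param organ_sets A single organ set or a list of them (organ codes,
#'   character vectors or [organ_group()]s).
#' @param by Carrier columns defining strata; default `c("gene", "sex")`.
#'   Use `character()` for a pooled table.  Strata of a sex incompatible
#'   with every member organ are dropped (e.g. males for endometrium).
#' @param grid Age-band grid from [age_bands()].
#' @return Data frame of class `incidence_table`: `set`, `by` columns,
#'   `lower`, `upper`, `person_years`, `events`, `air`.
#' @export
incidence_table <- function(cohort, organ_sets, by = c("gene", "sex"),
                            grid = age_bands()) {
  cohort <- score_prospective_events(cohort)
  if (inherits(organ_sets, "organ_group") || is.character(organ_sets)) {
    organ_sets <- list(organ_sets)
  }
  sets <- lapply(organ_sets, as_organ_group)
  stopifnot(all(by %in% c("gene", "sex")))
  ca <- cohort$carriers

  empty <- function() {
    out <- data.frame(set = character(), lower = numeric(),
                      upper = numeric(), person_years = numeric(),
                      events = integer(), air = numeric())
    for (b in by) out[[b]] <- character()
    out
  }
  if (nrow(ca) == 0L) {
    out <- empty()
    out <- out[c("set", by, "lower", "upper", "person_years", "events",
                 "air")]
    return(structure(out, by = by, grid = grid,
                     class = c("incidence_table", "data.frame")))
  }

  pieces <- lapply(sets, function(os) {
    pyd <- person_years(cohort, os, grid)
    keycols <- ca[match(pyd$carrier_id, ca$carrier_id), by, drop = FALSE]
    groups <- c(as.list(keycols), list(lower = pyd$lower))
    agg <- aggregate(pyd[c("person_years", "event")], by = groups, FUN = sum)
    if ("sex" %in% by) {
      ok <- vapply(agg$sex, function(s) any(organ_sex_ok(os$members, s)),
                   logical(1))
      agg <- agg[ok, , drop = FALSE]
    }
    agg$set <- os$name
    agg
  })
  out <- do.call(rbind, pieces)
  names(out)[names(out) == "event"] <- "events"
  out$upper <- grid$upper[match(out$lower, grid$lower)]
  out$air <- ifelse(out$person_years > 0, out$events / out$person_years,
                    NA_real_)
  out <- out[do.call(order, out[c("set", by, "lower")]),
             c("set", by, "lower", "upper", "person_years", "events", "air")]
  rownames(out) <- NULL
  structure(out, by = by, grid = grid,
            class = c("incidence_table", "data.frame"))
}

#' Nelson-Aalen cumulative incidence with Poisson confidence intervals
#'
#' For each stratum of an [incidence_table()], accumulates the cumulative
#' hazard `H(a) = sum(AIR_band * width)` over the grid and transforms it to
#' cumulative incidence `Q(a) = 1 - exp(-H(a))`, with risk set to zero at
#' the grid start (age 25 on the standard grid).  Band event counts are
#' treated as Poisson given the person-years, so `var H = sum d / PY^2`; the
#' 95% interval is log-normal on the hazard scale,
#' `H * exp(+-z * sqrt(var H) / H)`, mapped through `1 - exp(-.)`.  At ages
#' with no events accumulated yet the interval is `[0, 1 - exp(-3 / PY)]`
#' (exact Poisson zero-event bound, the "rule of three").
#'
#' @param table An [incidence_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame of class `cuminc_curve`: `set`, stratum columns,
#'   `age`, `cum_py`, `cum_events`, `H`, `var_H`, `Q`, `ci_low`, `ci_high`.
#' @export
cumulative_incidence <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "incidence_table"))
  by <- attr(table, "by")
  grid <- attr(table, "grid")
  z <- qnorm(1 - (1 - conf_level) / 2)
  key <- interaction(table[c("set", by)], drop = TRUE, lex.order = TRUE)

  pieces <- lapply(split(seq_len(nrow(table)), key), function(ix) {
    st <- table[ix, , drop = FALSE]
    st <- st[order(st$lower), , drop = FALSE]
    if (!isTRUE(all.equal(st$lower, grid$lower))) {
      stop("stratum does not cover the full age grid")
    }
    if (any(st$person_years == 0 & st$events > 0)) {
      stop("band with events but zero person-years in stratum ",
           paste(unlist(st[1, c("set", by)]), collapse = "/"))
    }
    w <- st$upper - st$lower
    air0 <- ifelse(st$person_years > 0, st$events / st$person_years, 0)
    H <- c(0, cumsum(air0 * w))
    # Poisson band counts: var(AIR_i) = d_i / PY_i^2, and each band enters
    # H with weight w_i, hence the squared width
    V <- c(0, cumsum(w^2 * ifelse(st$person_years > 0,
                                  st$events / st$person_years^2, 0)))
    cum_d <- c(0, cumsum(st$events))
    cum_py <- c(0, cumsum(st$person_years))
    Hlo <- Hhi <- numeric(length(H))
    pos <- cum_d > 0
    f <- exp(z * sqrt(V[pos]) / H[pos])
    Hlo[pos] <- H[pos] / f
    Hhi[pos] <- H[pos] * f
    Hhi[!pos] <- ifelse(cum_py[!pos] > 0, 3 / cum_py[!pos], 0)
    res <- data.frame(age = c(st$lower[1], st$upper),
                      cum_py = cum_py, cum_events = cum_d,
                      H = H, var_H = V,
                      Q = 1 - exp(-H),
                      ci_low = 1 - exp(-Hlo),
                      ci_high = 1 - exp(-Hhi))
    cbind(st[rep(1L, nrow(res)), c("set", by), drop = FALSE], res)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, by = by, conf_level = conf_level,
            class = c("cuminc_curve", "data.frame"))
}

#' Read cumulative incidence at a given age
#'
#' @param curve A [cumulative_incidence()] result.
#' @param age Grid age (years).
#' @return The rows of `curve` at `age`.
#' @export
risk_at <- function(curve, age) {
  stopifnot(inherits(curve, "cuminc_curve"))
  out <- curve[curve$age == age, , drop = FALSE]
  if (!nrow(out)) stop("age ", age, " is not on the curve grid")
  rownames(out) <- NULL
  out
}
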