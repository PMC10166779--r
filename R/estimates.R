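# Derived statistics: crude mortality at 75, median age of cancer onset via
# conditional-risk interpolation, and death tabulations by cancer type.

#' Crude mortality at 75 years
#'
#' The headline mortality statistic: the probability of dying by age 75
#' following a cancer in a given organ, computed as the cumulative incidence
#' of that cancer at 65 years multiplied by one minus the 10-year crude
#' survival after it, `M75 = Q65 * (1 - S10)`.  It is an empirical crude
#' quantity -- death from any cause, no competing-risk adjustment -- and is
#' displayed rounded to the nearest integer percent, half away from zero.
#'
#' @param q65 Cumulative incidence at 65 years, as a proportion in `[0, 1]`
#'   (vectorised).
#' @param s10 Ten-year crude survival after the cancer, proportion in
#'   `[0, 1]`.
#' @return Data frame with columns `q65`, `s10`, `m75` (proportion) and
#'   `m75_pct` (display value, integer percent).
#' @export
#' @examples
#' mortality_at_75(q65 = 0.484, s10 = 0.87)  # 6.29% -> displayed 6%
mortality_at_75 <- function(q65, s10) {
  if (any(!is.finite(q65)) || any(!is.finite(s10)) ||
      any(q65 < 0 | q65 > 1) || any(s10 < 0 | s10 > 1)) {
    stop("q65 and s10 must be proportions in [0, 1]")
  }
  m <- q65 * (1 - s10)
  data.frame(q65 = q65, s10 = s10, m75 = m,
             m75_pct = round_half_away(100 * m))
}

# First age at which the piecewise-linear interpolant of `val` over `age`
# rises to `thr`.  NA when the curve never reaches `thr` ("always below") or
# already starts at/above it ("always above", no upward crossing).  When the
# interpolant touches `thr` along a flat segment the left endpoint is
# returned.
first_crossing <- function(age, val, thr = 0.5) {
  if (!length(val) || is.na(val[1]) || val[1] >= thr) return(NA_real_)
  k <- which(val >= thr)[1]
  if (is.na(k)) return(NA_real_)
  a0 <- age[k - 1]; a1 <- age[k]
  v0 <- val[k - 1]; v1 <- val[k]
  a0 + (a1 - a0) * (thr - v0) / (v1 - v0)
}

#' Median age of cancer onset by conditional-risk interpolation
#'
#' Conditions the cumulative incidence on developing the cancer by the end
#' of the grid: `c(a) = Q(a) / Q(75)` (lifetime risk approximated by the
#' risk at 75).  The median onset age is the first age at which the
#' piecewise-linear interpolant of `c` over the five-year grid reaches 50%.
#' The conditional 95% CI curves (`ci / Q(75)`, truncated to `[0, 1]`) are
#' interpolated the same way: the lower age bound is the 50% crossing of
#' the conditional *upper* CI curve and the upper bound that of the
#' conditional *lower* curve.  A curve that never crosses 50% -- always
#' below it, or already above it at the first informative age -- yields
#' `NA`; the age-25 anchor, whose interval is degenerate by construction, is
#' excluded from the CI curves.  A stratum with `Q(75) = 0` is entirely
#' `NA`.
#'
#' @param curve A [cumulative_incidence()] result (any number of strata).
#' @return Data frame of class `onset_estimate`: stratum columns,
#'   `q_end` (risk at the grid end), `median_age`, `ci_low_age`,
#'   `ci_high_age` (years or `NA`).
#' @export
median_onset <- function(curve) {
  stopifnot(inherits(curve, "cuminc_curve"))
  by <- attr(curve, "by")
  key <- interaction(curve[c("set", by)], drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(seq_len(nrow(curve)), key), function(ix) {
    st <- curve[ix, , drop = FALSE]
    st <- st[order(st$age), , drop = FALSE]
    ages <- st$age
    q_end <- st$Q[nrow(st)]
    if (q_end <= 0) {
      med <- lo <- hi <- NA_real_
    } else {
      cc <- pmin(st$Q / q_end, 1)
      cu <- pmin(st$ci_high / q_end, 1)
      cl <- pmin(st$ci_low / q_end, 1)
      med <- first_crossing(ages, cc)
      lo <- first_crossing(ages[-1], cu[-1])
      hi <- first_crossing(ages[-1], cl[-1])
    }
    cbind(st[1L, c("set", by), drop = FALSE],
          data.frame(q_end = q_end, median_age = med,
                     ci_low_age = lo, ci_high_age = hi))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, by = by, class = c("onset_estimate", "data.frame"))
}

#' Deaths by cancer type and gene
#'
#' Tabulates, per member organ and gene, the number of carriers with a
#' scored prospective cancer in that organ and how many of them were dead at
#' last observation.  A carrier who died after cancers in two organs counts
#' in both organs' rows: the semantics are per cancer type, not per carrier,
#' and the total over the organ set is the column sum.
#'
#' @param cohort A `lynch_cohort`.
#' @param organ_set Organ set defining the cancer types tabulated; default
#'   the core Lynch-syndrome organs.
#' @return Data frame of class `death_table`: `organ`, `gene`, `n`,
#'   `n_deaths`, with attribute `total_deaths`.
#' @export
death_table <- function(cohort, organ_set = organ_groups()$ls_cancers) {
  cohort <- score_prospective_events(cohort)
  os <- as_organ_group(organ_set)
  ca <- cohort$carriers
  ev <- cohort$events
  pro <- ev[ev$timing == "prospective" & ev$organ %in% os$members, ,
            drop = FALSE]
  i <- match(pro$carrier_id, ca$carrier_id)
  pro$gene <- ca$gene[i]
  pro$dead <- as.integer(ca$vital_status[i] == "dead")
  cells <- expand.grid(organ = os$members, gene = .GENES,
                       stringsAsFactors = FALSE)
  key <- paste(pro$organ, pro$gene)
  cells$n <- as.integer(table(factor(key, levels = paste(cells$organ,
                                                         cells$gene))))
  cells$n_deaths <- vapply(seq_len(nrow(cells)), function(j) {
    sum(pro$dead[key == paste(cells$organ[j], cells$gene[j])])
  }, numeric(1))
  cells <- cells[order(match(cells$organ, os$members),
                       match(cells$gene, .GENES)), ]
  rownames(cells) <- NULL
  structure(cells, total_deaths = sum(cells$n_deaths),
            class = c("death_table", "data.frame"))
}

#' Shares of deaths by cancer type
#'
#' Computes each cancer type's share of all deaths over an organ set
#' partition, `100 * deaths / total deaths`.  With `groups`, member organs
#' are aggregated first (e.g. colorectal = colon + rectum).
#'
#' @param counts A [death_table()] or any data frame with columns `organ`
#'   and `n_deaths` (and optionally `n`).
#' @param groups Optional named list of character vectors of organ codes;
#'   organs not named in any group are reported individually.
#' @return Data frame: `cancer`, `n_deaths`, `share_pct` (NA with a warning
#'   when there are no deaths).
#' @export
#' @examples
#' \dontrun{
#' death_shares(ref_death_counts(),
#'              groups = list(colorectal = c("colon", "rectum")))
#' }
death_shares <- function(counts, groups = NULL) {
  stopifnot(all(c("organ", "n_deaths") %in% names(counts)))
  total <- sum(counts$n_deaths)
  if (is.null(groups)) groups <- list()
  grouped <- unlist(groups, use.names = FALSE)
  singles <- setdiff(unique(counts$organ), grouped)
  cancers <- c(groups, setNames(as.list(singles), singles))
  deaths <- vapply(cancers, function(org) {
    sum(counts$n_deaths[counts$organ %in% org])
  }, numeric(1))
  out <- data.frame(cancer = names(cancers), n_deaths = deaths,
                    share_pct = if (total > 0) 100 * deaths / total
                                else NA_real_)
  rownames(out) <- NULL
  if (total == 0) warning("no deaths in the organ set; shares undefined")
  attr(out, "total_deaths") <- total
  out
}
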