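# Synthetic surveillance cohorts from a piecewise-constant-hazard model,
# with closed-form ground truth for the downstream estimators.
#
# Per carrier: gene and sex drawn from the mixing proportions; inclusion age
# from a normal truncated at 25; end of follow-up from an exponential
# censoring hazard capped at an administrative cutoff age; one latent cancer
# age per organ by exact inverse-CDF sampling of the piecewise-constant
# hazard over the age grid (organs independent, latent-failure-time
# construction).  A latent cancer before inclusion is recorded as a
# prevalent cancer (blocking that organ, as in the registry design).  The
# death clock starts at the earliest prospective cancer only: death occurs
# after an exponential time with the organ-specific post-cancer hazard, and
# observation ends at the earlier of death and censoring.

#' Banded hazard rows for a simulation hazard table
#'
#' Convenience constructor for the `hazard_table` of a
#' [simulation_config()]: one row per (gene, sex, organ, band) with an
#' annual cancer hazard (events per person-year).
#'
#' @param gene Gene label.
#' @param sex Character vector of sexes the rows apply to.
#' @param organ Organ code.
#' @param rates Annual hazards, recycled to the number of grid bands.
#' @param grid Age-band grid from [age_bands()].
#' @return Data frame with columns `gene`, `sex`, `organ`, `lower`,
#'   `upper`, `hazard`.
#' @export
hazard_bands <- function(gene, sex, organ, rates, grid = age_bands()) {
  rates <- rep_len(rates, nrow(grid))
  do.call(rbind, lapply(sex, function(s) {
    data.frame(gene = toupper(gene), sex = toupper(s),
               organ = canon_vocab(organ, .ORGANS, "organ"),
               lower = grid$lower, upper = grid$upper, hazard = rates)
  }))
}

#' Default two-organ hazard table
#'
#' The reference simulation scenario: *MLH1* carriers of both sexes at risk
#' of colon cancer (hazard rising with age from 0.002 to 0.016 per year,
#' cumulative risk at 65 of about 30%, comparable to the registry's colon
#' estimates) and stomach cancer (constant 0.001 per year).
#'
#' @return A hazard table as used by [simulation_config()].
#' @export
default_hazard_table <- function() {
  colon <- c(0.002, 0.004, 0.006, 0.008, 0.010, 0.012, 0.014, 0.016,
             0.016, 0.016)
  rbind(hazard_bands("MLH1", c("F", "M"), "colon", colon),
        hazard_bands("MLH1", c("F", "M"), "stomach", 0.001))
}

#' Configure a synthetic cohort
#'
#' Defaults mirror the observed registry conditions: gene-specific mean
#' inclusion ages of 42.5/43.6/48.3/49.9 years for MLH1/MSH2/MSH6/PMS2
#' (spread sd 12 years, truncated at 25), 54% females, a censoring hazard of
#' 0.125 per year giving a mean follow-up of about 8 years, administrative
#' cutoff at age 80, and post-cancer death hazards reproducing the reported
#' 10-year survival after colon (87%) and stomach (63%) cancer.
#'
#' @param n_carriers Number of carriers.
#' @param hazard_table Data frame of per-(gene, sex, organ, band) annual
#'   cancer hazards; see [hazard_bands()].  Missing (gene, sex, organ)
#'   combinations mean zero hazard.
#' @param gene_mix Named probability vector over genes (must sum to 1).
#' @param sex_mix Probability that a carrier is female.
#' @param inclusion_age_mean Mean inclusion age, a single number or a named
#'   vector by gene.
#' @param inclusion_age_sd Standard deviation of the inclusion age (0 for a
#'   point mass).
#' @param post_cancer_death_hazard Named vector of annual death hazards
#'   after cancer, by organ; organs absent from the vector have hazard 0.
#' @param censor_hazard Annual rate of (non-death) end of follow-up.
#' @param admin_cutoff_age Administrative censoring age in years.
#' @param prevalent If `TRUE` (default) latent cancers before inclusion are
#'   recorded as prevalent cancers; if `FALSE`, cancer ages are drawn
#'   conditionally on no event before inclusion, so no prevalent cases
#'   occur.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_carriers,
                              hazard_table = default_hazard_table(),
                              gene_mix = c(MLH1 = 1),
                              sex_mix = 0.54,
                              inclusion_age_mean = c(MLH1 = 42.5,
                                                     MSH2 = 43.6,
                                                     MSH6 = 48.3,
                                                     PMS2 = 49.9),
                              inclusion_age_sd = 12,
                              post_cancer_death_hazard =
                                c(colon = log(1 / 0.87) / 10,
                                  stomach = log(1 / 0.63) / 10),
                              censor_hazard = 0.125,
                              admin_cutoff_age = 80,
                              prevalent = TRUE,
                              seed = NULL) {
  stopifnot(n_carriers >= 1,
            is.data.frame(hazard_table),
            all(c("gene", "sex", "organ", "lower", "upper", "hazard") %in%
                  names(hazard_table)),
            all(hazard_table$hazard >= 0),
            all(hazard_table$gene %in% .GENES),
            all(hazard_table$sex %in% .SEXES),
            all(hazard_table$organ %in% .ORGANS),
            all(names(gene_mix) %in% .GENES),
            abs(sum(gene_mix) - 1) < 1e-8, all(gene_mix >= 0),
            sex_mix >= 0, sex_mix <= 1,
            inclusion_age_sd >= 0,
            all(post_cancer_death_hazard >= 0),
            censor_hazard >= 0,
            admin_cutoff_age > 25)
  if (length(inclusion_age_mean) > 1 &&
      !all(names(gene_mix) %in% names(inclusion_age_mean))) {
    stop("inclusion_age_mean must cover every gene in gene_mix")
  }
  structure(list(n_carriers = as.integer(n_carriers),
                 hazard_table = hazard_table, gene_mix = gene_mix,
                 sex_mix = sex_mix,
                 inclusion_age_mean = inclusion_age_mean,
                 inclusion_age_sd = inclusion_age_sd,
                 post_cancer_death_hazard = post_cancer_death_hazard,
                 censor_hazard = censor_hazard,
                 admin_cutoff_age = admin_cutoff_age,
                 prevalent = isTRUE(prevalent), seed = seed),
            class = "sim_config")
}

# Cumulative hazard of a banded hazard (rows sorted by lower) evaluated at
# ages `a`, measured from the first band's lower edge.
pch_cumhaz <- function(a, bands) {
  out <- numeric(length(a))
  for (j in seq_len(nrow(bands))) {
    out <- out + bands$hazard[j] *
      pmax(0, pmin(a, bands$upper[j]) - bands$lower[j])
  }
  out
}

# Inverse of the cumulative banded hazard: the age at which the cumulative
# hazard from the first band's lower edge reaches E.  Inf when E exceeds
# the total hazard (no event before the grid end).
pch_invert <- function(E, bands) {
  width <- bands$upper - bands$lower
  C <- c(0, cumsum(bands$hazard * width))
  i <- findInterval(E, C)
  age <- rep(Inf, length(E))
  inside <- i <= nrow(bands)
  ii <- i[inside]
  h <- bands$hazard[ii]
  age[inside] <- ifelse(h > 0,
                        bands$lower[ii] + (E[inside] - C[ii]) / h,
                        bands$lower[ii])
  age
}

#' Simulate a surveillance cohort
#'
#' Draws a cohort from the piecewise-constant-hazard model described in
#' [simulation_config()].  Reproducible: the same config (including seed)
#' yields an identical cohort.  Simulated death never precedes a cancer
#' diagnosis and no prospective event is dated after the last observation.
#'
#' @param config A [simulation_config()].
#' @return A validated, scored `lynch_cohort`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_carriers
  genes <- sample(names(config$gene_mix), n, replace = TRUE,
                  prob = config$gene_mix)
  sexes <- ifelse(runif(n) < config$sex_mix, "F", "M")
  mu <- if (length(config$inclusion_age_mean) == 1L) {
    rep(unname(config$inclusion_age_mean), n)
  } else {
    unname(config$inclusion_age_mean[genes])
  }
  sd0 <- config$inclusion_age_sd
  incl <- if (sd0 > 0) {
    mu + sd0 * qnorm(runif(n, pnorm((25 - mu) / sd0), 1))
  } else {
    pmax(mu, 25)
  }
  fu <- if (config$censor_hazard > 0) rexp(n, config$censor_hazard) else
    rep(Inf, n)
  censor_age <- pmax(pmin(incl + fu, config$admin_cutoff_age), incl)

  ht <- config$hazard_table
  organs <- unique(ht$organ)
  evage <- matrix(Inf, n, length(organs), dimnames = list(NULL, organs))
  for (g in intersect(.GENES, unique(genes))) {
    for (s in .SEXES) {
      idx <- which(genes == g & sexes == s)
      if (!length(idx)) next
      for (o in organs) {
        bands <- ht[ht$gene == g & ht$sex == s & ht$organ == o, ,
                    drop = FALSE]
        if (!nrow(bands) || !organ_sex_ok(o, s)) next
        bands <- bands[order(bands$lower), , drop = FALSE]
        E <- rexp(length(idx))
        if (!config$prevalent) {
          E <- E + pch_cumhaz(pmax(incl[idx], bands$lower[1]), bands)
        }
        evage[idx, o] <- pch_invert(E, bands)
      }
    }
  }

  # observed prospective candidates; draws before inclusion become
  # prevalent cancers (when enabled) and never count as candidates
  cand <- evage
  cand[cand <= incl] <- Inf
  cand[cand > censor_age] <- Inf
  e1 <- do.call(pmin, as.data.frame(cand))
  o1 <- organs[max.col(-cand, ties.method = "first")]
  mu_d <- config$post_cancer_death_hazard[o1]
  mu_d[is.na(mu_d)] <- 0
  death_age <- e1 + rexp(n) / unname(mu_d)  # Inf when no event or hazard 0
  age_last <- pmin(censor_age, death_age)
  vital <- ifelse(is.finite(death_age) & death_age <= censor_age,
                  "dead", "alive")

  ids <- sprintf("S%06d", seq_len(n))
  carriers <- data.frame(carrier_id = ids, gene = genes, sex = sexes,
                         age_inclusion = incl, age_last_obs = age_last,
                         vital_status = vital)
  evs <- list()
  for (o in organs) {
    if (config$prevalent) {
      pv <- which(evage[, o] <= incl)
      if (length(pv)) {
        evs[[paste0(o, ".pv")]] <- data.frame(
          carrier_id = ids[pv], organ = o, age_dx = evage[pv, o],
          timing = "prevalent")
      }
    }
    pr <- which(is.finite(cand[, o]) & cand[, o] <= age_last)
    if (length(pr)) {
      evs[[paste0(o, ".pr")]] <- data.frame(
        carrier_id = ids[pr], organ = o, age_dx = cand[pr, o],
        timing = "prospective")
    }
  }
  events <- if (length(evs)) do.call(rbind, evs) else NULL
  validate_cohort(score_prospective_events(
    as_lynch_cohort(carriers, events)))
}

#' Closed-form ground truth for a simulation configuration
#'
#' The quantities the pipeline estimates, in closed form from the hazards:
#' cumulative incidence `Q*(a) = 1 - exp(-sum(lambda_band * width))` per
#' (gene, sex, organ) on the age grid; 10-year post-cancer survival
#' `S10* = exp(-10 * mu)` per organ; and crude mortality
#' `M75* = Q*(65) * (1 - S10*)`.
#'
#' @param config A [simulation_config()].
#' @return A list of class `ground_truth` with elements `curves` (long data
#'   frame: `gene`, `sex`, `organ`, `age`, `Q`) and `estimates` (one row
#'   per (gene, sex, organ): `q65`, `s10`, `m75`).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ht <- config$hazard_table
  key <- unique(ht[c("gene", "sex", "organ")])
  curves <- list()
  ests <- list()
  for (j in seq_len(nrow(key))) {
    bands <- ht[ht$gene == key$gene[j] & ht$sex == key$sex[j] &
                  ht$organ == key$organ[j], , drop = FALSE]
    bands <- bands[order(bands$lower), , drop = FALSE]
    ages <- c(bands$lower[1], bands$upper)
    Q <- 1 - exp(-pch_cumhaz(ages, bands))
    curves[[j]] <- cbind(key[j, , drop = FALSE], age = ages, Q = Q,
                         row.names = NULL)
    mu <- config$post_cancer_death_hazard[key$organ[j]]
    if (is.na(mu)) mu <- 0
    s10 <- exp(-10 * unname(mu))
    q65 <- 1 - exp(-pch_cumhaz(65, bands))
    ests[[j]] <- cbind(key[j, , drop = FALSE],
                       data.frame(q65 = q65, s10 = s10,
                                  m75 = q65 * (1 - s10)),
                       row.names = NULL)
  }
  structure(list(curves = do.call(rbind, curves),
                 estimates = do.call(rbind, ests)),
            class = "ground_truth")
}
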