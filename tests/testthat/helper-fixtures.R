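# Shared fixture builders and independent oracles, all generated in code.

mk_carriers <- function(id, gene = "MLH1", sex = "F", incl = 40, last = 50,
                        vital = "alive") {
  n <- length(id)
  data.frame(carrier_id = id, gene = rep_len(gene, n),
             sex = rep_len(sex, n), age_inclusion = rep_len(incl, n),
             age_last_obs = rep_len(last, n),
             vital_status = rep_len(vital, n), stringsAsFactors = FALSE)
}

mk_events <- function(id, organ, age, timing = "prospective") {
  data.frame(carrier_id = id, organ = organ, age_dx = age, timing = timing,
             stringsAsFactors = FALSE)
}

mk_cohort <- function(carriers, events = NULL) {
  validate_cohort(as_lynch_cohort(carriers, events))
}

# Independent day-resolution person-time counter: walks day midpoints from
# inclusion to the stopping age and bins them on the grid.  Per-carrier
# band totals are accurate to about a day.
brute_person_years <- function(incl, last, evage, grid) {
  nb <- nrow(grid)
  g0 <- min(grid$lower); g1 <- max(grid$upper)
  out <- matrix(0, length(incl), nb)
  for (i in seq_along(incl)) {
    stop_at <- min(evage[i], last[i], g1)
    if (stop_at <= incl[i]) next
    k <- floor((stop_at - incl[i]) * 365)
    if (k < 1) next
    t <- incl[i] + (seq_len(k) - 0.5) / 365
    t <- t[t >= g0 & t < g1]
    if (length(t)) {
      b <- findInterval(t, c(grid$lower, g1))
      out[i, ] <- tabulate(b, nb) / 365
    }
  }
  out
}

# Independent fine-grid scan for the 50% crossing of a piecewise-linear
# curve: interpolates on a 0.001-year grid and reports the first grid age
# at or above the threshold.
brute_first_crossing <- function(ages, vals, thr = 0.5, step = 0.001) {
  if (vals[1] >= thr) return(NA_real_)
  fine <- seq(min(ages), max(ages), by = step)
  v <- approx(ages, vals, xout = fine)$y
  i <- which(v >= thr)[1]
  if (is.na(i)) NA_real_ else fine[i]
}

# Wrap a bare data frame of grid ages / Q / CI columns as a cumulative
# incidence curve object (single stratum named in `set`).
as_curve <- function(df, by = character(0)) {
  structure(df, by = by, conf_level = 0.95,
            class = c("cuminc_curve", "data.frame"))
}

# Random non-decreasing cumulative-incidence curve on the standard grid,
# with pseudo confidence bands, for onset-interpolation property tests.
random_curve <- function() {
  inc <- rexp(10) * rbinom(10, 1, 0.7) * 0.05
  H <- c(0, cumsum(inc))
  Q <- 1 - exp(-H)
  spread <- runif(1, 0.1, 0.5)
  as_curve(data.frame(set = "sim", age = seq(25, 75, 5), Q = Q,
                      ci_low = pmax(0, Q * (1 - spread)),
                      ci_high = pmin(1, Q * (1 + spread))))
}
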