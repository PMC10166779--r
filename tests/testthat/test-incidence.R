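test_that("person-years split across bands with left truncation and stopping", {
  get_py <- function(co, organ = "colon") {
    p <- person_years(co, organ)
    p[p$person_years > 0 | p$event > 0, ]
  }

  # inclusion 40, last obs 52, no events: 5 + 5 + 2
  p1 <- get_py(mk_cohort(mk_carriers("a", incl = 40, last = 52)))
  expect_equal(p1$lower, c(40, 45, 50))
  expect_equal(p1$person_years, c(5, 5, 2))

  # colon event at 47 stops colon time; event credited to [45,50)
  p2 <- get_py(mk_cohort(mk_carriers("b", incl = 40, last = 60),
                         mk_events("b", "colon", 47)))
  expect_equal(p2$person_years, c(5, 2))
  expect_equal(p2$event, c(0, 1))
  expect_equal(p2$lower[p2$event == 1], 45)

  # grid truncation: inclusion 73, last obs 79 contributes [70,75) = 2 only
  p3 <- get_py(mk_cohort(mk_carriers("c", incl = 73, last = 79)))
  expect_equal(p3$lower, 70)
  expect_equal(p3$person_years, 2)

  # an event at exactly 75 is outside the grid and not counted
  p4 <- get_py(mk_cohort(mk_carriers("d", incl = 73, last = 79),
                         mk_events("d", "colon", 75)))
  expect_equal(sum(p4$event), 0)
  expect_equal(p4$person_years, 2)

  # ineligible carrier (prevalent colon) contributes all-zero rows
  p5 <- person_years(mk_cohort(mk_carriers("e", incl = 40, last = 60),
                               mk_events("e", "colon", 35, "prevalent")),
                     "colon")
  expect_true(all(p5$person_years == 0))
})

test_that("interval arithmetic agrees with a day-resolution counter", {
  set.seed(2024)
  grid <- age_bands()
  for (rep in 1:40) {
    n <- 5
    incl <- runif(n, 25, 78)
    last <- incl + runif(n, 0, 20)
    has_ev <- runif(n) < 0.4
    evage <- ifelse(has_ev, incl + runif(n, 0.01, pmax(last - incl, 0.02)),
                    Inf)
    evage <- pmin(evage, last)
    ca <- mk_carriers(sprintf("c%d", 1:n), incl = incl, last = last)
    ev <- mk_events(sprintf("c%d", which(is.finite(evage))), "colon",
                    evage[is.finite(evage)])
    co <- mk_cohort(ca, if (nrow(ev)) ev)
    p <- person_years(co, "colon", grid)
    got <- matrix(p$person_years, n, nrow(grid), byrow = TRUE)
    want <- brute_person_years(incl, last, evage, grid)
    expect_lt(max(abs(got - want)), 2 / 365)
    expect_lt(max(abs(rowSums(got) - rowSums(want))), 1 / 365 + 1e-9)
  }
})

test_that("incidence table sums person-years and events per stratum", {
  ca <- rbind(mk_carriers(sprintf("f%d", 1:10), incl = 40, last = 45),
              mk_carriers("m1", sex = "M", incl = 40, last = 45))
  ev <- mk_events("f1", "colon", 43)
  tab <- incidence_table(mk_cohort(ca, ev), "colon")
  band <- tab[tab$lower == 40 & tab$sex == "F", ]
  expect_equal(band$person_years, 9 * 5 + 3)
  expect_equal(band$events, 1)
  expect_equal(band$air, 1 / 48)
  expect_equal(tab$person_years[tab$sex == "M" & tab$lower == 40], 5)

  # empty cohort: empty table, no crash
  empty <- incidence_table(mk_cohort(mk_carriers(character(0))), "colon")
  expect_s3_class(empty, "incidence_table")
  expect_equal(nrow(empty), 0L)

  # sex-restricted organ drops the incompatible stratum
  tab2 <- incidence_table(mk_cohort(ca), "endometrium")
  expect_false("M" %in% tab2$sex)
})

test_that("cumulative incidence matches closed forms and zero-event bounds", {
  # single informative band with AIR = 0.01: Q(30) = 1 - exp(-0.05)
  ca <- mk_carriers(sprintf("c%d", 1:20), incl = 25, last = 30)
  ev <- mk_events("c1", "colon", 29.0)
  tab <- incidence_table(mk_cohort(ca, ev), "colon", by = character(0))
  py1 <- tab$person_years[tab$lower == 25]
  expect_equal(py1, 19 * 5 + 4)
  # rescale to AIR exactly 0.01 by construction: 1 event / 100 PY
  ca2 <- mk_carriers(sprintf("d%d", 1:21), incl = 25, last = 30)
  ca2$age_last_obs[21] <- 26
  ev2 <- mk_events("d21", "colon", 26)
  tab2 <- incidence_table(mk_cohort(ca2, ev2), "colon", by = character(0))
  expect_equal(tab2$person_years[1], 101)
  cc2 <- cumulative_incidence(tab2)
  expect_equal(risk_at(cc2, 30)$Q, 1 - exp(-5 / 101), tolerance = 1e-12)

  # no events anywhere: Q identically zero, upper bound = rule of three
  tab0 <- incidence_table(mk_cohort(ca), "colon", by = character(0))
  cc0 <- cumulative_incidence(tab0)
  expect_true(all(cc0$Q == 0))
  expect_true(all(cc0$ci_low == 0))
  expect_equal(risk_at(cc0, 30)$ci_high, 1 - exp(-3 / 100))
  expect_equal(risk_at(cc0, 25)$ci_high, 0)

  # a band with events but no person-years is an error
  broken <- tab2
  broken$person_years[1] <- 0
  expect_error(cumulative_incidence(broken), "zero person-years")
})

test_that("hand-computed Nelson-Aalen hazard on a small integer-age cohort", {
  ca <- rbind(
    mk_carriers("c1", incl = 30, last = 40),
    mk_carriers("c2", incl = 25, last = 50),
    mk_carriers("c3", incl = 47, last = 47),
    mk_carriers("c4", incl = 40, last = 72),
    mk_carriers("c5", incl = 52.5, last = 58.5),
    mk_carriers("c6", incl = 33, last = 80),
    mk_carriers("c7", incl = 68, last = 74),
    mk_carriers("c8", incl = 25, last = 26),
    mk_carriers("c9", sex = "M", incl = 40, last = 60),
    mk_carriers("c10", incl = 76, last = 79),
    mk_carriers("c11", incl = 30, last = 75),
    mk_carriers("c12", incl = 44, last = 46, vital = "dead")
  )
  ev <- rbind(
    mk_events("c1", "colon", 38),
    mk_events("c4", "colon", 35, "prevalent"),
    mk_events("c7", "colon", 74),
    mk_events("c8", "colon", 25.5),
    mk_events("c9", "rectum", 50),
    mk_events("c12", "colon", 46)
  )
  tab <- incidence_table(mk_cohort(ca, ev), "colon", by = character(0))
  # hand sums: [25,30): c2 5 + c8 0.5; [30,35): c1 5 + c2 5 + c6 2 + c11 5;
  # [35,40): c1 3 + c2 5 + c6 5 + c11 5; bands 40-50: c2/c6/c9/c11 at 5
  # plus c12 1; [50,55): c5 2.5 + c6/c9/c11; [55,60): c5 3.5 + c6/c9/c11;
  # [65,70): c6 5 + c7 2 + c11 5; [70,75): c6 5 + c7 4 + c11 5
  expect_equal(tab$person_years,
               c(5.5, 17, 18, 21, 21, 17.5, 18.5, 10, 12, 14))
  expect_equal(tab$events, c(1, 0, 1, 0, 1, 0, 0, 0, 0, 1))
  cc <- cumulative_incidence(tab)
  expect_equal(risk_at(cc, 75)$H,
               5 * (1 / 5.5 + 1 / 18 + 1 / 21 + 1 / 14),
               tolerance = 1e-12)
})

test_that("cumulative incidence is monotone with ordered confidence bounds", {
  co <- simulate_cohort(simulation_config(4000, seed = 77))
  cc <- cumulative_incidence(incidence_table(co, list("colon", "stomach")))
  for (k in split(seq_len(nrow(cc)),
                  interaction(cc$set, cc$gene, cc$sex, drop = TRUE))) {
    st <- cc[k, ]
    st <- st[order(st$age), ]
    expect_true(all(diff(st$Q) >= -1e-12))
    expect_true(all(st$ci_low <= st$Q + 1e-12))
    expect_true(all(st$Q <= st$ci_high + 1e-12))
    expect_equal(st$Q[st$age == 25], 0)
  }
})
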