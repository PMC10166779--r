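test_that("mortality at 75 multiplies incidence by case fatality", {
  m <- mortality_at_75(q65 = 0.484, s10 = 0.87)
  expect_equal(m$m75, 0.484 * 0.13, tolerance = 1e-12)
  expect_equal(m$m75_pct, 6)
  expect_equal(mortality_at_75(0.376, 0.92)$m75_pct, 3)
  expect_equal(mortality_at_75(0, 0.5)$m75, 0)
  expect_error(mortality_at_75(1.2, 0.9), "proportions")
  expect_error(mortality_at_75(0.5, -0.1), "proportions")

  # monotone in both arguments
  q <- seq(0, 1, 0.25)
  expect_true(all(diff(mortality_at_75(q, 0.8)$m75) >= 0))
  expect_true(all(diff(mortality_at_75(0.5, q)$m75) <= 0))
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(c(1.59, 0.459, 0.999, 2.5, 3.5)),
               c(2, 0, 1, 3, 4))
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(14.833, 1), 14.8)
})

test_that("median onset interpolates the conditional risk at 50%", {
  ages <- seq(25, 75, 5)
  lin <- as_curve(data.frame(set = "lin", age = ages,
                             Q = seq(0, 0.4, length.out = 11),
                             ci_low = 0, ci_high = 0.5))
  expect_equal(median_onset(lin)$median_age, 50)

  # all risk inside [45,50): median at the band midpoint crossing
  Qj <- ifelse(ages < 50, 0, 0.3)
  jump <- as_curve(data.frame(set = "jump", age = ages, Q = Qj,
                              ci_low = 0, ci_high = Qj))
  mj <- median_onset(jump)$median_age
  expect_equal(mj, 47.5)
  expect_gt(mj, 45); expect_lt(mj, 50)

  # c(50) = 0.4, c(55) = 0.6 -> 52.5 by linear interpolation
  Qc <- c(0, 0, 0, 0, 0.2, 0.4, 0.6, 0.8, 0.9, 1, 1)
  cur <- as_curve(data.frame(set = "c", age = ages, Q = Qc,
                             ci_low = pmax(Qc - 0.1, 0),
                             ci_high = pmin(Qc + 0.1, 1)))
  est <- median_onset(cur)
  expect_equal(est$median_age, 52.5)
  # CI ages: upper curve crosses earlier, lower curve later
  expect_lt(est$ci_low_age, est$median_age)
  expect_gt(est$ci_high_age, est$median_age)

  # zero lifetime risk: everything NA
  z <- as_curve(data.frame(set = "z", age = ages, Q = 0, ci_low = 0,
                           ci_high = 0))
  expect_true(all(is.na(
    median_onset(z)[c("median_age", "ci_low_age", "ci_high_age")])))

  # lower CI curve that never reaches 50%: upper onset age NA
  flat <- as_curve(data.frame(set = "f", age = ages,
                              Q = seq(0, 1, length.out = 11),
                              ci_low = seq(0, 0.4, length.out = 11),
                              ci_high = pmin(seq(0, 1.2,
                                                 length.out = 11), 1)))
  expect_true(is.na(median_onset(flat)$ci_high_age))
})

test_that("median onset matches a fine-grid scan of the same interpolant", {
  set.seed(77)
  for (i in 1:60) {
    cur <- random_curve()
    est <- median_onset(cur)
    q75 <- cur$Q[cur$age == 75]
    if (q75 <= 0) {
      expect_true(is.na(est$median_age))
      next
    }
    want <- brute_first_crossing(cur$age, pmin(cur$Q / q75, 1))
    if (is.na(want)) {
      expect_true(is.na(est$median_age))
    } else {
      expect_lt(abs(est$median_age - want), 0.01)
    }
  }
})

test_that("death table counts cancers per organ and deaths per carrier", {
  ca <- rbind(
    mk_carriers("a", incl = 40, last = 60, vital = "dead"),
    mk_carriers("b", gene = "MSH2", incl = 40, last = 70),
    mk_carriers("c", incl = 40, last = 55, vital = "dead")
  )
  ev <- rbind(
    mk_events("a", c("colon", "stomach"), c(50, 55)),  # dead after two cancers
    mk_events("b", "colon", 60),
    mk_events("c", "endometrium", 50)
  )
  dt <- death_table(mk_cohort(ca, ev))
  expect_equal(dt$n[dt$organ == "colon" & dt$gene == "MLH1"], 1L)
  expect_equal(dt$n_deaths[dt$organ == "colon" & dt$gene == "MLH1"], 1)
  # carrier "a" counts in both colon and stomach death rows
  expect_equal(dt$n_deaths[dt$organ == "stomach" & dt$gene == "MLH1"], 1)
  expect_equal(attr(dt, "total_deaths"), 3)

  sh <- death_shares(dt, groups = list(gyn = c("endometrium", "ovary")))
  expect_equal(sh$share_pct[sh$cancer == "gyn"], 100 / 3)

  # no deaths: shares undefined, flagged, no crash
  ca0 <- mk_carriers("x", incl = 40, last = 60)
  ev0 <- mk_events("x", "colon", 50)
  dt0 <- death_table(mk_cohort(ca0, ev0))
  expect_warning(sh0 <- death_shares(dt0), "undefined")
  expect_true(all(is.na(sh0$share_pct)))
})
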