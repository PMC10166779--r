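test_that("event scoring follows the first-tumour-per-organ rules", {
  # prevalent colon cancer blocks colon but not rectum
  co <- mk_cohort(
    mk_carriers("a", incl = 40, last = 60),
    rbind(mk_events("a", "colon", 38, "prevalent"),
          mk_events("a", "rectum", 50))
  )
  sc <- score_prospective_events(co)
  expect_false("a" %in% eligible_carriers(sc, "colon"))
  expect_true("a" %in% eligible_carriers(sc, "rectum"))
  pro <- sc$events[sc$events$timing == "prospective", ]
  expect_equal(pro$organ, "rectum")
  expect_equal(pro$age_dx, 50)

  # two prospective colon cancers: scored once, at the earlier age
  co2 <- mk_cohort(
    mk_carriers("b", incl = 40, last = 60),
    mk_events("b", c("colon", "colon"), c(55, 47))
  )
  sc2 <- score_prospective_events(co2)
  expect_equal(nrow(sc2$events), 1L)
  expect_equal(sc2$events$age_dx, 47)

  # synchronous same-organ pair counts once; same age in two organs counts twice
  co3 <- mk_cohort(
    mk_carriers("c", incl = 40, last = 60),
    rbind(mk_events("c", c("colon", "colon"), c(47, 47)),
          mk_events("c", "stomach", 47))
  )
  sc3 <- score_prospective_events(co3)
  expect_equal(sort(sc3$events$organ), c("colon", "stomach"))

  # no events: every organ eligible, nothing scored
  co4 <- mk_cohort(mk_carriers("d"))
  sc4 <- score_prospective_events(co4)
  expect_equal(nrow(sc4$events), 0L)
  expect_true(all(vapply(ls_organs()[1:2], function(o) {
    "d" %in% eligible_carriers(sc4, o)
  }, logical(1))))
})

test_that("scoring is idempotent and bounded by eligibility", {
  cfg <- simulation_config(400, seed = 42)
  co <- simulate_cohort(cfg)
  sc <- score_prospective_events(co)
  expect_identical(sc$events, score_prospective_events(sc)$events)
  for (o in c("colon", "stomach")) {
    pro <- sc$events[sc$events$timing == "prospective" & sc$events$organ == o, ]
    expect_lte(nrow(pro), length(eligible_carriers(sc, o)))
    expect_true(all(pro$carrier_id %in% eligible_carriers(sc, o)))
  }
})

test_that("validation rejects impossible records and can skip them", {
  bad_last <- mk_carriers("x", incl = 50, last = 45)
  expect_error(mk_cohort(bad_last), "x")

  male_endo <- mk_cohort(mk_carriers("ok"))  # baseline passes
  expect_s3_class(male_endo, "lynch_cohort")
  expect_error(
    mk_cohort(mk_carriers("y", sex = "M", incl = 40, last = 60),
              mk_events("y", "endometrium", 50)),
    "incompatible")

  expect_error(mk_cohort(mk_carriers("z", gene = "EPCAM")), "gene")
  expect_error(mk_cohort(mk_carriers("w", incl = 20, last = 30)), "25")

  expect_error(
    mk_cohort(mk_carriers("v", incl = 40, last = 60),
              mk_events("v", "colon", 40)),
    "at or before inclusion")

  # skip mode drops offending carriers and keeps the rest
  both <- rbind(mk_carriers("good", incl = 40, last = 50),
                mk_carriers("bad", incl = 50, last = 45))
  expect_message(
    co <- validate_cohort(as_lynch_cohort(both), on_invalid = "skip"),
    "skipped 1")
  expect_equal(co$carriers$carrier_id, "good")
  expect_equal(attr(co, "issues")$carrier_id, "bad")
})

test_that("cohort summary partitions observation time correctly", {
  ca <- rbind(mk_carriers("a", incl = 40, last = 52),
              mk_carriers("b", gene = "MSH2", sex = "M", incl = 30,
                          last = 30.5),
              mk_carriers("c", incl = 60, last = 75))
  co <- mk_cohort(ca)
  s <- cohort_summary(co)
  expect_equal(s$observation_years,
               sum(ca$age_last_obs - ca$age_inclusion))
  expect_equal(s$mean_follow_up, s$observation_years / 3)
  expect_equal(as.integer(s$n_by_gene[["MSH2"]]), 1L)
})

test_that("case-insensitive vocabulary is canonicalised on read", {
  ca <- mk_carriers("a", gene = "mlh1", sex = "f", vital = "Alive")
  ev <- mk_events("a", "Colon", 45, "Prospective")
  co <- mk_cohort(ca, ev)
  expect_equal(co$carriers$gene, "MLH1")
  expect_equal(co$carriers$sex, "F")
  expect_equal(co$events$organ, "colon")
})

test_that("cohort CSV round trip preserves records", {
  d <- withr::local_tempdir()
  co <- simulate_cohort(simulation_config(50, seed = 7))
  write_cohort(co, d)
  back <- validate_cohort(read_cohort(file.path(d, "carriers.csv"),
                                      file.path(d, "events.csv")))
  expect_equal(back$carriers, co$carriers, tolerance = 1e-12)
  expect_equal(back$events, co$events, tolerance = 1e-12)
})
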