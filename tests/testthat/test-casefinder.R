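win <- study_window()

test_that("hospital qualification: diagnosis, procedure and package pathways; window bounds", {
  expect_equal(nrow(qualify_hdr(mk_hdr("p1", "585.3;401.9"))), 1L)
  expect_equal(qualify_hdr(mk_hdr("p1", "585.3;401.9"))$rule,
               "hdr_diagnosis")
  expect_equal(qualify_hdr(mk_hdr("p1", "401.9", proc = "54.98"))$rule,
               "hdr_procedure")
  expect_equal(qualify_hdr(mk_hdr("p1", "401.9", svc = "P583"))$rule,
               "hdr_complex_service")
  expect_equal(nrow(qualify_hdr(mk_hdr("p1", "401.9"))), 0L)
  # discharge outside the window is silently ignored (inclusive bounds)
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "585.3", adm = "2011-12-20", dis = "2011-12-31"))), 0L)
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "585.3", adm = "2011-12-30", dis = "2012-01-01"))), 1L)
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "585.3", adm = "2017-12-30", dis = "2017-12-31"))), 1L)
})

test_that("acute-renal-failure exclusion eliminates dialysis-only acute records and nothing else", {
  # only qualifying evidence is procedure 39.95 and a 584.X diagnosis
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "584.9;401.9", proc = "39.95"))), 0L)
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "584.9", proc = "38.95"))), 0L)
  # an independent qualifying diagnosis disarms the exclusion
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "584.6;585.6", proc = "39.95"))), 1L)
  # a qualifying non-dialysis procedure also disarms it
  expect_equal(nrow(qualify_hdr(
    mk_hdr("p1", "584.9", proc = "39.95;55.69"))), 1L)
  # acute diagnosis without the flagged procedures: nothing to exclude,
  # but 584.X alone does not qualify either
  expect_equal(nrow(qualify_hdr(mk_hdr("p1", "584.9"))), 0L)
  # dialysis procedure without acute diagnosis qualifies
  expect_equal(nrow(qualify_hdr(mk_hdr("p1", "401.9", proc = "39.95"))),
               1L)
})

test_that("exemption qualification requires the code active at the prevalence date", {
  expect_equal(nrow(qualify_ter(mk_ter("p1"))), 1L)
  expect_equal(nrow(qualify_ter(mk_ter("p1", code = "025.V42.0"))), 1L)
  expect_equal(nrow(qualify_ter(mk_ter("p1", end = "2016-01-01"))), 0L)
  # end strictly after the prevalence date keeps it active; end on the
  # date does not (half-open convention)
  expect_equal(nrow(qualify_ter(mk_ter("p1", end = "2018-01-01"))), 1L)
  expect_equal(nrow(qualify_ter(mk_ter("p1", end = "2017-12-31"))), 0L)
  # registration before the window start still counts if active
  expect_equal(nrow(qualify_ter(mk_ter("p1", start = "2008-05-01"))), 1L)
  expect_equal(nrow(qualify_ter(mk_ter("p1", code = "025.720"))), 0L)
})

test_that("outpatient qualification pathways and their thresholds", {
  two <- rbind(mk_ossis("p1", "89.7", "2015-06-01"),
               mk_ossis("p1", "89.01", "2016-02-01"))
  t <- qualify_ossis(two, empty_reg("pharm"))
  expect_equal(t$rule, "ossis_two_visits")
  # same-day duplicate visits are billing artifacts, not two visits
  dup <- rbind(mk_ossis("p1", "89.7", "2015-06-01"),
               mk_ossis("p1", "89.7", "2015-06-01"))
  expect_equal(nrow(qualify_ossis(dup, empty_reg("pharm"))), 0L)
  # one visit + albumin
  vb <- rbind(mk_ossis("p1", "89.01", "2015-06-01"),
              mk_ossis("p1", "90.33.4", "2015-07-01", branch = ""))
  expect_equal(qualify_ossis(vb, empty_reg("pharm"))$rule,
               "ossis_visit_albumin")
  # one visit + listed drug: OSSIS trigger plus a supporting PHARM trigger
  vd <- qualify_ossis(mk_ossis("p1", "89.7"), mk_pharm("p1"))
  expect_setequal(vd$rule, c("ossis_visit_drug", "pharm_confirming"))
  expect_setequal(vd$source, c("OSSIS", "PHARM"))
  # one visit alone is below every threshold
  expect_equal(nrow(qualify_ossis(mk_ossis("p1", "89.7"),
                                  empty_reg("pharm"))), 0L)
  # a visit code without the nephrology branch does not count
  expect_equal(nrow(qualify_ossis(
    rbind(mk_ossis("p1", "89.7", "2015-06-01", branch = ""),
          mk_ossis("p1", "89.7", "2016-06-01", branch = "12")),
    empty_reg("pharm"))), 0L)
  # dialysis-related services qualify standalone, with wildcard extensions
  ds <- qualify_ossis(mk_ossis("p1", "39.95.1", branch = ""),
                      empty_reg("pharm"))
  expect_equal(ds$rule, "ossis_dialysis_service")
  expect_equal(nrow(qualify_ossis(mk_ossis("p1", "39.95.1", branch = ""),
                                  empty_reg("pharm"),
                                  dialysis_standalone = FALSE)), 0L)
})

test_that("drug qualification: one listed dispensing in window, none outside", {
  expect_equal(nrow(qualify_pharm(mk_pharm("p1", "B03XA02",
                                           "2015-06-01"))), 1L)
  expect_equal(nrow(qualify_pharm(mk_pharm("p1", "B03XA02",
                                           "2011-12-30"))), 0L)
  expect_equal(nrow(qualify_pharm(mk_pharm("p1", "C09AA05"))), 0L)
  # window boundaries inclusive
  expect_equal(nrow(qualify_pharm(mk_pharm("p1", date = "2012-01-01"))),
               1L)
  expect_equal(nrow(qualify_pharm(mk_pharm("p1", date = "2017-12-31"))),
               1L)
})

test_that("cohort resolution merges sources and applies death/residence exclusions", {
  dem <- mk_dem(c("p1", "p2", "p3"))
  dem$death_date[2] <- as.Date("2016-02-02")
  trig <- rbind(qualify_hdr(mk_hdr("p1", "585.3")),
                qualify_ossis(rbind(mk_ossis("p2", "89.7", "2015-06-01"),
                                    mk_ossis("p2", "89.01", "2015-07-01")),
                              empty_reg("pharm")),
                qualify_ter(mk_ter("p3")))
  coh <- resolve_cohort(trig, dem, win)
  expect_equal(coh$cases$person_id, c("p1", "p3"))
  expect_equal(coh$cases$sources, c("HDR", "TER"))
  expect_equal(coh$counts$n_excluded_death, 1L)
  # residence ending mid-window excludes
  dem2 <- mk_dem(c("p1", "p4"))
  dem2$residence_intervals[2] <- "1950-06-15/2017-06-30"
  dem2$residence[[2]] <- data.frame(start = as.Date("1950-06-15"),
                                    end = as.Date("2017-06-30"))
  trig2 <- rbind(qualify_hdr(mk_hdr("p1", "585.3")),
                 qualify_hdr(mk_hdr("p4", "585.3")))
  coh2 <- resolve_cohort(trig2, dem2, win)
  expect_equal(coh2$cases$person_id, "p1")
  expect_equal(coh2$counts$n_excluded_nonresident, 1L)
  # a qualified person missing from demographics is a linkage error
  expect_error(resolve_cohort(qualify_hdr(mk_hdr("zz", "585.3")), dem,
                              win), "zz")
})

test_that("source attribution matches a brute-force tally and partitions the cohort", {
  set.seed(99)
  srcs <- c("HDR", "TER", "OSSIS", "PHARM")
  for (trial in 1:20) {
    sets <- replicate(80, paste(sort(sample(srcs, sample(1:4, 1))),
                                collapse = ";"))
    cases <- data.frame(person_id = sprintf("p%02d", 1:80),
                        sources = sets, stringsAsFactors = FALSE)
    tab <- attribute_sources(cases)
    # brute force
    excl <- sapply(srcs, function(s) sum(sets == s))
    expect_equal(setNames(tab$exclusive_count, tab$source), excl[srcs],
                 ignore_attr = TRUE)
    expect_equal(attr(tab, "all_sources_count"),
                 sum(sets == "HDR;OSSIS;PHARM;TER"))
    # partition: exclusive + multi-source = total
    expect_equal(sum(tab$exclusive_count) +
                   attr(tab, "multi_source_count"), 80L)
  }
  # every case multi-source -> all exclusive counts zero
  allmulti <- data.frame(person_id = c("a", "b"),
                         sources = c("HDR;TER", "OSSIS;PHARM"))
  expect_true(all(attribute_sources(allmulti)$exclusive_count == 0L))
  # empty case list -> all-zero table
  none <- attribute_sources(data.frame(person_id = character(0),
                                       sources = character(0)))
  expect_true(all(none$exclusive_count == 0L))
  expect_equal(attr(none, "total"), 0L)
})

test_that("removing a non-qualifying record never changes the cohort", {
  dem <- mk_dem(c("p1", "p2"))
  base <- mk_bundle(dem, hdr = mk_hdr("p1", "585.3"))
  with_noise <- base
  with_noise$hdr <- rbind(with_noise$hdr, mk_hdr("p2", "401.9"))
  with_noise$pharm <- mk_pharm("p2", "C09AA05")
  with_noise$ossis <- mk_ossis("p2", "89.7")
  c1 <- identify_cases(base)
  c2 <- identify_cases(with_noise)
  expect_identical(c1$cases, c2$cases)
})

test_that("the confirmation-only drug rule removes standalone PHARM cases", {
  dem <- mk_dem(c("p1", "p2"))
  reg <- mk_bundle(dem, ossis = mk_ossis("p2", "89.7"),
                   pharm = rbind(mk_pharm("p1"), mk_pharm("p2")))
  default <- identify_cases(reg)
  expect_setequal(default$cases$person_id, c("p1", "p2"))
  strict <- identify_cases(reg, ossis_rule = "confirmation_only")
  # p1 has a drug but no visit: not a case under the strict parse
  expect_equal(strict$cases$person_id, "p2")
  expect_equal(strict$cases$sources, "OSSIS;PHARM")
})
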