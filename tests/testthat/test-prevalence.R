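test_that("completed age handles birthday boundaries and agrees with a day-count oracle", {
  ref <- as.Date("2017-12-31")
  expect_equal(age_at(as.Date("1932-12-31"), ref), 85L)
  expect_equal(age_at(as.Date("1933-01-01"), ref), 84L)
  expect_equal(age_at(ref, ref), 0L)
  expect_error(age_at(as.Date("2018-01-01"), ref), "after")
  # oracle: walk birthdays one year at a time
  oracle_age <- function(b, r) {
    a <- 0L
    repeat {
      nxt <- seq(b, by = "1 year", length.out = a + 2L)[a + 2L]
      if (nxt > r) return(a)
      a <- a + 1L
    }
  }
  set.seed(31)
  births <- as.Date("1920-01-01") + sample(0:35000, 60)
  refs <- as.Date("2017-12-31") - sample(0:2000, 60)
  keep <- births <= refs
  for (i in which(keep))
    expect_equal(age_at(births[i], refs[i]),
                 oracle_age(births[i], refs[i]))
})

test_that("crude rates and Wald intervals reproduce the published totals", {
  r <- crude_rate(99457, 5636510)
  expect_equal(round_half_up(r$rate, 2), 1.76)
  expect_equal(round_half_up(r$ci_low, 2), 1.75)
  expect_equal(round_half_up(r$ci_high, 2), 1.78)
  expect_equal(round_half_up(crude_rate(1604, 490339)$rate, 2), 0.33)
  expect_equal(crude_rate(0, 1000)$rate, 0)
  expect_error(crude_rate(5, 0), "positive")
  expect_error(crude_rate(11, 10), "population")
  # CI width shrinks as 1/sqrt(N) at fixed rate
  w <- function(n) {
    e <- crude_rate(round(0.02 * n), n)
    e$ci_high - e$ci_low
  }
  expect_true(w(1e4) > w(1e5))
  expect_equal(w(1e4) / w(1e6), 10, tolerance = 0.01)
  # Clopper-Pearson stays in [0, 100] and covers the point estimate
  cp <- crude_rate(2, 50, ci_method = "clopper-pearson")
  expect_true(cp$ci_low >= 0 && cp$ci_low <= cp$rate)
  expect_true(cp$ci_high >= cp$rate)
})

test_that("the full published stratum grid is reproduced, rates, CIs and ratios", {
  tab <- prevalence_table(table2_fixture())
  cell <- function(ac, sx) tab[tab$age_class == ac & tab$sex == sx, ]
  r2 <- function(x) round_half_up(x, 2)
  # printed per-sex cells: rate, lower, upper
  printed <- list(
    list("0-18", "male", 0.33, 0.31, 0.34),
    list("0-18", "female", 0.25, 0.24, 0.27),
    list("19-44", "male", 0.33, 0.32, 0.34),
    list("19-44", "female", 0.29, 0.28, 0.30),
    list("45-64", "male", 1.27, 1.25, 1.30),
    list("45-64", "female", 0.82, 0.80, 0.83),
    list("65-74", "male", 4.73, 4.65, 4.81),
    list("65-74", "female", 2.59, 2.54, 2.65),
    list("75-84", "male", 9.88, 9.74, 10.01),
    list("75-84", "female", 5.58, 5.50, 5.67),
    list("85+", "male", 14.18, 13.90, 14.46),
    list("85+", "female", 8.18, 8.03, 8.33),
    list("total", "male", 2.06, 2.04, 2.07),
    list("total", "female", 1.50, 1.48, 1.51))
  for (p in printed) {
    cl <- cell(p[[1]], p[[2]])
    expect_equal(r2(cl$rate), p[[3]], info = paste(p[[1]], p[[2]]))
    expect_equal(r2(cl$ci_low), p[[4]], info = paste(p[[1]], p[[2]]))
    expect_equal(r2(cl$ci_high), p[[5]], info = paste(p[[1]], p[[2]]))
  }
  # total column rates and the M/F ratio column
  totals <- list(list("0-18", 0.29, 1.30), list("19-44", 0.31, 1.14),
                 list("45-64", 1.03, 1.56), list("65-74", 3.58, 1.83),
                 list("75-84", 7.41, 1.77), list("85+", 10.15, 1.73),
                 list("total", 1.76, 1.37))
  for (p in totals) {
    cl <- cell(p[[1]], "total")
    expect_equal(r2(cl$rate), p[[2]], info = p[[1]])
    expect_equal(cl$rate_mf, p[[3]], info = p[[1]])
  }
  # row-sum property: margins equal the sums of their strata
  expect_equal(cell("total", "total")$cases, 99457)
  expect_equal(cell("total", "total")$population, 5636510)
  expect_equal(cell("total", "male")$population, 2700241)
  expect_equal(sum(tab$cases[tab$sex != "total" &
                               tab$age_class != "total"]), 99457)
})

test_that("person-level stratified rates agree with a per-person tally oracle", {
  sim <- generate_registries(sim_config(n_persons = 600, seed = 17))
  coh <- identify_cases(sim$registries)
  tab <- stratified_rates(coh, sim$registries$demographics)
  dem <- sim$registries$demographics
  pd <- as.Date("2017-12-31")
  # oracle: per-person loop
  for (sx in c("male", "female")) {
    for (i in seq_len(nrow(default_age_classes()))) {
      cls <- default_age_classes()[i, ]
      npop <- 0L; ncase <- 0L
      for (j in seq_len(nrow(dem))) {
        if (dem$sex[j] != sx) next
        alive <- is.na(dem$death_date[j]) || dem$death_date[j] > pd
        if (!alive || !resident_at(dem[j, , drop = FALSE], pd)) next
        a <- age_at(dem$birth_date[j], pd)
        if (a < cls$low || a > cls$high) next
        npop <- npop + 1L
        if (dem$person_id[j] %in% coh$cases$person_id)
          ncase <- ncase + 1L
      }
      cl <- tab[tab$age_class == cls$label & tab$sex == sx, ]
      expect_equal(cl$population, npop, info = paste(cls$label, sx))
      expect_equal(cl$cases, ncase, info = paste(cls$label, sx))
    }
  }
  # a case person missing from demographics is an error
  bad <- coh
  bad$cases <- rbind(bad$cases[1, ], bad$cases[1, ])
  bad$cases$person_id[2] <- "ghost"
  expect_error(stratified_rates(bad$cases, dem, prevalence_date = pd),
               "ghost")
})

test_that("direct standardization: identity, single stratum, hand-computed example", {
  t2 <- table2_fixture()
  m <- t2[t2$sex == "male", ]
  # weights proportional to the study population reproduce the crude rate
  std <- direct_standardized_rate(m$cases, m$population, m$population)
  crude <- 100 * sum(m$cases) / sum(m$population)
  expect_equal(std$rate, crude, tolerance = 1e-12)
  # single stratum equals that stratum's rate
  one <- direct_standardized_rate(50, 1000, 7)
  expect_equal(one$rate, 5)
  # two strata at 1% and 3%, weights 0.25/0.75 -> 2.5%
  two <- direct_standardized_rate(c(10, 30), c(1000, 1000),
                                  c(0.25, 0.75))
  expect_equal(two$rate, 2.5)
  # gamma interval exists and brackets the estimate
  g <- direct_standardized_rate(c(2, 5), c(400, 900), c(1, 3),
                                ci_method = "gamma")
  expect_true(g$ci_low < g$rate && g$rate < g$ci_high)
  expect_error(direct_standardized_rate(1, 0, 1), "zero-population")
})

test_that("rate ratios reproduce the published male:female column", {
  expect_equal(rate_ratio(2.06, 1.50), 1.37)
  expect_equal(rate_ratio(2.35, 1.39), 1.69)
  expect_equal(rate_ratio(1, 1), 1)
  expect_error(rate_ratio(1, 0), "positive")
})
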