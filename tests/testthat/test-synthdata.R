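prob_grid <- function(p) data.frame(
  age_class = rep(default_age_classes()$label, 2),
  sex = rep(c("male", "female"), each = 6), prob = p)

test_that("generation is deterministic given the seed", {
  a <- generate_registries(sim_config(n_persons = 300, seed = 77))
  b <- generate_registries(sim_config(n_persons = 300, seed = 77))
  expect_identical(a$truth, b$truth)
  for (k in names(a$registries))
    expect_identical(as.data.frame(a$registries[[k]]),
                     as.data.frame(b$registries[[k]]))
  c <- generate_registries(sim_config(n_persons = 300, seed = 78))
  expect_false(identical(a$truth$is_case, c$truth$is_case))
})

test_that("adding persons never reshuffles existing ones (stable substreams)", {
  small <- generate_registries(sim_config(n_persons = 150, seed = 13))
  big <- generate_registries(sim_config(n_persons = 220, seed = 13))
  expect_identical(small$truth, big$truth[1:150, ])
  ids <- small$truth$person_id
  for (k in c("hdr", "ter", "ossis", "pharm", "ldr")) {
    sub <- big$registries[[k]]
    sub <- sub[sub$person_id %in% ids, , drop = FALSE]
    rownames(sub) <- NULL
    expect_equal(as.data.frame(sub),
                 as.data.frame(small$registries[[k]]),
                 ignore_attr = TRUE)
  }
})

test_that("generated registries always satisfy the schema invariants", {
  sim <- generate_registries(sim_config(
    n_persons = 400, seed = 3,
    prevalence_by_stratum = prob_grid(0.3), dialysis_fraction = 0.5,
    noise = list(acute_renal_rate = 0.1, single_visit_rate = 0.1,
                 death_rate = 0.1, emigration_rate = 0.1,
                 background_rate = 0.1)))
  for (k in names(sim$registries))
    expect_no_error(as_registry(as.data.frame(sim$registries[[k]]), k))
})

test_that("the noise-free pipeline recovers planted cases, severity and dialysis exactly", {
  cfg <- sim_config(n_persons = 1000, seed = 41,
                    prevalence_by_stratum = prob_grid(0.25),
                    higher_severity_fraction = 0.2,
                    dialysis_fraction = 0.3)
  sim <- generate_registries(cfg)
  coh <- identify_cases(sim$registries)
  tr <- sim$truth
  planted <- sort(tr$person_id[tr$is_case])
  expect_identical(coh$cases$person_id, planted)
  m <- match(coh$cases$person_id, tr$person_id)
  expect_identical(coh$cases$severity, tr$severity[m])
  expect_identical(algorithm_dialysis_set(coh),
                   sort(tr$person_id[tr$on_dialysis]))
  # planted higher-severity share is recovered up to rounding of the
  # Bernoulli draw (exact against the generator's own bookkeeping)
  s <- severity_summary(coh)
  expect_equal(s$n_higher[s$group == "overall"],
               sum(tr$severity == "higher", na.rm = TRUE))
  expect_lt(abs(s$higher_share[s$group == "overall"] - 20), 5)
})

test_that("exclusion-channel noise never creates cases; deaths and emigrations drop exactly", {
  base_cfg <- sim_config(n_persons = 600, seed = 19,
                         prevalence_by_stratum = prob_grid(0.2))
  base <- generate_registries(base_cfg)
  base_cases <- identify_cases(base$registries)$cases$person_id

  # acute-renal-failure admissions are absorbed by the exclusion rule
  noisy_cfg <- sim_config(n_persons = 600, seed = 19,
                          prevalence_by_stratum = prob_grid(0.2),
                          noise = list(acute_renal_rate = 0.15,
                                       single_visit_rate = 0.15,
                                       background_rate = 0.15))
  noisy <- generate_registries(noisy_cfg)
  expect_gt(nrow(noisy$registries$hdr), nrow(base$registries$hdr))
  expect_identical(identify_cases(noisy$registries)$cases$person_id,
                   base_cases)

  # killed/emigrated planted cases always drop, by exact bookkeeping
  excl_cfg <- sim_config(n_persons = 600, seed = 19,
                         prevalence_by_stratum = prob_grid(0.2),
                         noise = list(death_rate = 0.15,
                                      emigration_rate = 0.15))
  excl <- generate_registries(excl_cfg)
  tr <- excl$truth
  expect_gt(sum(tr$excluded_reason != "none"), 0)
  coh <- identify_cases(excl$registries)
  surviving <- sort(tr$person_id[tr$is_case &
                                   tr$excluded_reason == "none"])
  expect_identical(coh$cases$person_id, surviving)
  expect_equal(length(base_cases) - nrow(coh$cases),
               sum(tr$excluded_reason != "none"))

  # all channels off returns the base bundle unchanged
  same <- apply_noise(base, base_cfg)
  expect_identical(same$truth, base$truth)
  expect_identical(same$registries, base$registries)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_persons = 0), "positive")
  expect_error(sim_config(prevalence_by_stratum = prob_grid(1.5)),
               "probabilities")
  expect_error(sim_config(higher_severity_fraction = -0.1),
               "probabilities")
  expect_error(sim_config(noise = list(bogus_rate = 0.5)), "bogus_rate")
  expect_error(sim_config(source_profile = c(HDR = 0, TER = 0,
                                             OSSIS = 0, PHARM = 1)),
               "positive emission")
})

test_that("the published stratum fixture is internally consistent", {
  t2 <- table2_fixture()
  expect_equal(sum(t2$cases), 99457)
  expect_equal(sum(t2$population), 5636510)
  expect_equal(sum(t2$cases[t2$sex == "male"]), 55532)
  expect_equal(sum(t2$population[t2$sex == "male"]), 2700241)
  expect_equal(sum(t2$cases[t2$sex == "female"]), 43925)
  expect_equal(t2$cases[t2$age_class == "85+" & t2$sex == "male"], 8578)
  expect_equal(t2$population[t2$age_class == "85+" & t2$sex == "male"],
               60502)
  # contribution fixture sums stay below the totals
  fx <- contribution_fixture()
  expect_lt(sum(fx$overall$exclusive), fx$overall$total)
  expect_lt(sum(fx$higher$exclusive), fx$higher$total)
  # reconstructed case table reproduces both accountings
  rc <- reconstruct_cases()
  expect_equal(nrow(rc), fx$overall$total)
  expect_equal(sum(rc$severity == "higher"), fx$higher$total)
})
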