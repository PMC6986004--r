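# Synthetic-registry generator. Real regional registries cannot be
# redistributed (person-level data are withheld under privacy law), so
# every pipeline stage is exercised on generated registries with planted
# ground truth: who is a case, their severity, who is on dialysis, and
# who is legitimately excluded (death/emigration). Noise channels inject
# the record patterns the algorithm must reject or survive.

#' Simulation configuration
#'
#' Defaults are fixed to the study conditions: the age/sex structure and
#' per-stratum case probabilities default to the published regional
#' population margins ([table2_fixture()]), the higher-severity fraction
#' to 21.3% of cases, and a quarter of higher-severity cases are on
#' dialysis. The source-emission profile gives each case an independent
#' chance of leaving qualifying traces in each registry (PHARM only for
#' higher-severity cases, since a listed-drug dispensing is itself a
#' higher-severity criterion), producing a multi-source mixture with
#' single-source and all-source cases. All noise channels default to 0:
#' the base output is noise-free.
#'
#' Noise rates (all per eligible person, Bernoulli):
#' \describe{
#'   \item{acute_renal_rate}{non-cases get a hospitalization with only a
#'     dialysis procedure (39.95) and an acute-renal-failure diagnosis
#'     (584.X) — the pattern the exclusion rule must eliminate.}
#'   \item{single_visit_rate}{non-cases get one unconfirmed nephrology
#'     visit (below every OSSIS threshold).}
#'   \item{death_rate, emigration_rate}{planted cases die before / leave
#'     the region before the prevalence date (legitimate exclusions;
#'     ground truth flags `excluded_reason`).}
#'   \item{background_rate}{anyone can get records with non-listed codes
#'     (hypertension admissions, ACE-inhibitor dispensings).}
#'   \item{dialysis_fp_rate}{surviving non-dialysis cases get a dialysis
#'     outpatient service without a registry entry (algorithm false
#'     positives; flagged `dialysis_fp` in ground truth).}
#'   \item{dialysis_fn_rate}{dialysis cases have their detectable
#'     dialysis records withheld (registry entry kept, two nephrology
#'     visits added so the person still qualifies; flagged
#'     `dialysis_fn`).}
#' }
#'
#' @param n_persons number of persons to simulate.
#' @param seed integer seed; the output is a pure function of the config.
#' @param age_sex_structure data frame `age_class`, `sex`, `weight`
#'   (sampling weights for the 12 strata).
#' @param prevalence_by_stratum data frame `age_class`, `sex`, `prob`
#'   (probability a person in that stratum is a planted case).
#' @param higher_severity_fraction probability a case is higher severity.
#' @param dialysis_fraction probability a higher-severity case is on
#'   chronic dialysis.
#' @param source_profile named probabilities `HDR`, `TER`, `OSSIS`,
#'   `PHARM` of a case emitting qualifying records in each source.
#' @param noise named list of channel rates (see above).
#' @param window a `study_window`.
#' @return a validated config list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 2000, seed = 1,
                       age_sex_structure = NULL,
                       prevalence_by_stratum = NULL,
                       higher_severity_fraction = 0.213,
                       dialysis_fraction = 0.25,
                       source_profile = c(HDR = 0.55, TER = 0.25,
                                          OSSIS = 0.65, PHARM = 0.45),
                       noise = list(), window = study_window()) {
  t2 <- table2_fixture()
  if (is.null(age_sex_structure))
    age_sex_structure <- data.frame(age_class = t2$age_class,
                                    sex = t2$sex,
                                    weight = t2$population,
                                    stringsAsFactors = FALSE)
  if (is.null(prevalence_by_stratum))
    prevalence_by_stratum <- data.frame(age_class = t2$age_class,
                                        sex = t2$sex,
                                        prob = t2$cases / t2$population,
                                        stringsAsFactors = FALSE)
  default_noise <- list(acute_renal_rate = 0, single_visit_rate = 0,
                        death_rate = 0, emigration_rate = 0,
                        background_rate = 0, dialysis_fp_rate = 0,
                        dialysis_fn_rate = 0)
  unknown <- setdiff(names(noise), names(default_noise))
  if (length(unknown))
    stop("unknown noise channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  noise <- utils::modifyList(default_noise, noise)
  probs <- c(unlist(noise), higher_severity_fraction, dialysis_fraction,
             source_profile, prevalence_by_stratum$prob)
  if (n_persons <= 0) stop("n_persons must be positive", call. = FALSE)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (sum(source_profile[c("HDR", "TER", "OSSIS")]) <= 0)
    stop("at least one of HDR/TER/OSSIS must have positive emission ",
         "probability", call. = FALSE)
  structure(list(n_persons = as.integer(n_persons),
                 seed = as.integer(seed),
                 age_sex_structure = age_sex_structure,
                 prevalence_by_stratum = prevalence_by_stratum,
                 higher_severity_fraction = higher_severity_fraction,
                 dialysis_fraction = dialysis_fraction,
                 source_profile = source_profile,
                 noise = noise, window = window),
            class = "sim_config")
}

# stable per-person substream: person i's records depend on (seed, i)
# only, so growing n_persons never reshuffles existing persons
.person_seed <- function(seed, i) {
  as.integer((as.numeric(seed %% 1048573L) * 2039L + i * 7919L) %%
               2147483647L) + 1L
}

.rand_day <- function(window, n = 1L) {
  span <- as.integer(window$end - window$start)
  window$start + sample.int(span + 1L, n, replace = n > 1L) - 1L
}

#' Generate synthetic registries with planted ground truth
#'
#' Deterministic given the config (per-person substreams keyed on the
#' seed). Every planted surviving case emits at least one record pattern
#' that satisfies the ascertainment rules in its selected sources; every
#' non-case emits nothing in the base output (noise channels add
#' non-qualifying or exclusion-trapped records); dialysis cases emit a
#' dialysis-registry row plus detectable dialysis evidence. With all
#' noise channels at 0 the pipeline recovers the planted case set,
#' severity labels and dialysis set exactly.
#'
#' @param config a [sim_config()].
#' @return list with `registries` (named list demographics/hdr/ter/ossis/
#'   pharm/ldr, all schema-validated) and `truth` (person_id, sex,
#'   birth_date, is_case, severity, on_dialysis, sources,
#'   excluded_reason, dialysis_fp, dialysis_fn).
#' @export
generate_registries <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  win <- config$window
  pd <- win$prevalence_date
  classes <- default_age_classes()
  struct <- config$age_sex_structure
  prev <- config$prevalence_by_stratum
  prev_key <- paste(prev$age_class, prev$sex)
  cls_idx <- match(struct$age_class, classes$label)

  n <- config$n_persons
  ids <- sprintf("P%06d", seq_len(n))
  sex <- character(n); birth <- rep(pd, n)
  is_case <- logical(n); severity <- rep(NA_character_, n)
  on_dial <- logical(n); sources <- character(n)

  hdr <- list(); ter <- list(); ossis <- list(); pharm <- list()
  ldr <- list()
  add <- function(store, row) c(store, list(row))

  for (i in seq_len(n)) {
    set.seed(.person_seed(config$seed, i))
    k <- sample.int(nrow(struct), 1L, prob = struct$weight)
    sex[i] <- struct$sex[k]
    lo <- classes$low[cls_idx[k]]
    hi <- min(classes$high[cls_idx[k]], 99)
    age <- sample(lo:hi, 1L)
    birth[i] <- pd - (365L * age + sample(0:364, 1L))
    p_case <- prev$prob[match(paste(struct$age_class[k], sex[i]),
                              prev_key)]
    is_case[i] <- stats::runif(1) < p_case
    if (!is_case[i]) next

    hs <- stats::runif(1) < config$higher_severity_fraction
    severity[i] <- if (hs) "higher" else "lower"
    on_dial[i] <- hs && stats::runif(1) < config$dialysis_fraction

    prof <- config$source_profile
    src <- logical(4); names(src) <- c("HDR", "TER", "OSSIS", "PHARM")
    for (try in 1:50) {
      src[] <- stats::runif(4) < prof[names(src)]
      if (!hs) src["PHARM"] <- FALSE
      if (any(src)) break
    }
    if (!any(src)) src["OSSIS"] <- TRUE
    if (on_dial[i]) src["OSSIS"] <- TRUE
    # a higher-severity non-dialysis case needs detectable severity
    # evidence: an advanced-stage admission or a listed drug
    if (hs && !on_dial[i] && !src["HDR"] && !src["PHARM"])
      src["PHARM"] <- TRUE

    if (src["HDR"]) {
      d <- .rand_day(win)
      adm <- max(win$start, d - sample(0:10, 1L))
      dx <- if (hs && !on_dial[i]) "585.4"
            else if (on_dial[i]) "585.6" else "585.3"
      hdr <- add(hdr, data.frame(
        person_id = ids[i], admission_date = adm, discharge_date = d,
        diagnoses = paste(dx, "401.9", sep = ";"),
        procedures = if (on_dial[i]) "39.95" else "",
        service_codes = "", stringsAsFactors = FALSE))
    }
    if (src["TER"]) {
      ter <- add(ter, data.frame(
        person_id = ids[i], code = "025.585",
        start_date = .rand_day(win), end_date = as.Date(NA),
        stringsAsFactors = FALSE))
    }
    if (src["OSSIS"]) {
      if (on_dial[i]) {
        ossis <- add(ossis, data.frame(
          person_id = ids[i], service_date = .rand_day(win),
          service_code = "39.95.1", branch = "",
          stringsAsFactors = FALSE))
      } else {
        d1 <- .rand_day(win)
        d2 <- d1 + if (d1 < win$end) sample.int(
          as.integer(win$end - d1), 1L) else -1L
        ossis <- add(ossis, data.frame(
          person_id = rep(ids[i], 2L), service_date = c(d1, d2),
          service_code = c("89.7", "89.01"), branch = "29",
          stringsAsFactors = FALSE))
      }
    }
    if (src["PHARM"]) {
      pharm <- add(pharm, data.frame(
        person_id = ids[i], dispensing_date = .rand_day(win),
        atc = sample(c("B03XA01", "B03XA02", "V03AE02"), 1L),
        stringsAsFactors = FALSE))
    }
    if (on_dial[i]) {
      ldr <- add(ldr, data.frame(
        person_id = ids[i], start_date = .rand_day(win),
        modality = sample(c("hemodialysis", "peritoneal"), 1L,
                          prob = c(0.8, 0.2)),
        stringsAsFactors = FALSE))
    }
    sources[i] <- paste(names(src)[src], collapse = ";")
  }

  bind <- function(lst, kind) {
    schema <- .registry_schemas[[kind]]
    if (length(lst) == 0L) {
      df <- as.data.frame(stats::setNames(
        replicate(length(schema), character(0), simplify = FALSE),
        schema), stringsAsFactors = FALSE)
    } else df <- do.call(rbind, c(lst, list(make.row.names = FALSE)))
    as_registry(df, kind)
  }
  demographics <- as_registry(data.frame(
    person_id = ids, sex = sex, birth_date = birth,
    death_date = as.Date(NA),
    residence_intervals = paste0(.fmt_date(birth), "/"),
    stringsAsFactors = FALSE), "demographics")
  truth <- data.frame(person_id = ids, sex = sex, birth_date = birth,
                      is_case = is_case, severity = severity,
                      on_dialysis = on_dial, sources = sources,
                      excluded_reason = "none", dialysis_fp = FALSE,
                      dialysis_fn = FALSE, stringsAsFactors = FALSE)
  sim <- list(registries = list(demographics = demographics,
                                hdr = bind(hdr, "hdr"),
                                ter = bind(ter, "ter"),
                                ossis = bind(ossis, "ossis"),
                                pharm = bind(pharm, "pharm"),
                                ldr = bind(ldr, "ldr")),
              truth = truth, config = config)
  apply_noise(sim, config)
}

#' Inject noise channels into a generated bundle
#'
#' Perturbs a base bundle according to the config's noise rates (see
#' [sim_config()]); ground truth is updated so that legitimately
#' excluded persons carry their `excluded_reason` and planted
#' false-positive/negative dialysis perturbations are flagged. With all
#' rates at zero the input is returned unchanged. Called by
#' [generate_registries()]; exposed for layering noise onto an existing
#' base.
#'
#' @param sim a bundle from [generate_registries()].
#' @param config a [sim_config()] supplying the noise rates and seed.
#' @return a bundle of the same shape.
#' @export
apply_noise <- function(sim, config = sim$config) {
  noise <- config$noise
  if (all(unlist(noise) == 0)) return(sim)
  reg <- sim$registries
  truth <- sim$truth
  win <- config$window
  n <- nrow(truth)
  pick <- function(eligible, rate, offset) {
    set.seed(.person_seed(config$seed, n + offset))
    which(eligible & stats::runif(n) < rate)
  }
  span <- as.integer(win$end - win$start)
  mid_day <- function(idx) {
    # deterministic in-window day strictly before the prevalence date
    win$start + (.person_seed(config$seed, idx) %% (span - 1L))
  }

  case_alive <- truth$is_case & truth$excluded_reason == "none"
  died <- pick(case_alive, noise$death_rate, 1L)
  if (length(died)) {
    i <- match(truth$person_id[died], reg$demographics$person_id)
    # death cannot precede birth (children born inside the window)
    d <- pmax(mid_day(died), reg$demographics$birth_date[i])
    reg$demographics$death_date[i] <- d
    truth$excluded_reason[died] <- "death"
  }
  still <- truth$is_case & truth$excluded_reason == "none"
  moved <- pick(still, noise$emigration_rate, 2L)
  if (length(moved)) {
    d <- mid_day(moved)
    i <- match(truth$person_id[moved], reg$demographics$person_id)
    for (k in seq_along(i)) {
      iv <- reg$demographics$residence[[i[k]]]
      iv$end[nrow(iv)] <- d[k]
      reg$demographics$residence[[i[k]]] <- iv
      reg$demographics$residence_intervals[i[k]] <- .fmt_intervals(iv)
    }
    truth$excluded_reason[moved] <- "emigration"
  }

  acute <- pick(!truth$is_case, noise$acute_renal_rate, 3L)
  if (length(acute)) {
    d <- mid_day(acute)
    reg$hdr <- rbind(reg$hdr, as_registry(data.frame(
      person_id = truth$person_id[acute], admission_date = d - 3L,
      discharge_date = d, diagnoses = "584.9;401.9",
      procedures = "39.95", service_codes = "",
      stringsAsFactors = FALSE), "hdr"))
  }
  lone <- pick(!truth$is_case, noise$single_visit_rate, 4L)
  if (length(lone)) {
    reg$ossis <- rbind(reg$ossis, as_registry(data.frame(
      person_id = truth$person_id[lone], service_date = mid_day(lone),
      service_code = "89.7", branch = "29",
      stringsAsFactors = FALSE), "ossis"))
  }
  bg <- pick(rep(TRUE, n), noise$background_rate, 5L)
  if (length(bg)) {
    reg$pharm <- rbind(reg$pharm, as_registry(data.frame(
      person_id = truth$person_id[bg], dispensing_date = mid_day(bg),
      atc = "C09AA05", stringsAsFactors = FALSE), "pharm"))
  }

  fp_eligible <- truth$is_case & !truth$on_dialysis &
    truth$excluded_reason == "none"
  fp <- pick(fp_eligible, noise$dialysis_fp_rate, 6L)
  if (length(fp)) {
    reg$ossis <- rbind(reg$ossis, as_registry(data.frame(
      person_id = truth$person_id[fp], service_date = mid_day(fp),
      service_code = "39.95.1", branch = "",
      stringsAsFactors = FALSE), "ossis"))
    truth$dialysis_fp[fp] <- TRUE
  }
  fn_eligible <- truth$on_dialysis & truth$excluded_reason == "none"
  fn <- pick(fn_eligible, noise$dialysis_fn_rate, 7L)
  if (length(fn)) {
    fid <- truth$person_id[fn]
    drop_ossis <- reg$ossis$person_id %in% fid &
      any_match(.norm(reg$ossis$service_code),
                default_catalog()$ossis_dialysis_services)
    reg$ossis <- reg$ossis[!drop_ossis, , drop = FALSE]
    hdr_rows <- which(reg$hdr$person_id %in% fid)
    if (length(hdr_rows))
      reg$hdr$procedures[hdr_rows] <- ""
    d <- mid_day(fn)
    reg$ossis <- rbind(reg$ossis, as_registry(data.frame(
      person_id = rep(fid, 2L),
      service_date = c(d, pmin(d + 30L, win$end)),
      service_code = rep(c("89.7", "89.01"), each = length(fn)),
      branch = "29", stringsAsFactors = FALSE), "ossis"))
    truth$dialysis_fn[fn] <- TRUE
  }
  for (k in names(reg)) {
    rownames(reg[[k]]) <- NULL
    attr(reg[[k]], "registry_kind") <- k
  }
  list(registries = reg, truth = truth, config = config)
}

#' Write a generated bundle to disk
#'
#' Emits the six registry CSVs plus `ground_truth.csv` into a directory.
#'
#' @param sim a bundle from [generate_registries()].
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_bundle <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(demographics = "demographics.csv", hdr = "hdr.csv",
             ter = "ter.csv", ossis = "ossis.csv", pharm = "pharm.csv",
             ldr = "ldr.csv")
  for (k in names(files))
    write_registry(sim$registries[[k]], file.path(outdir, files[[k]]), k)
  truth <- sim$truth
  truth$birth_date <- .fmt_date(truth$birth_date)
  utils::write.csv(truth, file.path(outdir, "ground_truth.csv"),
                   row.names = FALSE, na = "")
  invisible(outdir)
}

#' Read a registry bundle from a directory
#'
#' Counterpart of [write_bundle()]: reads `demographics.csv`, `hdr.csv`,
#' `ter.csv`, `ossis.csv`, `pharm.csv` and, when present, `ldr.csv`.
#'
#' @param dir directory containing the CSVs.
#' @param lenient passed to [read_registry()].
#' @return named list of validated registry data frames.
#' @export
read_bundle <- function(dir, lenient = FALSE) {
  files <- c(demographics = "demographics.csv", hdr = "hdr.csv",
             ter = "ter.csv", ossis = "ossis.csv", pharm = "pharm.csv",
             ldr = "ldr.csv")
  out <- list()
  for (k in names(files)) {
    path <- file.path(dir, files[[k]])
    if (k == "ldr" && !file.exists(path)) next
    out[[k]] <- read_registry(path, k, lenient = lenient)
  }
  out
}
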