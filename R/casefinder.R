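# Case identification: per-source qualification rules over the selection
# window, the acute-renal-failure exclusion, cohort resolution at the
# prevalence date and source-contribution accounting.

#' Define the selection window
#'
#' The default window is the six calendar years 2012-01-01 to 2017-12-31
#' with the prevalence date at the window end: alive-and-resident status
#' on that single date defines the prevalent population.
#'
#' @param start,end first and last day of the selection window (inclusive).
#' @param prevalence_date the prevalence date; must equal `end`.
#' @return object of class `study_window` with fields `start`, `end`,
#'   `prevalence_date`.
#' @export
study_window <- function(start = "2012-01-01", end = "2017-12-31",
                         prevalence_date = end) {
  start <- as.Date(start); end <- as.Date(end)
  prevalence_date <- as.Date(prevalence_date)
  stopifnot(!is.na(start), !is.na(end), start <= end)
  if (prevalence_date != end)
    stop("prevalence_date must equal the window end", call. = FALSE)
  structure(list(start = start, end = end,
                 prevalence_date = prevalence_date),
            class = "study_window")
}

.in_window <- function(d, window) {
  !is.na(d) & d >= window$start & d <= window$end
}

.empty_triggers <- function() {
  data.frame(person_id = character(0), source = character(0),
             rule = character(0), date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

.trigger_frame <- function(person_id, source, rule, date) {
  if (length(person_id) == 0L) return(.empty_triggers())
  data.frame(person_id = person_id, source = source, rule = rule,
             date = as.Date(date), stringsAsFactors = FALSE)
}

# Per-record evaluation of the hospital rules, shared between
# qualification and severity classification. Returns row-aligned logical
# flags plus the normalized code lists.
.hdr_flags <- function(hdr, catalog, window) {
  dx <- lapply(.split_multi(hdr$diagnoses), .norm)
  pr <- lapply(.split_multi(hdr$procedures), .norm)
  sv <- lapply(.split_multi(hdr$service_codes), .norm)
  in_win <- .in_window(hdr$discharge_date, window)
  dx_hit <- vapply(dx, function(v) any(any_match(v, catalog$hdr_diagnoses)),
                   logical(1))
  pr_q <- lapply(pr, function(v) v[any_match(v, catalog$hdr_procedures)])
  proc_excl <- vapply(pr_q, function(v)
    any(v %in% catalog$exclusion_procedures), logical(1))
  proc_other <- vapply(pr_q, function(v)
    any(!v %in% catalog$exclusion_procedures), logical(1))
  svc_hit <- vapply(sv, function(v)
    any(any_match(v, catalog$hdr_complex_services)), logical(1))
  acute <- vapply(dx, function(v)
    any(any_match(v, catalog$acute_renal_dx)), logical(1))
  # "records selected only with procedures 39.95/38.95 and a 584.XX
  # diagnosis are eliminated": the exclusion bites only when those
  # procedures are the sole qualifying evidence on the record
  excluded <- in_win & proc_excl & acute & !(dx_hit | proc_other | svc_hit)
  qualifies <- in_win & !excluded &
    (dx_hit | proc_excl | proc_other | svc_hit)
  list(dx = dx, pr = pr, sv = sv, in_win = in_win, dx_hit = dx_hit,
       proc_hit = proc_excl | proc_other, svc_hit = svc_hit,
       excluded = excluded, qualifies = qualifies)
}

#' Hospital-discharge qualification (HDR)
#'
#' A hospitalization qualifies when any of its diagnoses (primary or
#' secondary) matches the HDR diagnosis list, or any procedure matches the
#' procedure list, or any complex-outpatient-package code matches, with
#' the discharge date inside the window. Exclusion rule: a record whose
#' only qualifying evidence is procedure 39.95 (hemodialysis) and/or 38.95
#' (venous catheterization for renal dialysis) *and* that carries an
#' acute-renal-failure diagnosis (584.XX) is eliminated, to avoid
#' selecting acute renal failure as CKD. The exclusion is per record: the
#' person still qualifies if any other record does.
#'
#' @param hdr hospital registry data frame.
#' @param catalog a `ckd_catalog`.
#' @param window a `study_window`.
#' @return trigger data frame (person_id, source, rule, date), one row per
#'   qualifying record.
#' @export
qualify_hdr <- function(hdr, catalog = default_catalog(),
                        window = study_window()) {
  if (nrow(hdr) == 0L) return(.empty_triggers())
  fl <- .hdr_flags(hdr, catalog, window)
  q <- which(fl$qualifies)
  rule <- ifelse(fl$dx_hit[q], "hdr_diagnosis",
          ifelse(fl$proc_hit[q], "hdr_procedure", "hdr_complex_service"))
  .trigger_frame(hdr$person_id[q], "HDR", rule, hdr$discharge_date[q])
}

#' Ticket-exemption qualification (TER)
#'
#' A person qualifies when an exemption for CKD (025.585) or kidney
#' transplantation (025.V42.0) is registered and active at the prevalence
#' date: start on or before it and either no end date or an end date
#' strictly after it.
#'
#' @inheritParams qualify_hdr
#' @param ter exemption registry data frame.
#' @return trigger data frame, one row per active qualifying exemption.
#' @export
qualify_ter <- function(ter, catalog = default_catalog(),
                        window = study_window()) {
  if (nrow(ter) == 0L) return(.empty_triggers())
  pd <- window$prevalence_date
  code <- .norm(ter$code)
  hit <- any_match(code, catalog$ter_codes) &
    !is.na(ter$start_date) & ter$start_date <= pd &
    (is.na(ter$end_date) | ter$end_date > pd)
  .trigger_frame(ter$person_id[hit], "TER", "ter_exemption",
                 ter$start_date[hit])
}

#' Outpatient-service qualification (OSSIS)
#'
#' A person gains an OSSIS trigger when, within the window, they have
#' (a) nephrology visits (codes 89.7, 89.01, 89.03 with specialty branch
#' 29) on at least two distinct dates, or (b) at least one nephrology
#' visit plus a urine-albumin measurement (90.33.4), or (c) at least one
#' nephrology visit plus a dispensing of a listed drug, or (d) — when
#' `dialysis_standalone` is `TRUE` — at least one dialysis-related
#' outpatient service, which needs no visit confirmation. Pathway (c)
#' also emits a PHARM trigger for the supporting dispensing.
#'
#' @inheritParams qualify_hdr
#' @param ossis outpatient registry data frame.
#' @param pharm drug-dispensing registry data frame (confirmation for
#'   pathway c).
#' @param dialysis_standalone should dialysis-related services qualify
#'   directly (default `TRUE`)?
#' @return trigger data frame, one row per satisfied pathway per person.
#' @export
qualify_ossis <- function(ossis, pharm, catalog = default_catalog(),
                          window = study_window(),
                          dialysis_standalone = TRUE) {
  if (nrow(ossis) == 0L) return(.empty_triggers())
  code <- .norm(ossis$service_code)
  in_win <- .in_window(ossis$service_date, window)
  branch <- ifelse(is.na(ossis$branch), "", .norm(ossis$branch))
  is_visit <- in_win & branch == catalog$ossis_visit_branch &
    code %in% catalog$ossis_visit_codes
  is_albumin <- in_win & any_match(code, catalog$ossis_albumin_code)
  is_dial <- in_win & any_match(code, catalog$ossis_dialysis_services)

  # distinct visit dates per person
  vis <- unique(data.frame(person_id = ossis$person_id[is_visit],
                           date = ossis$service_date[is_visit]))
  nvis <- table(vis$person_id)
  first_two <- tapply(vis$date, vis$person_id,
                      function(d) sort(d)[min(2L, length(d))])

  drug_ok <- .in_window(pharm$dispensing_date, window) &
    any_match(.norm(pharm$atc), catalog$pharm_atc)
  drug_persons <- unique(pharm$person_id[drug_ok])

  out <- list()
  two <- names(nvis)[nvis >= 2L]
  out$a <- .trigger_frame(two, "OSSIS", "ossis_two_visits",
                          as.Date(first_two[two],
                                  origin = "1970-01-01"))
  one <- names(nvis)[nvis >= 1L]
  alb_persons <- unique(ossis$person_id[is_albumin])
  b <- intersect(one, alb_persons)
  first_vis <- tapply(vis$date, vis$person_id, min)
  out$b <- .trigger_frame(b, "OSSIS", "ossis_visit_albumin",
                          as.Date(first_vis[b], origin = "1970-01-01"))
  cc <- intersect(one, drug_persons)
  out$c <- .trigger_frame(cc, "OSSIS", "ossis_visit_drug",
                          as.Date(first_vis[cc], origin = "1970-01-01"))
  if (length(cc)) {
    sup <- pharm[drug_ok & pharm$person_id %in% cc, , drop = FALSE]
    first_disp <- tapply(sup$dispensing_date, sup$person_id, min)
    out$c_pharm <- .trigger_frame(names(first_disp), "PHARM",
                                  "pharm_confirming",
                                  as.Date(first_disp,
                                          origin = "1970-01-01"))
  }
  if (dialysis_standalone && any(is_dial)) {
    first_dial <- tapply(ossis$service_date[is_dial],
                         ossis$person_id[is_dial], min)
    out$d <- .trigger_frame(names(first_dial), "OSSIS",
                            "ossis_dialysis_service",
                            as.Date(first_dial, origin = "1970-01-01"))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Drug-dispensing qualification (PHARM)
#'
#' A person qualifies with at least one dispensing of a listed drug
#' (erythropoiesis-stimulating agents or phosphate/potassium binders)
#' inside the window. Whether this pathway stands alone or only confirms
#' a nephrology visit is controlled at the [identify_cases()] level via
#' `ossis_rule`.
#'
#' @inheritParams qualify_ossis
#' @return trigger data frame, one row per qualifying person (earliest
#'   dispensing date).
#' @export
qualify_pharm <- function(pharm, catalog = default_catalog(),
                          window = study_window()) {
  if (nrow(pharm) == 0L) return(.empty_triggers())
  ok <- .in_window(pharm$dispensing_date, window) &
    any_match(.norm(pharm$atc), catalog$pharm_atc)
  if (!any(ok)) return(.empty_triggers())
  first <- tapply(pharm$dispensing_date[ok], pharm$person_id[ok], min)
  .trigger_frame(names(first), "PHARM", "pharm_dispensing",
                 as.Date(first, origin = "1970-01-01"))
}

#' Resolve the prevalent cohort
#'
#' Takes the union of qualified persons across sources and applies the
#' prevalence-date exclusions: persons who died during the period (death
#' on or before the prevalence date) and persons not resident in the
#' region at the prevalence date are removed. One case per surviving
#' person, with merged triggers; a qualified person absent from the
#' demographics registry is an error (broken linkage).
#'
#' @param triggers trigger data frame (rbind of the qualify_* outputs).
#' @param demographics demographics registry data frame.
#' @param window a `study_window`.
#' @return object of class `ckd_cohort`: list with `cases` (person_id,
#'   sex, birth_date, sources, n_triggers, severity), `triggers`, `window`
#'   and flow-chart stage `counts`.
#' @export
resolve_cohort <- function(triggers, demographics,
                           window = study_window()) {
  triggers <- unique(triggers)
  orphans <- setdiff(triggers$person_id, demographics$person_id)
  if (length(orphans))
    stop("qualified person(s) absent from demographics: ",
         paste(sort(orphans), collapse = ", "), call. = FALSE)
  pd <- window$prevalence_date
  qualified <- unique(triggers$person_id)
  idx <- match(qualified, demographics$person_id)
  dead <- !is.na(demographics$death_date[idx]) &
    demographics$death_date[idx] <= pd
  res <- resident_at(demographics[idx, , drop = FALSE], pd)
  keep <- qualified[!dead & res]
  n_dead <- sum(dead)
  n_nonres <- sum(!dead & !res)

  trig <- triggers[triggers$person_id %in% keep, , drop = FALSE]
  src <- tapply(trig$source, trig$person_id,
                function(s) paste(sort(unique(s)), collapse = ";"))
  ntr <- table(trig$person_id)
  ids <- sort(keep)
  di <- match(ids, demographics$person_id)
  cases <- data.frame(person_id = ids,
                      sex = demographics$sex[di],
                      birth_date = demographics$birth_date[di],
                      sources = as.character(src[ids]),
                      n_triggers = as.integer(ntr[ids]),
                      severity = NA_character_,
                      stringsAsFactors = FALSE)
  rownames(cases) <- NULL
  per_source <- tapply(triggers$person_id, triggers$source,
                       function(p) length(unique(p)))
  counts <- list(
    qualified_by_source = per_source,
    n_qualified = length(qualified),
    n_excluded_death = n_dead,
    n_excluded_nonresident = n_nonres,
    n_cases = nrow(cases))
  structure(list(cases = cases,
                 triggers = trig[order(trig$person_id, trig$source,
                                       trig$date), , drop = FALSE],
                 window = window, counts = counts),
            class = "ckd_cohort")
}

#' Identify prevalent CKD cases from the linked registries
#'
#' The main entry point: runs the four per-source qualification rules
#' over the selection window, unions qualified persons, applies the
#' death/residence exclusions at the prevalence date and (by default)
#' classifies each case's severity. `ossis_rule` selects the reading of
#' the drug pathway: `"with_standalone_pharm"` (default) lets a listed
#' drug dispensing qualify on its own, `"confirmation_only"` requires a
#' nephrology visit alongside it.
#'
#' @param registries named list with elements `demographics`, `hdr`,
#'   `ter`, `ossis`, `pharm` (and optionally `ldr`), as returned by
#'   [read_registry()] or [generate_registries()].
#' @param window a `study_window`.
#' @param catalog a `ckd_catalog`.
#' @param ossis_rule `"with_standalone_pharm"` or `"confirmation_only"`.
#' @param ossis_dialysis_standalone should OSSIS dialysis-related services
#'   qualify without visit confirmation?
#' @param severity classify severity on the way out (default `TRUE`)?
#' @return a `ckd_cohort` (see [resolve_cohort()]); with
#'   `severity = TRUE` the `cases$severity` column is filled and an
#'   `evidence` audit table attached.
#' @examples
#' sim <- generate_registries(sim_config(n_persons = 300, seed = 7))
#' coh <- identify_cases(sim$registries)
#' coh
#' @export
identify_cases <- function(registries, window = study_window(),
                           catalog = default_catalog(),
                           ossis_rule = c("with_standalone_pharm",
                                          "confirmation_only"),
                           ossis_dialysis_standalone = TRUE,
                           severity = TRUE) {
  ossis_rule <- match.arg(ossis_rule)
  .check_catalog(catalog)
  need <- c("demographics", "hdr", "ter", "ossis", "pharm")
  missing <- setdiff(need, names(registries))
  if (length(missing))
    stop("registries list is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  trig <- rbind(
    qualify_hdr(registries$hdr, catalog, window),
    qualify_ter(registries$ter, catalog, window),
    qualify_ossis(registries$ossis, registries$pharm, catalog, window,
                  dialysis_standalone = ossis_dialysis_standalone),
    if (ossis_rule == "with_standalone_pharm")
      qualify_pharm(registries$pharm, catalog, window)
    else .empty_triggers())
  cohort <- resolve_cohort(trig, registries$demographics, window)
  if (severity)
    cohort <- classify_severity(cohort, registries, catalog)
  cohort
}

#' Source-contribution accounting
#'
#' Quantifies each registry's unique yield: a case contributes
#' exclusively to source S when S is its only source. Also reports the
#' count and share of cases found in all four databases. Shares are
#' percentages of the total case count, rounded half-away-from-zero to
#' one decimal.
#'
#' @param cases a `ckd_cohort` or a data frame with a `sources` column
#'   (semicolon-joined source set per case).
#' @return a `contribution_table` data frame (source, exclusive_count,
#'   exclusive_share) with attributes `total`, `multi_source_count`,
#'   `all_sources_count`, `all_sources_share`.
#' @export
attribute_sources <- function(cases) {
  if (inherits(cases, "ckd_cohort")) cases <- cases$cases
  sources <- c("HDR", "TER", "OSSIS", "PHARM")
  total <- nrow(cases)
  sets <- strsplit(cases$sources, ";", fixed = TRUE)
  n_src <- lengths(sets)
  excl <- vapply(sources, function(s)
    sum(n_src == 1L & vapply(sets, `[`, character(1), 1L) == s),
    numeric(1))
  all4 <- sum(vapply(sets, function(s) all(sources %in% s), logical(1)))
  share <- function(k) if (total == 0L) 0 else
    round_half_up(100 * k / total, 1)
  out <- data.frame(source = sources,
                    exclusive_count = as.integer(excl),
                    exclusive_share = share(excl),
                    stringsAsFactors = FALSE)
  structure(out,
            total = total,
            multi_source_count = as.integer(sum(n_src > 1L)),
            all_sources_count = as.integer(all4),
            all_sources_share = share(all4),
            class = c("contribution_table", "data.frame"))
}

#' @export
print.contribution_table <- function(x, ...) {
  cat("Source contribution over", attr(x, "total"), "cases\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("multi-source: %d; all four databases: %d (%.1f%%)\n",
              attr(x, "multi_source_count"),
              attr(x, "all_sources_count"),
              attr(x, "all_sources_share")))
  invisible(x)
}

#' @export
print.ckd_cohort <- function(x, ...) {
  cat("CKD prevalent cohort:", nrow(x$cases), "cases at",
      format(x$window$prevalence_date), "\n")
  sev <- table(x$cases$severity, useNA = "no")
  if (length(sev))
    cat("severity:", paste(names(sev), sev, sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
summary.ckd_cohort <- function(object, ...) {
  ct <- object$counts
  cat("Selection flow\n")
  for (s in names(ct$qualified_by_source))
    cat(sprintf("  qualified via %-5s : %d\n", s,
                ct$qualified_by_source[[s]]))
  cat(sprintf("  union of sources   : %d\n", ct$n_qualified))
  cat(sprintf("  excluded, died     : %d\n", ct$n_excluded_death))
  cat(sprintf("  excluded, moved    : %d\n", ct$n_excluded_nonresident))
  cat(sprintf("  prevalent cases    : %d\n", ct$n_cases))
  print(attribute_sources(object))
  invisible(object)
}
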