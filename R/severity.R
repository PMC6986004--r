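# Severity stratification: higher-severity cases are those with dialysis
# or kidney-transplant evidence, a hospitalization coded CKD stage IV or
# greater, or at least one dispensing of a listed drug during the
# selection window; all other prevalent cases are lower severity.

.empty_evidence <- function() {
  data.frame(person_id = character(0), kind = character(0),
             source = character(0), date = as.Date(character(0)),
             stringsAsFactors = FALSE)
}

.evidence_frame <- function(person_id, kind, source, date) {
  if (length(person_id) == 0L) return(.empty_evidence())
  data.frame(person_id = person_id, kind = kind, source = source,
             date = as.Date(date), stringsAsFactors = FALSE)
}

# scan all registries for severity evidence among `persons`
.severity_evidence <- function(persons, registries, catalog, window) {
  ev <- list()
  hdr <- registries$hdr
  hdr <- hdr[hdr$person_id %in% persons, , drop = FALSE]
  if (nrow(hdr)) {
    fl <- .hdr_flags(hdr, catalog, window)
    # a record eliminated by the acute-failure exclusion no longer exists
    # for the algorithm: its dialysis procedures carry no evidence
    live <- fl$in_win & !fl$excluded
    dial <- live & vapply(fl$pr, function(v)
      any(any_match(v, catalog$dialysis_procedures)), logical(1))
    tx_proc <- live & vapply(fl$pr, function(v)
      any(any_match(v, catalog$transplant_procedures)), logical(1))
    tx_dx <- live & vapply(fl$dx, function(v)
      any(any_match(v, catalog$transplant_dx)), logical(1))
    tx_svc <- live & vapply(fl$sv, function(v)
      any(any_match(v, catalog$transplant_services)), logical(1))
    adv <- live & vapply(fl$dx, function(v)
      any(any_match(v, catalog$severity_dx)), logical(1))
    d <- hdr$discharge_date
    ev$hd <- .evidence_frame(hdr$person_id[dial], "dialysis", "HDR",
                             d[dial])
    tx <- tx_proc | tx_dx | tx_svc
    ev$ht <- .evidence_frame(hdr$person_id[tx], "transplant", "HDR",
                             d[tx])
    ev$ha <- .evidence_frame(hdr$person_id[adv], "advanced_stage_dx",
                             "HDR", d[adv])
  }
  ossis <- registries$ossis
  ossis <- ossis[ossis$person_id %in% persons, , drop = FALSE]
  if (nrow(ossis)) {
    dial <- .in_window(ossis$service_date, window) &
      any_match(.norm(ossis$service_code), catalog$ossis_dialysis_services)
    ev$od <- .evidence_frame(ossis$person_id[dial], "dialysis", "OSSIS",
                             ossis$service_date[dial])
  }
  ter <- registries$ter
  ter <- ter[ter$person_id %in% persons, , drop = FALSE]
  if (nrow(ter)) {
    pd <- window$prevalence_date
    tx <- .norm(ter$code) %in% catalog$transplant_ter &
      !is.na(ter$start_date) & ter$start_date <= pd &
      (is.na(ter$end_date) | ter$end_date > pd)
    ev$tt <- .evidence_frame(ter$person_id[tx], "transplant", "TER",
                             ter$start_date[tx])
  }
  pharm <- registries$pharm
  pharm <- pharm[pharm$person_id %in% persons, , drop = FALSE]
  if (nrow(pharm)) {
    drug <- .in_window(pharm$dispensing_date, window) &
      any_match(.norm(pharm$atc), catalog$pharm_atc)
    ev$dr <- .evidence_frame(pharm$person_id[drug], "severity_drug",
                             "PHARM", pharm$dispensing_date[drug])
  }
  out <- do.call(rbind, c(ev, list(make.row.names = FALSE)))
  if (is.null(out)) out <- .empty_evidence()
  out[order(out$person_id, out$kind, out$date), , drop = FALSE]
}

#' Classify case severity
#'
#' Fills the cohort's `severity` column: a case is *higher* severity when
#' within the selection window it has (i) dialysis evidence — a dialysis
#' or dialysis-access procedure on a non-eliminated hospital record, or a
#' dialysis-related outpatient service; (ii) transplant evidence —
#' procedure 55.6X, diagnosis V42.0, exemption 025.V42.0 or a transplant
#' assessment/follow-up package; (iii) a hospitalization with a CKD
#' stage IV+ diagnosis (585.4X/585.5X/585.6X); or (iv) at least one
#' dispensing of a listed drug. Everything else is *lower* severity.
#' Classification is idempotent and monotone in evidence: adding records
#' that carry no severity evidence can never flip higher to lower.
#'
#' @param cohort a `ckd_cohort`.
#' @param registries the registry bundle the cohort was identified from.
#' @param catalog a `ckd_catalog`.
#' @return the cohort with `cases$severity` in `{"higher","lower"}` and an
#'   `evidence` audit data frame (person_id, kind, source, date).
#' @export
classify_severity <- function(cohort, registries,
                              catalog = default_catalog()) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  persons <- cohort$cases$person_id
  ev <- .severity_evidence(persons, registries, catalog, cohort$window)
  cohort$cases$severity <-
    ifelse(persons %in% unique(ev$person_id), "higher", "lower")
  cohort$evidence <- ev
  cohort
}

#' Severity summary
#'
#' Counts and percentage shares of higher/lower severity cases, overall
#' and by sex. Shares are rounded half-away-from-zero to one decimal; the
#' lower share is computed directly (and equals 100 minus the higher
#' share up to rounding).
#'
#' @param cases a classified `ckd_cohort`, or a data frame with
#'   `severity` (and optionally `sex`) columns.
#' @return data frame with rows for each group (`overall`, and each sex
#'   present): n, n_higher, n_lower, higher_share, lower_share.
#' @export
severity_summary <- function(cases) {
  if (inherits(cases, "ckd_cohort")) cases <- cases$cases
  if (any(is.na(cases$severity)))
    stop("cases are not classified; run classify_severity() first",
         call. = FALSE)
  one <- function(df, label) {
    n <- nrow(df)
    nh <- sum(df$severity == "higher")
    data.frame(group = label, n = n, n_higher = nh, n_lower = n - nh,
               higher_share = if (n) round_half_up(100 * nh / n, 1) else 0,
               lower_share = if (n) round_half_up(100 * (n - nh) / n, 1)
                             else 0,
               stringsAsFactors = FALSE)
  }
  out <- one(cases, "overall")
  if (!is.null(cases$sex))
    for (s in sort(unique(cases$sex)))
      out <- rbind(out, one(cases[cases$sex == s, , drop = FALSE], s))
  rownames(out) <- NULL
  out
}
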