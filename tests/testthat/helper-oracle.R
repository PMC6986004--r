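# Independent naive oracle: re-evaluates the ascertainment, severity and
# dialysis rules person by person, record by record, using its own
# regex-based code matching and interval handling. Deliberately slow and
# simple; shares no evaluation code with the package.

o_norm <- function(x) toupper(gsub("[. ]", "", x))

o_split <- function(cell) {
  v <- strsplit(ifelse(is.na(cell), "", cell), ";", fixed = TRUE)[[1]]
  o_norm(v[nzchar(v)])
}

o_any <- function(codes, regexes) {
  if (length(codes) == 0L) return(FALSE)
  any(vapply(regexes, function(r) any(grepl(r, codes)), logical(1)))
}

o_dx_re <- c("^2504", "^403", "^404", "^582", "^583", "^585", "^586",
             "^587", "^588", "^7531", "^5900", "^V56", "^V420$")
o_proc_other_re <- c("^556", "^3927$", "^5493$", "^3942$", "^3943$",
                     "^5523$", "^5498$")
o_proc_excl <- c("3995", "3895")
o_svc_re <- c("^P583$", "^P585A$", "^P585B$", "^PV420$")
o_ter_re <- c("^025585$", "^025V420$")
o_visit <- c("897", "8901", "8903")
o_dialsvc_re <- c("^3995", "^5498", "^3895$", "^5493$", "^39991$",
                  "^9782$", "^97291$")
o_atc <- c("B03XA01", "B03XA02", "B03XA03", "V03AE01", "V03AE02",
           "V03AE03", "V03AE05")
o_dialproc <- c("3995", "5498", "3927", "5493", "3942", "3943", "3895")
o_sevdx_re <- c("^5854", "^5855", "^5856")

o_resident <- function(res_string, date) {
  if (is.na(res_string) || !nzchar(res_string)) return(FALSE)
  for (iv in strsplit(res_string, ";", fixed = TRUE)[[1]]) {
    p <- strsplit(iv, "/", fixed = TRUE)[[1]]
    start <- as.Date(p[1])
    end <- if (length(p) > 1L && nzchar(p[2])) as.Date(p[2]) else NA
    if (start <= date && (is.na(end) || date < end)) return(TRUE)
  }
  FALSE
}

# full re-evaluation; returns data.frame(person_id, sources, severity,
# dialysis) for the prevalent cohort, sorted by person_id
oracle_identify <- function(registries, window = study_window(),
                            standalone_pharm = TRUE,
                            dialysis_standalone = TRUE) {
  dem <- registries$demographics
  ws <- window$start; we <- window$end; pd <- window$prevalence_date
  in_win <- function(d) !is.na(d) && d >= ws && d <= we
  out <- list()
  for (i in seq_len(nrow(dem))) {
    p <- dem$person_id[i]
    hdr <- registries$hdr[registries$hdr$person_id == p, , drop = FALSE]
    ter <- registries$ter[registries$ter$person_id == p, , drop = FALSE]
    oss <- registries$ossis[registries$ossis$person_id == p, ,
                            drop = FALSE]
    pha <- registries$pharm[registries$pharm$person_id == p, ,
                            drop = FALSE]
    hdr_q <- FALSE
    dial <- FALSE; transplant <- FALSE; adv <- FALSE
    for (r in seq_len(nrow(hdr))) {
      if (!in_win(hdr$discharge_date[r])) next
      dx <- o_split(hdr$diagnoses[r])
      pr <- o_split(hdr$procedures[r])
      sv <- o_split(hdr$service_codes[r])
      q_other <- o_any(dx, o_dx_re) || o_any(pr, o_proc_other_re) ||
        o_any(sv, o_svc_re)
      has_excl_proc <- any(pr %in% o_proc_excl)
      acute <- o_any(dx, "^584")
      eliminated <- has_excl_proc && acute && !q_other
      if (eliminated) next
      if (q_other || has_excl_proc) hdr_q <- TRUE
      if (any(pr %in% o_dialproc)) dial <- TRUE
      if (o_any(pr, "^556") || o_any(dx, "^V420$") ||
          o_any(sv, c("^P585B$", "^PV420$"))) transplant <- TRUE
      if (o_any(dx, o_sevdx_re)) adv <- TRUE
    }
    ter_q <- FALSE
    for (r in seq_len(nrow(ter))) {
      code <- o_norm(ter$code[r])
      active <- !is.na(ter$start_date[r]) && ter$start_date[r] <= pd &&
        (is.na(ter$end_date[r]) || ter$end_date[r] > pd)
      if (active && o_any(code, o_ter_re)) ter_q <- TRUE
      if (active && code == "025V420") transplant <- TRUE
    }
    visit_dates <- c(); albumin <- FALSE; dial_svc <- FALSE
    for (r in seq_len(nrow(oss))) {
      if (!in_win(oss$service_date[r])) next
      code <- o_norm(oss$service_code[r])
      br <- o_norm(ifelse(is.na(oss$branch[r]), "", oss$branch[r]))
      if (code %in% o_visit && br == "29")
        visit_dates <- c(visit_dates, oss$service_date[r])
      if (code == "90334") albumin <- TRUE
      if (o_any(code, o_dialsvc_re)) dial_svc <- TRUE
    }
    nvis <- length(unique(visit_dates))
    drug <- FALSE
    for (r in seq_len(nrow(pha)))
      if (in_win(pha$dispensing_date[r]) &&
          o_norm(pha$atc[r]) %in% o_atc) drug <- TRUE
    oss_q <- nvis >= 2 || (nvis >= 1 && albumin) || (nvis >= 1 && drug) ||
      (dialysis_standalone && dial_svc)
    pharm_q <- (standalone_pharm && drug) || (nvis >= 1 && drug)

    sources <- c(if (hdr_q) "HDR", if (oss_q) "OSSIS",
                 if (pharm_q) "PHARM", if (ter_q) "TER")
    if (length(sources) == 0L) next
    if (!is.na(dem$death_date[i]) && dem$death_date[i] <= pd) next
    if (!o_resident(dem$residence_intervals[i], pd)) next
    if (dial_svc) dial <- TRUE
    higher <- dial || transplant || adv || drug
    out[[p]] <- data.frame(
      person_id = p, sources = paste(sort(sources), collapse = ";"),
      severity = if (higher) "higher" else "lower",
      dialysis = dial, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res))
    res <- data.frame(person_id = character(0), sources = character(0),
                      severity = character(0), dialysis = logical(0),
                      stringsAsFactors = FALSE)
  res[order(res$person_id), , drop = FALSE]
}
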