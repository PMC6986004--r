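# Compact constructors for hand-built registry fixtures.

mk_dem <- function(ids, sex = "male", birth = "1950-06-15",
                   death = NA_character_, res = NULL) {
  n <- length(ids)
  if (is.null(res)) res <- "1950-06-15/"
  as_registry(data.frame(
    person_id = ids,
    sex = rep_len(sex, n),
    birth_date = rep_len(birth, n),
    death_date = rep_len(death, n),
    residence_intervals = rep_len(res, n),
    stringsAsFactors = FALSE), "demographics")
}

mk_hdr <- function(id, dx, proc = "", svc = "",
                   adm = "2015-03-01", dis = "2015-03-05") {
  as_registry(data.frame(
    person_id = id, admission_date = adm, discharge_date = dis,
    diagnoses = dx, procedures = proc, service_codes = svc,
    stringsAsFactors = FALSE), "hdr")
}

mk_ter <- function(id, code = "025.585", start = "2014-03-01",
                   end = NA_character_) {
  as_registry(data.frame(
    person_id = id, code = code, start_date = start, end_date = end,
    stringsAsFactors = FALSE), "ter")
}

mk_ossis <- function(id, code, date = "2015-06-01", branch = "29") {
  as_registry(data.frame(
    person_id = id, service_date = date, service_code = code,
    branch = branch, stringsAsFactors = FALSE), "ossis")
}

mk_pharm <- function(id, atc = "B03XA01", date = "2015-06-01") {
  as_registry(data.frame(
    person_id = id, dispensing_date = date, atc = atc,
    stringsAsFactors = FALSE), "pharm")
}

mk_ldr <- function(id, start = "2015-01-01", modality = "hemodialysis") {
  as_registry(data.frame(
    person_id = id, start_date = start, modality = modality,
    stringsAsFactors = FALSE), "ldr")
}

empty_reg <- function(kind) {
  cols <- list(
    demographics = c("person_id", "sex", "birth_date", "death_date",
                     "residence_intervals"),
    hdr = c("person_id", "admission_date", "discharge_date", "diagnoses",
            "procedures", "service_codes"),
    ter = c("person_id", "code", "start_date", "end_date"),
    ossis = c("person_id", "service_date", "service_code", "branch"),
    pharm = c("person_id", "dispensing_date", "atc"),
    ldr = c("person_id", "start_date", "modality"))[[kind]]
  df <- as.data.frame(setNames(
    replicate(length(cols), character(0), simplify = FALSE), cols),
    stringsAsFactors = FALSE)
  as_registry(df, kind)
}

# bundle builder: any registry omitted is empty
mk_bundle <- function(demographics, hdr = NULL, ter = NULL, ossis = NULL,
                      pharm = NULL, ldr = NULL) {
  list(demographics = demographics,
       hdr = hdr %||% empty_reg("hdr"),
       ter = ter %||% empty_reg("ter"),
       ossis = ossis %||% empty_reg("ossis"),
       pharm = pharm %||% empty_reg("pharm"),
       ldr = ldr %||% empty_reg("ldr"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
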