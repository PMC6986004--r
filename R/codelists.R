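# Code catalogue and wildcard matching for the four coding systems used by
# the ascertainment rules: ICD-9-CM diagnoses and procedures, regional
# outpatient service codes, exemption codes and ATC drug codes.

.code_systems <- c("icd9_dx", "icd9_proc", "regional_service", "exemption", "atc")

#' Normalize a clinical code
#'
#' Removes dots and surrounding whitespace and upper-cases, so that the
#' dotted and undotted spellings of the same code compare equal (ICD-9-CM
#' "585.4" and "5854", ATC " b03xa01 " and "B03XA01"). Normalization is
#' idempotent and identical across coding systems; the `system` argument
#' exists for interface symmetry with [match_code()] and is validated only.
#'
#' @param raw character vector of raw codes.
#' @param system coding system, one of `"icd9_dx"`, `"icd9_proc"`,
#'   `"regional_service"`, `"exemption"`, `"atc"`.
#' @return character vector of normalized codes.
#' @examples
#' normalize_code("585.4", "icd9_dx")    # "5854"
#' normalize_code("V42.0", "icd9_dx")    # "V420"
#' @export
normalize_code <- function(raw, system = "icd9_dx") {
  system <- match.arg(system, .code_systems)
  out <- .norm(raw)
  if (any(is.na(raw)) || any(!nzchar(out)))
    stop("empty code after normalization", call. = FALSE)
  out
}

# internal normalizer: tolerates empty vectors, used on pre-split cells
.norm <- function(raw) toupper(gsub("[. ]", "", raw))

#' Match a code against a wildcard pattern
#'
#' Patterns may end in a run of `X` characters (the "585.XX" convention of
#' the code table): the trailing `X`-run matches any — possibly empty —
#' extension of the preceding stem, so "585.XX" matches "585", "5853" and
#' "58531". A pattern without a trailing `X`-run requires exact equality.
#' The bare stem matches because ICD-9-CM permits 3-digit codes where no
#' fourth digit exists; prefix semantics is the standard claims-research
#' reading. Both arguments must already be normalized (see
#' [normalize_code()]); note an `X` inside a code (e.g. ATC "B03XA01") is
#' literal — only a pattern's trailing run is a wildcard.
#'
#' @param code character vector of normalized codes.
#' @param pattern single normalized pattern, possibly with trailing X-run.
#' @return logical vector, one element per code.
#' @examples
#' match_code("5853", "585XX")   # TRUE
#' match_code("5849", "585XX")   # FALSE
#' match_code("40391", "403XX")  # TRUE
#' @export
match_code <- function(code, pattern) {
  stopifnot(length(pattern) == 1L, nzchar(pattern))
  stem <- sub("X+$", "", pattern)
  if (nchar(stem) < nchar(pattern)) startsWith(code, stem) else code == pattern
}

#' Match a code against a set of patterns
#'
#' Vectorized over codes: `TRUE` where at least one pattern in the set
#' matches under [match_code()] semantics. Order of the pattern set is
#' irrelevant.
#'
#' @param code character vector of normalized codes.
#' @param patterns character vector of normalized patterns.
#' @return logical vector, one element per code.
#' @export
any_match <- function(code, patterns) {
  if (length(code) == 0L) return(logical(0))
  stems <- sub("X+$", "", patterns)
  wild <- nchar(stems) < nchar(patterns)
  res <- code %in% patterns[!wild]
  for (s in stems[wild]) res <- res | startsWith(code, s)
  res
}

#' The default code catalogue
#'
#' Returns the full code table driving the ascertainment rules, with every
#' code normalized (dots removed, trailing `X`-runs kept as wildcard
#' markers). Sets:
#' \describe{
#'   \item{hdr_diagnoses}{13 ICD-9-CM diagnosis patterns (diabetic
#'     nephropathy 250.4X through transplant status V42.0).}
#'   \item{hdr_procedures}{9 ICD-9-CM procedures (dialysis, dialysis
#'     access, kidney transplant, kidney biopsy).}
#'   \item{hdr_complex_services}{4 regional complex-outpatient-package
#'     codes (P583 family).}
#'   \item{ter_codes}{the CKD (025.585) and kidney-transplant (025.V42.0)
#'     exemption codes.}
#'   \item{ossis_visit_codes}{nephrology visit codes 89.7, 89.01, 89.03 —
#'     qualifying only with specialty branch `ossis_visit_branch` ("29").}
#'   \item{ossis_albumin_code}{urine albumin measurement 90.33.4.}
#'   \item{ossis_dialysis_services}{dialysis-related outpatient services
#'     (39.95.X, 54.98.X, 38.95, 54.93, 39.99.1, 97.82, 97.29.1).}
#'   \item{pharm_atc}{7 ATC codes: erythropoiesis-stimulating agents
#'     (B03XA01-03) and phosphate/potassium binders (V03AE01/02/03/05).}
#'   \item{severity_dx}{advanced-stage diagnoses 585.4X, 585.5X, 585.6X
#'     (CKD stage IV or greater).}
#'   \item{dialysis_procedures}{the HDR procedures counting as dialysis
#'     severity evidence (39.95, 54.98, 39.27, 54.93, 39.42, 39.43,
#'     38.95). Kidney biopsy 55.23 qualifies a hospitalization but is
#'     deliberately absent here: it is not dialysis, transplant, advanced
#'     stage or drug exposure.}
#'   \item{transplant_procedures, transplant_dx, transplant_ter,
#'     transplant_services}{kidney-transplant evidence (55.6X; V42.0;
#'     025.V42.0; P585B, PV420).}
#'   \item{acute_renal_dx}{584.XX, acute renal failure — drives the
#'     hospital-record exclusion rule.}
#'   \item{exclusion_procedures}{39.95 and 38.95, the two procedures the
#'     acute-failure exclusion applies to.}
#' }
#'
#' @return an object of class `ckd_catalog` (a named list of character
#'   vectors plus `ossis_visit_branch`).
#' @seealso [read_catalog()], [write_catalog()] to customize the lists.
#' @export
default_catalog <- function() {
  cat <- list(
    hdr_diagnoses = c(
      "2504X",  # diabetes with renal manifestations
      "403XX",  # hypertensive chronic kidney disease
      "404XX",  # hypertensive heart and chronic kidney disease
      "582XX",  # chronic glomerulonephritis
      "583XX",  # nephritis/nephropathy not specified as acute or chronic
      "585XX",  # chronic kidney disease
      "586XX",  # renal failure, unspecified
      "587XX",  # renal sclerosis, unspecified
      "588XX",  # disorders from impaired renal function
      "7531X",  # cystic kidney disease
      "5900X",  # chronic pyelonephritis
      "V56X",   # encounter for dialysis and dialysis catheter care
      "V420"    # kidney replaced by transplant
    ),
    hdr_procedures = c(
      "3995",   # hemodialysis
      "5498",   # peritoneal dialysis
      "556X",   # transplant of kidney
      "3927",   # arteriovenostomy for renal dialysis
      "5493",   # creation of cutaneoperitoneal fistula
      "3942",   # revision of AV shunt for renal dialysis
      "3943",   # removal of AV shunt for renal dialysis
      "3895",   # venous catheterization for renal dialysis
      "5523"    # closed percutaneous kidney biopsy
    ),
    hdr_complex_services = c("P583", "P585A", "P585B", "PV420"),
    ter_codes = c("025585", "025V420"),
    ossis_visit_codes = c("897", "8901", "8903"),
    ossis_visit_branch = "29",
    ossis_albumin_code = "90334",
    ossis_dialysis_services = c("3995X", "5498X", "3895", "5493",
                                "39991", "9782", "97291"),
    pharm_atc = c("B03XA01", "B03XA02", "B03XA03",
                  "V03AE01", "V03AE02", "V03AE03", "V03AE05"),
    severity_dx = c("5854X", "5855X", "5856X"),
    dialysis_procedures = c("3995", "5498", "3927", "5493",
                            "3942", "3943", "3895"),
    transplant_procedures = "556X",
    transplant_dx = "V420",
    transplant_ter = "025V420",
    transplant_services = c("P585B", "PV420"),
    acute_renal_dx = "584XX",
    exclusion_procedures = c("3995", "3895")
  )
  structure(cat, class = "ckd_catalog")
}

.check_catalog <- function(cat) {
  required <- names(default_catalog())
  missing <- setdiff(required, names(cat))
  if (length(missing))
    stop("catalog is missing sets: ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (nm in required) {
    v <- cat[[nm]]
    if (!is.character(v) || length(v) == 0L || any(!nzchar(v)))
      stop("catalog set '", nm, "' must be a non-empty character vector",
           call. = FALSE)
  }
  invisible(cat)
}

#' Read / write a code catalogue as YAML
#'
#' The catalogue is serializable as a plain YAML file so users can extend
#' or replace code lists; codes are normalized on read, so dotted
#' spellings ("585.XX") are accepted. The shipped [default_catalog()] is
#' reproduced bit-exactly by a write/read round trip.
#'
#' @param path file path of the YAML catalogue.
#' @param catalog a `ckd_catalog` object.
#' @return `read_catalog()` returns a `ckd_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  cat <- lapply(raw, function(v) .norm(as.character(v)))
  cat <- structure(cat, class = "ckd_catalog")
  .check_catalog(cat)
  cat
}

#' @rdname read_catalog
#' @export
write_catalog <- function(catalog, path) {
  .check_catalog(catalog)
  yaml::write_yaml(lapply(unclass(catalog), as.character), path)
  invisible(path)
}

#' @export
print.ckd_catalog <- function(x, ...) {
  cat("CKD ascertainment code catalogue\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, paste(x[[nm]], collapse = " ")))
  invisible(x)
}
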