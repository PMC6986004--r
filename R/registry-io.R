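# Data model and tabular IO for the six registries. One CSV per registry,
# UTF-8, header row, ISO-8601 dates; multi-valued diagnosis/procedure cells
# are semicolon-delimited. Residence history is a semicolon list of
# half-open intervals "start/end" with an open end written as "start/".

.registry_kinds <- c("demographics", "hdr", "ter", "ossis", "pharm", "ldr")

.registry_schemas <- list(
  demographics = c("person_id", "sex", "birth_date", "death_date",
                   "residence_intervals"),
  hdr   = c("person_id", "admission_date", "discharge_date",
            "diagnoses", "procedures", "service_codes"),
  ter   = c("person_id", "code", "start_date", "end_date"),
  ossis = c("person_id", "service_date", "service_code", "branch"),
  pharm = c("person_id", "dispensing_date", "atc"),
  ldr   = c("person_id", "start_date", "modality")
)

.date_cols <- list(
  demographics = c("birth_date", "death_date"),
  hdr   = c("admission_date", "discharge_date"),
  ter   = c("start_date", "end_date"),
  ossis = "service_date",
  pharm = "dispensing_date",
  ldr   = "start_date"
)

# optional (may be blank) fields per kind
.optional_cols <- list(
  demographics = "death_date",
  hdr   = c("procedures", "service_codes"),
  ter   = "end_date",
  ossis = "branch",
  pharm = character(0),
  ldr   = character(0)
)

# ATC prefix grammar: letter, 2 digits, letter, letter, 2 digits — any
# leading portion of that structure, up to the full 7 characters.
.atc_ok <- function(x) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", x)
}

# parse "start/end;start/" into a data.frame(start, end); NA end = open
.parse_intervals <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(start = as.Date(character(0)),
                      end = as.Date(character(0))))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "/", fixed = TRUE)
  start <- .parse_date(vapply(parts, `[`, character(1), 1L))
  end_raw <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "",
                    character(1))
  end <- .parse_date(ifelse(nzchar(end_raw), end_raw, NA_character_))
  open <- !nzchar(end_raw)
  if (any(is.na(start)) || any(is.na(end) & !open))
    stop("unparseable residence interval")
  data.frame(start = start, end = end)
}

.fmt_intervals <- function(df) {
  if (nrow(df) == 0L) return("")
  paste(paste0(.fmt_date(df$start), "/", .fmt_date(df$end)), collapse = ";")
}

# per-kind row validators: return character(0) or messages
.validate_rows <- function(df, kind) {
  msgs <- rep("", nrow(df))
  add <- function(bad, msg) {
    bad[is.na(bad)] <- FALSE
    msgs[bad] <<- paste0(msgs[bad], ifelse(nzchar(msgs[bad]), "; ", ""), msg)
  }
  add(!nzchar(df$person_id) | is.na(df$person_id), "empty person_id")
  for (col in .date_cols[[kind]]) {
    optional <- col %in% .optional_cols[[kind]]
    blank <- is.na(df[[paste0(".raw_", col)]]) |
      !nzchar(df[[paste0(".raw_", col)]])
    add(is.na(df[[col]]) & !blank, paste("unparseable date in", col))
    if (!optional) add(blank, paste("missing", col))
  }
  switch(kind,
    demographics = {
      add(!df$sex %in% c("male", "female"), "sex must be male/female")
      add(!is.na(df$death_date) & df$birth_date > df$death_date,
          "birth_date after death_date")
      for (i in seq_len(nrow(df))) {
        iv <- tryCatch(.parse_intervals(df$residence_intervals[i]),
                       error = function(e) NULL)
        if (is.null(iv)) {
          add(seq_len(nrow(df)) == i, "unparseable residence_intervals")
        } else if (nrow(iv) > 1L) {
          open_mid <- any(is.na(iv$end[-nrow(iv)]))
          ends <- iv$end[-nrow(iv)]
          overlap <- open_mid || any(ends > iv$start[-1L], na.rm = TRUE) ||
            is.unsorted(iv$start)
          if (overlap)
            add(seq_len(nrow(df)) == i,
                "residence intervals overlapping or unsorted")
        }
      }
    },
    hdr = {
      add(df$admission_date > df$discharge_date,
          "admission_date after discharge_date")
      ndx <- lengths(.split_multi(df$diagnoses))
      add(ndx < 1L, "at least one diagnosis required")
      add(ndx > 6L, "more than 6 diagnoses")
      add(lengths(.split_multi(df$procedures)) > 6L, "more than 6 procedures")
    },
    ter = {
      add(!nzchar(df$code) | is.na(df$code), "empty exemption code")
      add(!is.na(df$end_date) & df$start_date > df$end_date,
          "start_date after end_date")
    },
    ossis = add(!nzchar(df$service_code) | is.na(df$service_code),
                "empty service_code"),
    pharm = add(!.atc_ok(.norm(ifelse(is.na(df$atc), "", df$atc))),
                "atc violates ATC grammar"),
    ldr = add(!df$modality %in% c("hemodialysis", "peritoneal"),
              "modality must be hemodialysis/peritoneal")
  )
  msgs
}

#' Read a registry file
#'
#' Reads one of the six registry CSVs into a validated data frame. The
#' header must match the documented schema for the kind; dates are parsed
#' as ISO 8601; rows violating the type invariants (e.g. a discharge
#' before the admission, a malformed ATC code, overlapping residence
#' intervals) are rejected with row-number diagnostics — or, under
#' `lenient = TRUE`, reported as a warning and skipped.
#'
#' Schemas (column order as written by [write_registry()]):
#' \describe{
#'   \item{demographics}{person_id, sex, birth_date, death_date,
#'     residence_intervals (semicolon list of half-open "start/end"
#'     intervals, open end written "start/").}
#'   \item{hdr}{person_id, admission_date, discharge_date, diagnoses (1–6,
#'     semicolon-delimited), procedures (0–6), service_codes.}
#'   \item{ter}{person_id, code, start_date, end_date (blank = open).}
#'   \item{ossis}{person_id, service_date, service_code, branch.}
#'   \item{pharm}{person_id, dispensing_date, atc.}
#'   \item{ldr}{person_id, start_date, modality.}
#' }
#'
#' @param path CSV file path.
#' @param kind one of `"demographics"`, `"hdr"`, `"ter"`, `"ossis"`,
#'   `"pharm"`, `"ldr"`.
#' @param lenient if `TRUE`, invalid rows are dropped with a warning
#'   instead of aborting.
#' @return a data frame with parsed `Date` columns; demographics
#'   additionally carry a `residence` list column of interval data frames.
#' @export
read_registry <- function(path, kind, lenient = FALSE) {
  kind <- match.arg(kind, .registry_kinds)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  schema <- .registry_schemas[[kind]]
  if (!setequal(names(df), schema)) {
    missing <- setdiff(schema, names(df))
    extra <- setdiff(names(df), schema)
    stop("schema error for kind '", kind, "': ",
         if (length(missing)) paste("missing columns:",
                                    paste(missing, collapse = ", ")),
         if (length(missing) && length(extra)) "; ",
         if (length(extra)) paste("unexpected columns:",
                                  paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  df <- df[schema]
  as_registry(df, kind, lenient = lenient)
}

#' Validate and type a raw registry data frame
#'
#' The constructor behind [read_registry()]: enforces every type invariant
#' so that no invalid record enters the downstream modules. Useful when
#' records are built programmatically (as the synthetic generator does).
#'
#' @param df data frame with the kind's schema columns (character or
#'   already-typed).
#' @param kind registry kind (see [read_registry()]).
#' @param lenient drop invalid rows with a warning instead of aborting.
#' @return validated data frame with `Date` columns parsed.
#' @export
as_registry <- function(df, kind, lenient = FALSE) {
  kind <- match.arg(kind, .registry_kinds)
  schema <- .registry_schemas[[kind]]
  stopifnot(all(schema %in% names(df)))
  df <- as.data.frame(df)[schema]
  for (col in setdiff(schema, .date_cols[[kind]]))
    df[[col]] <- as.character(df[[col]])
  for (col in .date_cols[[kind]]) {
    raw <- if (inherits(df[[col]], "Date")) .fmt_date(df[[col]])
           else as.character(df[[col]])
    df[[paste0(".raw_", col)]] <- raw
    df[[col]] <- .parse_date(ifelse(is.na(raw) | !nzchar(raw),
                                    NA_character_, raw))
  }
  msgs <- if (nrow(df)) .validate_rows(df, kind) else character(0)
  bad <- which(nzchar(msgs))
  if (length(bad)) {
    detail <- paste0("row ", bad, ": ", msgs[bad], collapse = "\n  ")
    if (!lenient)
      stop("invalid ", kind, " records:\n  ", detail, call. = FALSE)
    warning("skipping ", length(bad), " invalid ", kind, " row(s):\n  ",
            detail, call. = FALSE)
    df <- df[-bad, , drop = FALSE]
  }
  df <- df[, schema, drop = FALSE]
  if (kind == "demographics") {
    df$residence <- lapply(df$residence_intervals, .parse_intervals)
  }
  rownames(df) <- NULL
  attr(df, "registry_kind") <- kind
  df
}

#' Write a registry file
#'
#' Writes records back to CSV in the documented schema; a read/write round
#' trip is lossless (field-by-field equality). An empty record list yields
#' a header-only file.
#'
#' @param records registry data frame (as returned by [read_registry()] or
#'   [as_registry()]).
#' @param path output CSV path.
#' @param kind registry kind; defaults to the data frame's
#'   `registry_kind` attribute.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, kind = NULL) {
  kind <- kind %||% attr(records, "registry_kind")
  if (is.null(kind)) stop("registry kind unknown; pass `kind`", call. = FALSE)
  kind <- match.arg(kind, .registry_kinds)
  schema <- .registry_schemas[[kind]]
  out <- as.data.frame(records)[schema]
  for (col in .date_cols[[kind]]) out[[col]] <- .fmt_date(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Regional residence at a given date
#'
#' Residence intervals are half-open `[start, end)`: a person is resident
#' on the interval's start date but not on its end date. Vital status is
#' not consulted here — death handling is a separate cohort-resolution
#' step.
#'
#' @param demographics demographics data frame (see [read_registry()]).
#' @param date a single date.
#' @return logical vector, one element per demographics row.
#' @examples
#' d <- as_registry(data.frame(
#'   person_id = "p1", sex = "female", birth_date = "1950-01-01",
#'   death_date = "", residence_intervals = "2010-01-01/2016-05-01"),
#'   "demographics")
#' resident_at(d, as.Date("2015-12-31"))  # TRUE
#' resident_at(d, as.Date("2016-05-01"))  # FALSE (half-open end)
#' @export
resident_at <- function(demographics, date) {
  date <- as.Date(date)
  stopifnot(length(date) == 1L, !is.na(date))
  res <- demographics$residence
  if (is.null(res)) res <- lapply(demographics$residence_intervals,
                                  .parse_intervals)
  vapply(res, function(iv) {
    any(iv$start <= date & (is.na(iv$end) | date < iv$end))
  }, logical(1))
}
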