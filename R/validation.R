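# Validation of dialysis ascertainment against the dialysis registry
# treated as gold standard: 2x2 confusion counts and Se/Sp/PPV/NPV.

#' Dialysis patients according to the algorithm
#'
#' The prevalent cases carrying dialysis evidence (a dialysis or
#' dialysis-access procedure on a non-eliminated hospital record, or a
#' dialysis-related outpatient service) within the selection window —
#' severity criterion (i). Requires a classified cohort.
#'
#' @param cohort a `ckd_cohort` with the `evidence` audit table (see
#'   [classify_severity()]).
#' @return character vector of person identifiers.
#' @export
algorithm_dialysis_set <- function(cohort) {
  stopifnot(inherits(cohort, "ckd_cohort"))
  if (is.null(cohort$evidence))
    stop("cohort has no severity evidence; run classify_severity()",
         call. = FALSE)
  ev <- cohort$evidence
  sort(unique(ev$person_id[ev$kind == "dialysis"]))
}

#' Dialysis patients according to the gold-standard registry
#'
#' Registry entrants with treatment start on or before the window end
#' who are alive and resident at the prevalence date. (Chronicity — at
#' least 90 days of treatment — is the registry's own inclusion rule and
#' is not re-checked.)
#'
#' @param ldr dialysis-registry data frame.
#' @param demographics demographics registry data frame.
#' @param window a `study_window`.
#' @return character vector of person identifiers.
#' @export
registry_dialysis_set <- function(ldr, demographics,
                                  window = study_window()) {
  pd <- window$prevalence_date
  keep <- !is.na(ldr$start_date) & ldr$start_date <= window$end
  ids <- unique(ldr$person_id[keep])
  idx <- match(ids, demographics$person_id)
  if (anyNA(idx))
    stop("registry person(s) absent from demographics: ",
         paste(sort(ids[is.na(idx)]), collapse = ", "), call. = FALSE)
  alive <- is.na(demographics$death_date[idx]) |
    demographics$death_date[idx] > pd
  res <- resident_at(demographics[idx, , drop = FALSE], pd)
  sort(ids[alive & res])
}

#' Confusion matrix and accuracy metrics against a gold standard
#'
#' Cross-classifies the algorithm's dialysis set against the registry's
#' within a reference population: tp = both, fp = algorithm only,
#' fn = registry only, tn = neither (the four cells partition the
#' population). Sensitivity tp/(tp+fn), specificity tn/(tn+fp),
#' PPV tp/(tp+fp) and NPV tn/(tn+fn), each as a percentage rounded
#' half-away-from-zero to one decimal; a metric with a zero denominator
#' (e.g. PPV under an empty algorithm set) is reported as `NA`
#' (not applicable) rather than 0.
#'
#' @param algorithm_set,registry_set character vectors of person
#'   identifiers, both subsets of `population`.
#' @param population character vector: the reference population (by
#'   default the full resident-alive population at the prevalence date).
#' @return object of class `ckd_validation`: counts `tp`, `fp`, `fn`,
#'   `tn` and metrics `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' confusion(c("a", "b"), c("a", "c"), letters[1:10])
#' @export
confusion <- function(algorithm_set, registry_set, population) {
  a <- unique(algorithm_set); r <- unique(registry_set)
  pop <- unique(population)
  out_of_pop <- setdiff(union(a, r), pop)
  if (length(out_of_pop))
    stop("set member(s) outside the reference population: ",
         paste(sort(out_of_pop), collapse = ", "), call. = FALSE)
  tp <- length(intersect(a, r))
  fp <- length(setdiff(a, r))
  fn <- length(setdiff(r, a))
  tn <- length(pop) - tp - fp - fn
  metric <- function(num, den)
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 ppv = metric(tp, tp + fp),
                 npv = metric(tn, tn + fn)),
            class = "ckd_validation")
}

#' Validate dialysis ascertainment end to end
#'
#' Convenience wrapper: derives the algorithm set from the classified
#' cohort, the gold-standard set from the dialysis registry, takes the
#' resident-alive population at the prevalence date as reference
#' denominator and returns the confusion result. The region-wide
#' denominator is the default because specificity of a rare-condition
#' classifier is conventionally quoted against the whole population;
#' pass `population_scope = "cohort"` for a cohort-only denominator.
#'
#' @param cohort a classified `ckd_cohort`.
#' @param registries registry bundle including `ldr` and `demographics`.
#' @param population_scope `"region"` (default) or `"cohort"`.
#' @return a `ckd_validation`.
#' @export
validate_dialysis <- function(cohort, registries,
                              population_scope = c("region", "cohort")) {
  population_scope <- match.arg(population_scope)
  if (is.null(registries$ldr))
    stop("registry bundle has no dialysis registry (ldr)", call. = FALSE)
  window <- cohort$window
  a <- algorithm_dialysis_set(cohort)
  r <- registry_dialysis_set(registries$ldr, registries$demographics,
                             window)
  dem <- registries$demographics
  pd <- window$prevalence_date
  pop <- if (population_scope == "region") {
    alive <- is.na(dem$death_date) | dem$death_date > pd
    dem$person_id[alive & resident_at(dem, pd)]
  } else union(cohort$cases$person_id, r)
  confusion(a, r, pop)
}

#' @export
print.ckd_validation <- function(x, ...) {
  cat("Dialysis ascertainment vs gold-standard registry\n")
  cat(sprintf("  tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", v)
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv)))
  invisible(x)
}
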