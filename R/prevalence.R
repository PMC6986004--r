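# Prevalence machinery: completed age, crude and stratum-specific rates
# with 95% CIs, direct standardization and male:female rate ratios.

#' Completed age at a reference date
#'
#' Whole-year age by calendar arithmetic: one is subtracted when the
#' birthday has not yet been reached in the reference year (Feb 29
#' birthdays count as reached on Mar 1 of common years).
#'
#' @param birth_date,reference_date `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @examples
#' age_at(as.Date("1932-12-31"), as.Date("2017-12-31"))  # 85
#' age_at(as.Date("1933-01-01"), as.Date("2017-12-31"))  # 84
#' @export
age_at <- function(birth_date, reference_date) {
  b <- as.Date(birth_date); r <- as.Date(reference_date)
  if (any(b > r, na.rm = TRUE))
    stop("birth_date after reference_date", call. = FALSE)
  by <- as.integer(format(b, "%Y")); ry <- as.integer(format(r, "%Y"))
  ry - by - as.integer(format(r, "%m%d") < format(b, "%m%d"))
}

#' Default age-class partition
#'
#' The partition 0–18, 19–44, 45–64, 65–74, 75–84, 85+ covering all ages
#' without overlap.
#'
#' @return data frame with `label`, `low`, `high` (inclusive bounds;
#'   `Inf` = open).
#' @export
default_age_classes <- function() {
  data.frame(label = c("0-18", "19-44", "45-64", "65-74", "75-84", "85+"),
             low = c(0, 19, 45, 65, 75, 85),
             high = c(18, 44, 64, 74, 84, Inf),
             stringsAsFactors = FALSE)
}

.age_class_of <- function(age, classes = default_age_classes()) {
  idx <- findInterval(age, classes$low)
  idx[age < 0] <- NA_integer_
  classes$label[idx]
}

.rate_estimate <- function(rate, ci_low, ci_high) {
  structure(list(rate = rate,
                 ci_low = max(0, ci_low),
                 ci_high = min(100, ci_high)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%.*f%% (95%%CI %.*f, %.*f)\n",
              digits, round_half_up(x$rate, digits),
              digits, round_half_up(x$ci_low, digits),
              digits, round_half_up(x$ci_high, digits)))
  invisible(x)
}

#' Crude prevalence rate with confidence interval
#'
#' Rate per 100 population, `cases / population * 100`, with a 95% CI on
#' the underlying proportion. Default CI is the Wald normal
#' approximation (appropriate at the millions-of-residents denominators
#' this machinery targets); an exact Clopper–Pearson interval is
#' available for small strata.
#'
#' @param cases,population non-negative counts, `cases <= population`,
#'   `population > 0`.
#' @param conf_level confidence level (default 0.95).
#' @param ci_method `"wald"` or `"clopper-pearson"`.
#' @return a `rate_estimate` (fields `rate`, `ci_low`, `ci_high`, all in
#'   percent, unrounded; the print method rounds to 2 decimals).
#' @examples
#' crude_rate(99457, 5636510)  # 1.76% (95%CI 1.75, 1.78)
#' @export
crude_rate <- function(cases, population, conf_level = 0.95,
                       ci_method = c("wald", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(cases) == 1L, length(population) == 1L)
  if (is.na(population) || population <= 0)
    stop("population must be positive", call. = FALSE)
  if (is.na(cases) || cases < 0 || cases > population)
    stop("cases must lie in [0, population]", call. = FALSE)
  p <- cases / population
  a <- (1 - conf_level) / 2
  if (ci_method == "wald") {
    z <- stats::qnorm(1 - a)
    se <- sqrt(p * (1 - p) / population)
    lo <- p - z * se; hi <- p + z * se
  } else {
    lo <- if (cases == 0) 0 else
      stats::qbeta(a, cases, population - cases + 1)
    hi <- if (cases == population) 1 else
      stats::qbeta(1 - a, cases + 1, population - cases)
  }
  .rate_estimate(100 * p, 100 * lo, 100 * hi)
}

#' Male:female rate ratio
#'
#' @param rate_m,rate_f rates in percent; `rate_f` must be positive.
#' @return the ratio rounded half-away-from-zero to 2 decimals.
#' @examples
#' rate_ratio(2.06, 1.50)  # 1.37
#' @export
rate_ratio <- function(rate_m, rate_f) {
  if (any(rate_f <= 0)) stop("female rate must be positive", call. = FALSE)
  round_half_up(rate_m / rate_f, 2)
}

#' Build a prevalence table from stratum counts
#'
#' The low-level constructor behind [stratified_rates()]: takes
#' per-(age class, sex) case and population counts and produces the full
#' table — stratum rates with CIs, per-age-class totals, per-sex totals,
#' the grand total and male:female rate ratios (computed from the
#' unrounded rates). This is also the entry point for re-deriving
#' published tables from their printed counts (see [table2_fixture()]).
#'
#' @param counts data frame with columns `age_class`, `sex`
#'   (male/female), `cases`, `population`.
#' @param conf_level,ci_method passed to [crude_rate()].
#' @return a `prevalence_table`: data frame with columns `age_class`,
#'   `sex` (male/female/total, age_class `"total"` rows for margins),
#'   `cases`, `population`, `rate`, `ci_low`, `ci_high` (percent,
#'   unrounded) and `rate_mf` (M/F ratio, on sex == "total" rows).
#' @export
prevalence_table <- function(counts, conf_level = 0.95,
                             ci_method = c("wald", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  stopifnot(all(c("age_class", "sex", "cases", "population") %in%
                  names(counts)))
  if (any(counts$cases < 0 | counts$cases > counts$population))
    stop("cases must lie in [0, population] in every stratum",
         call. = FALSE)
  agg <- function(df, age_class, sex) {
    data.frame(age_class = age_class, sex = sex,
               cases = sum(df$cases), population = sum(df$population),
               stringsAsFactors = FALSE)
  }
  classes <- unique(counts$age_class)
  rows <- list()
  for (ac in classes) {
    sub <- counts[counts$age_class == ac, , drop = FALSE]
    for (s in c("male", "female"))
      rows[[paste(ac, s)]] <- agg(sub[sub$sex == s, , drop = FALSE], ac, s)
    rows[[paste(ac, "total")]] <- agg(sub, ac, "total")
  }
  for (s in c("male", "female"))
    rows[[paste("total", s)]] <-
      agg(counts[counts$sex == s, , drop = FALSE], "total", s)
  rows[["total total"]] <- agg(counts, "total", "total")
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  est <- lapply(seq_len(nrow(tab)), function(i)
    if (tab$population[i] > 0)
      crude_rate(tab$cases[i], tab$population[i], conf_level, ci_method)
    else .rate_estimate(NA_real_, NA_real_, NA_real_))
  tab$rate <- vapply(est, `[[`, numeric(1), "rate")
  tab$ci_low <- vapply(est, `[[`, numeric(1), "ci_low")
  tab$ci_high <- vapply(est, `[[`, numeric(1), "ci_high")
  tab$rate_mf <- NA_real_
  for (i in which(tab$sex == "total")) {
    m <- tab$rate[tab$age_class == tab$age_class[i] & tab$sex == "male"]
    f <- tab$rate[tab$age_class == tab$age_class[i] & tab$sex == "female"]
    if (length(m) == 1L && length(f) == 1L && !is.na(f) && f > 0)
      tab$rate_mf[i] <- rate_ratio(m, f)
  }
  structure(tab, conf_level = conf_level, ci_method = ci_method,
            class = c("prevalence_table", "data.frame"))
}

#' @export
print.prevalence_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in c("rate", "ci_low", "ci_high"))
    y[[col]] <- round_half_up(y[[col]], 2)
  cat("Prevalence per 100 population (95% CI,", attr(x, "ci_method"),
      ")\n")
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Age/sex-specific prevalence from person-level data
#'
#' Builds the stratified prevalence table for a cohort: the denominator
#' in each stratum is the count of residents alive at the prevalence
#' date, the numerator the identified cases among them. Every case must
#' be present in the demographics registry.
#'
#' @param cases a `ckd_cohort` or data frame with `person_id`.
#' @param demographics demographics registry covering the whole resident
#'   population.
#' @param age_classes partition data frame (see [default_age_classes()]).
#' @param prevalence_date the prevalence date (defaults to the cohort's).
#' @param conf_level,ci_method passed to [crude_rate()].
#' @return a `prevalence_table` (see [prevalence_table()]).
#' @export
stratified_rates <- function(cases, demographics,
                             age_classes = default_age_classes(),
                             prevalence_date = NULL,
                             conf_level = 0.95,
                             ci_method = c("wald", "clopper-pearson")) {
  if (inherits(cases, "ckd_cohort")) {
    prevalence_date <- prevalence_date %||% cases$window$prevalence_date
    cases <- cases$cases
  }
  if (is.null(prevalence_date))
    stop("prevalence_date is required", call. = FALSE)
  prevalence_date <- as.Date(prevalence_date)
  miss <- setdiff(cases$person_id, demographics$person_id)
  if (length(miss))
    stop("case person(s) absent from demographics: ",
         paste(sort(miss), collapse = ", "), call. = FALSE)
  alive <- is.na(demographics$death_date) |
    demographics$death_date > prevalence_date
  pop <- demographics[alive & resident_at(demographics, prevalence_date),
                      , drop = FALSE]
  pop$age_class <- .age_class_of(age_at(pop$birth_date, prevalence_date),
                                 age_classes)
  pop$is_case <- pop$person_id %in% cases$person_id
  counts <- expand.grid(age_class = age_classes$label,
                        sex = c("male", "female"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  counts$population <- mapply(function(ac, s)
    sum(pop$age_class == ac & pop$sex == s), counts$age_class, counts$sex)
  counts$cases <- mapply(function(ac, s)
    sum(pop$is_case & pop$age_class == ac & pop$sex == s),
    counts$age_class, counts$sex)
  prevalence_table(counts, conf_level, ci_method)
}

#' Directly standardized rate
#'
#' Weighted average of stratum-specific rates with weights given by a
#' reference population (direct method): the rate the study population
#' would show if it had the reference's age/sex structure. Weights are
#' normalized internally; passing the study population itself reproduces
#' the crude rate exactly. The default CI is a normal approximation with
#' variance the weighted sum of per-stratum binomial variances; a
#' gamma-based interval in the Fay–Feuer style is available for sparse
#' strata.
#'
#' @param cases,population per-stratum counts (same length and order).
#' @param weights reference counts or proportions per stratum, strictly
#'   positive where `population > 0`.
#' @param conf_level confidence level.
#' @param ci_method `"normal"` or `"gamma"`.
#' @return a `rate_estimate` in percent.
#' @examples
#' # two strata at 1% and 3%, reference weights 1:3
#' direct_standardized_rate(c(10, 30), c(1000, 1000), c(0.25, 0.75))
#' @export
direct_standardized_rate <- function(cases, population, weights,
                                     conf_level = 0.95,
                                     ci_method = c("normal", "gamma")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(cases) == length(population),
            length(weights) == length(population))
  if (any(population <= 0 & weights > 0))
    stop("zero-population stratum with nonzero weight", call. = FALSE)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (sum(weights) <= 0) stop("weights sum to zero", call. = FALSE)
  w <- weights / sum(weights)
  p <- ifelse(population > 0, cases / population, 0)
  rate <- sum(w * p)
  a <- (1 - conf_level) / 2
  if (ci_method == "normal") {
    v <- sum(ifelse(population > 0,
                    w^2 * p * (1 - p) / population, 0))
    z <- stats::qnorm(1 - a)
    lo <- rate - z * sqrt(v); hi <- rate + z * sqrt(v)
  } else {
    # gamma interval on the weighted event sum (Fay–Feuer construction)
    wi <- ifelse(population > 0, w / population, 0)
    y <- sum(wi * cases)
    v <- sum(wi^2 * cases)
    wm <- max(wi)
    lo <- if (y == 0) 0 else
      stats::qgamma(a, shape = y^2 / v, scale = v / y)
    hi <- stats::qgamma(1 - a, shape = (y + wm)^2 / (v + wm^2),
                        scale = (v + wm^2) / (y + wm))
  }
  .rate_estimate(100 * rate, 100 * lo, 100 * hi)
}
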