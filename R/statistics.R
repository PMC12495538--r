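## dB-domain statistical pipeline for cohort reflection measurements.
## All statistics operate on S11 magnitude in dB ("log-normal" reflection,
## i.e. normal in dB). The aggregation order is fixed by the measurement
## protocol: mean of the 3 repeats per site, then averaging sites within a
## subject's thin/thick class, then cross-subject statistics per frequency.

.thin_sites <- c("1F", "6R", "6L", "7L", "7R", "8L", "8R")
.thick_sites <- c("1L", "1R", "2L", "2R", "3L", "3R", "4L", "4R", "5L", "5R")

#' Measurement-site taxonomy
#'
#' Site codes on hands, arms and face grouped by stratum-corneum class
#' (thin: forehead, forearms, cheeks; thick: palms and inner fingers).
#'
#' @return Named list with `thin` and `thick` character vectors.
#' @export
site_classes <- function() list(thin = .thin_sites, thick = .thick_sites)

.check_cohort <- function(data) {
  need <- c("subject_id", "site_code", "sc_class", "probe", "frequency",
            "repeat_index", "s11_db")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("cohort data is missing column(s): ", paste(miss, collapse = ", "))
  bad <- data$sc_class == "thin" & !data$site_code %in% .thin_sites |
    data$sc_class == "thick" & !data$site_code %in% .thick_sites
  if (any(bad))
    stop("sc_class labels inconsistent with the site taxonomy for site(s): ",
         paste(unique(data$site_code[bad]), collapse = ", "))
  invisible(data)
}

#' Per-subject reflection values
#'
#' Collapses a cohort dataset to one value per subject, stratum-corneum
#' class, probe and frequency: repeats are averaged first, then the sites
#' within the class are averaged.
#'
#' @param data Cohort data frame with columns `subject_id`, `site_code`,
#'   `sc_class`, `probe`, `frequency`, `repeat_index`, `s11_db` (optionally
#'   `sex`, `age_years`, `age_group`, carried through).
#' @param repeat_policy `"strict"` (default) errors unless every
#'   (subject, site, frequency) cell has exactly 3 repeats;
#'   `"available"` averages whatever repeats are present.
#' @return Data frame with one row per (subject, class, probe, frequency)
#'   and column `s11_db`.
#' @export
subject_values <- function(data, repeat_policy = c("strict", "available")) {
  repeat_policy <- match.arg(repeat_policy)
  .check_cohort(data)
  if (repeat_policy == "strict") {
    cnt <- stats::aggregate(repeat_index ~ subject_id + site_code + probe +
                              frequency, data, length)
    if (any(cnt$repeat_index != 3L))
      stop("strict repeat policy: expected exactly 3 repeats per ",
           "(subject, site, frequency); found cells with ",
           paste(sort(unique(cnt$repeat_index[cnt$repeat_index != 3L])),
                 collapse = "/"),
           " repeats")
  }
  per_site <- stats::aggregate(
    s11_db ~ subject_id + sc_class + probe + frequency + site_code,
    data, mean)
  vals <- stats::aggregate(
    s11_db ~ subject_id + sc_class + probe + frequency, per_site, mean)
  extra <- intersect(c("sex", "age_years", "age_group"), names(data))
  if (length(extra)) {
    subj <- unique(data[c("subject_id", extra)])
    if (anyDuplicated(subj$subject_id))
      stop("subject covariates are not constant within subject_id")
    vals <- merge(vals, subj, by = "subject_id", sort = FALSE)
  }
  vals[order(vals$sc_class, vals$probe, vals$frequency, vals$subject_id), ,
       drop = FALSE]
}

#' Cohort summary: mean and SD per class and frequency
#'
#' @inheritParams subject_values
#' @return Data frame with columns `sc_class`, `probe`, `frequency`,
#'   `mean_db`, `sd_db`, `n` (subjects).
#' @export
summarize_cohort <- function(data, repeat_policy = c("strict", "available")) {
  vals <- subject_values(data, repeat_policy)
  agg <- stats::aggregate(s11_db ~ sc_class + probe + frequency, vals,
                          function(x) c(mean = mean(x), sd = stats::sd(x),
                                        n = length(x)))
  out <- data.frame(sc_class = agg$sc_class, probe = agg$probe,
                    frequency = agg$frequency,
                    mean_db = agg$s11_db[, "mean"],
                    sd_db = agg$s11_db[, "sd"],
                    n = as.integer(agg$s11_db[, "n"]))
  if (any(out$n < 2)) stop("need at least 2 subjects per group for an SD")
  out[order(out$sc_class, out$probe, out$frequency), , drop = FALSE]
}

#' Shapiro-Wilk normality test on dB values
#'
#' Tests a per-frequency sample of dB reflection values for normality
#' (log-normal S11 magnitude). `p > 0.05` is read as compatible with
#' dB-normality.
#'
#' @param values Numeric vector, `n >= 3`; a constant sample is degenerate
#'   and raises an error.
#' @return The Shapiro-Wilk p-value.
#' @export
test_normality <- function(values) {
  if (length(values) < 3L) stop("need at least 3 values")
  if (stats::sd(values) == 0)
    stop("degenerate sample: all values identical")
  stats::shapiro.test(values)$p.value
}

#' Paired comparison of thin- versus thick-SC reflection
#'
#' Two-sided paired t-test of the per-subject difference
#' `thin - thick` (dB), with the 95% confidence interval of the mean
#' difference. A constant difference vector is handled as the degenerate
#' limit (CI collapses onto the constant; p is 1 for zero difference, 0
#' otherwise).
#'
#' @param thin,thick Numeric vectors of per-subject dB values, paired by
#'   subject (equal length, `n >= 2`).
#' @return List with `mean_diff_db`, `ci95_lo`, `ci95_hi`, `p`, `t`, `df`.
#' @export
paired_diff_test <- function(thin, thick) {
  if (length(thin) != length(thick))
    stop("thin and thick must be paired (equal length)")
  if (length(thin) < 2L) stop("need at least 2 pairs")
  d <- thin - thick
  if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
    m <- mean(d)
    return(list(mean_diff_db = m, ci95_lo = m, ci95_hi = m,
                p = if (m == 0) 1 else 0, t = if (m == 0) 0 else Inf,
                df = length(d) - 1L))
  }
  tt <- stats::t.test(thin, thick, paired = TRUE)
  list(mean_diff_db = unname(tt$estimate), ci95_lo = tt$conf.int[1],
       ci95_hi = tt$conf.int[2], p = tt$p.value, t = unname(tt$statistic),
       df = unname(tt$parameter))
}

#' Remove the frequency dependence of the group mean
#'
#' Subtracts the per-(class, probe, frequency) mean from subject-level dB
#' values, leaving residuals with zero mean at every frequency. Used before
#' comparing demographic groups so that the strong frequency trend does not
#' mask small group effects. Applying it twice is a no-op.
#'
#' @param values Subject-level data frame as returned by [subject_values].
#' @return The same data frame with `s11_db` replaced by residuals.
#' @export
normalize_by_frequency_mean <- function(values) {
  stopifnot(all(c("sc_class", "probe", "frequency", "s11_db") %in%
                  names(values)))
  key <- interaction(values$sc_class, values$probe, values$frequency,
                     drop = TRUE)
  values$s11_db <- values$s11_db - stats::ave(values$s11_db, key)
  values
}

#' Compare demographic groups on normalized residuals
#'
#' Pooled two-sample t-test and Bartlett variance-homogeneity test between
#' two levels of a grouping factor (sex or age group), per probe and
#' frequency. The pooled (classic) t-test is used because variance
#' homogeneity is checked alongside via Bartlett.
#'
#' @param residuals Subject-level data frame (typically from
#'   [normalize_by_frequency_mean]) including the factor column.
#' @param factor Name of the grouping column, e.g. `"sex"` or `"age_group"`.
#' @param levels Optional length-2 character vector selecting the two levels
#'   to compare (default: the two levels present, error if more).
#' @return Data frame per (sc_class, probe, frequency) with `mean_diff_db`
#'   (first minus second level), `p_t`, `p_bartlett`, `n1`, `n2`.
#' @export
group_comparison <- function(residuals, factor = "sex", levels = NULL) {
  stopifnot(factor %in% names(residuals))
  g <- residuals[[factor]]
  if (is.null(levels)) {
    levels <- unique(as.character(g))
    if (length(levels) != 2L)
      stop("factor has ", length(levels),
           " levels; supply `levels` to select two")
  }
  d <- residuals[g %in% levels, , drop = FALSE]
  keys <- unique(d[c("sc_class", "probe", "frequency")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$sc_class == keys$sc_class[i] & d$probe == keys$probe[i] &
               d$frequency == keys$frequency[i], ]
    x <- sub$s11_db[sub[[factor]] == levels[1]]
    y <- sub$s11_db[sub[[factor]] == levels[2]]
    if (length(x) < 2L || length(y) < 2L)
      stop("need >= 2 subjects per level at every frequency")
    same <- stats::sd(c(x - mean(x), y - mean(y))) == 0
    pt <- if (same && mean(x) == mean(y)) 1 else
      stats::t.test(x, y, var.equal = TRUE)$p.value
    pb <- if (same) 1 else stats::bartlett.test(list(x, y))$p.value
    data.frame(keys[i, , drop = FALSE], mean_diff_db = mean(x) - mean(y),
               p_t = pt, p_bartlett = pb, n1 = length(x), n2 = length(y))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coverage-percentile curves from a cohort summary
#'
#' `mean_db - k * sd_db` per frequency. Following the labeling convention of
#' the coverage skin models, `k = 1` is labeled "68% coverage" and `k = 2`
#' "95% coverage" (note these labels differ from one-sided normal coverage,
#' which would be ~84% and ~97.7%; the convention is reproduced, not
#' reinterpreted).
#'
#' @param summary Data frame from [summarize_cohort].
#' @param k Number of standard deviations to subtract (>= 0).
#' @return Data frame with columns of `summary` plus `curve_db` and `label`.
#' @export
coverage_curves <- function(summary, k) {
  stopifnot(all(c("mean_db", "sd_db") %in% names(summary)), k >= 0)
  out <- summary
  out$curve_db <- out$mean_db - k * out$sd_db
  out$label <- if (k == 0) "mean" else if (k == 1) "68% coverage" else
    if (k == 2) "95% coverage" else sprintf("mean-%gsd", k)
  out
}
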