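## Pairwise no-gold-standard comparison design and the study's statistical
## layer: per-observer summaries, one-way ANOVA across observers, Wilcoxon
## rank-sum volume comparisons. Target volume definition has no gold
## standard, so every observer is compared against every other observer.

#' All ordered pairwise agreement records for one patient
#'
#' For k observers, one record per ORDERED pair (test, reference): k(k-1)
#' records per patient, i.e. k-1 per observer. Overlap metrics use the
#' default evaluation region with the given margin; surface distances are
#' directed, test to reference.
#'
#' @param structures a [StructureSet-class] with >= 2 manual masks.
#' @param eval_margin_mm specificity evaluation-region margin (mm, default 20).
#' @return data.frame with one row per ordered pair: patient_id,
#'   test_observer, reference_observer, dsc, precision, sensitivity,
#'   specificity, mean_dta_cm, max_dta_cm (NA marks undefined metrics).
#' @export
pairwiseMetrics <- function(structures, eval_margin_mm = 20) {
  obs <- manualMasks(structures)
  if (length(obs) < 2)
    .gtv_error("designError", "pairwise comparison requires >= 2 observers")
  nm <- names(obs)
  pairs <- expand.grid(test = nm, reference = nm, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$test != pairs$reference, , drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- obs[[pairs$test[r]]]; b <- obs[[pairs$reference[r]]]
    met <- maskAgreement(a, b, margin_mm = eval_margin_mm)
    d <- dta(a, b)
    data.frame(patient_id = patientId(structures),
               test_observer = pairs$test[r],
               reference_observer = pairs$reference[r],
               dsc = met$dsc, precision = met$precision,
               sensitivity = met$sensitivity, specificity = met$specificity,
               mean_dta_cm = d$mean_dta_cm, max_dta_cm = d$max_dta_cm)
  })
  do.call(rbind, rows)
}

.metric_cols <- c("dsc", "precision", "sensitivity", "specificity",
                  "mean_dta_cm", "max_dta_cm")

#' Per-observer metric summaries
#'
#' For each test observer and metric: mean, sample standard deviation (n-1
#' denominator) and n over the defined (non-NA) values, pooled across
#' patients and reference observers. An observer/metric cell whose values are
#' all undefined yields NA with n = 0.
#'
#' @param records data.frame from [pairwiseMetrics()] (possibly several
#'   patients row-bound).
#' @return data.frame: observer, metric, mean, sd, n.
#' @export
observerSummary <- function(records) {
  stopifnot(nrow(records) > 0)
  out <- expand.grid(observer = unique(records$test_observer),
                     metric = .metric_cols, stringsAsFactors = FALSE)
  stats <- lapply(seq_len(nrow(out)), function(r) {
    v <- records[records$test_observer == out$observer[r], out$metric[r]]
    v <- v[!is.na(v)]
    data.frame(mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_,
               n = length(v))
  })
  cbind(out, do.call(rbind, stats))
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA: \code{F = (SSB/(k-1)) / (SSW/(N-k))}
#' with the p-value from the F distribution on (k-1, N-k) degrees of freedom.
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2 values).
#' @return list of class \code{TestResult}: statistic, df (length 2), p_value,
#'   method.
#' @export
oneWayAnova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2))
    .gtv_error("designError", "each ANOVA group needs >= 2 values")
  allv <- unlist(groups)
  k <- length(groups); N <- length(allv)
  if (max(allv) == min(allv))
    .gtv_error("degenerateVarianceError", "all values identical; ANOVA undefined")
  gm <- mean(allv)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(lengths(groups) * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0)
    .gtv_error("degenerateVarianceError",
               "zero within-group variance with unequal means; F undefined")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  structure(list(statistic = f, df = c(k - 1, N - k),
                 p_value = pf(f, k - 1, N - k, lower.tail = FALSE),
                 method = "one-way ANOVA"),
            class = "TestResult")
}

#' Wilcoxon rank-sum test
#'
#' Reports the rank-sum statistic W for sample \code{x} (mid-ranks for ties).
#' The two-sided p-value is exact (full enumeration of rank assignments) when
#' \code{length(x) + length(y) <= exact_limit} and there are no ties,
#' otherwise the normal approximation with tie correction and continuity
#' correction. The default limit of 20 keeps study-sized volume comparisons
#' (7 vs 7 patients) on the exact path.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_limit largest total sample size for exact enumeration.
#' @return a \code{TestResult} list: statistic (rank sum of x), p_value,
#'   method, exact (logical).
#' @export
wilcoxonRankSum <- function(x, y, exact_limit = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) > 0, length(y) > 0)
  nx <- length(x); ny <- length(y)
  ties <- any(duplicated(c(x, y)))
  use_exact <- (nx + ny) <= exact_limit && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact, correct = TRUE))
  W <- unname(wt$statistic) + nx * (nx + 1) / 2   # Mann-Whitney U -> rank sum
  structure(list(statistic = W, p_value = unname(wt$p.value),
                 method = "Wilcoxon rank sum", exact = use_exact),
            class = "TestResult")
}

#' Compare manual and automatic GTV sizes
#'
#' One Wilcoxon rank-sum test per (observer, multiplier) pair over the
#' per-patient volumes, plus per-source medians and ranges.
#'
#' @param manual_volumes named list: observer -> numeric per-patient volumes
#'   (ccm), all covering the same patients.
#' @param auto_volumes named list: multiplier -> numeric per-patient volumes.
#' @return list with \code{tests} (data.frame observer, multiplier, w, p_value)
#'   and \code{volumes} (data.frame source, median_ccm, min_ccm, max_ccm).
#' @export
sizeComparison <- function(manual_volumes, auto_volumes) {
  n_pat <- unique(c(lengths(manual_volumes), lengths(auto_volumes)))
  if (length(n_pat) != 1)
    .gtv_error("designError", "volume lists must cover the same patients")
  tests <- expand.grid(observer = names(manual_volumes),
                       multiplier = names(auto_volumes),
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tests)), function(r) {
    t <- wilcoxonRankSum(manual_volumes[[tests$observer[r]]],
                         auto_volumes[[tests$multiplier[r]]])
    data.frame(w = t$statistic, p_value = t$p_value)
  })
  tests <- cbind(tests, do.call(rbind, res))
  vols <- c(manual_volumes, auto_volumes)
  volumes <- data.frame(source = names(vols),
                        median_ccm = vapply(vols, median, numeric(1)),
                        min_ccm = vapply(vols, min, numeric(1)),
                        max_ccm = vapply(vols, max, numeric(1)),
                        row.names = NULL)
  list(tests = tests, volumes = volumes)
}

#' ANOVA across observers for every agreement metric
#'
#' Observations are the per-comparison metric values (k-1 per observer per
#' patient, pooled over patients); groups are the test observers. Undefined
#' (NA) values are dropped. This pools within-patient repeats exactly as a
#' naive one-way ANOVA would; within-patient correlation is ignored.
#'
#' @param records row-bound [pairwiseMetrics()] output for a cohort.
#' @param p_adjust optional multiplicity correction passed to
#'   [stats::p.adjust()] (e.g. \code{"holm"}); default \code{"none"}.
#' @return data.frame: metric, f, df1, df2, p_value.
#' @export
metricAnova <- function(records, p_adjust = "none") {
  rows <- lapply(.metric_cols, function(mc) {
    groups <- split(records[[mc]], records$test_observer)
    res <- oneWayAnova(groups)
    data.frame(metric = mc, f = res$statistic, df1 = res$df[1],
               df2 = res$df[2], p_value = res$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}
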