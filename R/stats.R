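#' Percent difference of a relative to b
#'
#' \code{100 * (a - b) / b}, the convention used for all WT-vs-KO contrasts
#' (e.g. 27 N vs 18 N maximum load is a 50\% difference).
#'
#' @param a,b numbers, \code{b != 0}.
#' @return Percent difference.
#' @export
percent_difference <- function(a, b) {
  if (any(b == 0)) undefined_metric("percent difference undefined for b = 0")
  100 * (a - b) / b
}

#' Unpaired two-tailed Student's t-test
#'
#' Classical pooled-variance two-sample t-test (Welch via \code{welch =
#' TRUE}). Degenerate zero-variance inputs are flagged: equal means give
#' p = 1, unequal means p = 0.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return \code{list(t, p, df, degenerate)}.
#' @export
ttest_unpaired <- function(x, y, welch = FALSE) {
  if (length(x) < 2 || length(y) < 2)
    data_error("need at least 2 values per group")
  if (sd(x) == 0 && sd(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                p = if (eq) 1 else 0,
                df = length(x) + length(y) - 2, degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

#' One-way analysis of variance
#'
#' Between/within mean-square F ratio across two or more groups.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return \code{list(f, p, df_between, df_within, degenerate)}.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    data_error("need >= 2 groups with >= 2 values each")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (sd(values) == 0)
    return(list(f = NaN, p = NA_real_, df_between = length(groups) - 1,
                df_within = length(values) - length(groups),
                degenerate = TRUE))
  tab <- anova(aov(values ~ g))
  list(f = tab[["F value"]][1], p = tab[["Pr(>F)"]][1],
       df_between = tab[["Df"]][1], df_within = tab[["Df"]][2],
       degenerate = FALSE)
}

#' Relative expression by the delta-delta-Ct method
#'
#' \code{dCt = Ct_target - Ct_reference} per sample; \code{ddCt} subtracts
#' the mean calibrator dCt; fold change is \code{2^(-ddCt)}.
#'
#' @param records \code{data.frame} with columns \code{sample_id},
#'   \code{ct_target}, \code{ct_reference}, \code{group}
#'   (\code{"calibrator"} or \code{"test"}).
#' @return \code{records} with \code{dct}, \code{ddct}, \code{fold_change}
#'   columns.
#' @export
ddct_fold_change <- function(records) {
  need <- c("sample_id", "ct_target", "ct_reference", "group")
  if (!all(need %in% names(records)))
    param_error("records need sample_id, ct_target, ct_reference, group")
  if (!any(records$group == "calibrator"))
    stop(errorCondition("no calibrator records",
                        class = c("osteomech_config_error",
                                  "osteomech_error")))
  if (any(records$ct_target <= 0 | records$ct_target >= 45 |
            records$ct_reference <= 0 | records$ct_reference >= 45))
    data_error("Ct values must lie in (0, 45)")
  dct <- records$ct_target - records$ct_reference
  ddct <- dct - mean(dct[records$group == "calibrator"])
  records$dct <- dct
  records$ddct <- ddct
  records$fold_change <- 2^(-ddct)
  records
}

#' Ratio of group means with a bootstrap confidence interval
#'
#' For indices like RANKL/OPG: \code{mean(numerator) / mean(denominator)},
#' with a seeded nonparametric bootstrap CI.
#'
#' @param numerator,denominator numeric samples.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return \code{list(ratio, ci_lower, ci_upper)}.
#' @export
ratio_metric <- function(numerator, denominator, n_boot = 2000, conf = 0.95,
                         seed = 1L) {
  if (mean(denominator) == 0)
    undefined_metric("ratio undefined for zero denominator mean")
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    num <- sample(numerator, replace = TRUE)
    den <- sample(denominator, replace = TRUE)
    if (mean(den) == 0) NA_real_ else mean(num) / mean(den)
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE)
  list(ratio = mean(numerator) / mean(denominator),
       ci_lower = unname(qs[1]), ci_upper = unname(qs[2]))
}

#' Assemble a cross-module phenotype report
#'
#' Takes named per-metric WT/KO samples and produces the cohort table: group
#' means, SDs, n, percent difference of means, and unpaired t-test p-value
#' per metric.
#'
#' @param metrics named list; each element is
#'   \code{list(wt = numeric, ko = numeric, units = "...")}.
#' @param provenance optional named list (seeds, inputs) stored as an
#'   attribute.
#' @return \code{data.frame}, one row per metric, with the provenance
#'   attached as the \code{"provenance"} attribute.
#' @export
build_report <- function(metrics, provenance = NULL) {
  if (length(metrics) == 0L)
    stop(errorCondition("no stage outputs supplied",
                        class = c("osteomech_validation_error",
                                  "osteomech_error")))
  rows <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    tt <- if (length(m$wt) >= 2 && length(m$ko) >= 2)
      ttest_unpaired(m$wt, m$ko) else list(t = NA_real_, p = NA_real_)
    data.frame(metric = nm,
               units = if (is.null(m$units)) "" else m$units,
               mean_wt = mean(m$wt), sd_wt = sd(m$wt), n_wt = length(m$wt),
               mean_ko = mean(m$ko), sd_ko = sd(m$ko), n_ko = length(m$ko),
               percent_difference = percent_difference(mean(m$wt),
                                                       mean(m$ko)),
               t = tt$t, p = tt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "provenance") <- c(list(package = "osteomech",
                                    version = "0.1.0",
                                    date = as.character(Sys.Date())),
                               provenance)
  out
}
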