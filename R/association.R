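#' Relative risk with log-method confidence interval
#'
#' Case/control relative risk for carrying a feature (a haplotype, a
#' haplotype group, or per-dog homozygosity). With `a` of `n1` case units
#' and `c` of `n2` control units carrying the feature,
#' \deqn{RR = (a/n_1) / (c/n_2)}
#' with the Katz log-method standard error
#' \eqn{se = \sqrt{1/a - 1/n_1 + 1/c - 1/n_2}},
#' z = |log RR| / se, two-sided p from the normal distribution, and 95%
#' confidence interval \eqn{\exp(\log RR \pm 1.96\, se)}. For haplotype
#' features the unit is the haplotype (two per dog); for homozygosity it
#' is the dog.
#'
#' Zero cells (`a == 0` or `c == 0`) are flagged `undefined` with no
#' continuity correction applied; all statistics are NA in that case.
#'
#' @param a case units carrying the feature.
#' @param n1 total case units.
#' @param c_ control units carrying the feature.
#' @param n2 total control units.
#' @return A one-row data frame of class `association_result`: `a`, `n1`,
#'   `c`, `n2`, `RR`, `log_se`, `z`, `p`, `ci_low`, `ci_high`, `flags`.
#' @examples
#' relative_risk(30, 122, 95, 628)  # RR 1.63, z 2.63
#' @export
relative_risk <- function(a, n1, c_, n2) {
  stopifnot(a >= 0, c_ >= 0, a <= n1, c_ <= n2,
            a == round(a), c_ == round(c_))
  if (a == 0 || c_ == 0) {
    return(structure(data.frame(a = a, n1 = n1, c = c_, n2 = n2,
                                RR = NA_real_, log_se = NA_real_,
                                z = NA_real_, p = NA_real_,
                                ci_low = NA_real_, ci_high = NA_real_,
                                flags = "undefined"),
                     class = c("association_result", "data.frame")))
  }
  rr <- (a / n1) / (c_ / n2)
  se <- sqrt(1 / a - 1 / n1 + 1 / c_ - 1 / n2)
  z <- abs(log(rr)) / se
  p <- 2 * (1 - stats::pnorm(z))
  structure(data.frame(a = a, n1 = n1, c = c_, n2 = n2, RR = rr,
                       log_se = se, z = z, p = p,
                       ci_low = exp(log(rr) - 1.96 * se),
                       ci_high = exp(log(rr) + 1.96 * se),
                       flags = ""),
            class = c("association_result", "data.frame"))
}

#' Per-haplotype case/control association scan
#'
#' One relative risk per haplotype, comparing its count against all other
#' haplotypes pooled, between a case and a control cohort. Haplotypes
#' absent from both cohorts are not emitted; haplotypes with fewer than
#' five carriers in total are flagged `low_count` (advisory only - no
#' multiple-testing correction is applied).
#'
#' @param counts data frame with a haplotype identifier column and one
#'   count column per cohort (e.g. [dla_cohort_counts()]).
#' @param case,control names of the case and control count columns.
#' @param id name of the identifier column.
#' @return Data frame: one [relative_risk()] row per haplotype, keyed by
#'   `id`.
#' @examples
#' scan <- haplotype_scan(dla_cohort_counts("dla_class_II"), "ad")
#' scan[scan$id == 2006, ]  # 2.4-fold AD risk
#' @export
haplotype_scan <- function(counts, case, control = "control", id = "id") {
  stopifnot(all(c(id, case, control) %in% names(counts)))
  n1 <- sum(counts[[case]]); n2 <- sum(counts[[control]])
  keep <- counts[[case]] + counts[[control]] > 0
  counts <- counts[keep, ]
  res <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    relative_risk(counts[[case]][i], n1, counts[[control]][i], n2)))
  low <- counts[[case]] + counts[[control]] < 5
  res$flags <- trimws(paste(res$flags,
                            ifelse(low, "low_count", "")))
  cbind(setNames(counts[id], "id"), res)
}

#' Relative risk of a haplotype group
#'
#' Pools the counts of a set of haplotypes (e.g. the minor class I
#' haplotypes 1008-1057 versus the major 1001-1007) into a single feature
#' and applies [relative_risk()].
#'
#' @inheritParams haplotype_scan
#' @param group identifiers of the haplotypes forming the feature.
#' @return A one-row [relative_risk()] result.
#' @examples
#' cc <- dla_cohort_counts("dla_class_I")
#' group_relative_risk(cc, cc$id >= 1008, case = "sa")  # RR 0.428
#' @export
group_relative_risk <- function(counts, group, case, control = "control",
                                id = "id") {
  member <- if (is.logical(group)) group else counts[[id]] %in% group
  if (!any(member)) stop("empty group")
  if (all(member)) stop("group covers all haplotypes (empty complement)")
  relative_risk(sum(counts[[case]][member]), sum(counts[[case]]),
                sum(counts[[control]][member]), sum(counts[[control]]))
}

#' Per-dog DLA homozygosity relative risk
#'
#' The feature is being homozygous for *any* haplotype in a region; the
#' unit of analysis is the dog, not the haplotype. Accepts either phased
#' diplotype data frames or pre-tabulated counts.
#'
#' @param case_dip,control_dip `diplotypes` data frames from [em_phase()]
#'   for the case and control cohorts (columns `hap1`, `hap2`).
#' @return A one-row [relative_risk()] result (counts are dogs).
#' @export
homozygosity_rr <- function(case_dip, control_dip) {
  a <- sum(case_dip$hap1 == case_dip$hap2)
  c_ <- sum(control_dip$hap1 == control_dip$hap2)
  relative_risk(a, nrow(case_dip), c_, nrow(control_dip))
}

#' @rdname homozygosity_rr
#' @param case_freq,control_freq homozygote frequencies among case and
#'   control dogs.
#' @param n_cases,n_controls cohort sizes (dogs). Counts are the
#'   frequencies times the cohort sizes rounded to the nearest dog.
#' @export
homozygosity_rr_from_freq <- function(case_freq, control_freq,
                                      n_cases, n_controls) {
  relative_risk(round(case_freq * n_cases), n_cases,
                round(control_freq * n_controls), n_controls)
}
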