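#' Per-locus and mean genetic diversity statistics
#'
#' Computes, for each locus with at least two typed individuals in the
#' subset: the total number of alleles Na, the effective number of alleles
#' Ne = 1 / sum(p^2), observed heterozygosity Ho (fraction of typed
#' individuals carrying two distinct alleles), expected heterozygosity
#' He = 1 - sum(p^2) (the uncorrected form), and the inbreeding index
#' FIS = (He - Ho) / He (0 where He = 0). Across-locus means are
#' unweighted; the standard error is the across-locus sample standard
#' deviation divided by the square root of the number of loci.
#'
#' Positive mean FIS indicates population substructure with an excess of
#' homozygotes (inbred subgroups); negative values indicate outbreeding.
#'
#' @param g a [genotype_table()].
#' @param subset individuals to assess (see [subset_genotypes()]).
#' @return An object of class `diversity_stats`: list with `per_locus`
#'   (data frame of locus, n, Na, Ne, Ho, He, FIS) and `summary`
#'   (data frame with `mean` and `se` rows per statistic).
#' @examples
#' g <- genotype_table(data.frame(id = c("a", "b")),
#'                     matrix(c(101L, 101L), 2, 1, dimnames = list(NULL, "L1")),
#'                     matrix(c(103L, 103L), 2, 1, dimnames = list(NULL, "L1")))
#' diversity_stats(g)$per_locus
#' @export
diversity_stats <- function(g, subset = NULL) {
  idx <- resolve_subset(g, subset)
  if (!length(idx)) stop("empty subset")
  rows <- lapply(g$loci, function(L) {
    a1 <- g$a1[idx, L]; a2 <- g$a2[idx, L]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2L) return(NULL)
    p <- as.numeric(table(c(a1[ok], a2[ok]))) / (2 * n)
    he <- 1 - sum(p^2)
    ho <- mean(a1[ok] != a2[ok])
    data.frame(locus = L, n = n, Na = length(p), Ne = 1 / sum(p^2),
               Ho = ho, He = he,
               FIS = if (he > 0) (he - ho) / he else 0)
  })
  per_locus <- do.call(rbind, rows)
  if (is.null(per_locus)) stop("no locus with >= 2 typed individuals")
  stats <- c("Na", "Ne", "Ho", "He", "FIS")
  summ <- data.frame(
    statistic = stats,
    mean = sapply(stats, function(s) mean(per_locus[[s]])),
    se = sapply(stats, function(s)
      stats::sd(per_locus[[s]]) / sqrt(nrow(per_locus))),
    row.names = NULL)
  structure(list(per_locus = per_locus, summary = summ,
                 n_individuals = length(idx)),
            class = "diversity_stats")
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats over %d loci, %d individuals\n",
              nrow(x$per_locus), x$n_individuals))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Write diversity statistics as a TSV
#'
#' One row per locus followed by `MEAN` and `SE` rows.
#'
#' @param ds a [diversity_stats()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_diversity_stats <- function(ds, path) {
  pl <- ds$per_locus
  mrow <- data.frame(locus = "MEAN", n = ds$n_individuals,
                     t(setNames(ds$summary$mean, ds$summary$statistic)))
  srow <- data.frame(locus = "SE", n = NA,
                     t(setNames(ds$summary$se, ds$summary$statistic)))
  out <- rbind(pl, mrow, srow)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
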