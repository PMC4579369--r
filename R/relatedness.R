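#' Internal relatedness
#'
#' Internal relatedness (IR) is a frequency-weighted heterozygosity
#' measure estimating how related an individual's parents were. With H
#' homozygous loci out of N typed loci and f_i the frequency of the i-th
#' of the 2N alleles the individual carries,
#' \deqn{IR = (2H - \sum f_i) / (2N - \sum f_i).}
#' The summation runs over *all* alleles in the genotype, both alleles at
#' every typed locus: under this convention the expected IR of offspring
#' of full siblings equals their parents' kinship (0.25). Loci with
#' missing calls are excluded from H, N and the frequency sum. Fully
#' homozygous individuals have IR = 1; rare-allele heterozygotes can fall
#' below 0 (bounded by -1).
#'
#' @param g a [genotype_table()].
#' @param freqs an [allele_freqs()] table; by default computed from `g`
#'   itself (the individual included). Alleles absent from `freqs` receive
#'   the floor frequency 1 / n_haplotypes at that locus.
#' @param loci optional locus subset.
#' @return Data frame with one row per individual: `id`, `IR`, `H`
#'   (homozygous typed loci), `N` (typed loci), `sum_f`. Individuals with
#'   no typed locus get NA.
#' @seealso [adjusted_internal_relatedness()], [mean_full_sib_ir()]
#' @export
internal_relatedness <- function(g, freqs = NULL, loci = NULL) {
  if (is.null(freqs)) freqs <- compute_allele_frequencies(g)
  use <- intersect(loci %||% g$loci, names(freqs$freq))
  dropped <- setdiff(loci %||% g$loci, use)
  if (length(dropped))
    message("loci absent from frequency table excluded: ",
            paste(dropped, collapse = ", "))
  n <- nrow(g$a1)
  H <- N <- integer(n); sumf <- numeric(n)
  for (L in use) {
    a1 <- g$a1[, L]; a2 <- g$a2[, L]
    ok <- !is.na(a1)
    p <- freqs$freq[[L]]
    floor_f <- 1 / freqs$n_hap[[L]]
    f1 <- p[as.character(a1)]; f2 <- p[as.character(a2)]
    f1[is.na(f1)] <- floor_f; f2[is.na(f2)] <- floor_f
    N <- N + ok
    H <- H + (ok & a1 == a2 & !is.na(a2))
    sumf <- sumf + ifelse(ok, f1 + f2, 0)
  }
  ir <- ifelse(N > 0, (2 * H - sumf) / (2 * N - sumf), NA_real_)
  data.frame(id = g$meta$id, IR = ir, H = H, N = N, sum_f = sumf,
             row.names = NULL)
}

#' Reference-adjusted internal relatedness
#'
#' Recomputes IR with the allele frequencies of an outbred reference
#' population substituted for the study population's own. Alleles the
#' reference never carries receive the floor frequency
#' 1 / (2 x reference sample size); loci missing from the reference are
#' excluded (with a message). Because breed-common alleles are rarer in a
#' diverse reference, adjusted IR shifts right of raw IR, exposing
#' diversity lost during breed formation.
#'
#' @param g a [genotype_table()].
#' @param ref reference [allele_freqs()] covering the typed loci.
#' @return As [internal_relatedness()], with column `IR` renamed
#'   `adjusted_IR`.
#' @export
adjusted_internal_relatedness <- function(g, ref) {
  res <- internal_relatedness(g, freqs = ref)
  names(res)[names(res) == "IR"] <- "adjusted_IR"
  res
}

#' Mean internal relatedness of simulated full-sib offspring
#'
#' Gene-drops offspring of full-sibling matings from an outbred base
#' population at the supplied allele frequencies and returns their mean IR
#' (computed with the base-population frequencies). For each offspring,
#' two unrelated parents are drawn in Hardy-Weinberg proportions, two full
#' siblings are bred from them, and the siblings are mated. Under the
#' all-allele IR convention the expectation is the full-sib kinship, 0.25;
#' with `mating = "unrelated"` the parents of the final offspring are
#' drawn independently and the expectation is 0.
#'
#' @param freqs base-population [allele_freqs()] (e.g.
#'   [standard_poodle_frequencies()]).
#' @param n_offspring number of offspring to simulate (>= 1000 for a
#'   stable mean).
#' @param seed integer seed.
#' @param mating `"full_sib"` or `"unrelated"`.
#' @return List with `mean_ir`, `se`, `n`, and the per-offspring `ir`
#'   vector.
#' @export
mean_full_sib_ir <- function(freqs, n_offspring = 1000, seed = 1,
                             mating = c("full_sib", "unrelated")) {
  mating <- match.arg(mating)
  loci <- names(freqs$freq)
  with_op_seed(seed, "mean_full_sib_ir", {
    n <- as.integer(n_offspring)
    H <- N <- integer(n); sumf <- numeric(n)
    pick <- function(m1, m2) ifelse(stats::runif(n) < 0.5, m1, m2)
    for (L in loci) {
      p <- freqs$freq[[L]]
      draw <- function() sample(names(p), n, replace = TRUE, prob = p)
      sA1 <- draw(); sA2 <- draw()  # grandsire
      dA1 <- draw(); dA2 <- draw()  # granddam
      if (mating == "full_sib") {
        sib1_1 <- pick(sA1, sA2); sib1_2 <- pick(dA1, dA2)
        sib2_1 <- pick(sA1, sA2); sib2_2 <- pick(dA1, dA2)
      } else {
        sib1_1 <- draw(); sib1_2 <- draw()
        sib2_1 <- draw(); sib2_2 <- draw()
      }
      o1 <- pick(sib1_1, sib1_2); o2 <- pick(sib2_1, sib2_2)
      H <- H + (o1 == o2)
      N <- N + 1L
      sumf <- sumf + p[o1] + p[o2]
    }
    ir <- (2 * H - sumf) / (2 * N - sumf)
    list(mean_ir = mean(ir), se = stats::sd(ir) / sqrt(n), n = n, ir = ir)
  })
}

#' Pairwise codominant genotypic distance
#'
#' Squared genetic distance between individuals, summed over loci at which
#' both are typed, using the codominant genotypic distance table:
#' identical genotypes 0; one shared allele 1 (whether `ii` vs `ij` or
#' `ij` vs `ik`); two heterozygotes with no shared allele 2; homozygote vs
#' non-matching heterozygote 3; two different homozygotes 4.
#'
#' @param g a [genotype_table()].
#' @return A symmetric matrix of squared distances with zero diagonal
#'   (class `dist_squared`). Pairs with no co-typed locus are NA (a
#'   warning is raised); they must be resolved before [pcoa()].
#' @export
genetic_distance <- function(g) {
  n <- nrow(g$a1)
  if (n < 2L) stop("need >= 2 individuals")
  D <- matrix(0, n, n, dimnames = list(g$meta$id, g$meta$id))
  shared <- matrix(0L, n, n)
  for (L in g$loci) {
    a1 <- g$a1[, L]; a2 <- g$a2[, L]
    ok <- !is.na(a1)
    hom <- a1 == a2
    m2 <- outer(a1, a1, "==") & outer(a2, a2, "==")      # identical genotype
    m1 <- outer(a1, a1, "==") | outer(a1, a2, "==") |
          outer(a2, a1, "==") | outer(a2, a2, "==")      # >= 1 shared allele
    bothhom <- outer(hom, hom, "&")
    bothhet <- outer(!hom, !hom, "&")
    d <- ifelse(m2, 0,
         ifelse(m1, 1,
         ifelse(bothhom, 4, ifelse(bothhet, 2, 3))))
    pairok <- outer(ok, ok, "&")
    d[!pairok] <- 0
    D <- D + d
    shared <- shared + pairok
  }
  if (any(shared == 0 & upper.tri(shared))) {
    warning("pairs with no co-typed locus recorded as NA")
    D[shared == 0] <- NA
  }
  diag(D) <- 0
  structure(D, class = c("dist_squared", "matrix"))
}

#' Principal coordinate analysis
#'
#' Classical metric scaling of a squared-distance matrix: Gower
#' double-centering of -D^2/2, eigendecomposition, coordinates equal to
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues (possible for non-Euclidean distances) are
#' reported but contribute no coordinates. Percent variance is relative to
#' the sum of positive eigenvalues.
#'
#' @param d squared-distance matrix from [genetic_distance()] (or any
#'   symmetric non-negative matrix of squared distances with zero
#'   diagonal).
#' @param axes number of coordinate axes to return.
#' @return List of class `pcoa`: `coordinates` (individuals x axes),
#'   `eigenvalues` (all, descending), `percent_variance` (per returned
#'   axis).
#' @export
pcoa <- function(d, axes = 3) {
  d <- unclass(d)
  if (anyNA(d)) stop("distance matrix contains NA")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("non-symmetric input")
  n <- nrow(d)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% d %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev)) * 1e-9
  pos <- which(ev > tol)
  k <- min(axes, length(pos))
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(ev[pos[seq_len(k)]]), k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = ev,
                 percent_variance = 100 * ev[pos[seq_len(k)]] / sum(ev[pos])),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("pcoa: %d individuals, %d axes (%.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              sum(x$percent_variance)))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Compares a per-individual statistic (e.g. IR or observed
#' heterozygosity) across cohorts: one-way ANOVA F test followed by Tukey
#' honest significant differences at 95% family-wise confidence. Groups
#' with fewer than two values are excluded with a warning.
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @return List of class `group_comparison`: `F`, `p`, `df`, `tukey`
#'   (data frame of pairwise differences, CI bounds and adjusted p), and
#'   `groups` (per-group n and mean).
#' @export
compare_groups <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  sizes <- table(labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups with < 2 values excluded: ",
            paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    values <- values[keep]; labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) stop("need >= 2 groups with >= 2 values")
  # C-locale level order so comparison labels are platform-independent
  f <- factor(labels, levels = sort(unique(labels), method = "radix"))
  fit <- stats::aov(values ~ f)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$f
  tukey <- data.frame(comparison = rownames(tk), tk, row.names = NULL)
  names(tukey) <- c("comparison", "diff", "lwr", "upr", "p_adj")
  groups <- data.frame(group = levels(f),
                       n = as.integer(table(f)),
                       mean = tapply(values, f, mean))
  structure(list(F = an$`F value`[1], p = an$`Pr(>F)`[1],
                 df = unname(an$Df), tukey = tukey, groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$F, x$p))
  print(x$tukey, digits = 4)
  invisible(x)
}
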