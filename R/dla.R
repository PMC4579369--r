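# DLA haplotype phasing by expectation-maximization.
#
# The DLA class I block (4 STRs) and class II block (3 STRs) sit in
# strong linkage disequilibrium on CFA12, so multilocus genotypes resolve
# into a small number of haplotypes. Phasing uses the classic multilocus
# EM over haplotype frequencies under random pairing of haplotypes
# (Hardy-Weinberg at the haplotype level).

hap_key <- function(m) apply(m, 1, paste, collapse = "/")
hap_split <- function(keys) lapply(strsplit(keys, "/", fixed = TRUE),
                                   as.integer)

# Enumerate the haplotype pairs consistent with one multilocus genotype.
# a, b: integer vectors of the two alleles per locus (unordered).
# Returns a 2-column character matrix of haplotype keys, hap1 <= hap2 in
# tuple order.
consistent_pairs <- function(a, b) {
  het <- which(a != b)
  k <- length(a)
  if (!length(het)) {
    key <- paste(a, collapse = "/")
    return(matrix(c(key, key), 1, 2))
  }
  free <- het[-1]  # first het locus anchored to avoid mirror duplicates
  n_comb <- 2L^length(free)
  h1 <- matrix(rep(a, each = n_comb), n_comb, k)
  h2 <- matrix(rep(b, each = n_comb), n_comb, k)
  if (length(free)) {
    flips <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(free))))
    for (j in seq_along(free)) {
      L <- free[j]
      h1[flips[, j], L] <- b[L]
      h2[flips[, j], L] <- a[L]
    }
  }
  k1 <- hap_key(h1); k2 <- hap_key(h2)
  swap <- mapply(function(x, y) {
    tx <- as.integer(strsplit(x, "/", fixed = TRUE)[[1]])
    ty <- as.integer(strsplit(y, "/", fixed = TRUE)[[1]])
    d <- tx - ty; d <- d[d != 0]
    length(d) > 0 && d[1] > 0
  }, k1, k2)
  cbind(ifelse(swap, k2, k1), ifelse(swap, k1, k2))
}

# Core EM on a list of per-individual candidate pair matrices.
# Returns frequencies over the candidate haplotype set, the final
# log-likelihood and per-individual posteriors of every pair.
run_em <- function(pair_list, haps, p0, max_iter = 2000, tol = 1e-8) {
  idx_list <- lapply(pair_list, function(m)
    cbind(match(m[, 1], haps), match(m[, 2], haps)))
  p <- p0
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    counts <- numeric(length(haps))
    ll <- 0
    for (ind in idx_list) {
      pri <- p[ind[, 1]] * p[ind[, 2]] * ifelse(ind[, 1] == ind[, 2], 1, 2)
      s <- sum(pri)
      if (s <= 0) {  # degenerate start; restart mass uniformly
        pri <- rep(1, nrow(ind)); s <- nrow(ind)
      }
      w <- pri / s
      ll <- ll + log(s)
      counts[ind[, 1]] <- counts[ind[, 1]] + w
      counts[ind[, 2]] <- counts[ind[, 2]] + w
    }
    if (ll < ll_old - 1e-9)
      stop("EM log-likelihood decreased (", ll_old, " -> ", ll, ")")
    p <- counts / (2 * length(idx_list))
    if (is.finite(ll_old) && ll - ll_old < tol) { ll_old <- ll; break }
    ll_old <- ll
  }
  post <- lapply(idx_list, function(ind) {
    pri <- p[ind[, 1]] * p[ind[, 2]] * ifelse(ind[, 1] == ind[, 2], 1, 2)
    pri / sum(pri)
  })
  list(p = setNames(p, haps), loglik = ll_old, post = post)
}

#' Phase a DLA region by expectation-maximization
#'
#' Estimates haplotype frequencies for one DLA STR block and assigns each
#' dog its maximum-posterior diplotype. The E-step weights every
#' haplotype pair consistent with a dog's multilocus genotype by its
#' probability under random pairing at the current frequencies; the
#' M-step re-estimates frequencies from the expected pair counts.
#' Iteration stops when the log-likelihood improves by less than `tol`
#' (or after `max_iter` iterations). Because the likelihood surface can
#' be multimodal, the EM is restarted from `n_starts` random frequency
#' vectors plus one uniform start, and the solution with the best final
#' log-likelihood is kept, making the result deterministic given the data
#' and `seed`.
#'
#' Dogs with a missing call at any region locus are excluded from phasing
#' and listed in the result. Dogs with at most one heterozygous locus are
#' phase-unambiguous and receive posterior exactly 1.
#'
#' @param g a [genotype_table()] containing the region's loci.
#' @param region `"dla_class_I"` (4 loci) or `"dla_class_II"` (3 loci).
#' @param loci loci forming the haplotype, in tuple order; defaults to the
#'   packaged panel ([dla_panel()]) when those loci are present in `g`.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @param n_starts random restarts in addition to the uniform start.
#' @param seed integer seed for the restarts.
#' @param min_freq haplotypes below this estimated frequency are pruned
#'   from the frequency table.
#' @return List of class `dla_phase`: `frequencies` (data frame
#'   `haplotype`, `frequency`, descending; frequencies sum to 1),
#'   `diplotypes` (data frame `id`, `hap1`, `hap2`, `posterior`),
#'   `n_haplotypes` (2 x phased dogs), `loglik`, `excluded` (ids not
#'   phased), `region`, `loci`.
#' @examples
#' \dontrun{
#' ph <- em_phase(g, "dla_class_I")
#' head(ph$frequencies)
#' }
#' @export
em_phase <- function(g, region = c("dla_class_I", "dla_class_II"),
                     loci = NULL, max_iter = 2000, tol = 1e-8,
                     n_starts = 10, seed = 1, min_freq = 1e-6) {
  region <- match.arg(region)
  if (is.null(loci)) {
    pan <- dla_panel()
    loci <- pan$locus[pan$region == region][order(
      pan$tuple_position[pan$region == region])]
  }
  miss <- setdiff(loci, g$loci)
  if (length(miss)) stop("region loci absent: ", paste(miss, collapse = ", "))
  a1 <- g$a1[, loci, drop = FALSE]; a2 <- g$a2[, loci, drop = FALSE]
  complete <- stats::complete.cases(a1)
  excluded <- g$meta$id[!complete]
  if (sum(complete) < 10L)
    stop("need >= 10 individuals typed at all region loci")
  ids <- g$meta$id[complete]
  a1 <- a1[complete, , drop = FALSE]; a2 <- a2[complete, , drop = FALSE]
  pair_list <- lapply(seq_along(ids), function(i)
    consistent_pairs(a1[i, ], a2[i, ]))
  haps <- sort(unique(unlist(lapply(pair_list, c))))
  n_h <- length(haps)
  starts <- with_op_seed(seed, "em_phase", {
    c(list(rep(1 / n_h, n_h)),
      lapply(seq_len(n_starts), function(s) {
        x <- stats::rexp(n_h); x / sum(x)
      }))
  })
  best <- NULL
  for (p0 in starts) {
    fit <- run_em(pair_list, haps, p0, max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$loglik > best$loglik + 1e-12) best <- fit
  }
  # maximum-posterior diplotype per dog; ties broken by the
  # lexicographically smallest haplotype tuple pair
  dip <- do.call(rbind, lapply(seq_along(ids), function(i) {
    m <- pair_list[[i]]; w <- best$post[[i]]
    if (nrow(m) == 1L) w <- 1
    top <- which(w >= max(w) - 1e-12)
    if (length(top) > 1L) top <- top[order(m[top, 1], m[top, 2])][1L]
    data.frame(id = ids[i], hap1 = m[top, 1], hap2 = m[top, 2],
               posterior = w[top])
  }))
  p <- best$p[best$p >= min_freq]
  p <- p / sum(p)
  freqs <- data.frame(haplotype = names(p), frequency = unname(p))
  freqs <- freqs[order(-freqs$frequency, freqs$haplotype), ]
  rownames(freqs) <- NULL
  structure(list(frequencies = freqs, diplotypes = dip,
                 n_haplotypes = 2L * length(ids), loglik = best$loglik,
                 excluded = excluded, region = region, loci = loci),
            class = "dla_phase")
}

#' @export
print.dla_phase <- function(x, ...) {
  cat(sprintf("dla_phase [%s]: %d dogs, %d haplotypes, loglik %.3f\n",
              x$region, x$n_haplotypes / 2, nrow(x$frequencies), x$loglik))
  print(utils::head(x$frequencies, 8), digits = 3)
  invisible(x)
}

#' Name haplotypes against the published registry
#'
#' Exact tuple matches receive their registry id (1001-1999 for class I,
#' 2001-2999 for class II); novel tuples receive provisional ids starting
#' at 9001, assigned in sorted tuple order so they are stable within a
#' run and can never collide with registry ids.
#'
#' @param haplotypes character vector of `/`-separated allele tuples (as
#'   in [em_phase()] output) or a list of integer vectors.
#' @param registry registry data frame ([dla_registry()] subset to one
#'   region).
#' @return Data frame `haplotype`, `id`, `novel`.
#' @export
name_haplotypes <- function(haplotypes, registry) {
  if (is.list(haplotypes))
    haplotypes <- vapply(haplotypes, paste, "", collapse = "/")
  lens <- lengths(strsplit(haplotypes, "/", fixed = TRUE))
  reg_len <- length(registry$alleles[[1]])
  if (any(lens != reg_len))
    stop("tuple length mismatch: expected ", reg_len, " alleles")
  reg_keys <- vapply(registry$alleles, paste, "", collapse = "/")
  id <- registry$id[match(haplotypes, reg_keys)]
  novel <- is.na(id)
  if (any(novel)) {
    novel_sorted <- sort(unique(haplotypes[novel]))
    id[novel] <- 9000L + match(haplotypes[novel], novel_sorted)
  }
  data.frame(haplotype = haplotypes, id = as.integer(id), novel = novel)
}

#' Join class I and class II diplotypes into extended haplotypes
#'
#' Chromosome-scale DLA haplotypes span both blocks (about 2 Mb). Given
#' per-region phased diplotypes for the same dogs, a second EM estimates
#' the frequencies of joint (class I, class II) haplotypes: each dog
#' contributes the two cis/trans pairings consistent with its per-region
#' diplotypes, and frequencies are seeded from the product of the
#' per-region solutions. Dogs phased in only one region are excluded (and
#' listed in the `excluded` attribute).
#'
#' @param dip1,dip2 `diplotypes` data frames from [em_phase()] for class I
#'   and class II.
#' @param max_iter,tol EM controls.
#' @return Data frame of class `extended_haplotypes`: `class_I`,
#'   `class_II`, `count` (two per dog, from the maximum-posterior
#'   pairing), sorted by count.
#' @export
extended_haplotypes <- function(dip1, dip2, max_iter = 2000, tol = 1e-8) {
  common <- intersect(dip1$id, dip2$id)
  excluded <- setdiff(union(dip1$id, dip2$id), common)
  if (!length(common)) stop("no individual phased in both regions")
  d1 <- dip1[match(common, dip1$id), ]
  d2 <- dip2[match(common, dip2$id), ]
  joint_key <- function(h1, h2) paste(h1, h2, sep = "|")
  pair_list <- lapply(seq_along(common), function(i) {
    cis <- c(joint_key(d1$hap1[i], d2$hap1[i]),
             joint_key(d1$hap2[i], d2$hap2[i]))
    trans <- c(joint_key(d1$hap1[i], d2$hap2[i]),
               joint_key(d1$hap2[i], d2$hap1[i]))
    m <- rbind(sort(cis), sort(trans))
    m[!duplicated(m), , drop = FALSE]
  })
  haps <- sort(unique(unlist(pair_list)))
  parts <- strsplit(haps, "|", fixed = TRUE)
  f1 <- tapply(c(d1$hap1, d1$hap2), c(d1$hap1, d1$hap2), length)
  f2 <- tapply(c(d2$hap1, d2$hap2), c(d2$hap1, d2$hap2), length)
  p0 <- vapply(parts, function(h)
    (f1[h[1]] %||% 0.5) * (f2[h[2]] %||% 0.5), 0)
  p0[is.na(p0)] <- 0.5
  p0 <- p0 / sum(p0)
  fit <- run_em(pair_list, haps, p0, max_iter = max_iter, tol = tol)
  counts <- integer(length(haps))
  for (i in seq_along(common)) {
    m <- pair_list[[i]]; w <- fit$post[[i]]
    if (nrow(m) == 1L) w <- 1
    top <- which.max(w)
    j <- match(m[top, ], haps)
    counts[j[1]] <- counts[j[1]] + 1L
    counts[j[2]] <- counts[j[2]] + 1L
  }
  keep <- counts > 0L
  out <- data.frame(
    class_I = vapply(parts[keep], `[`, "", 1),
    class_II = vapply(parts[keep], `[`, "", 2),
    count = counts[keep])
  out <- out[order(-out$count, out$class_I, out$class_II), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  class(out) <- c("extended_haplotypes", "data.frame")
  out
}

#' Check class I / class II homozygosity consistency
#'
#' Under the strong linkage disequilibrium of the DLA, a dog homozygous
#' for a class I haplotype should also be homozygous in class II. This
#' reports dogs violating that expectation (homozygous class I,
#' heterozygous class II) - a useful screen for phasing errors or
#' recombinants.
#'
#' @param dip1,dip2 `diplotypes` data frames from [em_phase()].
#' @return List with `violations` (count) and `ids`.
#' @export
homozygosity_consistency <- function(dip1, dip2) {
  common <- intersect(dip1$id, dip2$id)
  d1 <- dip1[match(common, dip1$id), ]
  d2 <- dip2[match(common, dip2$id), ]
  bad <- d1$hap1 == d1$hap2 & d2$hap1 != d2$hap2
  list(violations = sum(bad), ids = common[bad])
}
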