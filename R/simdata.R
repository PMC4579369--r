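# Seeded synthetic-data generation: bottlenecked pedigrees, gene-dropped
# STR genotypes, linked DLA haplotype blocks and liability-threshold
# disease phenotypes.

#' Simulation configuration
#'
#' Bundles every parameter of the simulator. All stochastic operations
#' derive their RNG stream from `seed` and the operation name, so a given
#' configuration reproduces bit-identical output regardless of the order
#' in which operations are called.
#'
#' @param seed integer seed.
#' @param n_founders founder census (half sires, half dams).
#' @param n_generations generations bred after the founders.
#' @param offspring_per_mating litter size retained per mating.
#' @param popular_sire_weight non-negative; sires are drawn with
#'   probability proportional to `exp(weight x quality)` with quality
#'   drawn once per sire from N(0, 1). 0 gives random mating; large values
#'   concentrate paternity in few sires (the popular-sire effect behind
#'   breed bottlenecks).
#' @param n_lines number of breeding lines (kennels). Founders are split
#'   evenly across lines; a mating's dam line is kept unless a migration
#'   event draws the sire from another line. Several lines plus drift
#'   yield the substructured population (inbred core, diverse outliers)
#'   whose pooled FIS is positive.
#' @param migration_rate probability that a mating's sire is drawn from
#'   outside the dam's line.
#' @param outlier_random_mating when TRUE (and `n_lines > 1`), sires for
#'   dams of the last line are drawn uniformly rather than by popularity,
#'   keeping that line outbred relative to the popular-sire core - the
#'   "genetic outlier" stratum of a bottlenecked breed.
#' @param allele_freqs base-population [allele_freqs()] for the genomic
#'   loci; default the packaged breed spectrum
#'   ([standard_poodle_frequencies()]).
#' @param n_genomic_loci number of genomic loci simulated (first columns
#'   of `allele_freqs`).
#' @param dla_freqs data frame `region`, `id`, `alleles`, `frequency`
#'   ([dla_registry()] layout) giving founder DLA haplotype frequencies,
#'   or NULL to skip the DLA block.
#' @param dla_linkage `"coupled"` (founder class II haplotype determined
#'   by the class I haplotype - complete founder linkage disequilibrium)
#'   or `"independent"`.
#' @param dla_outlier_flatten in `[0, 1]`; how strongly the haplotype
#'   spectrum of founders in the last (outlier) line is flattened toward
#'   uniform. 0 = all lines draw from the same skewed spectrum; larger
#'   values concentrate rare haplotypes in the outlier line, emulating
#'   minor-haplotype retention outside the bottlenecked core.
#' @param dla_recombination_rate per-meiosis recombination probability
#'   between the class I and class II blocks.
#' @param liability per-disease liability-threshold parameters: a named
#'   list of lists with `beta_inbreeding`, `beta_risk`, `risk_haplotypes`
#'   (registry ids), `threshold`, `sd`. Disease occurs when
#'   `beta_inbreeding * F + beta_risk * (risk haplotypes carried) + e`
#'   exceeds `threshold`, `e ~ N(0, sd)`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_founders = 60,
                       n_generations = 6,
                       offspring_per_mating = 2,
                       popular_sire_weight = 0,
                       n_lines = 1,
                       migration_rate = 0.05,
                       outlier_random_mating = FALSE,
                       allele_freqs = NULL,
                       n_genomic_loci = 33,
                       dla_freqs = NULL,
                       dla_linkage = c("coupled", "independent"),
                       dla_outlier_flatten = 0,
                       dla_recombination_rate = 0.01,
                       liability = list(
                         SA = list(beta_inbreeding = 8, beta_risk = 0,
                                   risk_haplotypes = integer(0),
                                   threshold = 2.2, sd = 1),
                         AD = list(beta_inbreeding = 2, beta_risk = 0,
                                   risk_haplotypes = integer(0),
                                   threshold = 2.1, sd = 1))) {
  stopifnot(popular_sire_weight >= 0, n_founders >= 4, n_lines >= 1,
            migration_rate >= 0, migration_rate <= 1,
            dla_recombination_rate >= 0, dla_recombination_rate <= 1)
  structure(list(seed = as.integer(seed), n_founders = n_founders,
                 n_generations = n_generations,
                 offspring_per_mating = offspring_per_mating,
                 popular_sire_weight = popular_sire_weight,
                 n_lines = n_lines, migration_rate = migration_rate,
                 outlier_random_mating = outlier_random_mating,
                 allele_freqs = allele_freqs,
                 n_genomic_loci = n_genomic_loci,
                 dla_freqs = dla_freqs,
                 dla_linkage = match.arg(dla_linkage),
                 dla_outlier_flatten = dla_outlier_flatten,
                 dla_recombination_rate = dla_recombination_rate,
                 liability = liability),
            class = "sim_config")
}

#' A bottlenecked, disease-bearing preset configuration
#'
#' Emulates the study system: a mid-century bottleneck driven by popular
#' sires, a skewed DLA haplotype spectrum taken from the published
#' registry, and two liability-threshold diseases - one (SA-like) tied
#' strongly to inbreeding, one (AD-like) tied weakly to inbreeding but
#' carrying a class II risk haplotype.
#'
#' @param seed integer seed.
#' @param n_founders,n_generations population shape (defaults 120
#'   founders - 30 per line - and 6 generations; smaller founder
#'   censuses let line-level drift swamp the systematic core/outlier
#'   contrast).
#' @return A [sim_config()].
#' @export
paper_like_config <- function(seed = 1, n_founders = 120,
                              n_generations = 6) {
  sim_config(seed = seed, n_founders = n_founders,
             n_generations = n_generations,
             offspring_per_mating = 3,
             popular_sire_weight = 3,
             n_lines = 4,
             migration_rate = 0.05,
             outlier_random_mating = TRUE,
             allele_freqs = standard_poodle_frequencies(),
             dla_freqs = dla_registry(),
             dla_outlier_flatten = 0.8,
             liability = list(
               SA = list(beta_inbreeding = 8, beta_risk = 0,
                         risk_haplotypes = integer(0),
                         threshold = 2.6, sd = 1),
               AD = list(beta_inbreeding = 0.5, beta_risk = 0.8,
                         risk_haplotypes = 2006L,
                         threshold = 1.6, sd = 1)))
}

#' Simulate a bottlenecked pedigree
#'
#' Generation 0 is `n_founders` unrelated founders (alternating sexes,
#' split evenly across `n_lines` breeding lines). Each later generation
#' keeps the census constant: matings draw a dam uniformly at random
#' (with replacement) and a sire from the same line (or, with probability
#' `migration_rate`, from all lines) with probability proportional to
#' `exp(popular_sire_weight x quality)`, quality drawn once per sire per
#' generation from N(0, 1). Each mating leaves `offspring_per_mating`
#' offspring, whose line is the dam's. Birth dates encode the generation
#' as a decade (1950 + 10 x generation).
#'
#' @param cfg a [sim_config()].
#' @return A [pedigree()] with `generation`, `sex` and `line` attributes
#'   (named vectors).
#' @export
simulate_pedigree <- function(cfg) {
  with_op_seed(cfg$seed, "simulate_pedigree", {
    nf <- cfg$n_founders
    id <- sprintf("G0_%03d", seq_len(nf))
    sex <- rep(c("M", "F"), length.out = nf)
    line <- setNames(rep(seq_len(cfg$n_lines), length.out = nf), id)
    rows <- data.frame(id = id, sire = NA_character_, dam = NA_character_,
                       dob = as.Date("1950-01-01"),
                       cohort = NA_character_)
    gen <- setNames(rep(0L, nf), id)
    sexes <- setNames(sex, id)
    prev <- id
    n_mat <- max(1L, round(nf / cfg$offspring_per_mating))
    for (g in seq_len(cfg$n_generations)) {
      sires <- prev[sexes[prev] == "M"]
      dams <- prev[sexes[prev] == "F"]
      if (!length(sires) || !length(dams)) break
      quality <- setNames(stats::rnorm(length(sires)), sires)
      w <- exp(cfg$popular_sire_weight * quality)
      new <- vector("list", n_mat)
      cnt <- 0L
      for (m in seq_len(n_mat)) {
        dm <- sample(dams, 1L)
        pool <- if (cfg$n_lines > 1L &&
                    stats::runif(1) >= cfg$migration_rate)
          sires[line[sires] == line[dm]] else sires
        if (!length(pool)) pool <- sires
        uniform <- isTRUE(cfg$outlier_random_mating) &&
          cfg$n_lines > 1L && line[dm] == cfg$n_lines
        s <- if (length(pool) == 1L) pool else if (uniform)
          sample(pool, 1L) else sample(pool, 1L, prob = w[pool])
        off <- data.frame(
          id = sprintf("G%d_%03d", g, cnt + seq_len(cfg$offspring_per_mating)),
          sire = s, dam = dm,
          dob = as.Date(sprintf("%d-01-01", 1950L + 10L * g)),
          cohort = NA_character_)
        cnt <- cnt + cfg$offspring_per_mating
        new[[m]] <- off
        line[off$id] <- line[dm]
      }
      newdf <- do.call(rbind, new)
      if (nrow(newdf) > nf) newdf <- newdf[seq_len(nf), ]
      gen[newdf$id] <- g
      sexes[newdf$id] <- rep(c("M", "F"), length.out = nrow(newdf))
      rows <- rbind(rows, newdf)
      prev <- newdf$id
    }
    ped <- pedigree(rows)
    attr(ped, "generation") <- gen
    attr(ped, "sex") <- sexes
    attr(ped, "line") <- line[ped$id]
    ped
  })
}

#' Simulate founder genotypes in Hardy-Weinberg proportions
#'
#' @param freqs an [allele_freqs()] table.
#' @param ids individual ids.
#' @param seed integer seed.
#' @param n_loci number of loci to use (first columns of `freqs`).
#' @return A [genotype_table()].
#' @export
simulate_founder_genotypes <- function(freqs, ids, seed = 1,
                                       n_loci = length(freqs$freq)) {
  loci <- names(freqs$freq)[seq_len(min(n_loci, length(freqs$freq)))]
  with_op_seed(seed, "simulate_founder_genotypes", {
    n <- length(ids)
    a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                       dimnames = list(ids, loci))
    for (L in loci) {
      p <- freqs$freq[[L]]
      al <- as.integer(names(p))
      a1[, L] <- sample(al, n, replace = TRUE, prob = p)
      a2[, L] <- sample(al, n, replace = TRUE, prob = p)
    }
    genotype_table(data.frame(id = ids), a1, a2)
  })
}

# Sample founder DLA chromosomes (class I id, class II id). `outlier` marks
# chromosomes belonging to outlier-line founders, whose haplotype spectrum
# is flattened toward uniform (they retain the rare haplotypes the
# bottlenecked core lost).
sample_founder_dla <- function(cfg, n_chrom, outlier = NULL) {
  reg <- cfg$dla_freqs
  r1 <- reg[reg$region == "dla_class_I", ]
  r2 <- reg[reg$region == "dla_class_II", ]
  p1 <- r1$frequency / sum(r1$frequency)
  p2 <- r2$frequency / sum(r2$frequency)
  fl <- cfg$dla_outlier_flatten %||% 0
  draw1 <- function(n, p) sample(r1$id, n, replace = TRUE, prob = p)
  c1 <- integer(n_chrom)
  if (is.null(outlier) || fl == 0) outlier <- rep(FALSE, n_chrom)
  c1[!outlier] <- draw1(sum(!outlier), p1)
  if (any(outlier)) {
    pf <- (1 - fl) * p1 + fl / length(p1)
    c1[outlier] <- draw1(sum(outlier), pf)
  }
  if (cfg$dla_linkage == "coupled") {
    # complete founder LD: class II determined by class I via rank pairing
    c2 <- r2$id[order(-p2)][pmin(match(c1, r1$id[order(-p1)]), nrow(r2))]
  } else {
    c2 <- sample(r2$id, n_chrom, replace = TRUE, prob = p2)
  }
  cbind(class_I = c1, class_II = c2)
}

#' Gene-drop genotypes through a pedigree
#'
#' Each non-founder inherits one uniformly chosen allele per parent per
#' locus, independently across loci. When the configuration carries DLA
#' haplotype frequencies, founders additionally receive two DLA
#' chromosomes (a class I and a class II haplotype each); gametes pass
#' whole blocks, recombining between the class I and class II blocks with
#' the configured per-meiosis probability. DLA STR genotype columns are
#' derived from the haplotype tuples.
#'
#' @param ped a [pedigree()].
#' @param founder_genotypes [genotype_table()] covering every founder of
#'   `ped` at the genomic loci.
#' @param cfg a [sim_config()].
#' @return A [genotype_table()] over all pedigree members. When the DLA
#'   block is simulated, the true phased haplotype ids are attached as
#'   attribute `dla_truth` (data frame `id`, `cI_1`, `cI_2`, `cII_1`,
#'   `cII_2`).
#' @export
gene_drop <- function(ped, founder_genotypes, cfg) {
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  miss <- setdiff(founders, founder_genotypes$meta$id)
  if (length(miss)) stop("missing founder genotypes: ",
                         paste(miss, collapse = ", "))
  loci <- founder_genotypes$loci
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids); di <- match(ped$dam, ids)
  ord <- attr(ped, "topo_order") %||% seq_len(n)
  with_op_seed(cfg$seed, "gene_drop", {
    a1 <- a2 <- matrix(NA_integer_, n, length(loci),
                       dimnames = list(ids, loci))
    fidx <- match(founders, founder_genotypes$meta$id)
    a1[match(founders, ids), ] <- founder_genotypes$a1[fidx, , drop = FALSE]
    a2[match(founders, ids), ] <- founder_genotypes$a2[fidx, , drop = FALSE]
    L <- length(loci)
    for (v in ord) {
      if (is.na(si[v])) next
      pick_s <- stats::runif(L) < 0.5
      pick_d <- stats::runif(L) < 0.5
      a1[v, ] <- ifelse(pick_s, a1[si[v], ], a2[si[v], ])
      a2[v, ] <- ifelse(pick_d, a1[di[v], ], a2[di[v], ])
    }
    dla_truth <- NULL
    if (!is.null(cfg$dla_freqs)) {
      line <- attr(ped, "line")
      outlier <- if (!is.null(line) && cfg$n_lines > 1L)
        rep(line[match(founders, ped$id)] == cfg$n_lines, 2L)
      else NULL
      fd <- sample_founder_dla(cfg, 2L * length(founders), outlier)
      # chromosome c in 1:2 per individual: columns I and II hap ids
      cI <- cII <- matrix(NA_integer_, n, 2, dimnames = list(ids, NULL))
      fpos <- match(founders, ids)
      cI[fpos, 1] <- fd[seq_along(founders), "class_I"]
      cI[fpos, 2] <- fd[length(founders) + seq_along(founders), "class_I"]
      cII[fpos, 1] <- fd[seq_along(founders), "class_II"]
      cII[fpos, 2] <- fd[length(founders) + seq_along(founders), "class_II"]
      r <- cfg$dla_recombination_rate
      gamete <- function(parent) {
        i <- sample.int(2L, 1L)
        j <- if (stats::runif(1) < r) 3L - i else i
        c(cI[parent, i], cII[parent, j])
      }
      for (v in ord) {
        if (is.na(si[v])) next
        gs <- gamete(si[v]); gd <- gamete(di[v])
        cI[v, ] <- c(gs[1], gd[1]); cII[v, ] <- c(gs[2], gd[2])
      }
      dla_truth <- data.frame(id = ids, cI_1 = cI[, 1], cI_2 = cI[, 2],
                              cII_1 = cII[, 1], cII_2 = cII[, 2])
      # derive STR genotype columns from the haplotype tuples
      reg <- cfg$dla_freqs
      tup <- function(idv, region) {
        m <- match(idv, reg$id[reg$region == region])
        do.call(rbind, reg$alleles[reg$region == region][m])
      }
      pan <- dla_panel()
      for (region in c("dla_class_I", "dla_class_II")) {
        rl <- pan$locus[pan$region == region][order(
          pan$tuple_position[pan$region == region])]
        h1 <- tup(if (region == "dla_class_I") cI[, 1] else cII[, 1], region)
        h2 <- tup(if (region == "dla_class_I") cI[, 2] else cII[, 2], region)
        colnames(h1) <- colnames(h2) <- rl
        a1 <- cbind(a1, h1); a2 <- cbind(a2, h2)
      }
    }
    g <- genotype_table(ped[, "id", drop = FALSE], a1, a2)
    g$meta$cohort <- ped$cohort
    attr(g, "dla_truth") <- dla_truth
    g
  })
}

#' Assign liability-threshold disease phenotypes
#'
#' For each disease d in the configuration, dog i is affected when
#' `beta_inbreeding * F_i + beta_risk * k_i + e_i > threshold`, where F_i
#' is the pedigree inbreeding coefficient, k_i the number of risk
#' haplotypes carried (from the gene-dropped DLA truth), and
#' `e_i ~ N(0, sd)` an independent environmental deviate. Diseases are
#' generated independently.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @param dla_truth optional `dla_truth` data frame (from [gene_drop()]);
#'   required when any disease has `beta_risk != 0`.
#' @return Data frame `id`, `F`, one logical column per disease, and
#'   `cohort` (first affected disease in configuration order, else
#'   `"healthy"`).
#' @export
simulate_disease <- function(ped, cfg, dla_truth = NULL) {
  Fv <- coi(ped, ped$id)
  with_op_seed(cfg$seed, "simulate_disease", {
    out <- data.frame(id = ped$id, F = Fv)
    cohort <- rep("healthy", nrow(ped))
    for (dn in names(cfg$liability)) {
      par <- cfg$liability[[dn]]
      k <- 0
      if (par$beta_risk != 0) {
        if (is.null(dla_truth))
          stop("dla_truth required for risk-haplotype effects")
        k <- rowSums(cbind(
          dla_truth$cI_1 %in% par$risk_haplotypes,
          dla_truth$cI_2 %in% par$risk_haplotypes,
          dla_truth$cII_1 %in% par$risk_haplotypes,
          dla_truth$cII_2 %in% par$risk_haplotypes))
      }
      liab <- par$beta_inbreeding * Fv + par$beta_risk * k +
        stats::rnorm(nrow(ped), 0, par$sd)
      aff <- liab > par$threshold
      out[[dn]] <- aff
      cohort[aff & cohort == "healthy"] <- dn
    }
    out$cohort <- cohort
    out
  })
}

#' Simulate an outbred reference allele-frequency table
#'
#' Produces a village-dog-like reference spectrum: each locus keeps the
#' base population's alleles, adds novel alleles, and flattens the
#' frequency distribution toward uniform, so expected heterozygosity
#' exceeds the base population's at every locus. Deterministic given the
#' seed.
#'
#' @param freqs base [allele_freqs()] (default the packaged breed
#'   spectrum).
#' @param seed integer seed.
#' @param n_extra novel alleles added per locus.
#' @param flatten weight on the uniform component (0-1).
#' @param n_individuals nominal reference sample size (sets `n_hap`).
#' @return An [allele_freqs()] object.
#' @export
simulate_reference_population <- function(freqs = NULL, seed = 1,
                                          n_extra = 4, flatten = 0.75,
                                          n_individuals = 533) {
  freqs <- freqs %||% standard_poodle_frequencies()
  with_op_seed(seed, "simulate_reference_population", {
    ref <- lapply(freqs$freq, function(p) {
      al <- as.integer(names(p))
      extra <- max(al) + seq_len(n_extra)
      p_pad <- c(p, setNames(rep(0, n_extra), extra))
      u <- rep(1 / length(p_pad), length(p_pad))
      jit <- stats::rexp(length(p_pad))
      q <- (1 - flatten) * p_pad + flatten * u
      q <- 0.9 * q + 0.1 * jit / sum(jit)
      q / sum(q)
    })
    allele_freqs(ref, setNames(rep(2L * n_individuals, length(ref)),
                               names(ref)))
  })
}

#' Run the full simulator
#'
#' Convenience wrapper: simulates the pedigree, founder genotypes,
#' gene-dropped genotypes (with DLA blocks when configured) and disease
#' phenotypes, and stamps cohorts into the genotype metadata.
#'
#' @param cfg a [sim_config()].
#' @return List with `pedigree`, `genotypes`, `phenotypes`, `dla_truth`
#'   and `config`.
#' @export
simulate_dataset <- function(cfg) {
  freqs <- cfg$allele_freqs %||% standard_poodle_frequencies()
  ped <- simulate_pedigree(cfg)
  founders <- ped$id[is.na(ped$sire) & is.na(ped$dam)]
  fg <- simulate_founder_genotypes(freqs, founders, seed = cfg$seed,
                                   n_loci = cfg$n_genomic_loci)
  g <- gene_drop(ped, fg, cfg)
  pheno <- simulate_disease(ped, cfg, attr(g, "dla_truth"))
  g$meta$cohort <- pheno$cohort[match(g$meta$id, pheno$id)]
  ped$cohort <- pheno$cohort[match(ped$id, pheno$id)]
  list(pedigree = ped, genotypes = g, phenotypes = pheno,
       dla_truth = attr(g, "dla_truth"), config = cfg)
}
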