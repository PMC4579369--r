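test_that("IR matches hand-evaluated formula cases", {
  # fully homozygous -> IR = 1 regardless of frequencies
  g <- make_g(L1 = rbind(c(1, 1)), L2 = rbind(c(3, 3)))
  fr <- make_freqs(list(L1 = c(`1` = 0.6, `2` = 0.4),
                        L2 = c(`3` = 0.1, `4` = 0.9)))
  expect_equal(internal_relatedness(g, fr)$IR, 1)

  # one locus, heterozygous, both alleles at frequency 0.5 -> IR = -1
  g2 <- make_g(L1 = rbind(c(1, 2)))
  fr2 <- make_freqs(list(L1 = c(`1` = 0.5, `2` = 0.5)))
  expect_equal(internal_relatedness(g2, fr2)$IR, -1)

  # two loci: hom for freq-0.5 allele, het with 0.25/0.25 -> IR = 0.2
  g3 <- make_g(L1 = rbind(c(1, 1)), L2 = rbind(c(1, 2)))
  fr3 <- make_freqs(list(L1 = c(`1` = 0.5, `2` = 0.5),
                         L2 = c(`1` = 0.25, `2` = 0.25, `3` = 0.5)))
  r3 <- internal_relatedness(g3, fr3)
  expect_equal(r3$IR, (2 - 1.5) / (4 - 1.5))
  expect_equal(r3$H, 1L); expect_equal(r3$N, 2L)

  # missing loci drop out of H, N and sum_f
  g4 <- make_g(L1 = rbind(c(1, 1)), L2 = rbind(c(NA, NA)))
  r4 <- internal_relatedness(g4, fr3)
  expect_equal(r4$N, 1L)
  expect_equal(r4$IR, 1)
})

test_that("adjusted IR uses reference frequencies with a floor for novel alleles", {
  g <- make_g(L1 = rbind(c(1, 2)))
  ref <- make_freqs(list(L1 = c(`1` = 0.9, `2` = 0.05, `3` = 0.05)),
                    n_hap = 1066L)
  r <- adjusted_internal_relatedness(g, ref)
  expect_equal(r$adjusted_IR, (0 - 0.95) / (2 - 0.95), tolerance = 1e-12)

  # allele absent from the reference gets floor 1/n_hap
  g2 <- make_g(L1 = rbind(c(1, 99)))
  r2 <- adjusted_internal_relatedness(g2, ref)
  expect_equal(r2$sum_f, 0.9 + 1 / 1066)

  # homozygous dog: adjusted IR = 1 whatever the reference
  g3 <- make_g(L1 = rbind(c(2, 2)))
  expect_equal(adjusted_internal_relatedness(g3, ref)$adjusted_IR, 1)
})

test_that("a drifted breed shifts right of its raw IR when judged by a diverse reference", {
  cfg <- sim_config(seed = 2, n_founders = 60, n_generations = 5,
                    offspring_per_mating = 2, popular_sire_weight = 2,
                    allele_freqs = standard_poodle_frequencies())
  sim <- simulate_dataset(cfg)
  ref <- simulate_reference_population(seed = 2)
  raw <- internal_relatedness(sim$genotypes)
  adj <- adjusted_internal_relatedness(sim$genotypes, ref)
  expect_gt(mean(adj$adjusted_IR), mean(raw$IR))
})

test_that("IR is invariant under locus and allele relabeling", {
  set.seed(3)
  g <- make_g(A = cbind(sample(1:4, 10, TRUE), sample(1:4, 10, TRUE)),
              B = cbind(sample(1:3, 10, TRUE), sample(1:3, 10, TRUE)))
  ir <- internal_relatedness(g)$IR
  # relabel loci (swap columns)
  g2 <- subset_genotypes(g, loci = c("B", "A"))
  expect_equal(internal_relatedness(g2)$IR, ir)
  # relabel alleles consistently (+100)
  g3 <- genotype_table(g$meta, g$a1 + 100L, g$a2 + 100L)
  expect_equal(internal_relatedness(g3)$IR, ir)
})

test_that("adding loci moves IR in the expected direction", {
  fr <- make_freqs(list(L1 = c(`1` = 0.5, `2` = 0.5),
                        L2 = c(`1` = 0.5, `2` = 0.5)))
  base <- internal_relatedness(make_g(L1 = rbind(c(1, 2))),
                               make_freqs(list(L1 = c(`1` = .5, `2` = .5))))
  with_hom <- internal_relatedness(
    make_g(L1 = rbind(c(1, 2)), L2 = rbind(c(1, 1))), fr)
  expect_gte(with_hom$IR, base$IR)
  with_het <- internal_relatedness(
    make_g(L1 = rbind(c(1, 2)), L2 = rbind(c(1, 2))), fr)
  expect_lte(with_het$IR, base$IR)
})

test_that("full-sib offspring IR has expectation 0.25; unrelated parents 0", {
  # exact single-locus enumeration oracle (ratio of expectations = 0.25)
  expect_equal(fullsib_ir_ratio_exact(3), 0.25, tolerance = 1e-9)
  expect_equal(fullsib_ir_ratio_exact(5), 0.25, tolerance = 1e-9)

  fr <- standard_poodle_frequencies()
  r <- mean_full_sib_ir(fr, n_offspring = 600, seed = 4)
  expect_lt(abs(r$mean_ir - 0.25), 0.025)
  r0 <- mean_full_sib_ir(fr, n_offspring = 600, seed = 4,
                         mating = "unrelated")
  expect_lt(abs(r0$mean_ir), 0.02)
  # determinism
  expect_identical(r$mean_ir, mean_full_sib_ir(fr, 600, seed = 4)$mean_ir)
})

test_that("codominant genotypic distance follows the definition table", {
  d <- function(x, y) {
    g <- make_g(L1 = rbind(x, y))
    unname(genetic_distance(g)[1, 2])
  }
  expect_equal(d(c(1, 1), c(1, 1)), 0)
  expect_equal(d(c(1, 2), c(1, 2)), 0)
  expect_equal(d(c(1, 1), c(1, 2)), 1)
  expect_equal(d(c(1, 2), c(1, 3)), 1)
  expect_equal(d(c(1, 2), c(3, 4)), 2)
  expect_equal(d(c(1, 1), c(2, 3)), 3)
  expect_equal(d(c(1, 1), c(2, 2)), 4)
  # summed over loci; missing loci excluded pairwise
  g <- make_g(L1 = rbind(c(1, 1), c(2, 2)), L2 = rbind(c(1, 2), c(NA, NA)))
  expect_equal(unname(genetic_distance(g)[1, 2]), 4)
})

test_that("PCoA reproduces classical-scaling identities", {
  # two individuals at squared distance 4 -> eigenvalues (2, 0), coords +-1
  D <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc <- pcoa(D, axes = 2)
  expect_equal(sort(pc$eigenvalues), c(0, 2), tolerance = 1e-12)
  expect_equal(unname(sort(abs(pc$coordinates[, 1]))), c(1, 1),
               tolerance = 1e-12)

  # three mutually equidistant individuals -> two equal positive eigenvalues
  D3 <- matrix(1, 3, 3) - diag(3)
  pc3 <- pcoa(D3, axes = 2)
  pos <- pc3$eigenvalues[pc3$eigenvalues > 1e-9]
  expect_length(pos, 2)
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("full-rank PCoA coordinates reproduce the input distances", {
  set.seed(9)
  g <- make_g(A = cbind(sample(1:4, 8, TRUE), sample(1:4, 8, TRUE)),
              B = cbind(sample(1:4, 8, TRUE), sample(1:4, 8, TRUE)),
              C = cbind(sample(1:3, 8, TRUE), sample(1:3, 8, TRUE)))
  D <- genetic_distance(g)
  pc <- pcoa(D, axes = 8)
  rec <- as.matrix(dist(pc$coordinates))^2
  expect_equal(unname(rec), unname(unclass(D)), tolerance = 1e-8)
  # eigenvalue sum equals the trace of the centered matrix
  n <- nrow(D)
  C <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * C %*% unclass(D) %*% C
  expect_equal(sum(pc$eigenvalues), sum(diag(G)), tolerance = 1e-8)
  # agreement with the stats implementation of classical MDS
  cm <- stats::cmdscale(sqrt(unclass(D)), k = 2, eig = TRUE)
  expect_equal(abs(unname(pc$coordinates[, 1:2])), abs(unname(cm$points)),
               tolerance = 1e-6)
})

test_that("group comparison reproduces ANOVA edge cases and Fig-2-style contrasts", {
  v <- c(1, 2, 3, 1, 2, 3)
  lab <- rep(c("a", "b"), each = 3)
  cg <- compare_groups(v, lab)
  expect_equal(cg$F, 0)
  expect_equal(cg$p, 1)

  set.seed(13)
  x <- c(rnorm(30), rnorm(30, 10))  # 10 pooled SDs apart
  cg2 <- compare_groups(x, rep(c("a", "b"), each = 30))
  expect_lt(cg2$p, 1e-6)

  expect_warning(
    cg3 <- compare_groups(c(rnorm(5), rnorm(5, 1), 3),
                          c(rep("a", 5), rep("b", 5), "tiny")),
    "excluded")
  expect_equal(sort(cg3$groups$group), c("a", "b"))
})
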