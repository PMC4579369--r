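test_that("kinship and COI match textbook relationships", {
  ped <- ped_full_sib()
  expect_equal(kinship(ped, "A", "S1"), 0.25)   # parent-offspring
  expect_equal(kinship(ped, "S1", "S2"), 0.25)  # full siblings
  expect_equal(kinship(ped, "A", "B"), 0)       # unrelated founders
  expect_equal(coi(ped, "X"), 0.25)             # full-sib offspring
  expect_equal(kinship(ped, "S1", "S2"), kinship(ped, "S2", "S1"))

  half <- make_ped("
id,sire,dam
S,,
D1,,
D2,,
H1,S,D1
H2,S,D2
")
  expect_equal(kinship(half, "H1", "H2"), 0.125)
  expect_equal(coi(ped_cousins(), "X"), 0.0625)  # first cousins
  expect_error(kinship(ped, "A", "nope"), "not found")
})

test_that("generation caps truncate deep common ancestry per path", {
  ped <- ped_deep_chain(12)
  expect_equal(coi(ped, "X", g = 10), 0)
  expect_equal(coi(ped, "X", g = 15), 0.5^23)
  expect_equal(coi(ped, "X", g = 15), oracle_coi(ped, "X"))
  # monotone in the cap
  caps <- c(5, 10, 12, 20, Inf)
  vals <- sapply(caps, function(g) coi(ped, "X", g = g))
  expect_true(all(diff(vals) >= 0))
})

test_that("recursive kinship equals the path-counting oracle on fixtures", {
  fixtures <- list(ped_full_sib(), ped_cousins(), ped_deep_chain(4))
  for (ped in fixtures) {
    ids <- ped$id
    for (a in ids) for (b in ids) {
      expect_equal(kinship(ped, a, b), oracle_kinship(ped, a, b),
                   tolerance = 1e-12,
                   info = paste(a, b))
    }
    expect_equal(coi(ped, ids), sapply(ids, function(x) oracle_coi(ped, x)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # and on a simulated pedigree with overlapping ancestry
  cfg <- sim_config(seed = 21, n_founders = 10, n_generations = 3,
                    offspring_per_mating = 2,
                    allele_freqs = standard_poodle_frequencies(),
                    n_genomic_loci = 2)
  ped <- simulate_pedigree(cfg)
  some <- ped$id[seq(1, nrow(ped), by = 4)]
  for (a in some) expect_equal(coi(ped, a), oracle_coi(ped, a),
                               tolerance = 1e-12)
})

test_that("gene-drop IBD converges to pedigree kinship", {
  ped <- ped_cousins()
  est <- drop_kinship(ped, "C1", "C2", n_drops = 2e4, seed = 5)
  expect_lt(abs(est - kinship(ped, "C1", "C2")), 0.01)
})

test_that("founder-set contributions follow the stopped recursion", {
  ped <- make_ped("
id,sire,dam
S,,
U,,
V,,
C,S,U
GC,C,V
")
  expect_equal(founder_contribution(ped, "S", ids = "S")$coefficient, 1)
  expect_equal(founder_contribution(ped, "S", ids = "C")$coefficient, 0.5)
  expect_equal(founder_contribution(ped, "S", ids = "GC")$coefficient, 0.25)
  expect_equal(founder_contribution(ped, c("S", "U"), ids = "C")$coefficient, 1)
  # recursion stops at set members: related set members not double counted
  ped2 <- make_ped("
id,sire,dam
F,,
M,,
K,F,M
X,K,M
")
  # set {F, K}: K is in the set even though F is K's sire
  expect_equal(founder_contribution(ped2, c("F", "K"), ids = "X")$coefficient,
               0.5)
  # contribution to all founders is 1
  allf <- ped2$id[is.na(ped2$sire) & is.na(ped2$dam)]
  expect_equal(founder_contribution(ped2, allf, ids = "X")$coefficient, 1)
  expect_error(founder_contribution(ped2, character(0)), "empty")
})

test_that("founder contribution agrees with gene-dropped allele origins", {
  cfg <- sim_config(seed = 31, n_founders = 8, n_generations = 3,
                    offspring_per_mating = 2,
                    allele_freqs = standard_poodle_frequencies(),
                    n_genomic_loci = 1)
  ped <- simulate_pedigree(cfg)
  founders <- ped$id[is.na(ped$sire)]
  target <- ped$id[nrow(ped)]
  f <- founders[1]
  expected <- founder_contribution(ped, f, ids = target)$coefficient
  # Monte-Carlo allele-origin frequency over 10000 single-locus drops
  n_drops <- 10000
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  set.seed(99)
  A1 <- A2 <- matrix(0L, nrow(ped), n_drops)
  for (v in attr(ped, "topo_order")) {
    if (is.na(si[v])) { A1[v, ] <- v; A2[v, ] <- v } else {
      p <- runif(n_drops) < 0.5
      A1[v, ] <- ifelse(p, A1[si[v], ], A2[si[v], ])
      p <- runif(n_drops) < 0.5
      A2[v, ] <- ifelse(p, A1[di[v], ], A2[di[v], ])
    }
  }
  ti <- match(target, ped$id); fi <- match(f, ped$id)
  observed <- mean((A1[ti, ] == fi) + (A2[ti, ] == fi)) / 2
  expect_equal(observed, expected, tolerance = 0.02)
})

test_that("influential-ancestor ranking matches exhaustive genome origins", {
  ped <- ped_full_sib()
  rk <- influential_ancestors(ped, ref = "X", k = 5)
  founders <- rk[rk$id %in% c("A", "B"), ]
  expect_equal(founders$raw, c(0.5, 0.5))

  # popular sire: S sires every reference dog from unrelated dams
  pop <- make_ped("
id,sire,dam
S,,
D1,,
D2,,
D3,,
R1,S,D1
R2,S,D2
R3,S,D3
")
  rk2 <- influential_ancestors(pop, ref = c("R1", "R2", "R3"), k = 4)
  expect_equal(rk2$id[1], "S")
  expect_equal(rk2$marginal[1], 0.5)

  # 3-generation pedigree: marginals of a complete ranking attribute the
  # whole genome, and raw values match the path-enumeration oracle
  ped3 <- ped_cousins()
  ref <- "X"
  rk3 <- influential_ancestors(ped3, ref, k = 20)
  expect_true(all(rk3$marginal >= -1e-12))
  expect_equal(sum(rk3$marginal), 1, tolerance = 1e-12)
  for (i in seq_len(nrow(rk3))) {
    expect_equal(rk3$raw[i], oracle_contribution(ped3, "X", rk3$id[i]),
                 tolerance = 1e-12)
  }
})

test_that("ancestor selection ties break by birth date then id", {
  ped <- pedigree(data.frame(
    id = c("older", "younger", "kid"),
    sire = c(NA, NA, "older"), dam = c(NA, NA, "younger"),
    dob = as.Date(c("1950-01-01", "1960-01-01", "1970-01-01"))))
  rk <- influential_ancestors(ped, "kid", k = 2)
  expect_equal(rk$id[1], "older")
})

test_that("ancestry-disease curves bin coefficients and flag empty bins", {
  ped <- make_ped("
id,sire,dam
T,,
U,,
C1,T,U
C2,T,U
C3,,
")
  curve <- ancestry_disease_curve(ped, "T", affected = c("C1", "C2"),
                                  healthy = "C3", bin_width = 0.25)
  # C1, C2 have coefficient 0.5; C3 has 0
  hot <- curve[curve$bin_low == 0.5, ]
  expect_equal(hot$affected, 2)
  expect_equal(hot$healthy, 0)
  expect_true(is.na(hot$ratio))
  expect_error(ancestry_disease_curve(ped, "T", "C1", "C1", 0.1), "overlap")
  expect_error(ancestry_disease_curve(ped, "T", "C1", "C3", 0), "positive")

  # ancestry-linked disease yields elevated ratios above the threshold
  cfg <- sim_config(seed = 41, n_founders = 40, n_generations = 4,
                    offspring_per_mating = 2, popular_sire_weight = 2,
                    allele_freqs = standard_poodle_frequencies(),
                    n_genomic_loci = 1)
  sped <- simulate_pedigree(cfg)
  top <- influential_ancestors(sped, sped$id[attr(sped, "generation") == 4],
                               k = 1)$id
  contrib <- founder_contribution(sped, top)$coefficient
  set.seed(42)
  risk <- ifelse(contrib > 0.3, 0.6, 0.05)
  aff <- sped$id[runif(nrow(sped)) < risk]
  hea <- setdiff(sped$id, aff)
  cv <- ancestry_disease_curve(sped, top, aff, hea, bin_width = 0.3)
  lo <- cv$ratio[cv$bin_low == 0]
  hi <- cv$ratio[cv$bin_low == 0.3]
  expect_gt(hi, lo)
})

test_that("decade summaries aggregate dated dogs per cohort", {
  ped <- pedigree(data.frame(
    id = c("F1", "F2", "a", "b", "c", "nodate"),
    sire = c(NA, NA, "F1", "F1", "F1", "F1"),
    dam = c(NA, NA, "F2", "F2", "F2", "F2"),
    dob = as.Date(c("1950-01-01", "1950-01-01", "1961-02-03", "1965-05-05",
                    "1969-12-31", NA)),
    cohort = c(NA, NA, "SA", "healthy", "healthy", "SA")))
  # contributions 0.5 each via F1; one manual contribution check
  ds <- decade_summary(ped, sets = list(f1 = "F1"), g_list = 5)
  row60 <- ds[ds$decade == 1960 & ds$cohort == "total", ]
  expect_equal(row60$n, 3L)
  expect_equal(row60$pct_f1, 50)
  expect_equal(attr(ds, "n_undated"), 1L)
  expect_true("SA" %in% ds$cohort[ds$decade == 1960])

  # hand-set contributions 0.2/0.4/0.6 average to 40%
  ped2 <- pedigree(data.frame(
    id = c("S", "U", "p1", "p2", "x1", "x2", "x3"),
    sire = c(NA, NA, "S", "p1", "p1", "p2", NA),
    dam = c(NA, NA, "U", "U", "U", "U", NA),
    dob = as.Date(c(NA, NA, NA, NA, "1980-01-01", "1980-06-01",
                    "1980-09-01"))))
  # contributions to {S}: x1 = 0.25, x2 = 0.125 ... construct instead with
  # direct values: use three dogs whose coefficients are 0.2/0.4/0.6 via a
  # synthetic set is awkward; check the mean formula on computed values
  ds2 <- decade_summary(ped2, sets = list(s = "S"), g_list = 5,
                        by_cohort = FALSE)
  expected <- mean(founder_contribution(ped2, "S",
                                        ids = c("x1", "x2", "x3"))$coefficient)
  expect_equal(ds2$pct_s[ds2$decade == 1980], 100 * expected)
})

test_that("bottleneck pedigrees show rising then plateauing founder ancestry", {
  cfg <- sim_config(seed = 51, n_founders = 60, n_generations = 6,
                    offspring_per_mating = 3, popular_sire_weight = 3,
                    allele_freqs = standard_poodle_frequencies(),
                    n_genomic_loci = 1)
  ped <- simulate_pedigree(cfg)
  gen <- attr(ped, "generation")
  top <- influential_ancestors(ped, ped$id[gen == 6], k = 3)$id
  ds <- decade_summary(ped, sets = list(top = top), g_list = 5,
                       by_cohort = FALSE)
  ds <- ds[order(ds$decade), ]
  pct <- ds$pct_top
  # rises from the founder decade and does not collapse afterwards
  expect_gt(pct[3], pct[1])
  expect_gt(tail(pct, 1), 0.5 * max(pct))
  # COI columns are non-decreasing in the cap
  ds2 <- decade_summary(ped, sets = list(top = top), g_list = c(3, 10),
                        by_cohort = FALSE)
  expect_true(all(ds2$coi_10 >= ds2$coi_3 - 1e-12))
})
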