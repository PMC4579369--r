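# Independent oracles the implementation is checked against.

# --- Wright path-counting kinship -----------------------------------------
# All ancestor paths from x, as vectors of ids starting at x.
all_paths_up <- function(ped, x) {
  row <- match(x, ped$id)
  out <- list(c(x))
  for (p in c(ped$sire[row], ped$dam[row])) {
    if (is.na(p)) next
    out <- c(out, lapply(all_paths_up(ped, p), function(pa) c(x, pa)))
  }
  out
}

# kinship(a, b) = sum over common ancestors A and pairs of paths meeting
# only at A of (1/2)^(n1 + n2 + 1) * (1 + F_A)
oracle_kinship <- function(ped, a, b) {
  if (a == b) return(0.5 * (1 + oracle_coi(ped, a)))
  pa <- all_paths_up(ped, a)
  pb <- all_paths_up(ped, b)
  total <- 0
  for (p1 in pa) for (p2 in pb) {
    A <- p1[length(p1)]
    if (p2[length(p2)] != A) next
    if (length(intersect(p1, p2)) != 1L) next
    total <- total + 0.5^((length(p1) - 1) + (length(p2) - 1) + 1) *
      (1 + oracle_coi(ped, A))
  }
  total
}

oracle_coi <- function(ped, x) {
  row <- match(x, ped$id)
  s <- ped$sire[row]; d <- ped$dam[row]
  if (is.na(s) || is.na(d)) return(0)
  oracle_kinship(ped, s, d)
}

# Expected genome fraction of x descending from ancestor f:
# sum over paths x -> f of (1/2)^path_length
oracle_contribution <- function(ped, x, f) {
  paths <- all_paths_up(ped, x)
  sum(vapply(paths, function(p) {
    hit <- match(f, p)
    if (is.na(hit) || hit != length(p)) return(0)
    0.5^(length(p) - 1)
  }, 0))
}

# --- Monte-Carlo gene-drop kinship ----------------------------------------
# Drops a single locus with unique founder alleles n_drops times
# (vectorized) and estimates kinship(a, b) as the probability that random
# alleles, one from each, are identical by descent.
drop_kinship <- function(ped, a, b, n_drops = 1e5, seed = 1) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  A1 <- A2 <- matrix(0L, n, n_drops)
  ord <- attr(ped, "topo_order")
  lab <- 0L
  for (v in ord) {
    if (is.na(si[v])) {          # founder: unique chromosome labels
      A1[v, ] <- lab + 1L; A2[v, ] <- lab + 2L; lab <- lab + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[v, ] <- ifelse(pick, A1[si[v], ], A2[si[v], ])
      pick <- stats::runif(n_drops) < 0.5
      A2[v, ] <- ifelse(pick, A1[di[v], ], A2[di[v], ])
    }
  }
  ia <- match(a, ped$id); ib <- match(b, ped$id)
  mean((A1[ia, ] == A1[ib, ]) + (A1[ia, ] == A2[ib, ]) +
       (A2[ia, ] == A1[ib, ]) + (A2[ia, ] == A2[ib, ])) / 4
}

# --- Exact full-sib IR expectation at one locus ---------------------------
# k equifrequent alleles; enumerates grandparent allele draws and all
# meiosis outcomes; returns E[2H - sum_f] / E[2N - sum_f].
fullsib_ir_ratio_exact <- function(k) {
  num <- 0; den <- 0; f <- 1 / k
  combos <- expand.grid(g1 = 1:k, g2 = 1:k, g3 = 1:k, g4 = 1:k)
  meio <- expand.grid(s1a = 1:2, s1b = 1:2, s2a = 1:2, s2b = 1:2,
                      o1 = 1:2, o2 = 1:2)
  for (i in seq_len(nrow(combos))) {
    gp <- as.integer(combos[i, ])
    for (j in seq_len(nrow(meio))) {
      m <- as.integer(meio[j, ])
      sib1 <- c(gp[m[1]], gp[2 + m[2]])
      sib2 <- c(gp[m[3]], gp[2 + m[4]])
      off <- c(sib1[m[5]], sib2[m[6]])
      w <- 1 / (nrow(combos) * nrow(meio))
      num <- num + w * (2 * (off[1] == off[2]) - 2 * f)
      den <- den + w * (2 - 2 * f)
    }
  }
  num / den
}

# --- Exhaustive likelihood grid for the 2-locus phasing toy ---------------
# Data: n_xx dogs homozygous A-X, n_yy homozygous B-Y, one A/B x X/Y dog.
# Grid-searches haplotype frequencies (AX, AY, BX, BY) on the simplex and
# returns the cis-pair posterior at the maximum-likelihood point.
grid_cis_posterior <- function(n_xx = 5, n_yy = 5, step = 0.02) {
  best_ll <- -Inf; best <- NULL
  grid <- seq(step, 1 - step, by = step)
  for (pAX in grid) for (pBY in grid) {
    rest <- 1 - pAX - pBY
    if (rest < 0) next
    for (pAY in seq(0, rest, by = step)) {
      pBX <- rest - pAY
      ll <- 2 * n_xx * log(pAX) + 2 * n_yy * log(pBY) +
        log(2 * pAX * pBY + 2 * pAY * pBX)
      if (ll > best_ll) { best_ll <- ll; best <- c(pAX, pAY, pBX, pBY) }
    }
  }
  cis <- 2 * best[1] * best[4]
  trans <- 2 * best[2] * best[3]
  cis / (cis + trans)
}
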