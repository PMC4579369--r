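# Builders for small in-memory fixtures.

# genotype table from a list of per-locus allele pair matrices:
# make_g(L1 = rbind(c(1,1), c(1,2)), L2 = ...) -> 2 dogs
make_g <- function(..., ids = NULL, cohort = NULL) {
  loci <- list(...)
  n <- nrow(loci[[1]])
  ids <- ids %||% paste0("d", seq_len(n))
  a1 <- sapply(loci, function(m) as.integer(m[, 1]))
  a2 <- sapply(loci, function(m) as.integer(m[, 2]))
  if (n == 1L) { a1 <- t(a1); a2 <- t(a2) }
  colnames(a1) <- colnames(a2) <- names(loci)
  meta <- data.frame(id = ids)
  if (!is.null(cohort)) meta$cohort <- cohort
  genotype_table(meta, a1, a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frequency table from named list of named numeric vectors
make_freqs <- function(freq, n_hap = 1000L) {
  allele_freqs(freq, setNames(rep(n_hap, length(freq)), names(freq)))
}

make_ped <- function(text) {
  d <- read.table(text = text, header = TRUE, sep = ",",
                  colClasses = "character", strip.white = TRUE)
  if (!is.null(d$dob)) d$dob <- as.Date(d$dob)
  pedigree(d)
}

# full sibling mating: offspring X of sibs S1 x S2 from founders A, B
ped_full_sib <- function() make_ped("
id,sire,dam
A,,
B,,
S1,A,B
S2,A,B
X,S1,S2
")

# first-cousin mating
ped_cousins <- function() make_ped("
id,sire,dam
GA,,
GB,,
P1,GA,GB
P2,GA,GB
M1,,
M2,,
C1,P1,M1
C2,P2,M2
X,C1,C2
")

# sole common ancestor `depth` generations above X
ped_deep_chain <- function(depth = 12) {
  rows <- data.frame(id = "A", sire = NA, dam = NA)
  for (br in c("s", "d")) {
    prev <- "A"
    for (i in seq_len(depth - 1)) {
      nid <- paste0(br, i)
      rows <- rbind(rows, data.frame(id = nid, sire = prev, dam = NA))
      prev <- nid
    }
  }
  rows <- rbind(rows, data.frame(id = "X", sire = paste0("s", depth - 1),
                                 dam = paste0("d", depth - 1)))
  pedigree(rows)
}
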