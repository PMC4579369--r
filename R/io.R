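#' Construct a genotype table
#'
#' A genotype table holds unordered biallelic STR calls for a set of
#' individuals at a panel of loci, plus per-dog metadata (cohort, region of
#' origin, variety, sex). Alleles are integer fragment sizes or repeat
#' counts; decimal repeat designations (e.g. 19.2) are stored as integers
#' scaled by ten. A missing call is missing for both alleles.
#'
#' @param meta data frame with at least an `id` column (unique); optional
#'   `cohort`, `region`, `variety`, `sex` columns are filled with
#'   `"unknown"` when absent.
#' @param a1,a2 integer matrices, one row per individual and one column per
#'   locus (column names are the locus names). Allele pairs are unordered;
#'   they are stored with `a1 <= a2`.
#' @return An object of class `genotype_table` with elements `meta`,
#'   `loci`, `a1`, `a2`.
#' @seealso [read_genotypes()], [compute_allele_frequencies()]
#' @export
genotype_table <- function(meta, a1, a2) {
  stopifnot(is.data.frame(meta), "id" %in% names(meta))
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) stop("duplicate individual ids")
  for (col in c("cohort", "region", "variety", "sex")) {
    if (is.null(meta[[col]])) meta[[col]] <- "unknown"
    meta[[col]] <- as.character(meta[[col]])
  }
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  stopifnot(nrow(a1) == nrow(meta), identical(dim(a1), dim(a2)),
            !is.null(colnames(a1)))
  if (!identical(is.na(a1), is.na(a2)))
    stop("missing calls must be missing for both alleles")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp }
  rownames(a1) <- rownames(a2) <- meta$id
  structure(list(meta = meta[c("id", "cohort", "region", "variety", "sex")],
                 loci = colnames(a1), a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% calls typed)\n",
              nrow(x$a1), ncol(x$a1), 100 * mean(!is.na(x$a1))))
  if (length(unique(x$meta$cohort)) > 1L)
    print(table(cohort = x$meta$cohort))
  invisible(x)
}

#' Subset a genotype table by individuals and/or loci
#'
#' @param g a [genotype_table()].
#' @param subset individuals to keep: ids, indices, a logical vector, or a
#'   function of the metadata data frame returning a logical vector.
#' @param loci optional character vector of locus names to keep.
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(g, subset = NULL, loci = NULL) {
  idx <- resolve_subset(g, subset)
  cols <- if (is.null(loci)) g$loci else {
    miss <- setdiff(loci, g$loci)
    if (length(miss)) stop("unknown loci: ", paste(miss, collapse = ", "))
    loci
  }
  genotype_table(g$meta[idx, , drop = FALSE],
                 g$a1[idx, cols, drop = FALSE],
                 g$a2[idx, cols, drop = FALSE])
}

#' Read a genotype CSV
#'
#' Expects a header row with `id`, optional metadata columns (`cohort`,
#' `region`, `variety`, `sex`), and two columns per locus named
#' `LOCUS.1`/`LOCUS.2`. Empty cells and `0` are missing; a cell that fails
#' to parse as a number becomes a missing call and is counted in the
#' `n_unparseable` attribute (with a single warning).
#'
#' @param path CSV file path.
#' @param loci optional character vector restricting/ordering the loci.
#' @return A [genotype_table()]; attribute `n_unparseable` counts cells
#'   that were blanked and attribute `n_missing` the missing calls in the
#'   parsed table.
#' @export
read_genotypes <- function(path, loci = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!"id" %in% names(raw)) stop("genotype CSV must have an 'id' column")
  if (anyDuplicated(raw$id)) stop("duplicate individual ids in ", path)
  meta_cols <- intersect(c("id", "cohort", "region", "variety", "sex"),
                         names(raw))
  gcols <- setdiff(names(raw), meta_cols)
  base <- sub("\\.[12]$", "", gcols)
  for (b in unique(base)) {
    have <- gcols[base == b]
    if (!setequal(have, paste0(b, c(".1", ".2"))))
      stop("unpaired locus column for locus '", b, "'")
  }
  locus_names <- unique(base)
  if (!is.null(loci)) {
    miss <- setdiff(loci, locus_names)
    if (length(miss)) stop("loci absent from file: ",
                           paste(miss, collapse = ", "))
    locus_names <- loci
  }
  parse_col <- function(x) {
    x <- trimws(x)
    x[x == "" | x == "0" | toupper(x) == "NA"] <- NA
    suppressWarnings(as.numeric(x))
  }
  n_bad <- 0L
  a1 <- a2 <- matrix(NA_integer_, nrow(raw), length(locus_names),
                     dimnames = list(raw$id, locus_names))
  for (L in locus_names) {
    r1 <- trimws(raw[[paste0(L, ".1")]]); r2 <- trimws(raw[[paste0(L, ".2")]])
    v1 <- parse_col(r1); v2 <- parse_col(r2)
    bad <- (is.na(v1) & !(r1 %in% c("", "0", NA) | toupper(r1) == "NA")) |
           (is.na(v2) & !(r2 %in% c("", "0", NA) | toupper(r2) == "NA"))
    n_bad <- n_bad + sum(bad)
    v1[bad] <- NA; v2[bad] <- NA
    half <- xor(is.na(v1), is.na(v2))  # half-missing pair -> all missing
    v1[half] <- NA; v2[half] <- NA
    a1[, L] <- as.integer(round(v1)); a2[, L] <- as.integer(round(v2))
  }
  if (n_bad > 0L)
    warning(n_bad, " unparseable allele cell(s) set to missing")
  g <- genotype_table(raw[meta_cols], a1, a2)
  attr(g, "n_unparseable") <- n_bad
  attr(g, "n_missing") <- sum(is.na(g$a1))
  g
}

#' Write a genotype table as CSV
#'
#' Inverse of [read_genotypes()]: missing calls become empty cells, so a
#' valid file round-trips cell-identically.
#'
#' @param g a [genotype_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  out <- g$meta
  for (L in g$loci) {
    out[[paste0(L, ".1")]] <- ifelse(is.na(g$a1[, L]), "", g$a1[, L])
    out[[paste0(L, ".2")]] <- ifelse(is.na(g$a2[, L]), "", g$a2[, L])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Allele frequencies of a genotype table
#'
#' Frequencies are computed within an explicit subset using per-locus
#' pairwise deletion: at each locus, the frequency of allele *a* is its
#' count among non-missing calls divided by twice the number of
#' non-missing individuals at that locus. Loci with no non-missing call in
#' the subset are excluded and listed in the result.
#'
#' @param g a [genotype_table()].
#' @param subset individuals to use (see [subset_genotypes()]); default all.
#' @return An object of class `allele_freqs`: list with `freq` (per locus,
#'   a named numeric vector of frequencies summing to 1), `n_hap` (per
#'   locus, the number of allele observations) and `excluded` (loci with
#'   no data).
#' @export
compute_allele_frequencies <- function(g, subset = NULL) {
  idx <- resolve_subset(g, subset)
  if (!length(idx)) stop("empty subset")
  freq <- list(); n_hap <- integer(0); excluded <- character(0)
  for (L in g$loci) {
    al <- c(g$a1[idx, L], g$a2[idx, L])
    al <- al[!is.na(al)]
    if (!length(al)) { excluded <- c(excluded, L); next }
    tab <- table(al)
    freq[[L]] <- setNames(as.numeric(tab) / length(al), names(tab))
    n_hap[L] <- length(al)
  }
  allele_freqs(freq, n_hap, excluded)
}

#' Construct an allele-frequency table
#'
#' @param freq named list; per locus a named numeric vector
#'   (names = allele designations) of frequencies summing to 1.
#' @param n_hap named integer vector: allele observations per locus.
#' @param excluded loci dropped for lack of data.
#' @return An `allele_freqs` object.
#' @export
allele_freqs <- function(freq, n_hap, excluded = character(0)) {
  stopifnot(is.list(freq), all(names(freq) %in% names(n_hap) |
                                 length(n_hap) == length(freq)))
  for (L in names(freq)) {
    p <- freq[[L]]
    if (any(p <= 0)) stop("non-positive frequency at locus ", L)
    if (abs(sum(p) - 1) > 1e-9)
      stop("frequencies at locus ", L, " sum to ", fmt_num(sum(p)))
  }
  structure(list(freq = freq, n_hap = n_hap[names(freq)],
                 excluded = excluded),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele_freqs: %d loci, %d alleles total\n",
              length(x$freq), sum(lengths(x$freq))))
  if (length(x$excluded))
    cat("excluded loci:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write an allele-frequency TSV
#'
#' Format: columns `locus`, `allele`, `frequency`, `n_haplotypes`.
#' Frequencies are renormalized per locus to absorb printing round-off.
#'
#' @param path TSV file path.
#' @return An [allele_freqs()] object.
#' @export
read_allele_frequencies <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("locus", "allele", "frequency", "n_haplotypes") %in%
                  names(d)))
  freq <- lapply(split(d, d$locus), function(x)
    setNames(x$frequency / sum(x$frequency), x$allele))
  n_hap <- sapply(split(d, d$locus), function(x) as.integer(x$n_haplotypes[1]))
  allele_freqs(freq, n_hap)
}

#' @rdname read_allele_frequencies
#' @param af an [allele_freqs()] object.
#' @export
write_allele_frequencies <- function(af, path) {
  rows <- do.call(rbind, lapply(names(af$freq), function(L)
    data.frame(locus = L, allele = names(af$freq[[L]]),
               frequency = unname(af$freq[[L]]),
               n_haplotypes = unname(af$n_hap[L]))))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a pedigree
#'
#' A pedigree is a data frame of `id`, `sire`, `dam` (NA = unknown),
#' optional `dob` (`Date`) and `cohort`. Parent references must resolve to
#' rows of the pedigree or be unknown, and the parent graph must be
#' acyclic (no individual its own ancestor).
#'
#' @param df data frame with columns `id`, `sire`, `dam` and optionally
#'   `dob`, `cohort`.
#' @return An object of class `pedigree` (a validated data frame).
#' @export
pedigree <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "sire", "dam") %in% names(df)))
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire); df$dam <- as.character(df$dam)
  df$sire[df$sire %in% c("", "NA")] <- NA
  df$dam[df$dam %in% c("", "NA")] <- NA
  if (anyDuplicated(df$id)) stop("duplicate ids in pedigree")
  for (col in c("sire", "dam")) {
    bad <- !is.na(df[[col]]) & !(df[[col]] %in% df$id)
    if (any(bad))
      stop("unresolved ", col, " reference: ",
           paste(unique(df[[col]][bad]), collapse = ", "))
  }
  if (is.null(df$dob)) df$dob <- as.Date(NA)
  if (is.null(df$cohort)) df$cohort <- NA_character_
  # Kahn topological sort; leftovers lie on a cycle.
  idx <- seq_len(nrow(df))
  parent <- cbind(match(df$sire, df$id), match(df$dam, df$id))
  indeg <- rowSums(!is.na(parent))
  children <- split(rep(idx, 2)[!is.na(c(parent))],
                    c(parent)[!is.na(c(parent))])
  queue <- idx[indeg == 0L]; seen <- 0L; order <- integer(nrow(df))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    order[seen] <- v
    for (ch in children[[as.character(v)]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(df)) {
    bad <- df$id[indeg > 0L][1L]
    stop("individual is its own ancestor: ", bad)
  }
  structure(df[c("id", "sire", "dam", "dob", "cohort")],
            class = c("pedigree", "data.frame"),
            topo_order = order)
}

#' Read a pedigree CSV
#'
#' Format: `id,sire,dam,dob,cohort`; empty parent fields mean unknown.
#' Birth dates are parsed as ISO (`YYYY-MM-DD`) or `DD/MM/YYYY`;
#' unparseable dates are stored as missing.
#'
#' @param path CSV file path.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("id", "sire", "dam") %in% names(d)))
  if (!is.null(d$dob)) {
    dob <- as.Date(d$dob, format = "%Y-%m-%d")
    alt <- as.Date(d$dob, format = "%d/%m/%Y")
    dob[is.na(dob)] <- alt[is.na(dob)]
    d$dob <- dob
  }
  pedigree(d)
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$sire) & is.na(x$dam))
  cat(sprintf("pedigree: %d individuals (%d founders)\n", nrow(x), founders))
  invisible(x)
}
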