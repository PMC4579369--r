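# Loaders for the packaged reference tables (plain TSV under extdata).

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "strdiv")
  if (path == "") stop("fixture not found: ", name)
  path
}

#' Published Standard Poodle genomic STR allele frequencies
#'
#' Breed-wide allele frequencies at the 33-locus genomic STR panel,
#' pooled over the genotyped Standard Poodle, Miniature Poodle and cross
#' cohorts. Frequencies are renormalized per locus (the printed values
#' carry three-decimal round-off). Decimal repeat designations are stored
#' as integers scaled by ten.
#'
#' @param include_mini_only keep alleles observed only in Miniature
#'   Poodles (default TRUE).
#' @return An [allele_freqs()] object over 33 loci; `n_hap` is the pooled
#'   haplotype count (2 x 761 dogs).
#' @export
standard_poodle_frequencies <- function(include_mini_only = TRUE) {
  d <- utils::read.table(ext_file("genomic_str_frequencies.tsv"),
                         header = TRUE, sep = "\t")
  if (!include_mini_only) d <- d[d$mini_only == 0L, ]
  freq <- lapply(split(d, d$locus), function(x)
    setNames(x$frequency / sum(x$frequency), x$allele))
  freq <- freq[unique(d$locus)]
  allele_freqs(freq, setNames(rep(2L * 761L, length(freq)), names(freq)))
}

#' The genomic STR panel definition
#'
#' @return Data frame of locus name, chromosome, and known alleles per
#'   locus of the 33-locus genomic panel.
#' @export
genomic_panel <- function() {
  d <- utils::read.table(ext_file("genomic_str_frequencies.tsv"),
                         header = TRUE, sep = "\t")
  data.frame(locus = unique(d$locus),
             chromosome = d$chromosome[!duplicated(d$locus)],
             n_alleles = as.integer(table(d$locus)[unique(d$locus)]))
}

#' The DLA STR panel definition
#'
#' Four class I and three class II STR loci on CFA12; `tuple_position`
#' gives each locus's place in the haplotype tuple.
#'
#' @return Data frame of locus, region, tuple position and allele size
#'   range.
#' @export
dla_panel <- function() {
  utils::read.table(ext_file("dla_str_panel.tsv"), header = TRUE,
                    sep = "\t")
}

#' The published DLA STR haplotype registry
#'
#' STR-based DLA class I (ids 1001-1057, 4-locus tuples) and class II
#' (ids 2001-2028, 3-locus tuples) haplotypes with their breed-wide
#' frequencies and, where established, the corresponding exon-2
#' DRB1/DQA1/DQB1 haplotype names.
#'
#' @param region `"dla_class_I"`, `"dla_class_II"` or `"both"`.
#' @return Data frame with `region`, `id`, `alleles` (list column of
#'   integer tuples), `frequency`, `mini_only`, `exon2`.
#' @export
dla_registry <- function(region = c("both", "dla_class_I", "dla_class_II")) {
  region <- match.arg(region)
  d <- utils::read.table(ext_file("dla_haplotype_registry.tsv"),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (region != "both") d <- d[d$region == region, ]
  d$alleles <- lapply(strsplit(d$tuple, "/", fixed = TRUE), as.integer)
  d
}

#' Published case/control DLA haplotype counts
#'
#' Haplotype counts (two per dog) in USA Standard Poodle cohorts: healthy
#' controls (314 dogs), Addison's disease (AD, 74 dogs) and sebaceous
#' adenitis (SA, 61 dogs).
#'
#' @param region `"dla_class_I"` or `"dla_class_II"`.
#' @return Data frame `id`, `ad`, `sa`, `control` of haplotype counts;
#'   column sums are 148, 122 and 628.
#' @export
dla_cohort_counts <- function(region = c("dla_class_I", "dla_class_II")) {
  region <- match.arg(region)
  f <- if (region == "dla_class_I") "dla_class1_cohort_counts.tsv"
       else "dla_class2_cohort_counts.tsv"
  utils::read.table(ext_file(f), header = TRUE, sep = "\t")
}

#' Published per-dog DLA homozygosity frequencies
#'
#' @return Data frame of disease (AD/SA), DLA region, homozygote
#'   frequency among case and control dogs, and cohort sizes.
#' @export
dla_homozygosity_frequencies <- function() {
  utils::read.table(ext_file("dla_homozygosity_frequencies.tsv"),
                    header = TRUE, sep = "\t")
}

#' Named founder sets for ancestry indices
#'
#' The ancestor lists behind the %MCB (midcentury bottleneck, 10 dogs),
#' %Wycliffe (5 dogs) and %OEA (Old English Apricot, 7 dogs) ancestry
#' percentages.
#'
#' @return Named list of character vectors of registered names.
#' @export
founder_sets <- function() {
  d <- utils::read.table(ext_file("founder_sets.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  split(d$dog, d$set_name)
}
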