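#' Run the full analysis pipeline
#'
#' Executes the standard stage sequence on one dataset - diversity
#' statistics, internal relatedness (raw and, given a reference,
#' adjusted), genotypic distance and PCoA, DLA phasing of both regions,
#' haplotype / group / homozygosity associations, and pedigree metrics -
#' writing one TSV per stage plus a JSON run manifest. Every TSV starts
#' with `#` comment lines carrying the package version and a hash of the
#' configuration, so reruns are diffable; a rerun with identical inputs
#' and seed is byte-identical. A stage failure aborts with the stage
#' name; the partial output of the failed stage is kept with a
#' `.partial` suffix.
#'
#' @param genotypes a [genotype_table()] or path to a genotype CSV.
#' @param pedigree_data optional [pedigree()] or path to a pedigree CSV.
#' @param reference optional reference [allele_freqs()] (or frequency TSV
#'   path) for adjusted IR.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param case_cohorts,control_cohort cohort labels used for association
#'   stages (skipped when the labels are absent).
#' @param founder_set_list named list of founder sets for pedigree
#'   summaries (default: none).
#' @param axes PCoA axes to write.
#' @return The manifest (named list), invisibly written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(genotypes, pedigree_data = NULL, reference = NULL,
                         out_dir = "strdiv-out", seed = 1,
                         case_cohorts = c("SA", "AD"),
                         control_cohort = "healthy",
                         founder_set_list = NULL, axes = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage0 <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  input_hashes <- list()
  if (is.character(genotypes)) {
    genotypes <- stage0("read_genotypes", {
      input_hashes$genotypes <- unname(tools::md5sum(genotypes))
      read_genotypes(genotypes)
    })
  }
  if (is.character(pedigree_data)) {
    pedigree_data <- stage0("read_pedigree", {
      if (!file.exists(pedigree_data))
        stop("pedigree file not found: ", pedigree_data)
      input_hashes$pedigree <- unname(tools::md5sum(pedigree_data))
      read_pedigree(pedigree_data)
    })
  }
  if (is.character(reference)) {
    reference <- stage0("read_reference", {
      input_hashes$reference <- unname(tools::md5sum(reference))
      read_allele_frequencies(reference)
    })
  }
  cfg_hash <- substr(paste(
    digest_config(list(seed = seed, axes = axes,
                       case = case_cohorts, control = control_cohort))),
    1, 12)
  version <- as.character(utils::packageVersion("strdiv"))
  artifacts <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(c(paste0("# strdiv ", version),
                 paste0("# config ", cfg_hash),
                 paste0("# seed ", seed)), con)
    suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                        row.names = FALSE))
    close(con)
    artifacts <<- c(artifacts, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      partial <- file.path(out_dir, paste0(name, ".partial"))
      writeLines(conditionMessage(e), partial)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  pan <- dla_panel()
  dla_loci <- intersect(pan$locus, genotypes$loci)
  genomic <- setdiff(genotypes$loci, pan$locus)
  g_gen <- subset_genotypes(genotypes, loci = genomic)

  stage("diversity", {
    ds <- diversity_stats(g_gen)
    emit(ds$per_locus, "diversity")
    emit(ds$summary, "diversity_summary")
  })
  ir <- stage("ir", {
    ir <- internal_relatedness(g_gen)
    if (!is.null(reference)) {
      adj <- adjusted_internal_relatedness(g_gen, reference)
      ir$adjusted_IR <- adj$adjusted_IR
    }
    emit(ir, "ir")
    ir
  })
  stage("pcoa", {
    d <- genetic_distance(g_gen)
    pc <- pcoa(d, axes = axes)
    emit(data.frame(id = rownames(pc$coordinates), pc$coordinates), "pcoa")
    emit(data.frame(axis = seq_along(pc$percent_variance),
                    percent_variance = pc$percent_variance),
         "pcoa_variance")
  })
  phases <- list()
  if (length(dla_loci) == 7L) {
    for (region in c("dla_class_I", "dla_class_II")) {
      phases[[region]] <- stage(paste0("phase_", region), {
        ph <- em_phase(genotypes, region, seed = seed)
        reg <- dla_registry(region)
        named <- name_haplotypes(ph$frequencies$haplotype, reg)
        freqs <- cbind(named["id"], ph$frequencies)
        emit(freqs, paste0("haplotypes_", region))
        dipn <- ph$diplotypes
        dipn$hap1_id <- name_haplotypes(dipn$hap1, reg)$id
        dipn$hap2_id <- name_haplotypes(dipn$hap2, reg)$id
        emit(dipn[c("id", "hap1_id", "hap2_id", "posterior")],
             paste0("diplotypes_", region))
        ph
      })
    }
    stage("extended_haplotypes", {
      ext <- extended_haplotypes(phases$dla_class_I$diplotypes,
                                 phases$dla_class_II$diplotypes)
      emit(as.data.frame(ext), "extended_haplotypes")
    })
  }
  cohorts <- genotypes$meta$cohort
  if (length(phases) &&
      sum(cohorts %in% control_cohort) >= 5) {
    for (case in intersect(case_cohorts, cohorts)) {
      for (region in names(phases)) {
        stage(paste0("assoc_", case, "_", region), {
          dip <- phases[[region]]$diplotypes
          lab <- cohorts[match(dip$id, genotypes$meta$id)]
          counts <- hap_counts_by_cohort(dip, lab,
                                         c(case, control_cohort))
          scan <- haplotype_scan(counts, case = case,
                                 control = control_cohort,
                                 id = "haplotype")
          emit(scan, paste0("assoc_", case, "_", region))
          hz <- homozygosity_rr(dip[lab == case, ],
                                dip[lab == control_cohort, ])
          emit(hz, paste0("assoc_homozygosity_", case, "_", region))
        })
      }
    }
  }
  if (!is.null(pedigree_data)) {
    stage("pedigree", {
      caps <- c(10, 15)
      cois <- sapply(caps, function(g) coi(pedigree_data,
                                           pedigree_data$id, g = g))
      colnames(cois) <- paste0("coi_", caps)
      emit(data.frame(id = pedigree_data$id, cois), "coi")
      if (!is.null(founder_set_list)) {
        ds <- decade_summary(pedigree_data, founder_set_list, g_list = caps)
        if (nrow(ds)) emit(ds, "decade_summary")
      }
    })
  }
  manifest <- list(package = "strdiv", version = version, seed = seed,
                   config_hash = cfg_hash, inputs = input_hashes,
                   artifacts = basename(unique(artifacts)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Tabulate per-cohort haplotype counts from hard diplotype assignments.
hap_counts_by_cohort <- function(dip, labels, cohorts) {
  haps <- sort(unique(c(dip$hap1, dip$hap2)))
  out <- data.frame(haplotype = haps)
  for (ch in cohorts) {
    sel <- labels == ch & !is.na(labels)
    out[[ch]] <- as.integer(
      table(factor(c(dip$hap1[sel], dip$hap2[sel]), levels = haps)))
  }
  out
}

digest_config <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * seq_along(v)) %% .Machine$integer.max)
}
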