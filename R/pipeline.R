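#' Pipeline run configuration
#'
#' Collects the named thresholds of the analysis (with the published values
#' as defaults) plus generator settings and seeds. The configuration is
#' serialized verbatim into the run manifest so that a run is reproducible
#' from its outputs.
#'
#' @param homozygosity_threshold Minor/major non-shared read ratio below
#'   which a genotype is homozygous (default 0.15).
#' @param expectation_threshold PSM confidence cutoff (default 0.001,
#'   strict \code{<}).
#' @param minor_fraction,fold_margin Allele-imbalance rule (defaults 0.5
#'   and 1.5).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param flag20,flag30 Allele fold-change flag thresholds (defaults 0.2,
#'   0.3).
#' @param min_allele_peptides Minimum unique allele-specific peptides per
#'   tissue (default 3).
#' @param n_patients,alleles_per_gene,depth,dispersion,detect_prob,intensity_cv
#'   Synthetic cohort scale and noise settings.
#' @param loh_rate,imbalance_rate Injected event rates.
#' @param tumor_log2fc Injected tumor log2 fold change (single number).
#' @param seed Master seed for all generator stages.
#' @param study Study label recorded in outputs.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(homozygosity_threshold = 0.15,
                       expectation_threshold = 0.001,
                       minor_fraction = 0.5, fold_margin = 1.5,
                       alpha = 0.05, flag20 = 0.2, flag30 = 0.3,
                       min_allele_peptides = 3L,
                       n_patients = 12L, alleles_per_gene = 4L,
                       depth = 1000, dispersion = 0.05,
                       detect_prob = 0.8, intensity_cv = 0.2,
                       loh_rate = 0.08, imbalance_rate = 0.08,
                       tumor_log2fc = 0.8, seed = 1L,
                       study = "synthetic") {
  cfg <- as.list(environment())
  stopifnot(cfg$homozygosity_threshold > 0, cfg$homozygosity_threshold < 1,
            cfg$expectation_threshold >= 0, cfg$alpha > 0, cfg$alpha < 1,
            cfg$minor_fraction > 0, cfg$minor_fraction < 1,
            cfg$fold_margin >= 1, cfg$min_allele_peptides >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort under the configuration, then executes genotyping on
#' simulated reads, LOH and imbalance calling, allele-level RNA
#' quantification and normalization, PSM filtering and allele-aware protein
#' quantification, and the cohort statistics, writing every table as TSV
#' into \code{out_dir} together with a JSON manifest carrying the full
#' configuration and its hash. Identical configurations produce identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list of the in-memory results (\code{genotypes},
#'   \code{loh}, \code{imbalance}, \code{rna}, \code{protein},
#'   \code{differential}, \code{homozygosity}, \code{manifest_path}).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("hlarun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  gen <- stage("simulate", {
    dbres <- make_allele_db(alleles_per_gene = config$alleles_per_gene,
                            seed = config$seed)
    freqs <- lapply(split(dbres$db$two_field, dbres$db$gene),
                    function(a) stats::setNames(rep(1 / length(a), length(a)), a))
    cohort <- make_cohort(config$n_patients, freqs,
                          loh_rate = config$loh_rate,
                          imbalance_rate = config$imbalance_rate,
                          seed = config$seed + 1L)
    rna <- make_rna(cohort, dbres$db, depth = config$depth,
                    dispersion = config$dispersion,
                    tumor_log2fc = config$tumor_log2fc,
                    emit_reads = TRUE, seed = config$seed + 2L)
    ms <- make_psm_tables(cohort, dbres$db,
                          gene_log2fc = config$tumor_log2fc,
                          detect_prob = config$detect_prob,
                          intensity_cv = config$intensity_cv,
                          seed = config$seed + 3L)
    list(dbres = dbres, cohort = cohort, rna = rna, ms = ms)
  })
  db <- gen$dbres$db

  genotypes <- stage("genotyping", {
    rows <- list()
    for (smp in names(gen$rna$reads)) {
      for (g in names(gen$rna$reads[[smp]])) {
        sub <- subset_db(db, db$gene == g)
        compat <- build_compatibility(gen$rna$reads[[smp]][[g]], sub)
        rows[[length(rows) + 1L]] <-
          call_genotype(compat, config$homozygosity_threshold,
                        sample_id = smp, gene = g)
      }
    }
    do.call(rbind, rows)
  })

  loh <- stage("loh", {
    gt <- genotypes
    gt$patient <- sub("-[TN]$", "", gt$sample_id)
    gt$tissue <- sub("^.*-", "", gt$sample_id)
    tum <- gt[gt$tissue == "T", ]; tum$sample_id <- tum$patient
    nor <- gt[gt$tissue == "N", ]; nor$sample_id <- nor$patient
    compare_genotype_pairs(tum, nor)
  })

  rna_norm <- stage("rna_quant", {
    normalize_counts(gen$rna$counts + 0, pseudocount = 1)
  })

  imbalance <- stage("imbalance", {
    rows <- list()
    for (i in seq_len(nrow(gen$cohort$normal))) {
      ng <- gen$cohort$normal[i, ]; tg <- gen$cohort$tumor[i, ]
      if (ng$homozygous || tg$homozygous) next
      tcol <- paste0(ng$sample_id, "-T"); ncol <- paste0(ng$sample_id, "-N")
      te <- gen$rna$counts[c(ng$allele1, ng$allele2), tcol] + 1
      ne <- gen$rna$counts[c(ng$allele1, ng$allele2), ncol] + 1
      rows[[length(rows) + 1L]] <-
        detect_imbalance(te, ne, config$minor_fraction, config$fold_margin,
                         patient_id = ng$sample_id, gene = ng$gene)
    }
    do.call(rbind, rows)
  })

  protein <- stage("ms_quant", {
    search_db <- build_search_database(
      common_proteome = gen$ms$background_proteome, db = db)
    psms <- filter_psms(gen$ms$psms, config$expectation_threshold)
    agg <- aggregate_peptides(psms, gen$ms$design)
    spec <- classify_specificity(unique(agg$peptide), search_db)
    ratios <- peptide_log_ratio(agg, gen$ms$design, floor = 0)
    genos <- rbind(
      transform(gen$cohort$tumor, sample_id = paste0(sample_id, "-T")),
      transform(gen$cohort$normal, sample_id = paste0(sample_id, "-N")))
    quant <- protein_abundance(agg, gen$ms$design, spec, genos, db,
                               mode = "hla_gene")
    list(psms = psms, spec = spec, ratios = ratios, quant = quant,
         genotypes = genos)
  })

  differential <- stage("cohort_stats", {
    eligible <- peptide_gene_ratios(protein$ratios, protein$spec,
                                    protein$genotypes, db)
    tum <- eligible[grepl("-T$", eligible$sample_id), ]
    nor <- eligible[grepl("-N$", eligible$sample_id), ]
    tum$patient_id <- sub("-T$", "", tum$sample_id)
    nor$patient_id <- sub("-N$", "", nor$sample_id)
    paired_differential(tum, nor, alpha = config$alpha)
  })

  homozygosity <- stage("homozygosity", {
    gt <- rbind(cbind(gen$cohort$tumor, tissue = "T"),
                cbind(gen$cohort$normal, tissue = "N"))
    homozygosity_rates(gt, strata = c("tissue", "gene"))
  })

  # outputs + manifest
  write_genotypes(genotypes, file.path(out_dir, "genotypes.tsv"))
  for (nm in c("loh", "imbalance", "differential", "homozygosity")) {
    utils::write.table(get(nm), file.path(out_dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(protein$quant, file.path(out_dir, "protein_hla_gene.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_count_table(rna_norm, file.path(out_dir, "rna_normalized.tsv"))
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  manifest <- list(config = unclass(config),
                   config_hash = unname(tools::md5sum(
                     textConnection_write(cfg_json, out_dir))),
                   outputs = sort(list.files(out_dir, pattern = "\\.tsv$")))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(genotypes = genotypes, loh = loh, imbalance = imbalance,
                 rna = rna_norm, protein = protein,
                 differential = differential, homozygosity = homozygosity,
                 manifest_path = manifest_path, out_dir = out_dir))
}

# md5 of the serialized config (written next to the outputs)
textConnection_write <- function(json, out_dir) {
  path <- file.path(out_dir, "config.json")
  writeLines(json, path)
  path
}

#' Subset an allele database
#'
#' @param db An [allele_db()].
#' @param keep Logical or integer index over records.
#' @return The subset as an [allele_db()].
#' @export
subset_db <- function(db, keep) {
  structure(list(name = db$name[keep], gene = db$gene[keep],
                 two_field = db$two_field[keep], cds = db$cds[keep],
                 protein = db$protein[keep], p_groups = db$p_groups),
            class = "allele_db")
}

#' Per-sample eligible peptide ratios for the gene-level paired test
#'
#' Restricts centered peptide ratios to HLA-gene-specific peptides matching
#' the sample's own genotype and annotates each row with the gene -- the
#' peptide population entering [paired_differential()].
#'
#' @param ratios [peptide_log_ratio()] output.
#' @param spec [classify_specificity()] output.
#' @param genotypes Genotype table covering the samples.
#' @param db An [allele_db()].
#' @param il_equivalent Collapse I/L when matching (default FALSE).
#' @return Data frame \code{sample_id}, \code{gene}, \code{peptide},
#'   \code{log2_ratio}.
#' @export
peptide_gene_ratios <- function(ratios, spec, genotypes, db,
                                il_equivalent = FALSE) {
  cand <- spec[spec$class == "hla_gene_specific", , drop = FALSE]
  x <- merge(ratios, cand[, c("peptide", "hla_gene")], by = "peptide")
  x$gene <- sub("^HLA-", "", x$hla_gene)
  keep <- vapply(seq_len(nrow(x)), function(i) {
    gt <- genotypes[genotypes$sample_id == x$sample_id[i] &
                      genotypes$gene == x$gene[i], , drop = FALSE]
    if (nrow(gt) == 0L) return(FALSE)
    match_to_genotype(x$peptide[i], gt[1L, ], db, il_equivalent)$genotype_matched
  }, logical(1))
  out <- x[keep, c("sample_id", "gene", "peptide", "log2_ratio")]
  rownames(out) <- NULL
  out
}
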