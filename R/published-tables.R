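#' Published CPTAC tumor/normal HLA-I genotype discrepancies
#'
#' The 21 published tumor/adjacent-normal genotype rows from the CPTAC
#' LUAD, LSCC, HNSCC and CCRCC cohorts in which RNA-level HLA class I
#' genotyping disagreed between the two tissues of a patient, shipped as a
#' plain-text table. These rows are the worked example for [detect_loh()]:
#' all but one discrepancy is a tumor loss of heterozygosity; the one
#' exception (LSCC patient C3N-01893) is heterozygous in the tumor while
#' the normal is homozygous.
#'
#' @return Data frame with columns \code{study}, \code{gene},
#'   \code{patient_id}, \code{tumor_allele1}, \code{tumor_allele2},
#'   \code{normal_allele1}, \code{normal_allele2}.
#' @export
cptac_discrepant_genotypes <- function() {
  path <- system.file("extdata", "cptac_hla_discrepant_genotypes.tsv",
                      package = "hlaquant", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Paired RNAseq sample counts of the four CPTAC cohorts
#'
#' Number of patients with both tumor and adjacent-normal RNAseq in the
#' four published cohorts whose genotype discrepancies are shipped with the
#' package; the denominator for LOH prevalence.
#'
#' @return Named integer vector (LUAD, LSCC, HNSCC, CCRCC).
#' @export
cptac_paired_rnaseq_counts <- function() {
  c(LUAD = 102L, LSCC = 95L, HNSCC = 61L, CCRCC = 75L)
}

#' Loss-of-heterozygosity calls on the published discrepancy table
#'
#' Runs [detect_loh()] over every row of
#' [cptac_discrepant_genotypes()] and summarises per study: the number of
#' distinct patients with at least one LOH gene, and the LOH prevalence
#' among paired RNAseq patients.
#'
#' @return A list: \code{calls} (one row per genotype row, with
#'   \code{study}, \code{patient_id}, \code{gene}, \code{status},
#'   \code{lost_allele}) and \code{by_study} (per study: \code{n_loh},
#'   \code{n_paired}, \code{percent_loh}).
#' @export
cptac_loh_summary <- function() {
  tab <- cptac_discrepant_genotypes()
  calls <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    cbind(study = r$study,
          detect_loh(genotype_table(r$patient_id, r$gene,
                                    r$tumor_allele1, r$tumor_allele2),
                     genotype_table(r$patient_id, r$gene,
                                    r$normal_allele1, r$normal_allele2)))
  }))
  paired <- cptac_paired_rnaseq_counts()
  by_study <- do.call(rbind, lapply(names(paired), function(s) {
    loh_pat <- unique(calls$patient_id[calls$study == s & calls$status == "loh"])
    data.frame(study = s, n_loh = length(loh_pat),
               n_paired = unname(paired[s]),
               percent_loh = round(100 * length(loh_pat) / paired[s], 1),
               stringsAsFactors = FALSE)
  }))
  list(calls = calls, by_study = by_study)
}
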