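#' Construct a genotype table
#'
#' A genotype is an unordered pair of two-field allele names for one sample
#' and one HLA class I gene. Pairs are stored sorted so that equality is
#' order-insensitive; homozygosity means the two entries are identical.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param gene Character vector of genes (\code{"A"}, \code{"B"}, \code{"C"}).
#' @param allele1,allele2 Character vectors of allele names (reduced to
#'   two-field form on construction).
#' @return A data frame with columns \code{sample_id}, \code{gene},
#'   \code{allele1}, \code{allele2}, \code{homozygous}.
#' @export
genotype_table <- function(sample_id, gene, allele1, allele2) {
  if (length(allele1) == 0L) {
    return(data.frame(sample_id = character(0), gene = character(0),
                      allele1 = character(0), allele2 = character(0),
                      homozygous = logical(0)))
  }
  a1 <- to_two_field(allele1)
  a2 <- to_two_field(allele2)
  pg <- parse_allele(a1)$gene
  if (any(pg != parse_allele(a2)$gene) || any(pg != gene)) {
    stop("genotype alleles must belong to the stated gene", call. = FALSE)
  }
  swap <- a2 < a1
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  data.frame(sample_id = sample_id, gene = gene,
             allele1 = a1, allele2 = a2,
             homozygous = a1 == a2, stringsAsFactors = FALSE)
}

#' Read / write genotype tables
#'
#' TSV with columns \code{sample_id}, \code{gene}, \code{allele1},
#' \code{allele2} holding WMDA two-field allele strings.
#'
#' @param path File path.
#' @return For the reader, a genotype table as from [genotype_table()].
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  genotype_table(tab$sample_id, tab$gene, tab$allele1, tab$allele2)
}

#' @rdname read_genotypes
#' @param genotypes A genotype table.
#' @export
write_genotypes <- function(genotypes, path) {
  utils::write.table(genotypes[c("sample_id", "gene", "allele1", "allele2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
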