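#' Build a personalized transcript reference
#'
#' Removes the annotated HLA class I entries from a common transcript
#' reference and replaces them with the coding sequences of the sample's own
#' alleles, so that allele-level RNA quantification sees exactly the two
#' (or one, if homozygous) sequences that are present in the sample.
#'
#' HLA entries in the common reference are recognized by an identifier
#' predicate -- a regular expression on the entry name -- not by sequence
#' similarity.
#'
#' @param common_ref Named character vector of transcript sequences (or a
#'   FASTA path).
#' @param genotypes Genotype table for a single sample ([genotype_table()]).
#' @param db An [allele_db()] supplying the allele coding sequences.
#' @param hla_id_regex Regular expression matching the identifiers of HLA
#'   class I entries to remove (default matches names like \code{"HLA-A..."}
#'   or parseable allele names).
#' @return Named character vector: retained common entries in their original
#'   order, followed by one entry per distinct sample allele, sorted by
#'   canonical name.
#' @export
build_personalized_transcript_reference <- function(common_ref, genotypes, db,
                                                    hla_id_regex = "^HLA-[ABC]") {
  if (is.character(common_ref) && length(common_ref) == 1L && file.exists(common_ref)) {
    common_ref <- read_fasta(common_ref)
  }
  stopifnot(is.character(common_ref), !is.null(names(common_ref)))
  drop <- grepl(hla_id_regex, names(common_ref))
  if (!any(drop) && nrow(genotypes) > 0L) {
    warning("hla_id_regex matched no entries of the common reference; ",
            "check the HLA identifier predicate", call. = FALSE)
  }
  kept <- common_ref[!drop]
  alleles <- sort(unique(c(genotypes$allele1, genotypes$allele2)))
  added <- character(0)
  if (length(alleles) > 0L) {
    idx <- vapply(alleles, function(a) {
      hits <- db_lookup(db, a)
      if (length(hits) == 0L) {
        stop("allele missing from database: ", a, call. = FALSE)
      }
      hits[1L]
    }, integer(1))
    added <- db$cds[idx]
    names(added) <- alleles
  }
  c(kept, added)
}

#' Build a provenance-tagged protein search database
#'
#' Concatenates the common proteome, the full HLA allele protein set and a
#' contaminant list into the search space used for peptide specificity
#' classification. Every record is tagged \code{standard}, \code{hla} or
#' \code{contaminant}; duplicate sequences are retained (specificity
#' classification resolves them). For \code{standard} records the gene symbol
#' is taken from a \code{gene=} tag in the header when present, else the
#' record identifier; \code{hla} records carry \code{"HLA-A"}-style gene
#' labels derived from the allele name.
#'
#' @param common_proteome Named character vector of protein sequences (or a
#'   FASTA path).
#' @param db An [allele_db()]; must be non-empty.
#' @param contaminants Named character vector of contaminant proteins (or a
#'   FASTA path); may be empty.
#' @return An object of class \code{"search_db"}: a data frame with columns
#'   \code{id}, \code{gene}, \code{provenance}, \code{seq},
#'   \code{hla_two_field} (NA for non-HLA records).
#' @export
build_search_database <- function(common_proteome, db, contaminants = character(0)) {
  as_seqs <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x) else x
  }
  common_proteome <- as_seqs(common_proteome)
  contaminants <- as_seqs(contaminants)
  if (!inherits(db, "allele_db") || length(db$name) == 0L) {
    stop("empty allele database: HLA quantification impossible", call. = FALSE)
  }
  gene_of <- function(headers) {
    tag <- regmatches(headers, regexpr("gene=[^ ]+", headers))
    ids <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
    out <- ids
    has <- grepl("gene=", headers)
    out[has] <- sub("^gene=", "", regmatches(headers, regexpr("gene=[^ ]+", headers)))
    out
  }
  std <- NULL
  if (length(common_proteome) > 0L) {
    std <- data.frame(
      id = vapply(strsplit(names(common_proteome), "\\s+"), `[`, character(1), 1L),
      gene = gene_of(names(common_proteome)),
      provenance = rep("standard", length(common_proteome)),
      seq = unname(common_proteome),
      hla_two_field = rep(NA_character_, length(common_proteome)),
      stringsAsFactors = FALSE)
  }
  hla <- data.frame(
    id = db$name, gene = paste0("HLA-", db$gene),
    provenance = "hla", seq = db$protein,
    hla_two_field = db$two_field, stringsAsFactors = FALSE)
  cont <- NULL
  if (length(contaminants) > 0L) {
    cont <- data.frame(
      id = vapply(strsplit(names(contaminants), "\\s+"), `[`, character(1), 1L),
      gene = gene_of(names(contaminants)),
      provenance = rep("contaminant", length(contaminants)),
      seq = unname(contaminants),
      hla_two_field = rep(NA_character_, length(contaminants)),
      stringsAsFactors = FALSE)
  }
  out <- rbind(std, hla, cont)
  rownames(out) <- NULL
  class(out) <- c("search_db", "data.frame")
  out
}
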