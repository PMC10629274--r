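#' HLA allele sequence database
#'
#' Holds full-length coding sequences (and their translations) of HLA class I
#' alleles, keyed by canonical allele name, with optional P-group membership.
#' Translations are checked against supplied protein sequences at load time;
#' only full-length, in-frame coding sequences are accepted.
#'
#' @param cds Named character vector of nucleotide coding sequences; names are
#'   allele identifiers parseable by [parse_allele()].
#' @param protein Optional named character vector of protein sequences, same
#'   names as \code{cds}. When omitted, proteins are obtained by translation.
#'   When present, each must equal the translated cds.
#' @param p_groups Optional data frame with columns \code{gene},
#'   \code{field1}, \code{field2}, \code{p_group} (logical) giving P-group
#'   membership at protein-level resolution.
#' @return An object of class \code{"allele_db"}: a list with elements
#'   \code{name} (canonical names), \code{gene}, \code{two_field},
#'   \code{cds}, \code{protein} (parallel character vectors) and
#'   \code{p_groups}.
#' @export
allele_db <- function(cds, protein = NULL, p_groups = NULL) {
  stopifnot(is.character(cds), !is.null(names(cds)), all(nzchar(names(cds))))
  parsed <- parse_allele(names(cds))
  canon <- format_allele(parsed)
  if (anyDuplicated(canon)) {
    stop("duplicate canonical allele names in database: ",
         paste(unique(canon[duplicated(canon)]), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(cds) %% 3L != 0L)) {
    stop("coding sequence length must be a multiple of 3 for: ",
         paste(canon[nchar(cds) %% 3L != 0L], collapse = ", "), call. = FALSE)
  }
  translated <- translate_cds(cds)
  if (is.null(protein)) {
    protein <- translated
  } else {
    protein <- unname(protein[names(cds)])
    mism <- protein != translated
    if (any(is.na(protein)) || any(mism)) {
      stop("protein sequence does not match translated cds for: ",
           paste(canon[is.na(protein) | mism], collapse = ", "), call. = FALSE)
    }
  }
  if (any(!nzchar(protein))) stop("empty protein sequence", call. = FALSE)
  structure(list(
    name      = canon,
    gene      = parsed$gene,
    two_field = to_two_field_raw(parsed),
    cds       = unname(cds),
    protein   = unname(protein),
    p_groups  = p_groups
  ), class = "allele_db")
}

# two-field reduction of an already-parsed table, preserving the P flag
to_two_field_raw <- function(parsed) {
  parsed$field3 <- NA_integer_
  format_allele(parsed)
}

translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "error"))
  sub("\\*$", "", aa)
}

#' @export
print.allele_db <- function(x, ...) {
  cat("HLA allele database:", length(x$name), "alleles (",
      paste(vapply(split(x$name, x$gene), length, integer(1)),
            names(split(x$name, x$gene)), collapse = ", "), ")\n")
  invisible(x)
}

#' Look up database records by two-field reduction
#'
#' @param db An [allele_db()].
#' @param name Single allele name; matched after reduction to two fields.
#' @return Integer indices of matching records (possibly several when the
#'   database is at three-field resolution).
#' @export
db_lookup <- function(db, name) {
  stopifnot(inherits(db, "allele_db"), length(name) == 1L)
  which(db$two_field == to_two_field(name, db))
}

#' Read an allele database from FASTA
#'
#' Headers must carry the allele name as the first whitespace-delimited
#' token (an IMGT/HLA-style \code{"HLA-"} prefix is accepted).
#'
#' @param fasta Path to a nucleotide FASTA of full-length coding sequences.
#' @param p_group_tsv Optional path to a TSV with columns \code{allele}
#'   (two-field name) and \code{p_group} (TRUE/FALSE).
#' @return An [allele_db()].
#' @export
read_allele_db <- function(fasta, p_group_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  cds <- as.character(seqs)
  names(cds) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  p_groups <- NULL
  if (!is.null(p_group_tsv)) {
    tab <- utils::read.delim(p_group_tsv, stringsAsFactors = FALSE)
    pa <- parse_allele(tab$allele)
    p_groups <- data.frame(gene = pa$gene, field1 = pa$field1,
                           field2 = pa$field2, p_group = as.logical(tab$p_group))
  }
  allele_db(cds, p_groups = p_groups)
}

#' Write named sequences as wrapped FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 60 columns).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Generic (nucleotide or protein) reader; the full header line is kept as
#' the name so that key=value provenance tags survive a round trip.
#'
#' @param path FASTA path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- as.character(seqs)
  names(out) <- names(seqs)
  out
}
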