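#' Parse HLA class I allele names
#'
#' Parses allele identifiers in IMGT/WMDA notation, e.g. \code{"A*24:02P"},
#' \code{"HLA-B*13:02P"} or \code{"C*07:02:01"}. Only the classical class I
#' heavy-chain genes HLA-A, HLA-B and HLA-C are supported. An optional
#' \code{"HLA-"} prefix is normalized away; numeric fields are zero-padded to
#' at least two digits in the canonical rendering, and a trailing \code{"P"}
#' marks membership of a P-group (alleles with identical peptide-binding
#' domain protein sequence).
#'
#' @param x Character vector of allele names.
#' @return A data frame of class \code{"hla_allele"} with one row per input
#'   and columns \code{gene} (\code{"A"}, \code{"B"} or \code{"C"}),
#'   \code{field1} (allele group), \code{field2} (protein), \code{field3}
#'   (coding-sequence synonym, \code{NA} for two-field names) and
#'   \code{p_group} (logical).
#' @examples
#' parse_allele(c("A*24:02P", "HLA-B*13:02P", "C*07:02:01"))
#' @seealso [format_allele()], [to_two_field()], [allele_group()]
#' @export
parse_allele <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  stripped <- sub("^HLA-", "", x)
  m <- regmatches(stripped,
                  regexec("^([A-Za-z0-9]+)\\*([0-9]+):([0-9]+)(?::([0-9]+))?(P?)$",
                          stripped, perl = TRUE))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed HLA allele name: ", paste(sQuote(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  gene <- vapply(m, `[`, character(1), 2L)
  unsupported <- !gene %in% c("A", "B", "C")
  if (any(unsupported)) {
    stop("unsupported HLA gene ", paste(sQuote(unique(gene[unsupported])), collapse = ", "),
         "; only class I genes A, B, C are handled", call. = FALSE)
  }
  f3 <- vapply(m, `[`, character(1), 5L)
  out <- data.frame(
    gene    = gene,
    field1  = as.integer(vapply(m, `[`, character(1), 3L)),
    field2  = as.integer(vapply(m, `[`, character(1), 4L)),
    field3  = ifelse(nzchar(f3), suppressWarnings(as.integer(f3)), NA_integer_),
    p_group = vapply(m, `[`, character(1), 6L) == "P",
    stringsAsFactors = FALSE
  )
  if (any(out$field1 <= 0L | out$field2 <= 0L, na.rm = TRUE)) {
    stop("allele numeric fields must be positive", call. = FALSE)
  }
  class(out) <- c("hla_allele", "data.frame")
  out
}

#' Render parsed alleles in canonical form
#'
#' Inverse of [parse_allele()]: numeric fields zero-padded to two digits,
#' no \code{"HLA-"} prefix, \code{"P"} suffix when the name carries one.
#'
#' @param a An \code{"hla_allele"} data frame from [parse_allele()], or a
#'   character vector (normalized by a parse/render round trip).
#' @return Character vector of canonical names.
#' @export
format_allele <- function(a) {
  if (is.character(a)) a <- parse_allele(a)
  stopifnot(inherits(a, "hla_allele") || is.data.frame(a))
  pad <- function(n) formatC(n, width = 2, flag = "0")
  f3 <- ifelse(is.na(a$field3), "", paste0(":", pad(a$field3)))
  paste0(a$gene, "*", pad(a$field1), ":", pad(a$field2), f3,
         ifelse(a$p_group, "P", ""))
}

#' Reduce allele names to two-field (protein-level) resolution
#'
#' Drops the third (coding-sequence synonym) field. When the allele database
#' carries a P-group table, the P flag is set from it; otherwise the flag in
#' the input name is preserved -- no equivalence class is ever invented.
#' Idempotent.
#'
#' @param x Character vector of allele names (any supported resolution).
#' @param db Optional [allele_db()] whose \code{p_groups} table maps
#'   two-field proteins to P-group membership.
#' @return Character vector of canonical two-field names.
#' @export
to_two_field <- function(x, db = NULL) {
  a <- parse_allele(x)
  a$field3 <- NA_integer_
  if (!is.null(db) && !is.null(db$p_groups) && nrow(db$p_groups) > 0L) {
    key  <- paste(a$gene, a$field1, a$field2)
    pkey <- paste(db$p_groups$gene, db$p_groups$field1, db$p_groups$field2)
    hit  <- match(key, pkey)
    a$p_group <- ifelse(is.na(hit), a$p_group, db$p_groups$p_group[hit])
  }
  format_allele(a)
}

#' Allele-group label
#'
#' The allele group (gene plus first numeric field, e.g. \code{"B*15"})
#' collects alleles with similar protein sequences; it is the unit of the
#' cohort frequency-enrichment analysis.
#'
#' @param x Character vector of allele names.
#' @return Character vector of group labels such as \code{"B*15"}.
#' @export
allele_group <- function(x) {
  a <- parse_allele(x)
  paste0(a$gene, "*", formatC(a$field1, width = 2, flag = "0"))
}
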