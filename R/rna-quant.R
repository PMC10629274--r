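#' Allele-level read counting for one sample
#'
#' Distributes the reads of a sample across the two alleles of its genotype:
#' reads compatible with exactly one allele count fully towards it, and
#' reads compatible with both are apportioned by \code{shared_split}.
#' The default \code{"proportional"} splits shared reads in proportion to
#' the unique counts -- the EM fixed point for a two-sequence reference,
#' which keeps the recovered allele ratio unbiased; \code{"even"} splits
#' them 50/50 (one EM step from a uniform start), which shrinks ratios
#' towards 1 when many reads fall in conserved regions. When both unique
#' counts are zero the shared reads are split evenly in either mode.
#' Homozygous genotypes put all compatible reads on the single allele.
#' Counts may be fractional.
#'
#' @param compat A [build_compatibility()] matrix whose columns include the
#'   genotype's alleles.
#' @param genotype One-row genotype table for the sample and gene.
#' @param shared_split \code{"proportional"} or \code{"even"}.
#' @return Named numeric vector of counts, one entry per distinct allele.
#' @export
quantify_alleles <- function(compat, genotype,
                             shared_split = c("proportional", "even")) {
  shared_split <- match.arg(shared_split)
  stopifnot(is.matrix(compat), nrow(genotype) == 1L)
  a1 <- genotype$allele1; a2 <- genotype$allele2
  if (!all(c(a1, a2) %in% colnames(compat))) {
    stop("genotype alleles absent from the compatibility matrix", call. = FALSE)
  }
  if (genotype$homozygous) {
    out <- sum(compat[, a1])
    names(out) <- a1
    return(out)
  }
  c1 <- compat[, a1]; c2 <- compat[, a2]
  u1 <- sum(c1 & !c2); u2 <- sum(c2 & !c1); s <- sum(c1 & c2)
  w1 <- if (shared_split == "proportional" && u1 + u2 > 0) u1 / (u1 + u2) else 0.5
  out <- c(u1 + s * w1, u2 + s * (1 - w1))
  names(out) <- c(a1, a2)
  out
}

#' Library-size normalization to a log2 expression matrix
#'
#' Scales each sample by a size factor, adds a pseudocount and takes log2 --
#' a variance-tamed log scale in place of a full variance-stabilizing
#' transformation. Two size-factor methods are available:
#' \code{"column_sum"} (size factor proportional to the library size,
#' normalized to mean 1) and \code{"median_ratio"} (median of per-feature
#' ratios to the geometric-mean reference sample; requires every feature to
#' be nonzero in every sample, else falls back to column sums with a
#' warning). The method and pseudocount are recorded as attributes.
#'
#' @param counts Numeric matrix, features x samples, non-negative.
#' @param pseudocount Added before the log (default 1, so a zero count maps
#'   to 0).
#' @param method Size-factor method; see Details.
#' @return Matrix of class \code{"expression_matrix"} with attributes
#'   \code{method}, \code{pseudocount}, \code{size_factors}.
#' @export
normalize_counts <- function(counts, pseudocount = 1,
                             method = c("column_sum", "median_ratio")) {
  method <- match.arg(method)
  stopifnot(is.matrix(counts), all(counts >= 0))
  cs <- colSums(counts)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[cs == 0], collapse = ", "), call. = FALSE)
  }
  if (method == "median_ratio") {
    if (any(counts == 0)) {
      warning("zero counts present; median-of-ratios undefined, ",
              "falling back to column-sum scaling", call. = FALSE)
      method <- "column_sum"
    }
  }
  sf <- if (method == "median_ratio") {
    log_geo <- rowMeans(log(counts))
    apply(counts, 2L, function(col) exp(stats::median(log(col) - log_geo)))
  } else {
    cs / mean(cs)
  }
  out <- log2(sweep(counts, 2L, sf, "/") + pseudocount)
  attr(out, "method") <- method
  attr(out, "pseudocount") <- pseudocount
  attr(out, "size_factors") <- sf
  class(out) <- c("expression_matrix", class(out))
  out
}

#' Gene-level expression from allele-level values
#'
#' For a heterozygous sample the gene total is the log of the sum of the two
#' alleles' linear expressions, \code{log2(2^a1 + 2^a2)}; for a homozygous
#' sample the single allele's value is the gene value.
#'
#' @param a1,a2 Log2-scale allele expression values (vectors recycle).
#' @param homozygous Logical; when TRUE, \code{a1} is returned unchanged.
#' @return Log2-scale gene expression.
#' @export
gene_total_from_alleles <- function(a1, a2 = NULL, homozygous = FALSE) {
  if (homozygous || is.null(a2)) return(a1)
  log2(2^a1 + 2^a2)
}

#' Read / write count tables with a metadata header
#'
#' TSV with features in rows and samples in columns; normalization metadata
#' is carried in \code{#key=value} comment lines.
#'
#' @param x Matrix to write.
#' @param path File path.
#' @export
write_count_table <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in c("method", "pseudocount")) {
    if (!is.null(attr(x, key))) writeLines(paste0("#", key, "=", attr(x, key)), con)
  }
  writeLines(paste(c("feature", colnames(x)), collapse = "\t"), con)
  utils::write.table(data.frame(feature = rownames(x), x, check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  out <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(out) <- tab[[1L]]
  for (m in meta) {
    kv <- strsplit(sub("^#", "", m), "=", fixed = TRUE)[[1L]]
    attr(out, kv[1L]) <- kv[2L]
  }
  out
}
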