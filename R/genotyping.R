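#' Read-to-allele compatibility matrix
#'
#' A read is compatible with a candidate allele when every k-mer of the read
#' occurs in the allele coding sequence -- a simplified stand-in for de
#' Bruijn graph pseudoalignment. Reads shorter than \code{k} are compatible
#' with nothing and counted in the \code{dropped_short} attribute.
#'
#' @param reads Character vector of read sequences (names become read ids;
#'   unnamed reads are numbered).
#' @param db An [allele_db()] (or a subset of one) providing the candidate
#'   allele coding sequences.
#' @param k K-mer length (default 31, the typical pseudoalignment k).
#' @return A logical matrix reads x alleles of class \code{"compat_matrix"},
#'   with row names read ids, column names canonical allele names, and an
#'   attribute \code{dropped_short} giving the number of too-short reads.
#' @export
build_compatibility <- function(reads, db, k = 31L) {
  stopifnot(is.character(reads), inherits(db, "allele_db"), k >= 1L)
  if (is.null(names(reads))) names(reads) <- paste0("read", seq_along(reads))
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  allele_kmers <- lapply(db$cds, kmers)
  compat <- matrix(FALSE, nrow = length(reads), ncol = length(db$name),
                   dimnames = list(names(reads), db$name))
  short <- nchar(reads) < k
  live <- which(!short)
  if (length(live) > 0L) {
    rk_list <- lapply(reads[live], kmers)
    rk_all <- unlist(rk_list, use.names = FALSE)
    rk_read <- factor(rep(seq_along(live), vapply(rk_list, length, integer(1))),
                      levels = seq_along(live))
    for (j in seq_along(allele_kmers)) {
      miss <- !(rk_all %in% allele_kmers[[j]])
      compat[live, j] <- rowsum(as.integer(miss), rk_read)[, 1L] == 0L
    }
  }
  attr(compat, "dropped_short") <- sum(short)
  class(compat) <- c("compat_matrix", class(compat))
  compat
}

#' Call a genotype from a compatibility matrix
#'
#' Greedy iterative pair selection: the first allele is the one compatible
#' with the most reads; the second is the one explaining the most additional
#' reads; each member is then re-ranked against the other until the selected
#' pair is stable (ties broken by canonical name order throughout). The pair
#' is collapsed to a homozygous call when the minor-to-major ratio of
#' non-shared read counts falls below \code{homozygosity_threshold}
#' (strict \code{<} at the boundary).
#'
#' @param compat A [build_compatibility()] matrix.
#' @param homozygosity_threshold Minor/major non-shared count ratio below
#'   which the call is homozygous (default 0.15).
#' @param sample_id,gene Identifiers attached to the returned genotype row.
#' @return One-row genotype table ([genotype_table()]) with additional
#'   columns \code{nonshared_major}, \code{nonshared_minor},
#'   \code{minor_major_ratio}.
#' @export
call_genotype <- function(compat, homozygosity_threshold = 0.15,
                          sample_id = "sample", gene = NULL) {
  stopifnot(is.matrix(compat))
  alleles <- colnames(compat)
  n_reads <- colSums(compat)
  if (all(n_reads == 0L)) {
    stop("no read is compatible with any candidate allele: no call", call. = FALSE)
  }
  best <- function(scores, exclude = integer(0)) {
    scores[exclude] <- -Inf
    top <- which(scores == max(scores))
    top[order(alleles[top])][1L]
  }
  explained <- function(i, j) sum(compat[, i] | compat[, j])
  partner <- function(i) {
    best(vapply(seq_along(alleles), function(j) explained(i, j), numeric(1)),
         exclude = i)
  }
  a1 <- best(n_reads)
  if (length(alleles) == 1L) {
    a2 <- a1
  } else {
    a2 <- partner(a1)
    for (iter in seq_len(50L)) {
      a1_new <- partner(a2)
      a2_new <- partner(a1_new)
      if (setequal(c(a1_new, a2_new), c(a1, a2))) { a1 <- a1_new; a2 <- a2_new; break }
      a1 <- a1_new; a2 <- a2_new
    }
  }
  ns1 <- sum(compat[, a1] & !compat[, a2])
  ns2 <- sum(compat[, a2] & !compat[, a1])
  if (ns1 == 0L && ns2 == 0L) {
    warning("all reads shared between the selected pair: degenerate evidence, ",
            "calling homozygous for the first-ranked allele", call. = FALSE)
    major <- min(alleles[c(a1, a2)])
    pair <- c(major, major)
    ratio <- 0
  } else {
    major_i <- if (ns1 > ns2 || (ns1 == ns2 && alleles[a1] < alleles[a2])) a1 else a2
    minor_i <- if (major_i == a1) a2 else a1
    ratio <- min(ns1, ns2) / max(ns1, ns2)
    pair <- if (ratio < homozygosity_threshold) {
      rep(alleles[major_i], 2L)
    } else {
      c(alleles[major_i], alleles[minor_i])
    }
  }
  if (is.null(gene)) gene <- parse_allele(pair[1L])$gene
  out <- genotype_table(sample_id, gene, pair[1L], pair[2L])
  out$nonshared_major <- max(ns1, ns2)
  out$nonshared_minor <- min(ns1, ns2)
  out$minor_major_ratio <- ratio
  out
}

#' Compare paired tumor/normal genotypes for loss of heterozygosity
#'
#' Classifies the discrepancy between a tumor and a matched adjacent-normal
#' genotype of the same patient and gene:
#' \describe{
#'   \item{concordant}{identical unordered pairs;}
#'   \item{loh}{normal heterozygous, tumor homozygous for one of the normal
#'     alleles -- the tumor has lost the other allele (reported as
#'     \code{lost_allele});}
#'   \item{reverse_discrepancy}{tumor heterozygous while the normal is
#'     homozygous (the opposite direction, biologically implausible as a
#'     somatic loss and flagged separately);}
#'   \item{other_discrepancy}{any other disagreement.}
#' }
#'
#' @param tumor,normal One-row genotype tables ([genotype_table()]) for the
#'   same patient and gene.
#' @return A one-row data frame with columns \code{patient_id}, \code{gene},
#'   \code{status}, \code{lost_allele} (NA unless status is \code{loh}).
#' @export
detect_loh <- function(tumor, normal) {
  stopifnot(nrow(tumor) == 1L, nrow(normal) == 1L)
  if (tumor$gene != normal$gene) {
    stop("tumor and normal genotypes are for different genes", call. = FALSE)
  }
  tp <- c(tumor$allele1, tumor$allele2)
  np <- c(normal$allele1, normal$allele2)
  lost <- NA_character_
  if (identical(sort(tp), sort(np))) {
    status <- "concordant"
  } else if (!normal$homozygous && tumor$homozygous && tp[1L] %in% np) {
    status <- "loh"
    lost <- setdiff(np, tp[1L])
  } else if (normal$homozygous && !tumor$homozygous) {
    status <- "reverse_discrepancy"
  } else {
    status <- "other_discrepancy"
  }
  data.frame(patient_id = tumor$sample_id, gene = tumor$gene,
             status = status, lost_allele = lost, stringsAsFactors = FALSE)
}

#' Apply [detect_loh()] across a cohort of paired genotypes
#'
#' @param tumor,normal Genotype tables covering the same patients and genes
#'   (matched on \code{sample_id} and \code{gene}).
#' @return Data frame of LOH calls, one row per patient-gene pair present in
#'   both tables.
#' @export
compare_genotype_pairs <- function(tumor, normal) {
  key_t <- paste(tumor$sample_id, tumor$gene)
  key_n <- paste(normal$sample_id, normal$gene)
  common <- intersect(key_t, key_n)
  calls <- lapply(common, function(k) {
    detect_loh(tumor[key_t == k, , drop = FALSE][1L, ],
               normal[key_n == k, , drop = FALSE][1L, ])
  })
  do.call(rbind, calls)
}

#' Call allele expression imbalance in a heterozygous tumor
#'
#' A heterozygous gene is imbalanced when, on the linear scale, the minor
#' allele's RNA expression in tumor is less than \code{minor_fraction} of
#' the major allele's, and the tumor major/minor fold difference is at least
#' \code{fold_margin} times the matched normal's fold difference.
#'
#' @param tumor_expr,normal_expr Numeric length-2 vectors of strictly
#'   positive linear-scale allele expression (same allele order).
#' @param minor_fraction Tumor minor/major threshold (default 0.5).
#' @param fold_margin Required tumor-vs-normal fold inflation (default 1.5).
#' @param patient_id,gene Identifiers for the returned row.
#' @return One-row data frame with \code{imbalanced}, \code{tumor_ratio},
#'   \code{normal_ratio} (minor/major, in (0, 1]).
#' @export
detect_imbalance <- function(tumor_expr, normal_expr, minor_fraction = 0.5,
                             fold_margin = 1.5, patient_id = "patient",
                             gene = NA_character_) {
  stopifnot(length(tumor_expr) == 2L, length(normal_expr) == 2L)
  if (any(c(tumor_expr, normal_expr) <= 0)) {
    stop("allele expression must be strictly positive on the linear scale ",
         "(add pseudocounts before linearizing)", call. = FALSE)
  }
  tr <- min(tumor_expr) / max(tumor_expr)
  nr <- min(normal_expr) / max(normal_expr)
  imb <- (tr < minor_fraction) && ((1 / tr) >= fold_margin * (1 / nr))
  data.frame(patient_id = patient_id, gene = gene, imbalanced = imb,
             tumor_ratio = tr, normal_ratio = nr, stringsAsFactors = FALSE)
}
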