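#' In-silico tryptic digestion
#'
#' Cleaves after lysine (K) or arginine (R) except when the next residue is
#' proline, emits all products with up to \code{missed_cleavages} internal
#' missed sites, and filters to the given length window.
#'
#' @param protein Amino-acid sequence (single string, 20-letter alphabet).
#' @param missed_cleavages Maximum internal missed cleavage sites (0--2).
#' @param min_len,max_len Peptide length bounds (defaults 7 and 40, the
#'   usual identifiable tryptic range).
#' @return Character vector of distinct peptides, sorted.
#' @export
digest <- function(protein, missed_cleavages = 2L, min_len = 7L, max_len = 40L) {
  stopifnot(length(protein) == 1L, missed_cleavages >= 0L, missed_cleavages <= 2L)
  res <- strsplit(protein, "")[[1L]]
  bad <- !res %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  if (any(bad)) {
    stop("invalid residue ", sQuote(res[which(bad)[1L]]),
         " at position ", which(bad)[1L], call. = FALSE)
  }
  n <- length(res)
  # cut points: after position i when res[i] is K/R and res[i+1] is not P
  cuts <- which(res %in% c("K", "R"))
  cuts <- cuts[cuts == n | res[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, if (!n %in% cuts) n)  # fragment boundaries
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1L]
  peps <- character(0)
  for (i in seq_along(starts)) {
    for (m in 0:missed_cleavages) {
      j <- i + m
      if (j > length(ends)) break
      len <- ends[j] - starts[i] + 1L
      if (len >= min_len && len <= max_len) {
        peps <- c(peps, substr(protein, starts[i], ends[j]))
      }
    }
  }
  sort(unique(peps))
}

#' Read / write PSM tables
#'
#' Wide TSV: columns \code{peptide}, \code{plex_id}, \code{fraction},
#' \code{charge}, \code{scan}, \code{expectation}, then one intensity
#' column per TMT reporter channel. Channel columns are remembered in a
#' \code{"channels"} attribute.
#'
#' @param path File path.
#' @return Data frame of PSM records with attribute \code{channels}.
#' @export
read_psm_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("peptide", "plex_id", "fraction", "charge", "scan", "expectation")
  missing <- setdiff(fixed, names(tab))
  if (length(missing) > 0L) {
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  attr(tab, "channels") <- setdiff(names(tab), fixed)
  tab
}

#' @rdname read_psm_table
#' @param psms PSM data frame.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

psm_channels <- function(psms) {
  ch <- attr(psms, "channels")
  if (is.null(ch)) {
    ch <- setdiff(names(psms),
                  c("peptide", "plex_id", "fraction", "charge", "scan", "expectation"))
  }
  ch
}

#' Filter PSMs on identification confidence and reporter presence
#'
#' Keeps records whose expectation value is strictly below the threshold and
#' that carry at least one positive reporter intensity; order-preserving.
#'
#' @param psms PSM data frame ([read_psm_table()] layout).
#' @param expectation_threshold Strict upper bound on the expectation value
#'   (default 0.001).
#' @return Filtered PSM data frame.
#' @export
filter_psms <- function(psms, expectation_threshold = 0.001) {
  ch <- psm_channels(psms)
  rep_mat <- as.matrix(psms[, ch, drop = FALSE])
  rep_mat[is.na(rep_mat)] <- 0
  keep <- psms$expectation < expectation_threshold & rowSums(rep_mat > 0) > 0
  out <- psms[keep, , drop = FALSE]
  attr(out, "channels") <- ch
  out
}

#' Classify peptide specificity against the search database
#'
#' Exact substring matching of each peptide against every record of a
#' provenance-tagged [build_search_database()]. A peptide hitting any
#' non-HLA record is discarded (\code{discard_nonhla_overlap}); one hitting
#' alleles of more than one HLA gene is discarded
#' (\code{discard_multi_hla_gene}); otherwise it is
#' \code{hla_gene_specific}. Isoleucine and leucine are distinct residues by
#' default (peptides must match at 100%); set \code{il_equivalent = TRUE} to
#' collapse them for sensitivity analysis.
#'
#' @param peptides Character vector of (modification-stripped) peptide
#'   sequences.
#' @param search_db A [build_search_database()].
#' @param il_equivalent Treat I and L as the same residue (default FALSE).
#' @return Data frame with one row per peptide: \code{peptide},
#'   \code{class}, \code{hla_gene} (the single gene for
#'   \code{hla_gene_specific} peptides, else NA), and list columns
#'   \code{hit_genes}, \code{hit_hla_alleles} (two-field names).
#' @export
classify_specificity <- function(peptides, search_db, il_equivalent = FALSE) {
  stopifnot(inherits(search_db, "search_db"))
  seqs <- search_db$seq
  pep_m <- peptides
  if (il_equivalent) {
    seqs <- gsub("I", "L", seqs, fixed = TRUE)
    pep_m <- gsub("I", "L", pep_m, fixed = TRUE)
  }
  is_hla <- search_db$provenance == "hla"
  rows <- lapply(seq_along(peptides), function(i) {
    hits <- which(vapply(seqs, function(s) grepl(pep_m[i], s, fixed = TRUE),
                         logical(1), USE.NAMES = FALSE))
    hit_genes <- unique(search_db$gene[hits])
    hla_hits <- hits[is_hla[hits]]
    nonhla <- any(!is_hla[hits])
    hla_genes <- unique(search_db$gene[hla_hits])
    cls <- if (length(hla_hits) > 0L && nonhla) {
      "discard_nonhla_overlap"
    } else if (length(hla_genes) > 1L) {
      "discard_multi_hla_gene"
    } else if (length(hla_hits) > 0L) {
      "hla_gene_specific"
    } else if (nonhla) {
      "non_hla"
    } else {
      "unmapped"
    }
    list(class = cls,
         hla_gene = if (cls == "hla_gene_specific") hla_genes else NA_character_,
         hit_genes = hit_genes,
         hit_hla_alleles = unique(search_db$hla_two_field[hla_hits]))
  })
  out <- data.frame(
    peptide = peptides,
    class = vapply(rows, `[[`, character(1), "class"),
    hla_gene = vapply(rows, `[[`, character(1), "hla_gene"),
    stringsAsFactors = FALSE)
  out$hit_genes <- lapply(rows, `[[`, "hit_genes")
  out$hit_hla_alleles <- lapply(rows, `[[`, "hit_hla_alleles")
  out
}

#' Match an HLA-gene-specific peptide to a sample genotype
#'
#' A peptide is genotype-matched when its sequence occurs within the protein
#' sequence of at least one of the sample's two alleles; it is
#' allele-specific when it occurs in exactly one.
#'
#' @param peptide Peptide sequence (HLA-gene-specific).
#' @param genotype One-row genotype table for the peptide's gene.
#' @param db An [allele_db()] providing allele protein sequences.
#' @param il_equivalent Collapse I/L before matching (default FALSE).
#' @return One-row data frame: \code{peptide}, \code{genotype_matched},
#'   \code{allele_resolution} (\code{"allele_specific"},
#'   \code{"allele_shared"} or \code{"unmatched"}), \code{allele} (the
#'   matching allele for allele-specific peptides, else NA).
#' @export
match_to_genotype <- function(peptide, genotype, db, il_equivalent = FALSE) {
  stopifnot(nrow(genotype) == 1L)
  alleles <- unique(c(genotype$allele1, genotype$allele2))
  prot <- vapply(alleles, function(a) {
    hits <- db_lookup(db, a)
    if (length(hits) == 0L) stop("allele missing from database: ", a, call. = FALSE)
    db$protein[hits[1L]]
  }, character(1))
  pep_m <- peptide
  if (il_equivalent) {
    prot <- gsub("I", "L", prot, fixed = TRUE)
    pep_m <- gsub("I", "L", pep_m, fixed = TRUE)
  }
  in_allele <- vapply(prot, function(s) grepl(pep_m, s, fixed = TRUE), logical(1))
  n_hit <- sum(in_allele)
  resolution <- if (n_hit == 0L) "unmatched"
                else if (genotype$homozygous || n_hit == length(alleles)) "allele_shared"
                else "allele_specific"
  data.frame(peptide = peptide,
             genotype_matched = n_hit > 0L,
             allele_resolution = resolution,
             allele = if (resolution == "allele_specific") alleles[in_allele] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Aggregate PSM reporter intensities to peptide level
#'
#' Sums reporter ion intensities over scans, charges and chromatographic
#' fractions, per peptide, per plex, per channel. Missing intensities
#' contribute zero.
#'
#' @param psms Filtered PSM data frame.
#' @param design Plex design data frame (columns \code{plex_id},
#'   \code{channel}, \code{sample_id}, \code{is_reference}); when supplied,
#'   PSMs carrying a plex id absent from the design are an error.
#' @return Long data frame: \code{peptide}, \code{plex_id}, \code{channel},
#'   \code{intensity}.
#' @export
aggregate_peptides <- function(psms, design = NULL) {
  ch <- psm_channels(psms)
  if (!is.null(design)) {
    unknown <- setdiff(unique(psms$plex_id), unique(design$plex_id))
    if (length(unknown) > 0L) {
      stop("PSMs reference unknown plex id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (nrow(psms) == 0L) {
    return(data.frame(peptide = character(0), plex_id = character(0),
                      channel = character(0), intensity = numeric(0)))
  }
  long <- do.call(rbind, lapply(ch, function(cc) {
    data.frame(peptide = psms$peptide, plex_id = psms$plex_id, channel = cc,
               intensity = ifelse(is.na(psms[[cc]]), 0, psms[[cc]]),
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(intensity ~ peptide + plex_id + channel, data = long, FUN = sum)
  agg[order(agg$peptide, agg$plex_id, agg$channel), , drop = FALSE]
}

#' Peptide-level log2 ratios to the pooled reference
#'
#' Forms \code{log2((sample + floor) / (reference + floor))} per peptide and
#' sample from aggregated intensities, then median-centers each sample
#' across all of its quantified peptides (the "median normalized" peptide
#' scale). Centering offsets are recorded as an attribute.
#'
#' @param agg Aggregated intensities from [aggregate_peptides()].
#' @param design Plex design data frame; exactly one reference channel per
#'   plex.
#' @param floor Small positive constant added to numerator and denominator
#'   (default 0; a zero reference intensity with a zero floor is an error).
#' @return Data frame \code{peptide}, \code{plex_id}, \code{sample_id},
#'   \code{log2_ratio} (centered), \code{log2_ratio_raw}; attribute
#'   \code{centering_offsets} (named per-sample medians that were
#'   subtracted).
#' @export
peptide_log_ratio <- function(agg, design, floor = 0) {
  ref <- design[design$is_reference, , drop = FALSE]
  if (any(table(ref$plex_id) != 1L) || !setequal(unique(design$plex_id), ref$plex_id)) {
    stop("plex design must contain exactly one reference channel per plex",
         call. = FALSE)
  }
  if (nrow(agg) == 0L) {
    out <- data.frame(peptide = character(0), plex_id = character(0),
                      sample_id = character(0), log2_ratio = numeric(0),
                      log2_ratio_raw = numeric(0))
    attr(out, "centering_offsets") <- numeric(0)
    return(out)
  }
  ref_int <- agg[paste(agg$plex_id, agg$channel) %in% paste(ref$plex_id, ref$channel), ]
  ref_key <- paste(ref_int$peptide, ref_int$plex_id)
  smp <- design[!design$is_reference, , drop = FALSE]
  x <- merge(agg, smp, by = c("plex_id", "channel"))
  x$ref_intensity <- ref_int$intensity[match(paste(x$peptide, x$plex_id), ref_key)]
  x$ref_intensity[is.na(x$ref_intensity)] <- 0
  if (floor == 0 && any(x$ref_intensity == 0)) {
    stop("zero reference intensity with floor = 0: ratio undefined", call. = FALSE)
  }
  x$log2_ratio_raw <- log2((x$intensity + floor) / (x$ref_intensity + floor))
  offs <- tapply(x$log2_ratio_raw, x$sample_id, stats::median)
  x$log2_ratio <- x$log2_ratio_raw - offs[x$sample_id]
  out <- x[order(x$peptide, x$plex_id, x$sample_id),
           c("peptide", "plex_id", "sample_id", "log2_ratio", "log2_ratio_raw")]
  rownames(out) <- NULL
  attr(out, "centering_offsets") <- offs
  out
}

#' Median-center a protein table across samples
#'
#' Subtracts the per-feature median over samples, the whole-proteome
#' convention for relative abundance tables.
#'
#' @param x Matrix, features x samples.
#' @return Centered matrix with attribute \code{centering} = "per-feature
#'   median across samples".
#' @export
median_center_rows <- function(x) {
  out <- sweep(x, 1L, apply(x, 1L, stats::median, na.rm = TRUE), "-")
  attr(out, "centering") <- "per-feature median across samples"
  out
}

#' Allele-aware protein abundance from aggregated peptide intensities
#'
#' Sums the reporter intensities of the selected peptides for each sample
#' and takes the log2 ratio of that sum to the matching pooled-reference
#' sum. Peptide selection depends on the mode:
#' \describe{
#'   \item{whole_proteome_gene}{peptides uniquely mapped to one gene;}
#'   \item{hla_gene}{HLA-gene-specific peptides matching the sample's own
#'     genotype (per gene);}
#'   \item{hla_allele}{genotype-matched peptides occurring in exactly one of
#'     the sample's two alleles (per allele; homozygous samples therefore
#'     have no allele-level rows).}
#' }
#' Entries with no contributing peptide are absent, not zero.
#'
#' @param agg Aggregated intensities ([aggregate_peptides()]).
#' @param design Plex design data frame.
#' @param specificity Output of [classify_specificity()] covering the
#'   peptides in \code{agg}.
#' @param genotypes Genotype table covering the design's samples (required
#'   for the HLA modes).
#' @param db An [allele_db()] (required for the HLA modes).
#' @param mode Quantification mode; see Details.
#' @param floor Intensity floor as in [peptide_log_ratio()].
#' @param il_equivalent Collapse I/L when matching peptides to genotypes.
#' @return Data frame: \code{sample_id}, \code{feature} (gene symbol or
#'   allele name), \code{log2_ratio}, \code{n_peptides}.
#' @export
protein_abundance <- function(agg, design, specificity, genotypes = NULL,
                              db = NULL,
                              mode = c("hla_gene", "hla_allele", "whole_proteome_gene"),
                              floor = 0, il_equivalent = FALSE) {
  mode <- match.arg(mode)
  ref <- design[design$is_reference, , drop = FALSE]
  smp <- design[!design$is_reference, , drop = FALSE]
  spec_of <- specificity[match(unique(agg$peptide), specificity$peptide), , drop = FALSE]
  rows <- list()
  for (si in seq_len(nrow(smp))) {
    sid <- smp$sample_id[si]; plex <- smp$plex_id[si]; chan <- smp$channel[si]
    ref_chan <- ref$channel[ref$plex_id == plex][1L]
    in_plex <- agg$plex_id == plex
    peptides <- unique(agg$peptide[in_plex])
    sel <- list()  # feature -> peptide vector
    if (mode == "whole_proteome_gene") {
      for (p in peptides) {
        srow <- specificity[specificity$peptide == p, , drop = FALSE]
        if (nrow(srow) == 0L) next
        genes <- srow$hit_genes[[1L]]
        if (length(genes) == 1L) sel[[genes]] <- c(sel[[genes]], p)
      }
    } else {
      stopifnot(!is.null(genotypes), !is.null(db))
      cand <- specificity[specificity$class == "hla_gene_specific" &
                            specificity$peptide %in% peptides, , drop = FALSE]
      for (pi in seq_len(nrow(cand))) {
        gene_short <- sub("^HLA-", "", cand$hla_gene[pi])
        gt <- genotypes[genotypes$sample_id == sid & genotypes$gene == gene_short, ,
                        drop = FALSE]
        if (nrow(gt) == 0L) next
        m <- match_to_genotype(cand$peptide[pi], gt[1L, ], db, il_equivalent)
        if (mode == "hla_gene" && m$genotype_matched) {
          sel[[cand$hla_gene[pi]]] <- c(sel[[cand$hla_gene[pi]]], cand$peptide[pi])
        } else if (mode == "hla_allele" &&
                   m$allele_resolution == "allele_specific") {
          sel[[m$allele]] <- c(sel[[m$allele]], cand$peptide[pi])
        }
      }
    }
    for (feat in names(sel)) {
      peps <- unique(sel[[feat]])
      s_sum <- sum(agg$intensity[in_plex & agg$channel == chan &
                                   agg$peptide %in% peps])
      r_sum <- sum(agg$intensity[in_plex & agg$channel == ref_chan &
                                   agg$peptide %in% peps])
      if (floor == 0 && r_sum == 0) {
        stop("zero reference intensity sum with floor = 0 for ", feat, call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, feature = feat,
        log2_ratio = log2((s_sum + floor) / (r_sum + floor)),
        n_peptides = length(peps), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(sample_id = character(0), feature = character(0),
                      log2_ratio = numeric(0), n_peptides = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$sample_id, out$feature), , drop = FALSE]
}

#' Matched vs unmatched peptide expression, per gene
#'
#' For each sample, takes the median centered log2 ratio over the sample's
#' genotype-matched peptides of a gene and over its unmatched peptides, then
#' compares the two with a paired t-test across samples. Samples lacking
#' either group are excluded; fewer than two usable pairs yields a flagged,
#' not-computable result rather than an error. A zero-variance difference is
#' reported as no evidence (p = 1) when the mean difference is zero, and as
#' p = 0 when it is an exact constant shift.
#'
#' @param ratios Peptide-level ratios from [peptide_log_ratio()].
#' @param matched Data frame \code{sample_id}, \code{peptide},
#'   \code{genotype_matched} flagging each (sample, peptide) pair.
#' @return One-row data frame: \code{n_pairs}, \code{mean_difference}
#'   (matched minus unmatched), \code{se}, \code{t}, \code{p},
#'   \code{computable}.
#' @export
matched_vs_unmatched_stats <- function(ratios, matched) {
  x <- merge(ratios, matched, by = c("sample_id", "peptide"))
  med <- function(sid, want) {
    v <- x$log2_ratio[x$sample_id == sid & x$genotype_matched == want]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }
  sids <- unique(x$sample_id)
  m <- vapply(sids, med, numeric(1), want = TRUE)
  u <- vapply(sids, med, numeric(1), want = FALSE)
  ok <- !is.na(m) & !is.na(u)
  d <- m[ok] - u[ok]
  if (length(d) < 2L) {
    return(data.frame(n_pairs = length(d), mean_difference = NA_real_,
                      se = NA_real_, t = NA_real_, p = NA_real_,
                      computable = FALSE))
  }
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    p <- if (abs(mean(d)) < .Machine$double.eps^0.5) 1 else 0
    return(data.frame(n_pairs = length(d), mean_difference = mean(d),
                      se = 0, t = NA_real_, p = p, computable = TRUE))
  }
  tt <- stats::t.test(d)
  data.frame(n_pairs = length(d), mean_difference = mean(d),
             se = stats::sd(d) / sqrt(length(d)),
             t = unname(tt$statistic), p = tt$p.value, computable = TRUE)
}
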