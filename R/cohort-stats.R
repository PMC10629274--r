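#' Homozygosity rates by stratum
#'
#' Fraction of samples whose two alleles are identical, per gene and tissue
#' class (or any other stratification columns carried on the genotype
#' table).
#'
#' @param genotypes Genotype table; may carry extra columns named in
#'   \code{strata}.
#' @param strata Character vector of stratifying column names
#'   (default \code{"gene"}).
#' @return Data frame with the strata columns plus \code{n},
#'   \code{n_homozygous}, \code{rate}. Empty strata are absent.
#' @export
homozygosity_rates <- function(genotypes, strata = "gene") {
  stopifnot(all(strata %in% names(genotypes)))
  key <- interaction(genotypes[strata], drop = TRUE, sep = "\r")
  parts <- split(genotypes, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    cbind(g[1L, strata, drop = FALSE],
          data.frame(n = nrow(g), n_homozygous = sum(g$homozygous),
                     rate = mean(g$homozygous)))
  }))
  rownames(out) <- NULL
  out[do.call(order, out[strata]), , drop = FALSE]
}

#' Paired tumor/normal differential expression per patient
#'
#' For each patient and gene, compares the eligible peptide log2 ratios in
#' tumor against those in normal with a two-sample t-test (Welch by
#' default), then adjusts p-values with Benjamini-Hochberg across all
#' patients of the same gene (and study, when supplied). The log2 fold
#' change is the difference of means.
#'
#' @param tumor,normal Data frames with columns \code{patient_id},
#'   \code{gene}, \code{log2_ratio} (one row per eligible peptide).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return Data frame per patient-gene: \code{patient_id}, \code{gene},
#'   \code{log2fc}, \code{p}, \code{p_adj}, \code{direction}
#'   (\code{"over"}, \code{"under"}, \code{"ns"}), \code{computable},
#'   \code{n_tumor}, \code{n_normal}. Pairs with fewer than two peptides on
#'   either side are flagged not-computable and excluded from the BH family.
#' @export
paired_differential <- function(tumor, normal, alpha = 0.05, pooled = FALSE) {
  key_t <- paste(tumor$patient_id, tumor$gene)
  key_n <- paste(normal$patient_id, normal$gene)
  keys <- union(unique(key_t), unique(key_n))
  if (length(keys) == 0L) {
    return(data.frame(patient_id = character(0), gene = character(0),
                      n_tumor = integer(0), n_normal = integer(0),
                      log2fc = numeric(0), p = numeric(0),
                      computable = logical(0), p_adj = numeric(0),
                      direction = character(0)))
  }
  res <- lapply(keys, function(k) {
    tv <- tumor$log2_ratio[key_t == k]
    nv <- normal$log2_ratio[key_n == k]
    id <- strsplit(k, " ", fixed = TRUE)[[1L]]
    base <- data.frame(patient_id = id[1L], gene = id[2L],
                       n_tumor = length(tv), n_normal = length(nv),
                       stringsAsFactors = FALSE)
    if (length(tv) < 2L || length(nv) < 2L ||
        (stats::sd(tv) == 0 && stats::sd(nv) == 0)) {
      return(cbind(base, log2fc = if (length(tv) && length(nv))
        mean(tv) - mean(nv) else NA_real_,
        p = NA_real_, computable = FALSE))
    }
    tt <- stats::t.test(tv, nv, var.equal = pooled)
    cbind(base, log2fc = mean(tv) - mean(nv), p = tt$p.value, computable = TRUE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (g in unique(out$gene)) {
    i <- which(out$gene == g & out$computable)
    out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$direction <- ifelse(!out$computable | is.na(out$p_adj) | out$p_adj >= alpha,
                          "ns", ifelse(out$log2fc > 0, "over", "under"))
  out[order(out$patient_id, out$gene), , drop = FALSE]
}

#' Allele-level tumor/normal fold changes with flag thresholds
#'
#' Computes per-allele protein log2 fold changes (tumor minus normal) from
#' allele-specific peptide quantifications, restricted to patients whose
#' gene-level paired test was significant, and to alleles supported by at
#' least \code{min_peptides} unique allele-specific peptides in both
#' tissues. Linear fold-change flags: \code{flag20} when the allele departs
#' from 1 by more than 20% in either direction; \code{flag30} when the
#' allele is overexpressed by more than 30%.
#'
#' @param tumor_quant,normal_quant Allele-mode [protein_abundance()] tables
#'   (\code{sample_id} = patient), for tumor and normal tissue.
#' @param significant Character vector of patient ids that passed the
#'   gene-level paired test (adjusted p < alpha).
#' @param rna Optional data frame \code{patient_id}, \code{allele},
#'   \code{log2fc_rna} merged into the output.
#' @param min_peptides Minimum unique allele-specific peptides per tissue
#'   (default 3).
#' @return Data frame: \code{patient_id}, \code{allele},
#'   \code{log2fc_protein}, \code{log2fc_rna}, \code{n_peptides_tumor},
#'   \code{n_peptides_normal}, \code{flag20}, \code{flag30}.
#' @export
allele_fold_changes <- function(tumor_quant, normal_quant, significant,
                                rna = NULL, min_peptides = 3L) {
  m <- merge(tumor_quant, normal_quant, by = c("sample_id", "feature"),
             suffixes = c("_tumor", "_normal"))
  m <- m[m$sample_id %in% significant &
           m$n_peptides_tumor >= min_peptides &
           m$n_peptides_normal >= min_peptides, , drop = FALSE]
  out <- data.frame(patient_id = m$sample_id, allele = m$feature,
                    log2fc_protein = m$log2_ratio_tumor - m$log2_ratio_normal,
                    n_peptides_tumor = m$n_peptides_tumor,
                    n_peptides_normal = m$n_peptides_normal,
                    stringsAsFactors = FALSE)
  fc <- 2^out$log2fc_protein
  out$flag20 <- abs(fc - 1) > 0.2
  out$flag30 <- fc > 1.3
  if (!is.null(rna)) {
    out <- merge(out, rna, by.x = c("patient_id", "allele"),
                 by.y = c("patient_id", "allele"), all.x = TRUE)
  }
  out[order(out$patient_id, out$allele), , drop = FALSE]
}

#' Allele-group frequency enrichment against population expectations
#'
#' Compares observed allele-group frequencies in a cohort (each patient
#' contributing two alleles per gene) with ancestry-weighted expected
#' frequencies, using a two-sided exact binomial test per group and BH
#' adjustment within each gene. A group is flagged enriched when its
#' adjusted p-value is below \code{alpha} and its observed frequency
#' exceeds the expected by more than \code{excess_threshold} (default 50%).
#'
#' @param genotypes Genotype table for one cohort (normal-tissue genotypes).
#' @param expected_afs Data frame \code{group}, \code{ancestry}, \code{af}
#'   of population allele-group frequencies.
#' @param ancestry_weights Named numeric vector of cohort ancestry
#'   composition (sums to 1); defaults to a single unnamed ancestry when
#'   \code{expected_afs} has one.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param excess_threshold Required relative excess (default 0.5).
#' @return Data frame per observed group: \code{group}, \code{gene},
#'   \code{count}, \code{total}, \code{observed_af}, \code{expected_af},
#'   \code{excess}, \code{p}, \code{p_adj}, \code{enriched}. Groups absent
#'   from the expected table are excluded with a warning.
#' @export
allele_frequency_enrichment <- function(genotypes, expected_afs,
                                        ancestry_weights = NULL,
                                        alpha = 0.05, excess_threshold = 0.5) {
  if (is.null(ancestry_weights)) {
    anc <- unique(expected_afs$ancestry)
    ancestry_weights <- stats::setNames(rep(1 / length(anc), length(anc)), anc)
  }
  alleles <- data.frame(gene = rep(genotypes$gene, 2L),
                        allele = c(genotypes$allele1, genotypes$allele2))
  alleles$group <- allele_group(alleles$allele)
  rows <- list()
  for (g in sort(unique(alleles$gene))) {
    sub <- alleles[alleles$gene == g, , drop = FALSE]
    total <- nrow(sub)
    counts <- table(sub$group)
    for (grp in names(counts)) {
      ea <- expected_afs[expected_afs$group == grp, , drop = FALSE]
      if (nrow(ea) == 0L) {
        warning("allele group ", grp, " absent from the expected-frequency table; ",
                "excluded", call. = FALSE)
        next
      }
      w <- ancestry_weights[ea$ancestry]
      w[is.na(w)] <- 0
      expected <- sum(w * ea$af) / sum(ancestry_weights)
      obs <- unname(counts[grp])
      p <- stats::binom.test(obs, total, p = expected,
                             alternative = "two.sided")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, gene = g, count = obs, total = total,
        observed_af = obs / total, expected_af = expected,
        excess = obs / total / expected - 1, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (g in unique(out$gene)) {
    i <- which(out$gene == g)
    out$p_adj[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out$enriched <- out$p_adj < alpha & out$excess > excess_threshold
  out[order(out$gene, out$group), , drop = FALSE]
}

#' Variance partition: protein ~ RNA (+ covariate score)
#'
#' Fits ordinary least squares of protein expression on RNA expression, and
#' on RNA plus a per-sample covariate score, and reports how much variance
#' the score adds (the R-squared comparison), the sign and size of the
#' score coefficient, and the correlation of the base-model residuals with
#' the score.
#'
#' @param protein,rna,score Numeric vectors over the same samples.
#' @return A list: \code{r2_base}, \code{r2_full}, \code{coef_score},
#'   \code{coef_score_se}, \code{residual_trend} (Pearson correlation of
#'   base residuals with the score), \code{n}, \code{collinear}.
#'   Collinear predictors flag the result and leave coefficients absent.
#' @export
variance_partition <- function(protein, rna, score) {
  ok <- stats::complete.cases(protein, rna, score)
  protein <- protein[ok]; rna <- rna[ok]; score <- score[ok]
  if (length(protein) < 3L) stop("need at least 3 complete samples", call. = FALSE)
  if (stats::sd(rna) == 0 || stats::sd(score) == 0) {
    stop("constant predictor", call. = FALSE)
  }
  fit_base <- stats::lm(protein ~ rna)
  X <- cbind(1, rna, score)
  collinear <- qr(X)$rank < 3L
  if (collinear) {
    return(list(r2_base = summary(fit_base)$r.squared, r2_full = NA_real_,
                coef_score = NA_real_, coef_score_se = NA_real_,
                residual_trend = NA_real_, n = length(protein),
                collinear = TRUE))
  }
  fit_full <- stats::lm(protein ~ rna + score)
  cf <- summary(fit_full)$coefficients
  list(r2_base = summary(fit_base)$r.squared,
       r2_full = summary(fit_full)$r.squared,
       coef_score = unname(cf["score", "Estimate"]),
       coef_score_se = unname(cf["score", "Std. Error"]),
       residual_trend = stats::cor(stats::residuals(fit_base), score),
       n = length(protein), collinear = FALSE)
}

#' Correlation with degenerate-input handling
#'
#' Pearson or Spearman correlation (average ranks for ties) with the test
#' p-value; constant input yields an undefined-correlation flag instead of
#' an error.
#'
#' @param x,y Numeric vectors (pairwise complete observations are used).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return A list: \code{estimate}, \code{p}, \code{n}, \code{defined}.
#' @export
expression_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(estimate = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}
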