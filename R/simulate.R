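AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# residue sampling weights: tryptic-site density close to real proteins
# (K + R about 11%), proline kept modest so cleavage suppression is rare
aa_weights <- function() {
  w <- rep(1, 20)
  names(w) <- AA20
  w["K"] <- 1.4; w["R"] <- 1.4; w["P"] <- 0.5
  w / sum(w)
}

# one deterministic codon per amino acid for back-translation
CODON_OF <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

back_translate <- function(protein) {
  paste(CODON_OF[strsplit(protein, "")[[1L]]], collapse = "")
}

mutate_protein <- function(protein, n_subs) {
  res <- strsplit(protein, "")[[1L]]
  pos <- sample(seq_along(res), n_subs)
  for (p in pos) {
    res[p] <- sample(setdiff(AA20, res[p]), 1L)
  }
  paste(res, collapse = "")
}

#' Simulate a homologous HLA-like allele database
#'
#' Builds, per gene, a base protein of about 365 residues and derives
#' alleles from it by amino-acid point substitutions, mirroring the
#' structure of the real HLA class I locus: alleles of one gene are nearly
#' identical (most tryptic peptides shared), genes are homologous to each
#' other (some peptides hit several genes), and each allele retains at
#' least one allele-unique tryptic peptide. Generation is retried (bounded)
#' until every allele has both a unique and a within-gene shared peptide.
#'
#' @param n_genes Number of genes (default 3: A, B, C).
#' @param alleles_per_gene Alleles per gene (default 4).
#' @param substitution_rate Per-residue substitution rate between an allele
#'   and its gene's base sequence (default 0.02).
#' @param gene_divergence Per-residue divergence between genes
#'   (default 0.05, high homology).
#' @param protein_length Base protein length (default 365 residues).
#' @param seed Integer seed; the same (seed, parameters) reproduce the
#'   database exactly.
#' @return A list: \code{db} (an [allele_db()]), \code{truth} (per-allele
#'   inventory of unique and shared tryptic peptides), \code{params}.
#' @export
make_allele_db <- function(n_genes = 3L, alleles_per_gene = 4L,
                           substitution_rate = 0.02, gene_divergence = 0.05,
                           protein_length = 365L, seed = 1L) {
  stopifnot(n_genes >= 1L, n_genes <= 3L, alleles_per_gene >= 1L)
  set.seed(seed)
  genes <- c("A", "B", "C")[seq_len(n_genes)]
  w <- aa_weights()
  for (attempt in seq_len(25L)) {
    ancestor <- paste(sample(AA20, protein_length, replace = TRUE, prob = w),
                      collapse = "")
    proteins <- character(0)
    for (g in genes) {
      base <- mutate_protein(ancestor, max(1L, round(gene_divergence * protein_length)))
      for (i in seq_len(alleles_per_gene)) {
        nm <- sprintf("%s*%02d:01", g, i)
        proteins[nm] <- mutate_protein(base,
                                       max(1L, round(substitution_rate * protein_length)))
      }
    }
    if (substitution_rate == 0) {
      # degenerate fixture: alleles of a gene are identical on purpose
      for (g in genes) {
        idx <- grep(paste0("^", g, "\\*"), names(proteins))
        proteins[idx] <- proteins[idx[1L]]
      }
    }
    peps <- lapply(proteins, digest, missed_cleavages = 0L)
    unique_peps <- lapply(seq_along(peps), function(i) {
      others <- unique(unlist(peps[-i]))
      setdiff(peps[[i]], others)
    })
    shared_within <- lapply(seq_along(peps), function(i) {
      g <- sub("\\*.*", "", names(peps)[i])
      mates <- setdiff(grep(paste0("^", g, "\\*"), names(peps)), i)
      intersect(peps[[i]], unique(unlist(peps[mates])))
    })
    names(unique_peps) <- names(shared_within) <- names(peps)
    ok <- substitution_rate == 0 ||
      (all(vapply(unique_peps, length, integer(1)) >= 1L) &&
         all(vapply(shared_within, length, integer(1)) >= 1L))
    if (ok) break
  }
  if (!ok) {
    stop("could not satisfy unique/shared peptide constraints after bounded ",
         "retries; adjust substitution_rate or alleles_per_gene", call. = FALSE)
  }
  cds <- vapply(proteins, back_translate, character(1))
  db <- allele_db(cds)
  list(db = db,
       truth = list(unique_peptides = unique_peps,
                    shared_within_gene = shared_within),
       params = list(n_genes = n_genes, alleles_per_gene = alleles_per_gene,
                     substitution_rate = substitution_rate,
                     gene_divergence = gene_divergence,
                     protein_length = protein_length, seed = seed))
}

#' Simulate a paired tumor/normal cohort of genotypes
#'
#' Normal genotypes are drawn allele-wise i.i.d. from per-gene allele
#' frequencies (so homozygosity follows Hardy-Weinberg). Tumor genotypes
#' equal the normal ones, except that with probability \code{loh_rate} a
#' heterozygous gene collapses to one uniformly chosen allele (loss of
#' heterozygosity), and otherwise with probability \code{imbalance_rate} a
#' heterozygous gene is marked for RNA allele imbalance with a recorded
#' minor/major factor. Events are mutually exclusive per gene.
#'
#' @param n_patients Number of patients.
#' @param allele_frequencies Named list (per gene) of named numeric vectors
#'   of allele frequencies summing to 1.
#' @param loh_rate,imbalance_rate Per-gene event probabilities (defaults
#'   0.05 each, inside the low prevalence seen in paired cancer cohorts).
#' @param imbalance_range Range of the injected tumor minor/major factor
#'   (default c(0.15, 0.30)).
#' @param seed Integer seed.
#' @return A list: \code{normal}, \code{tumor} (genotype tables keyed by
#'   \code{patient_id} in \code{sample_id}), and \code{truth} with one row
#'   per patient-gene: \code{event} in \{none, loh, imbalance\},
#'   \code{lost_allele}, \code{imbalance_factor}.
#' @export
make_cohort <- function(n_patients, allele_frequencies,
                        loh_rate = 0.05, imbalance_rate = 0.05,
                        imbalance_range = c(0.15, 0.30), seed = 1L) {
  stopifnot(all(vapply(allele_frequencies,
                       function(f) abs(sum(f) - 1) < 1e-8, logical(1))))
  set.seed(seed)
  pid <- sprintf("P%03d", seq_len(n_patients))
  normal <- tumor <- list()
  truth <- list()
  for (g in names(allele_frequencies)) {
    f <- allele_frequencies[[g]]
    a1 <- sample(names(f), n_patients, replace = TRUE, prob = f)
    a2 <- sample(names(f), n_patients, replace = TRUE, prob = f)
    t1 <- a1; t2 <- a2
    event <- rep("none", n_patients)
    lost <- rep(NA_character_, n_patients)
    factor_ <- rep(NA_real_, n_patients)
    u <- stats::runif(n_patients)
    for (i in seq_len(n_patients)) {
      if (a1[i] == a2[i]) next
      if (u[i] < loh_rate) {
        event[i] <- "loh"
        keep <- sample(c(a1[i], a2[i]), 1L)
        lost[i] <- setdiff(c(a1[i], a2[i]), keep)
        t1[i] <- t2[i] <- keep
      } else if (u[i] < loh_rate + imbalance_rate) {
        event[i] <- "imbalance"
        factor_[i] <- stats::runif(1L, imbalance_range[1L], imbalance_range[2L])
      }
    }
    normal[[g]] <- genotype_table(pid, g, a1, a2)
    tumor[[g]] <- genotype_table(pid, g, t1, t2)
    truth[[g]] <- data.frame(patient_id = pid, gene = g, event = event,
                             lost_allele = lost, imbalance_factor = factor_,
                             stringsAsFactors = FALSE)
  }
  list(normal = do.call(rbind, normal), tumor = do.call(rbind, tumor),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       params = list(n_patients = n_patients, loh_rate = loh_rate,
                     imbalance_rate = imbalance_rate,
                     imbalance_range = imbalance_range, seed = seed))
}

#' Simulate allele-level RNA counts (and optionally reads) for a cohort
#'
#' Expected per-gene counts are \code{depth}, scaled in tumor samples by an
#' injected per-patient log2 fold change; within a gene the two alleles
#' split the expectation evenly, except that injected imbalance multiplies
#' the minor allele of the tumor by the recorded factor and loss of
#' heterozygosity puts everything on the retained allele. Counts are
#' negative binomial at the given dispersion (a dispersion of 0 collapses
#' to the rounded expectation -- the deterministic noiseless limit).
#'
#' @param cohort A [make_cohort()] result.
#' @param db An [allele_db()] (used for read simulation).
#' @param depth Expected reads per gene in a normal sample (default 1000).
#' @param dispersion Negative-binomial dispersion (default 0.05).
#' @param tumor_log2fc Function of n returning injected per-patient-gene
#'   tumor log2 fold changes, or a single number recycled; default 0.
#' @param emit_reads Also simulate reads from the allele coding sequences.
#' @param read_length,error_rate Read simulation parameters.
#' @param seed Integer seed.
#' @return A list: \code{counts} (allele x sample matrix; sample columns are
#'   \code{<patient>-T} and \code{<patient>-N}), \code{truth} (expected
#'   allele counts and injected fold changes), optionally \code{reads}
#'   (named list of read vectors per sample per gene).
#' @export
make_rna <- function(cohort, db, depth = 1000, dispersion = 0.05,
                     tumor_log2fc = 0, emit_reads = FALSE,
                     read_length = 75L, error_rate = 0, seed = 1L) {
  set.seed(seed)
  genos <- rbind(cbind(cohort$tumor, tissue = "T"),
                 cbind(cohort$normal, tissue = "N"))
  genos$column <- paste0(genos$sample_id, "-", genos$tissue)
  patients <- unique(cohort$normal$sample_id)
  genes <- unique(cohort$normal$gene)
  lfc <- if (is.function(tumor_log2fc)) {
    matrix(tumor_log2fc(length(patients) * length(genes)),
           nrow = length(patients), dimnames = list(patients, genes))
  } else {
    matrix(tumor_log2fc, nrow = length(patients), ncol = length(genes),
           dimnames = list(patients, genes))
  }
  samples <- unique(genos$column)
  counts <- matrix(0, nrow = length(db$name), ncol = length(samples),
                   dimnames = list(db$two_field, samples))
  truth_rows <- list()
  reads <- if (emit_reads) stats::setNames(vector("list", length(samples)), samples)
  for (r in seq_len(nrow(genos))) {
    g <- genos[r, ]
    tr <- cohort$truth[cohort$truth$patient_id == g$sample_id &
                         cohort$truth$gene == g$gene, ]
    gene_mu <- depth * if (g$tissue == "T") 2^lfc[g$sample_id, g$gene] else 1
    if (g$homozygous) {
      mu <- stats::setNames(gene_mu, g$allele1)
    } else {
      split_ <- c(0.5, 0.5)
      if (g$tissue == "T" && tr$event == "imbalance") {
        f <- tr$imbalance_factor
        split_ <- c(1, f) / (1 + f)  # allele2 is the injected minor allele
      }
      mu <- stats::setNames(gene_mu * split_, c(g$allele1, g$allele2))
    }
    obs <- if (dispersion <= 0) round(mu) else {
      stats::setNames(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                      names(mu))
    }
    counts[names(obs), g$column] <- obs
    truth_rows[[r]] <- data.frame(
      patient_id = g$sample_id, tissue = g$tissue, gene = g$gene,
      allele = names(mu), expected = unname(mu), observed = unname(obs),
      log2fc = if (g$tissue == "T") lfc[g$sample_id, g$gene] else 0,
      stringsAsFactors = FALSE)
    if (emit_reads) {
      gene_reads <- character(0)
      for (a in names(obs)) {
        idx <- db_lookup(db, a)
        gene_reads <- c(gene_reads,
                        simulate_reads(db$cds[idx[1L]], obs[[a]], read_length,
                                       error_rate))
      }
      reads[[g$column]][[g$gene]] <- gene_reads
    }
  }
  out <- list(counts = counts,
              truth = do.call(rbind, c(truth_rows, list(make.row.names = FALSE))),
              params = list(depth = depth, dispersion = dispersion,
                            read_length = read_length, error_rate = error_rate,
                            seed = seed))
  if (emit_reads) out$reads <- reads
  out
}

#' Simulate reads from a coding sequence
#'
#' Uniform start positions, uniform substitution errors. Uses the current
#' RNG stream; seed management belongs to the caller.
#'
#' @param cds Single coding sequence.
#' @param n Number of reads.
#' @param read_length Read length (trimmed to the sequence if longer).
#' @param error_rate Per-base substitution probability.
#' @return Character vector of reads.
#' @export
simulate_reads <- function(cds, n, read_length = 75L, error_rate = 0) {
  L <- nchar(cds)
  rl <- min(read_length, L)
  if (n < 1L) return(character(0))
  starts <- sample.int(L - rl + 1L, n, replace = TRUE)
  reads <- substring(cds, starts, starts + rl - 1L)
  if (error_rate > 0) {
    for (i in seq_len(n)) {
      hit <- which(stats::runif(rl) < error_rate)
      if (length(hit) > 0L) {
        r <- strsplit(reads[i], "")[[1L]]
        for (p in hit) r[p] <- sample(setdiff(c("A", "C", "G", "T"), r[p]), 1L)
        reads[i] <- paste(r, collapse = "")
      }
    }
  }
  reads
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of reads.
#' @param path Output path.
#' @param id_prefix Read id prefix.
#' @export
write_fastq <- function(reads, path, id_prefix = "read") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(paste0("@", id_prefix, i), reads[i], "+",
                 strrep("I", nchar(reads[i]))), con)
  }
  invisible(path)
}

TMT11_CHANNELS <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                    "130N", "130C", "131N", "131C")

#' Simulate TMT PSM tables with a pooled reference channel
#'
#' Assigns samples to TMT plexes (the last channel of each plex carries the
#' pooled reference, a mixture of the plex members), digests the alleles
#' carried by the plex members, and emits PSM rows for each peptide that is
#' detected in the plex. Detection is per (peptide, plex) -- isobaric
#' identification is plex-level, so a peptide carried by one member is
#' quantified in every channel. Reporter intensities are proportional to
#' the per-sample true abundance of the alleles containing the peptide,
#' plus a small co-isolation background (so peptides absent from a sample
#' still show compressed, nonzero signal, as in real TMT data), with
#' log-normal noise of the given coefficient of variation. Each detected
#' peptide is split over 1--3 PSMs with random charges and fractions; true
#' PSMs draw expectation values strictly below 0.001, decoys at or above it.
#'
#' @param cohort A [make_cohort()] result.
#' @param db The [make_allele_db()] database the cohort was drawn from.
#' @param gene_log2fc Injected tumor protein log2 fold change: a single
#'   number, or a matrix patients x genes (default 0).
#' @param plex_size Channels per plex, 10 or 11 (default 11).
#' @param detect_prob Per-(peptide, plex) detection probability (default 0.7).
#' @param intensity_cv Log-normal intensity coefficient of variation
#'   (default 0.2).
#' @param base_abundance Linear abundance of one allele dose in a normal
#'   sample (default 1000).
#' @param background Co-isolation background intensity as a fraction of
#'   \code{base_abundance} (default 0.02).
#' @param decoy_fraction Fraction of additional decoy PSM rows with
#'   expectation values at or above 0.001 (default 0).
#' @param n_background Number of constant-abundance non-HLA background
#'   proteins (default 30). Their peptides anchor the per-sample median
#'   centering, as the bulk proteome does in a real study.
#' @param seed Integer seed.
#' @return A list: \code{psms} (PSM data frame, [read_psm_table()] layout),
#'   \code{design} (plex design data frame),
#'   \code{background_proteome} (named character vector, for the search
#'   database), \code{truth} (per sample and allele true abundance; per
#'   peptide detectability).
#' @export
make_psm_tables <- function(cohort, db, gene_log2fc = 0, plex_size = 11L,
                            detect_prob = 0.7, intensity_cv = 0.2,
                            base_abundance = 1000, background = 0.02,
                            decoy_fraction = 0, n_background = 30L, seed = 1L) {
  stopifnot(plex_size %in% c(10L, 11L))
  set.seed(seed)
  genos <- rbind(cbind(cohort$tumor, tissue = "T"),
                 cbind(cohort$normal, tissue = "N"))
  genos$column <- paste0(genos$sample_id, "-", genos$tissue)
  samples <- sort(unique(genos$column))
  patients <- unique(cohort$normal$sample_id)
  genes <- unique(cohort$normal$gene)
  if (is.matrix(gene_log2fc)) {
    lfc <- gene_log2fc
  } else {
    lfc <- matrix(gene_log2fc, nrow = length(patients), ncol = length(genes),
                  dimnames = list(patients, genes))
  }
  # true linear abundance per sample x allele (dose x gene fold change)
  abund <- matrix(0, nrow = length(samples), ncol = length(db$name),
                  dimnames = list(samples, db$two_field))
  for (r in seq_len(nrow(genos))) {
    g <- genos[r, ]
    fold <- if (g$tissue == "T") 2^lfc[g$sample_id, g$gene] else 1
    tr <- cohort$truth[cohort$truth$patient_id == g$sample_id &
                         cohort$truth$gene == g$gene, ]
    if (g$homozygous) {
      abund[g$column, g$allele1] <- base_abundance * fold
    } else if (g$tissue == "T" && tr$event == "imbalance") {
      f <- tr$imbalance_factor
      abund[g$column, g$allele1] <- base_abundance * fold / (1 + f) * 1
      abund[g$column, g$allele2] <- base_abundance * fold / (1 + f) * f
    } else {
      abund[g$column, c(g$allele1, g$allele2)] <- base_abundance * fold / 2
    }
  }
  # constant-abundance background proteome (anchors median centering)
  w <- aa_weights()
  bg <- vapply(seq_len(n_background), function(i) {
    paste(sample(AA20, 300L, replace = TRUE, prob = w), collapse = "")
  }, character(1))
  names(bg) <- sprintf("BG%03d", seq_len(n_background))
  bg_pep_sets <- lapply(bg, digest, missed_cleavages = 0L)
  if (n_background > 0L) {
    bg_abund <- matrix(base_abundance, nrow = length(samples), ncol = n_background,
                       dimnames = list(samples, names(bg)))
    abund <- cbind(abund, bg_abund)
  }
  channels <- TMT11_CHANNELS[seq_len(plex_size)]
  members_per_plex <- plex_size - 1L
  n_plex <- ceiling(length(samples) / members_per_plex)
  design <- list()
  psm_rows <- list()
  peptide_detect <- list()
  scan_counter <- 0L
  pep_sets <- c(lapply(db$protein, digest, missed_cleavages = 0L), bg_pep_sets)
  names(pep_sets) <- c(db$two_field, names(bg))
  for (px in seq_len(n_plex)) {
    plex_id <- sprintf("plex%02d", px)
    members <- samples[((px - 1L) * members_per_plex + 1L):
                         min(px * members_per_plex, length(samples))]
    design[[px]] <- data.frame(
      plex_id = plex_id,
      channel = c(channels[seq_along(members)], channels[plex_size]),
      sample_id = c(members, "pooled_reference"),
      is_reference = c(rep(FALSE, length(members)), TRUE),
      stringsAsFactors = FALSE)
    # peptide universe of the plex: peptides of alleles carried by members
    present <- colnames(abund)[colSums(abund[members, , drop = FALSE]) > 0]
    universe <- sort(unique(unlist(pep_sets[match(present, names(pep_sets))])))
    detected <- stats::runif(length(universe)) < detect_prob
    peptide_detect[[px]] <- data.frame(plex_id = plex_id, peptide = universe,
                                       detected = detected,
                                       stringsAsFactors = FALSE)
    for (pep in universe[detected]) {
      carriers <- names(pep_sets)[vapply(pep_sets, function(s) pep %in% s,
                                         logical(1))]
      true_member <- rowSums(abund[members, carriers, drop = FALSE]) +
        background * base_abundance
      true_ref <- mean(true_member)
      true_all <- c(true_member, true_ref)
      noisy <- if (intensity_cv > 0) {
        sdlog <- sqrt(log(1 + intensity_cv^2))
        true_all * stats::rlnorm(length(true_all), -sdlog^2 / 2, sdlog)
      } else {
        true_all
      }
      n_psm <- sample.int(3L, 1L)
      prop <- stats::runif(n_psm)
      prop <- prop / sum(prop)
      for (j in seq_len(n_psm)) {
        scan_counter <- scan_counter + 1L
        row <- data.frame(peptide = pep, plex_id = plex_id,
                          fraction = sample.int(24L, 1L),
                          charge = sample(2:4, 1L),
                          scan = scan_counter,
                          expectation = stats::runif(1L, 1e-6, 9e-4),
                          stringsAsFactors = FALSE)
        ints <- noisy * prop[j]
        chan_of <- c(channels[seq_along(members)], channels[plex_size])
        for (ci in seq_len(plex_size)) row[[channels[ci]]] <- 0
        for (ci in seq_along(ints)) row[[chan_of[ci]]] <- unname(ints[ci])
        psm_rows[[length(psm_rows) + 1L]] <- row
      }
    }
  }
  psms <- do.call(rbind, psm_rows)
  if (decoy_fraction > 0 && nrow(psms) > 0L) {
    n_decoy <- ceiling(decoy_fraction * nrow(psms))
    idx <- sample.int(nrow(psms), n_decoy, replace = TRUE)
    decoys <- psms[idx, , drop = FALSE]
    decoys$expectation <- stats::runif(n_decoy, 0.001, 0.05)
    decoys$scan <- scan_counter + seq_len(n_decoy)
    psms <- rbind(psms, decoys)
  }
  rownames(psms) <- NULL
  attr(psms, "channels") <- channels
  list(psms = psms, design = do.call(rbind, design),
       background_proteome = bg,
       truth = list(abundance = abund,
                    detection = do.call(rbind, peptide_detect)),
       params = list(plex_size = plex_size, detect_prob = detect_prob,
                     intensity_cv = intensity_cv,
                     base_abundance = base_abundance, background = background,
                     decoy_fraction = decoy_fraction, seed = seed))
}
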