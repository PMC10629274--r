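test_that("tryptic digestion matches worked cleavage examples", {
  expect_equal(digest("AKRPGK", 0, min_len = 1), sort(c("AK", "RPGK")))
  expect_equal(digest("MKAKR", 1, min_len = 1),
               sort(c("MK", "AK", "R", "MKAK", "AKR")))
  # no cleavage site: the whole sequence if within bounds
  expect_equal(digest("MAGICSEQ", 0), "MAGICSEQ")
  expect_equal(digest("MAG", 0), character(0))
  expect_error(digest("MAXK", 0), "invalid residue")
  expect_error(digest("MAXK", 0), "position 3")
})

test_that("digestion equals the brute-force substring oracle on random sequences", {
  set.seed(6)
  for (i in 1:40) {
    prot <- random_protein(sample(10:60, 1))
    mc <- sample(0:2, 1)
    mn <- sample(c(1, 5, 7), 1)
    expect_equal(digest(prot, mc, min_len = mn, max_len = 40),
                 digest_oracle(prot, mc, min_len = mn, max_len = 40),
                 info = paste("seq:", prot, "mc:", mc, "min:", mn))
  }
})

test_that("PSM filtering applies strict expectation cutoff and reporter presence", {
  psms <- data.frame(peptide = c("AAAAAAK", "CCCCCCK", "DDDDDDK", "EEEEEEK"),
                     plex_id = "plex01", fraction = 1, charge = 2, scan = 1:4,
                     expectation = c(0.0005, 0.001, 0.0009, 0.0001),
                     `126` = c(100, 100, 0, 0),
                     `127N` = c(50, 50, 0, NA),
                     check.names = FALSE)
  attr(psms, "channels") <- c("126", "127N")
  kept <- filter_psms(psms)
  # 0.001 is dropped at the strict boundary; all-zero reporters are dropped
  expect_equal(kept$peptide, "AAAAAAK")
  # order preserved on a larger keep set
  psms$expectation <- c(1e-5, 2e-5, 3e-5, 0.5)
  psms$`126` <- c(1, 2, 3, 4)
  expect_equal(filter_psms(psms)$peptide, c("AAAAAAK", "CCCCCCK", "DDDDDDK"))
})

test_that("peptide specificity classes follow the discard rules", {
  sdb <- tiny_search_db(standard = c("STD1 gene=GAPDH" = "MSSSSSPKGGGK"))
  spec <- classify_specificity(
    c(PEP_A_SHARED, PEP_A1_UNIQ, PEP_MULTIGENE, PEP_CONTAM, "SSSSSPK"), sdb)
  expect_equal(spec$class[spec$peptide == PEP_A_SHARED], "hla_gene_specific")
  expect_equal(spec$hla_gene[spec$peptide == PEP_A_SHARED], "HLA-A")
  expect_equal(spec$class[spec$peptide == PEP_A1_UNIQ], "hla_gene_specific")
  expect_equal(spec$class[spec$peptide == PEP_MULTIGENE], "discard_multi_hla_gene")
  expect_equal(spec$class[spec$peptide == PEP_CONTAM], "discard_nonhla_overlap")
  expect_equal(spec$class[spec$peptide == "SSSSSPK"], "non_hla")
  expect_setequal(spec$hit_hla_alleles[spec$peptide == PEP_A_SHARED][[1]],
                  c("A*01:01", "A*02:01", "A*03:01"))
})

test_that("adding database records never rescues a discarded peptide", {
  base <- tiny_search_db()
  bigger <- tiny_search_db(standard = c("EXTRA gene=EXTRA" = "MWWWWWWKPPPPPPK"))
  for (pep in c(PEP_A_SHARED, PEP_MULTIGENE, PEP_CONTAM, PEP_A1_UNIQ)) {
    c1 <- classify_specificity(pep, base)$class
    c2 <- classify_specificity(pep, bigger)$class
    if (c1 != "hla_gene_specific") expect_false(c2 == "hla_gene_specific")
  }
})

test_that("isoleucine/leucine handling is exact by default, collapsible on request", {
  # peptide differing from a database leucine run only by I
  sdb <- tiny_search_db()
  pep_il <- sub("L", "I", PEP_MULTIGENE)  # one L -> I
  expect_equal(classify_specificity(pep_il, sdb)$class, "unmapped")
  expect_equal(classify_specificity(pep_il, sdb, il_equivalent = TRUE)$class,
               "discard_multi_hla_gene")
})

test_that("genotype matching resolves allele-specific and shared peptides", {
  db <- tiny_db()
  het <- genotype_table("s", "A", "A*01:01", "A*02:01")
  m <- match_to_genotype(PEP_A1_UNIQ, het, db)
  expect_true(m$genotype_matched)
  expect_equal(m$allele_resolution, "allele_specific")
  expect_equal(m$allele, "A*01:01")
  m <- match_to_genotype(PEP_A_SHARED, het, db)
  expect_equal(m$allele_resolution, "allele_shared")
  expect_true(is.na(m$allele))
  # peptide from an allele the sample does not carry
  m <- match_to_genotype(PEP_A3_UNIQ, het, db)
  expect_false(m$genotype_matched)
  expect_equal(m$allele_resolution, "unmatched")
  # homozygous samples have no allele-specific peptides
  hom <- genotype_table("s", "A", "A*01:01", "A*01:01")
  expect_equal(match_to_genotype(PEP_A1_UNIQ, hom, db)$allele_resolution,
               "allele_shared")
  expect_error(match_to_genotype(PEP_A1_UNIQ,
                                 genotype_table("s", "C", "C*09:09", "C*09:09"),
                                 db),
               "missing from database")
})

psm_fixture <- function() {
  psms <- data.frame(
    peptide = c(PEP_A1_UNIQ, PEP_A1_UNIQ, PEP_A_SHARED),
    plex_id = "plex01", fraction = c(1, 2, 1), charge = c(2, 3, 2),
    scan = 1:3, expectation = 1e-4,
    `126` = c(100, 50, 300), `127N` = c(40, 20, 120), `131C` = c(50, 25, 100),
    check.names = FALSE)
  attr(psms, "channels") <- c("126", "127N", "131C")
  psms
}

psm_design <- function() {
  data.frame(plex_id = "plex01", channel = c("126", "127N", "131C"),
             sample_id = c("s1", "s2", "pooled_reference"),
             is_reference = c(FALSE, FALSE, TRUE))
}

test_that("reporter aggregation sums over scans, charges and fractions", {
  agg <- aggregate_peptides(psm_fixture(), psm_design())
  a1 <- agg[agg$peptide == PEP_A1_UNIQ, ]
  expect_equal(a1$intensity[a1$channel == "126"], 150)
  expect_equal(a1$intensity[a1$channel == "127N"], 60)
  sh <- agg[agg$peptide == PEP_A_SHARED, ]
  expect_equal(sh$intensity[sh$channel == "126"], 300)
  bad <- psm_fixture()
  bad$plex_id <- "plexXX"
  expect_error(aggregate_peptides(bad, psm_design()), "unknown plex")
})

test_that("peptide ratios to the pooled reference are centered per sample", {
  agg <- aggregate_peptides(psm_fixture(), psm_design())
  ratios <- peptide_log_ratio(agg, psm_design())
  raw <- ratios$log2_ratio_raw[ratios$sample_id == "s1"]
  # s1: 150/75 = 2x and 300/100 = 3x before centering
  expect_setequal(round(raw, 10), round(log2(c(2, 3)), 10))
  # per-sample median of centered ratios is exactly zero
  meds <- tapply(ratios$log2_ratio, ratios$sample_id, median)
  expect_equal(as.vector(meds), c(0, 0))
  # degenerate reference
  agg$intensity[agg$channel == "131C"] <- 0
  expect_error(peptide_log_ratio(agg, psm_design()), "zero reference")
  bad_design <- psm_design()
  bad_design$is_reference <- FALSE
  expect_error(peptide_log_ratio(agg, bad_design), "reference channel")
})

test_that("protein abundance sums genotype-matched peptides and reports peptide counts", {
  sdb <- tiny_search_db()
  agg <- aggregate_peptides(psm_fixture(), psm_design())
  genos <- rbind(genotype_table("s1", "A", "A*01:01", "A*02:01"),
                 genotype_table("s2", "A", "A*03:01", "A*03:01"))
  spec <- classify_specificity(unique(agg$peptide), sdb)
  quant <- protein_abundance(agg, psm_design(), spec, genos, tiny_db(),
                             mode = "hla_gene")
  # s1 carries A*01:01: both peptides match; sums 150+300 vs reference 75+100
  s1 <- quant[quant$sample_id == "s1", ]
  expect_equal(s1$log2_ratio, log2(450 / 175))
  expect_equal(s1$n_peptides, 2)
  # s2 is homozygous A*03:01: only the gene-shared peptide matches
  s2 <- quant[quant$sample_id == "s2", ]
  expect_equal(s2$log2_ratio, log2(120 / 100))
  expect_equal(s2$n_peptides, 1)

  # allele mode: only allele-specific peptides; homozygous s2 has no rows
  aq <- protein_abundance(agg, psm_design(), spec, genos, tiny_db(),
                          mode = "hla_allele")
  expect_equal(aq$sample_id, "s1")
  expect_equal(aq$feature, "A*01:01")
  expect_equal(aq$log2_ratio, log2(150 / 75))
  expect_equal(aq$n_peptides, 1)

  # whole-proteome mode uses gene-unique peptides (multi-gene peptides drop)
  wq <- protein_abundance(agg, psm_design(), spec, mode = "whole_proteome_gene")
  expect_true(all(wq$feature == "HLA-A"))
})

test_that("matched vs unmatched statistics recover an injected boost", {
  # exact constant shift: difference c, zero variance handled as p = 0
  samples <- paste0("s", 1:6)
  ratios <- data.frame(
    sample_id = rep(samples, each = 4),
    peptide = rep(c("m1", "m2", "u1", "u2"), 6),
    plex_id = "p1",
    log2_ratio = rep(c(1.5, 1.5, 0, 0), 6))
  matched <- data.frame(sample_id = rep(samples, each = 4),
                        peptide = rep(c("m1", "m2", "u1", "u2"), 6),
                        genotype_matched = rep(c(TRUE, TRUE, FALSE, FALSE), 6))
  st <- matched_vs_unmatched_stats(ratios, matched)
  expect_equal(st$mean_difference, 1.5)
  expect_equal(st$p, 0)
  # identical medians: no evidence
  ratios$log2_ratio <- 0
  expect_equal(matched_vs_unmatched_stats(ratios, matched)$p, 1)
  # fewer than two usable pairs: flagged, not an error
  st <- matched_vs_unmatched_stats(ratios[1:4, ], matched[1:4, ])
  expect_false(st$computable)

  # noisy boost: estimate within 2 SE of truth, p-value against the t oracle
  set.seed(17)
  delta <- 0.8
  n <- 12
  m_med <- delta + rnorm(n, 0, 0.2)
  u_med <- rnorm(n, 0, 0.2)
  ratios2 <- data.frame(
    sample_id = rep(paste0("t", 1:n), each = 2),
    peptide = rep(c("m1", "u1"), n),
    log2_ratio = as.vector(rbind(m_med, u_med)))
  matched2 <- data.frame(sample_id = rep(paste0("t", 1:n), each = 2),
                         peptide = rep(c("m1", "u1"), n),
                         genotype_matched = rep(c(TRUE, FALSE), n))
  st <- matched_vs_unmatched_stats(ratios2, matched2)
  expect_lt(abs(st$mean_difference - delta), 2 * st$se)
  oracle <- t.test(m_med, u_med, paired = TRUE)
  expect_equal(st$p, oracle$p.value)
  expect_equal(st$mean_difference, unname(oracle$estimate))
})
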