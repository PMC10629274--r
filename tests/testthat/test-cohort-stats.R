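test_that("homozygosity rates count identical pairs per stratum", {
  gt <- rbind(
    genotype_table(paste0("s", 1:10), "A",
                   c(rep("A*01:01", 3), rep("A*02:01", 7)),
                   c(rep("A*01:01", 3), rep("A*03:01", 7))),
    genotype_table(paste0("s", 1:4), "B",
                   rep("B*07:02", 4), paste0("B*0", c(7, 8, 8, 8), ":02")))
  rates <- homozygosity_rates(gt)
  expect_equal(rates$rate[rates$gene == "A"], 0.3)
  expect_equal(rates$n[rates$gene == "A"], 10)
  expect_equal(rates$rate[rates$gene == "B"], 0.25)
  all_het <- genotype_table(paste0("s", 1:5), "C", rep("C*01:02", 5),
                            rep("C*02:02", 5))
  expect_equal(homozygosity_rates(all_het)$rate, 0)
})

test_that("simulated cohorts reach Hardy-Weinberg homozygosity", {
  freqs <- list(A = c("A*01:01" = 0.5, "A*02:01" = 0.5),
                B = c("B*01:01" = 0.7, "B*02:01" = 0.2, "B*03:01" = 0.1))
  cohort <- make_cohort(800, freqs, loh_rate = 0, imbalance_rate = 0, seed = 19)
  rates <- homozygosity_rates(cohort$normal)
  for (g in names(freqs)) {
    expected <- sum(freqs[[g]]^2)
    se <- sqrt(expected * (1 - expected) / 800)
    expect_lt(abs(rates$rate[rates$gene == g] - expected), 3 * se)
  }
})

test_that("per-patient paired tests match the t-test oracle and flag directions", {
  tumor <- data.frame(patient_id = "p1", gene = "A",
                      log2_ratio = c(2.0, 2.1, 1.9))
  normal <- data.frame(patient_id = "p1", gene = "A",
                       log2_ratio = c(0.0, 0.1, -0.1))
  res <- paired_differential(tumor, normal)
  expect_equal(res$log2fc, 2.0)
  oracle <- t.test(tumor$log2_ratio, normal$log2_ratio)
  expect_equal(res$p, oracle$p.value)
  expect_lt(res$p, 1e-3)
  expect_equal(res$direction, "over")
  # identical tumor and normal peptide populations: fold change 0, ns
  res0 <- paired_differential(
    data.frame(patient_id = "p", gene = "A", log2_ratio = c(1, 2, 3)),
    data.frame(patient_id = "p", gene = "A", log2_ratio = c(1, 2, 3)))
  expect_equal(res0$log2fc, 0)
  expect_equal(res0$direction, "ns")
  # too few peptides: not computable, no exception
  res1 <- paired_differential(
    data.frame(patient_id = "p", gene = "A", log2_ratio = 1),
    data.frame(patient_id = "p", gene = "A", log2_ratio = c(0, 0.2)))
  expect_false(res1$computable)
  expect_equal(res1$direction, "ns")
})

test_that("BH adjustment matches the step-up oracle and is monotone", {
  # direct check of the adjustment used across patients within a gene
  p <- c(0.01, 0.02, 0.04)
  expect_equal(p.adjust(p, "BH"), c(0.03, 0.03, 0.04))
  tumor <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(patient_id = paste0("p", i), gene = "A",
               log2_ratio = c(1, 1.1, 0.9) * i / 10)
  }))
  normal <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(patient_id = paste0("p", i), gene = "A",
               log2_ratio = c(0, 0.1, -0.1))
  }))
  res <- paired_differential(tumor, normal)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(all(res$p_adj >= res$p))
  expect_equal(order(res$p), order(res$p_adj))
})

test_that("allele fold-change flags and the three-peptide rule apply", {
  tq <- data.frame(sample_id = c("p1", "p1", "p2", "p3"),
                   feature = c("A*01:01", "A*02:01", "A*01:01", "A*01:01"),
                   log2_ratio = c(log2(1.35), log2(1.10), log2(2), log2(1.5)),
                   n_peptides = c(5, 4, 3, 3))
  nq <- data.frame(sample_id = c("p1", "p1", "p2", "p3"),
                   feature = c("A*01:01", "A*02:01", "A*01:01", "A*01:01"),
                   log2_ratio = 0,
                   n_peptides = c(4, 3, 2, 3))
  fc <- allele_fold_changes(tq, nq, significant = c("p1", "p2"))
  # p2 fails the >= 3 peptide rule in normal; p3 is not significant
  expect_setequal(paste(fc$patient_id, fc$allele),
                  c("p1 A*01:01", "p1 A*02:01"))
  expect_true(fc$flag20[fc$allele == "A*01:01"])
  expect_true(fc$flag30[fc$allele == "A*01:01"])
  expect_false(fc$flag20[fc$allele == "A*02:01"])
  expect_false(fc$flag30[fc$allele == "A*02:01"])
})

test_that("frequency enrichment reproduces the printed excess and the binomial oracle", {
  # the published LUAD B*15 pair: observed 18.9% vs expected 10.74% is a
  # 76% excess
  expect_equal(round(0.189 / 0.1074 - 1, 2), 0.76)

  gt <- genotype_table(paste0("s", 1:100), "B",
                       c(rep("B*15:01", 20), rep("B*07:02", 80)),
                       c(rep("B*15:01", 20), rep("B*40:01", 80)))
  expected <- data.frame(group = c("B*15", "B*07", "B*40"),
                         ancestry = "EUR", af = c(0.10, 0.45, 0.43))
  enr <- allele_frequency_enrichment(gt, expected,
                                     ancestry_weights = c(EUR = 1))
  b15 <- enr[enr$group == "B*15", ]
  expect_equal(b15$count, 40)
  expect_equal(b15$observed_af, 0.2)
  expect_equal(b15$excess, 1)
  # two-sided exact binomial oracle by enumeration of outcome probabilities
  n <- 200; p0 <- 0.10
  dens <- dbinom(0:n, n, p0)
  p_oracle <- sum(dens[dens <= dbinom(40, n, p0) * (1 + 1e-7)])
  expect_equal(b15$p, p_oracle, tolerance = 1e-10)
  expect_equal(enr$p_adj, p.adjust(enr$p, "BH"))
  expect_true(b15$enriched)
  # observed equal to expected: excess 0, never enriched
  gt2 <- genotype_table(paste0("s", 1:10), "B", rep("B*07:02", 10),
                        rep("B*40:01", 10))
  expected2 <- data.frame(group = c("B*07", "B*40"), ancestry = "EUR",
                          af = c(0.5, 0.5))
  enr2 <- allele_frequency_enrichment(gt2, expected2, c(EUR = 1))
  expect_equal(enr2$excess, c(0, 0))
  expect_false(any(enr2$enriched))
  # unknown group excluded with a warning
  expect_warning(
    allele_frequency_enrichment(gt, expected[-1, ], c(EUR = 1)),
    "absent from the expected-frequency table")
})

test_that("ancestry weighting averages expected frequencies", {
  gt <- genotype_table(paste0("s", 1:10), "A", rep("A*01:01", 10),
                       rep("A*01:01", 10))
  expected <- data.frame(group = c("A*01", "A*01"), ancestry = c("EUR", "AFR"),
                         af = c(0.2, 0.4))
  enr <- allele_frequency_enrichment(gt, expected,
                                     ancestry_weights = c(EUR = 0.75, AFR = 0.25))
  expect_equal(enr$expected_af, 0.75 * 0.2 + 0.25 * 0.4)
})

test_that("variance partition separates RNA and covariate contributions", {
  set.seed(23)
  n <- 200
  rna <- rnorm(n)
  score <- rnorm(n)
  # null covariate adds (almost) nothing
  protein <- rna + rnorm(n, 0, 0.5)
  vp <- variance_partition(protein, rna, score)
  expect_lt(vp$r2_full - vp$r2_base, 0.02)
  # exact linear identity (lm warns about the perfect fit, as expected)
  vp2 <- suppressWarnings(variance_partition(rna - score, rna, score))
  expect_equal(vp2$r2_full, 1)
  expect_equal(vp2$coef_score, -1)
  # collinear predictors flagged
  vp3 <- variance_partition(protein, rna, 2 * rna)
  expect_true(vp3$collinear)
  expect_true(is.na(vp3$coef_score))
  expect_error(variance_partition(protein, rep(1, n), score), "constant")
  # injected effect recovered within 2 SE in most replicates
  hits <- 0
  beta <- -0.6
  set.seed(29)
  for (r in 1:40) {
    rna_r <- rnorm(60); score_r <- rnorm(60)
    prot_r <- 0.8 * rna_r + beta * score_r + rnorm(60, 0, 0.4)
    vpr <- variance_partition(prot_r, rna_r, score_r)
    if (abs(vpr$coef_score - beta) <= 2 * vpr$coef_score_se) hits <- hits + 1
    expect_gt(vpr$r2_full, vpr$r2_base)
  }
  expect_gte(hits / 40, 0.9)
})

test_that("correlations agree with the reference implementation and handle ties", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4, 2.2)
  y <- c(0.9, 2.8, 2.5, 4.9, 4.0, 2.4)
  pc <- expression_correlation(x, y, "pearson")
  expect_equal(pc$estimate, cor(x, y), tolerance = 1e-12)
  sc <- expression_correlation(x, y, "spearman")
  expect_equal(sc$estimate, cor(x, y, method = "spearman"), tolerance = 1e-12)
  # monotone transform: spearman 1, pearson below 1
  z <- exp(seq(0.5, 3, length.out = 10))
  expect_equal(expression_correlation(seq_along(z), z, "spearman")$estimate, 1)
  expect_lt(expression_correlation(seq_along(z), z, "pearson")$estimate, 1)
  expect_equal(expression_correlation(1:5, 2 * (1:5) + 1, "pearson")$estimate, 1)
  expect_false(expression_correlation(rep(1, 5), 1:5)$defined)
})
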