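# Handcrafted sequence fixtures with fully known tryptic structure.
# Proteins are concatenations of designed peptides, each ending in K and
# containing no internal K/R, so a zero-missed-cleavage digest returns
# exactly the designed peptide set.

codon_table <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                 G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                 M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                 S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

encode_cds <- function(protein) {
  paste(codon_table[strsplit(protein, "")[[1L]]], collapse = "")
}

# peptide building blocks
PEP_A_SHARED  <- "GGGGGGAK"   # in both A alleles only
PEP_A1_UNIQ   <- "VVVVVTK"    # unique to A*01:01
PEP_A2_UNIQ   <- "YYYYYTK"    # unique to A*02:01
PEP_A3_UNIQ   <- "CCCCCHK"    # unique to A*03:01 (not in default genotypes)
PEP_MULTIGENE <- "LLLLLLGK"   # in gene A and gene B alleles
PEP_CONTAM    <- "MMMMMMK"    # in A*01:01 and in a contaminant keratin
PEP_B_SHARED  <- "QQQQQQSK"   # in both B alleles only
PEP_B1_UNIQ   <- "FFFFFDK"    # unique to B*01:01
PEP_B2_UNIQ   <- "HHHHHDK"    # unique to B*02:01

tiny_proteins <- function() {
  c("A*01:01" = paste0(PEP_A1_UNIQ, PEP_A_SHARED, PEP_MULTIGENE, PEP_CONTAM),
    "A*02:01" = paste0(PEP_A2_UNIQ, PEP_A_SHARED, PEP_MULTIGENE),
    "A*03:01" = paste0(PEP_A3_UNIQ, PEP_A_SHARED),
    "B*01:01" = paste0(PEP_B1_UNIQ, PEP_B_SHARED, PEP_MULTIGENE),
    "B*02:01" = paste0(PEP_B2_UNIQ, PEP_B_SHARED, PEP_MULTIGENE))
}

tiny_db <- function() {
  prot <- tiny_proteins()
  allele_db(vapply(prot, encode_cds, character(1)))
}

tiny_contaminants <- function() {
  c("KRT_SYN contaminant" = paste0("AAAAPGGDLK", PEP_CONTAM))
}

tiny_search_db <- function(standard = character(0)) {
  build_search_database(standard, tiny_db(), tiny_contaminants())
}

# independent brute-force tryptic digestion: enumerate every substring and
# keep those whose boundaries are valid cleavage points and whose internal
# missed-cleavage count is within budget
digest_oracle <- function(protein, missed_cleavages, min_len, max_len) {
  res <- strsplit(protein, "")[[1L]]
  n <- length(res)
  site <- vapply(seq_len(n), function(p) {
    p < n && res[p] %in% c("K", "R") && res[p + 1L] != "P"
  }, logical(1))
  cum <- c(0L, cumsum(site))  # cum[p + 1] = number of sites in 1..p
  peps <- character(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      left_ok <- i == 1L || site[i - 1L]
      right_ok <- j == n || site[j]
      if (!left_ok || !right_ok) next
      internal <- cum[j] - cum[i]  # sites strictly inside [i, j)
      if (internal <= missed_cleavages) {
        peps <- c(peps, substr(protein, i, j))
      }
    }
  }
  sort(unique(peps))
}

random_protein <- function(n, include_p = TRUE) {
  alph <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  paste(sample(alph, n, replace = TRUE), collapse = "")
}

# uniform allele frequencies over a generated database, per gene
uniform_freqs <- function(db) {
  lapply(split(db$two_field, db$gene),
         function(a) stats::setNames(rep(1 / length(a), length(a)), a))
}
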