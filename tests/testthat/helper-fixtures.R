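# Shared fixtures: the printed motif sequences, the reporter construct
# structures, amplicon flanks, and random-structure generators.

MOTIF_SEQ <- c(CA18   = "TCGGCAGCGGCAGCGAGG",
               CACA20 = "TCGGCAGCGGCACAGCGAGG",
               CGCA20 = "TCGGCAGCGGCGCAGCGAGG")

FLANK5 <- "ATTGGCTAGCTTAGCCATGGTACCTTGACA"
FLANK3 <- "GTCAAGGTACCATGGCTAAGCTAGCCAATT"

# reporter construct set: control alleles of 4/7/10/12 repeats and the
# pathogenic 14- and 16-repeat alleles
CONSTRUCT_4  <- alleleStructure(c(rep("CACA20", 3), "CA18"))
CONSTRUCT_7  <- alleleStructure(c(rep("CACA20", 4), "CA18", "CACA20", "CA18"))
CONSTRUCT_10 <- alleleStructure(c(rep("CACA20", 7), "CA18", "CACA20", "CA18"))
CONSTRUCT_12 <- alleleStructure(c("CACA20", rep("CGCA20", 10), "CA18"))
CONSTRUCT_14 <- alleleStructure(c(rep("CACA20", 2), rep("CGCA20", 10),
                                  "CACA20", "CA18"))
CONSTRUCT_16 <- alleleStructure(c("CACA20", rep("CGCA20", 13),
                                  "CACA20", "CA18"))

# common 8-repeat control allele used by the methylation fixtures
REF8 <- composeAllele(alleleStructure(c(rep("CACA20", 5), "CA18",
                                        "CACA20", "CA18")))

random_structure <- function(min_rep = 2L, max_rep = 12L,
                             ids = c("CA18", "CACA20", "CGCA20")) {
  alleleStructure(sample(ids, sample(min_rep:max_rep, 1L), replace = TRUE))
}

random_amplicon_pair <- function(...) {
  a <- random_structure(...)
  b <- random_structure(...)
  list(a = a, b = b,
       mixed = superpose(paste0(FLANK5, composeAllele(a), FLANK3),
                         paste0(FLANK5, composeAllele(b), FLANK3),
                         FLANK5, FLANK3))
}

# unphased genotype matrix drawn from a haplotype distribution
draw_genotypes <- function(haps, freqs, n, seed) {
  set.seed(seed)
  i1 <- sample(length(haps), n, TRUE, freqs)
  i2 <- sample(length(haps), n, TRUE, freqs)
  g <- t(vapply(seq_len(n), function(k) {
    h1 <- strsplit(haps[i1[k]], "|", fixed = TRUE)[[1]]
    h2 <- strsplit(haps[i2[k]], "|", fixed = TRUE)[[1]]
    vapply(seq_along(h1), function(j)
      paste(sort(c(h1[j], h2[j])), collapse = "/"), character(1))
  }, character(nchar(gsub("[^|]", "", haps[1])) + 1L)))
  as.data.frame(g, stringsAsFactors = FALSE)
}
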