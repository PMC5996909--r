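test_that("default alphabet holds the three printed motifs", {
  ab <- defaultMotifAlphabet()
  expect_identical(motifSequences(ab), MOTIF_SEQ)
  # motifs differ only beyond the shared 10-nt head
  expect_true(all(startsWith(motifSequences(ab), "TCGGCAGCGG")))
  expect_error(motifAlphabet(c(CA18 = "acgt")), "uppercase")
  expect_error(motifAlphabet(c(A = "ACGT", A = "ACGG")), "unique")
})

test_that("composeAllele concatenates motifs and splices insertions", {
  # 4-repeat reporter construct: 3x CACA20 + 1x CA18 -> 78 nt
  s <- composeAllele(CONSTRUCT_4)
  expect_identical(s, paste0(strrep(MOTIF_SEQ[["CACA20"]], 3),
                             MOTIF_SEQ[["CA18"]]))
  expect_identical(nchar(s), 78L)
  expect_identical(composeAllele(alleleStructure("CA18")),
                   "TCGGCAGCGGCAGCGAGG")
  ai <- alleleStructure("CGCA20",
                        data.frame(afterIndex = 0L, sequence = "AAAA"))
  expect_identical(composeAllele(ai), paste0(MOTIF_SEQ[["CGCA20"]], "AAAA"))
  expect_error(composeAllele(alleleStructure("NOPE")), "unknown motif")
})

test_that("decomposeSequence recovers printed structures and reports failures", {
  d <- decomposeSequence(composeAllele(CONSTRUCT_4))
  expect_identical(motifs(d), c("CACA20", "CACA20", "CACA20", "CA18"))
  expect_identical(repeatCount(d), 4L)
  expect_identical(motifs(decomposeSequence("TCGGCAGCGGCAGCGAGG")), "CA18")
  # untileable: failing offset reported
  err <- tryCatch(decomposeSequence(paste0(MOTIF_SEQ[["CA18"]], "AAAA")),
                  error = conditionMessage)
  expect_match(err, "offset 18")
  # insertion too long for the bound
  long_ins <- paste0(MOTIF_SEQ[["CA18"]], strrep("A", 25),
                     MOTIF_SEQ[["CA18"]])
  expect_error(decomposeSequence(long_ins, allowInsertions = TRUE,
                                 maxInsertionLen = 20L))
  expect_s4_class(decomposeSequence(long_ins, allowInsertions = TRUE,
                                    maxInsertionLen = 30L),
                  "AlleleStructure")
})

test_that("atypical insertion alleles round-trip with 12- and 20-nt segments", {
  for (ins_len in c(12L, 20L)) {
    seg <- strrep("AC", ins_len / 2L)
    a <- alleleStructure(c("CACA20", "CACA20", "CA18"),
                         data.frame(afterIndex = 1L, sequence = seg))
    d <- decomposeSequence(composeAllele(a), allowInsertions = TRUE)
    expect_identical(alleleName(d), alleleName(a))
    expect_identical(classifyAllele(d), "ATYPICAL_INSERTION")
  }
})

test_that("decompose-compose round-trips on random structures", {
  set.seed(101)
  for (k in 1:300) {
    a <- random_structure(2L, 17L)
    s <- composeAllele(a)
    d <- decomposeSequence(s)
    expect_identical(motifs(d), motifs(a))
    expect_identical(composeAllele(d), s)
  }
})

test_that("tiling is unique for the default alphabet (exhaustive to 4 motifs)", {
  # enumerate every tiling by brute force and compare to the decomposer
  ids <- names(MOTIF_SEQ)
  all_tilings <- function(s) {
    if (s == "") return(list(character(0)))
    out <- list()
    for (id in ids) {
      m <- MOTIF_SEQ[[id]]
      if (startsWith(s, m))
        for (rest in all_tilings(substring(s, nchar(m) + 1L)))
          out[[length(out) + 1L]] <- c(id, rest)
    }
    out
  }
  combos <- expand.grid(rep(list(ids), 4), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(combos))) {
    comp <- as.character(unlist(combos[r, ]))
    s <- composeAllele(alleleStructure(comp))
    tl <- all_tilings(s)
    expect_length(tl, 1L)
    expect_identical(tl[[1]], comp)
    expect_identical(motifs(decomposeSequence(s)), comp)
  }
})

test_that("countCpg matches direct scans and is additive over motifs", {
  expect_identical(countCpg(MOTIF_SEQ[["CA18"]]), 3L)
  expect_identical(countCpg(MOTIF_SEQ[["CACA20"]]), 3L)
  expect_identical(countCpg(MOTIF_SEQ[["CGCA20"]]), 4L)
  per_motif <- vapply(MOTIF_SEQ, countCpg, integer(1))
  set.seed(7)
  for (k in 1:25) {
    a <- random_structure(2L, 16L)
    expect_identical(countCpg(a),
                     as.integer(sum(per_motif[motifs(a)])))
  }
})

test_that("the 16-repeat pathogenic allele gains 37 CpGs over 8-repeat controls", {
  eight_repeat_controls <- list(
    alleleStructure(c(rep("CACA20", 5), "CA18", "CACA20", "CA18")),
    alleleStructure(c(rep("CACA20", 6), rep("CA18", 2))),
    alleleStructure(rep("CA18", 8)),
    alleleStructure(rep("CACA20", 8)))
  for (ctrl in eight_repeat_controls)
    expect_identical(countCpg(CONSTRUCT_16) - countCpg(ctrl), 37L)
})

test_that("classifyAllele applies the repeat-count and motif thresholds", {
  expect_identical(classifyAllele(CONSTRUCT_16), "PATHOGENIC_CANDIDATE")
  # the 17-repeat allele with 14 CGCA20 motifs is a pathogenic candidate
  a17 <- alleleStructure(c("CACA20", rep("CGCA20", 14), "CACA20", "CA18"))
  expect_identical(classifyAllele(a17), "PATHOGENIC_CANDIDATE")
  expect_identical(classifyAllele(CONSTRUCT_7), "CONTROL_TYPICAL")
  a11 <- alleleStructure(c(rep("CACA20", 2), rep("CGCA20", 8), "CA18"))
  expect_identical(classifyAllele(a11), "DISEASE_MOTIF_CARRIER")
  # thresholds are configurable
  expect_identical(classifyAllele(a11, minPathogenicRepeats = 11L),
                   "PATHOGENIC_CANDIDATE")
})

test_that("classifyGenotype is recessive and symmetric", {
  aff <- diploidGenotype(CONSTRUCT_16, CONSTRUCT_16)
  expect_identical(classifyGenotype(aff), "AFFECTED")
  a11 <- alleleStructure(c(rep("CACA20", 2), rep("CGCA20", 8), "CA18"))
  expect_identical(classifyGenotype(diploidGenotype(a11, CONSTRUCT_7)),
                   "UNAFFECTED")
  expect_identical(classifyGenotype(diploidGenotype(CONSTRUCT_7, CONSTRUCT_7)),
                   "UNAFFECTED")
  carr <- diploidGenotype(CONSTRUCT_16, CONSTRUCT_7)
  expect_identical(classifyGenotype(carr), "CARRIER")
  # symmetry in the two alleles
  set.seed(11)
  for (k in 1:20) {
    x <- random_structure(2L, 17L); y <- random_structure(2L, 17L)
    expect_identical(classifyGenotype(diploidGenotype(x, y)),
                     classifyGenotype(diploidGenotype(y, x)))
  }
})

test_that("nomenclature emitter and parser are mutual inverses", {
  expect_identical(alleleName(CONSTRUCT_4), "3xCACA20+CA18")
  expect_identical(alleleName(CONSTRUCT_7), "4xCACA20+CA18+CACA20+CA18")
  ai <- alleleStructure(c("CACA20", "CACA20", "CA18"),
                        data.frame(afterIndex = 1L, sequence = "ACACAC"))
  expect_identical(alleleName(ai), "2xCACA20+[ins:ACACAC]+CA18")
  set.seed(13)
  for (k in 1:50) {
    a <- random_structure(2L, 17L)
    expect_identical(alleleName(parseAlleleName(alleleName(a))),
                     alleleName(a))
  }
  expect_error(parseAlleleName("[ins:ACGT]+CA18"), "before any motif")
})

test_that("summarizeCohort reports spectrum, heterozygosity and carrier percent", {
  # single homozygote
  s1 <- summarizeCohort(list(diploidGenotype(CONSTRUCT_7, CONSTRUCT_7)))
  expect_identical(s1$nDistinctAlleles, 1L)
  expect_identical(s1$heterozygosity, 0)
  # 8 carrier alleles of 760 -> 1% at whole-percent rounding
  a11 <- alleleStructure(c(rep("CACA20", 2), rep("CGCA20", 8), "CA18"))
  gts <- c(replicate(8, diploidGenotype(a11, CONSTRUCT_7)),
           replicate(372, diploidGenotype(CONSTRUCT_7, CONSTRUCT_4)))
  s2 <- summarizeCohort(gts)
  expect_identical(s2$nAlleles, 760L)
  expect_identical(s2$carrierPercentWhole, 1)
  expect_equal(s2$carrierAllelePercent, round(100 * 8 / 760, 2))
  expect_identical(s2$heterozygosityPercent, 100)
  expect_error(summarizeCohort(list()), "at least one")
})
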