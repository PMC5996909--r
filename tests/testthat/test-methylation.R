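test_that("bisulfiteConvert follows the conversion chemistry", {
  ref <- MOTIF_SEQ[["CA18"]]
  n_cpg <- countCpg(ref)
  # efficiency 1, all CpGs methylated: every non-CpG C reads T, CpG Cs kept
  rd <- bisulfiteConvert(ref, rep(TRUE, n_cpg), 1)
  chars <- strsplit(rd, "")[[1]]
  refc <- strsplit(ref, "")[[1]]
  cpg_c <- cpgSites(ref) + 1L
  expect_true(all(chars[cpg_c] == "C"))
  non_cpg_c <- setdiff(which(refc == "C"), cpg_c)
  expect_true(all(chars[non_cpg_c] == "T"))
  # efficiency 1, no methylation: all Cs read T
  rd0 <- bisulfiteConvert(ref, rep(FALSE, n_cpg), 1)
  expect_false(grepl("C", rd0))
  expect_identical(gsub("C", "T", ref), rd0)
  expect_error(bisulfiteConvert(ref, rep(TRUE, n_cpg + 1L), 1), "per CpG")
})

test_that("observed conversion fraction matches the binomial expectation", {
  ref <- strrep(MOTIF_SEQ[["CA18"]], 3)
  cpg <- cpgSites(ref)
  non_cpg_c <- sum(strsplit(ref, "")[[1]] == "C") - length(cpg)
  set.seed(71)
  n_reads <- 400L
  conv <- 0L
  for (k in seq_len(n_reads)) {
    rd <- bisulfiteConvert(ref, rep(TRUE, length(cpg)), 0.9)
    conv <- conv + sum(strsplit(rd, "")[[1]] == "T") -
      sum(strsplit(ref, "")[[1]] == "T")
  }
  total <- n_reads * non_cpg_c
  ci <- stats::binom.test(conv, total, 0.9)$conf.int
  expect_true(ci[1] <= 0.9 && 0.9 <= ci[2])
  expect_lt(abs(conv / total - 0.9), 0.02)
})

test_that("filterClones keeps good clones and rejects each planted violation", {
  ds <- generateBisulfiteDataset(REF8, perCpgProb = 0.03, nSamples = 2L,
                                 clonesPerSample = 5L,
                                 plantedFailures = c("conversion", "identity",
                                                     "n_at_c", "gaps"),
                                 seed = 3L)
  cs <- filterClones(ds$clones, REF8)
  tab <- cloneTable(cs)
  planted <- ds$groundTruth$planted
  expect_identical(tab$read[!tab$kept],
                   unname(ds$clones[planted]))
  expect_identical(tab$failReasons[!tab$kept],
                   c("conversion", "identity", "n_at_c", "gaps"))
  expect_true(all(tab$kept[seq_len(10)]))
  # a perfect fully-converted unmethylated clone is kept
  cs0 <- filterClones(gsub("C", "T", REF8), REF8)
  expect_true(cloneTable(cs0)$kept)
})

test_that("relaxing any threshold never shrinks the kept set", {
  ds <- generateBisulfiteDataset(REF8, perCpgProb = 0.03, nSamples = 1L,
                                 clonesPerSample = 6L, efficiency = 0.95,
                                 plantedFailures = c("conversion", "gaps"),
                                 seed = 5L)
  base <- defaultFilterParams()
  kept0 <- cloneTable(filterClones(ds$clones, REF8, base))$kept
  relaxed <- list(
    modifyList(base, list(minConversion = 0.85)),
    modifyList(base, list(minIdentity = 0.80)),
    modifyList(base, list(maxNAtC = 0.30)),
    modifyList(base, list(maxGaps = 0.30)))
  for (p in relaxed) {
    kept1 <- cloneTable(filterClones(ds$clones, REF8, p))$kept
    expect_true(all(kept1[kept0]))
  }
})

test_that("methylation calls round-trip known states at efficiency 1", {
  cpg_n <- countCpg(REF8)
  set.seed(73)
  for (k in 1:5) {
    st <- stats::runif(cpg_n) < 0.3
    rd <- bisulfiteConvert(REF8, st, 1)
    cs <- filterClones(rd, REF8)
    expect_identical(as.numeric(cloneCalls(cs)[1, ]), as.numeric(st))
  }
})

test_that("quantifyMethylation counts per-CpG and global fractions", {
  cpg_n <- countCpg(REF8)
  # 10 clones, one CpG methylated in 3 of them -> 30% at that site
  states <- matrix(FALSE, 10, cpg_n)
  states[1:3, 5] <- TRUE
  reads <- vapply(seq_len(10), function(i)
    bisulfiteConvert(REF8, states[i, ], 1), character(1))
  cs <- filterClones(reads, REF8)
  q <- quantifyMethylation(cs)
  expect_equal(q$perCpg$fraction[5], 0.3, tolerance = 1e-12)
  expect_equal(q$global, 3 / (10 * cpg_n), tolerance = 1e-12)
  # global equals the call-count-weighted mean of per-CpG fractions
  expect_equal(q$global,
               sum(q$perCpg$fraction * q$perCpg$calls) / sum(q$perCpg$calls),
               tolerance = 1e-12)
  # all clones methylated everywhere at efficiency 1 -> 100%
  all_m <- vapply(seq_len(4), function(i)
    bisulfiteConvert(REF8, rep(TRUE, cpg_n), 1), character(1))
  expect_equal(quantifyMethylation(filterClones(all_m, REF8))$global, 1)
})

test_that("group fractions fall inside exact binomial CIs of the planted regime", {
  ref16 <- composeAllele(CONSTRUCT_16)
  rcps <- generateBisulfiteDataset(ref16, perCpgProb = 0.017, nSamples = 7L,
                                   clonesPerSample = 10L, seed = 3L)
  ctrl <- generateBisulfiteDataset(REF8, perCpgProb = 0.028, nSamples = 7L,
                                   clonesPerSample = 10L, seed = 4L)
  qA <- quantifyMethylation(filterClones(rcps$clones, ref16))
  qB <- quantifyMethylation(filterClones(ctrl$clones, REF8))
  # a methylated call arises from true methylation or a conversion failure
  # at an unmethylated CpG: p_call = p + (1 - p)(1 - efficiency)
  eff <- rcps$groundTruth$efficiency
  pA <- 0.017 + (1 - 0.017) * (1 - eff)
  pB <- 0.028 + (1 - 0.028) * (1 - eff)
  ciA <- stats::binom.test(qA$nMethylated, qA$nCalls, pA)$conf.int
  ciB <- stats::binom.test(qB$nMethylated, qB$nCalls, pB)$conf.int
  expect_true(ciA[1] <= pA && pA <= ciA[2])
  expect_true(ciB[1] <= pB && pB <= ciB[2])
})

# exact enumeration oracle over all tables with the observed margins
fisher_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  prob_of <- function(a) {
    b <- m - a; c_ <- k - a; d <- n - k + a
    exp(lchoose(m, a) + lchoose(n, c_) - lchoose(m + n, k))
  }
  as_ <- max(0, k - n):min(k, m)
  probs <- vapply(as_, prob_of, numeric(1))
  p_obs <- prob_of(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("fisherExact2x2 matches full margin-fixed enumeration", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2)), 1, tolerance = 1e-12)
  # [[10,0],[0,10]]: the two extreme tables out of choose(20,10) orderings
  expect_equal(fisherExact2x2(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(75)
  for (k in 1:200) {
    tab <- matrix(sample(0:25, 4, TRUE), 2)
    if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0 ||
        sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0) next
    p <- fisherExact2x2(tab)
    expect_equal(p, fisher_enum(tab), tolerance = 1e-12)
    # agreement with the standard implementation as an extra cross-check
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("methylationGroupTest pools calls and runs per-CpG tests", {
  set.seed(76)
  callsA <- matrix(as.numeric(stats::runif(200) < 0.02), 20)
  callsB <- matrix(as.numeric(stats::runif(200) < 0.3), 20)
  res <- methylationGroupTest(callsA, callsB, perCpg = TRUE)
  expect_equal(res$table[1, 1], sum(callsA == 1))
  expect_true(res$p < 0.05 && res$significant)
  expect_identical(nrow(res$perCpgTests), ncol(callsA))
  expect_true(all(res$perCpgTests$pBonferroni >= res$perCpgTests$p - 1e-15))
})
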