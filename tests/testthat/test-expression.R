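make_wells <- function(percents, neg = 0.02, pos = 1.02, reps = 3L,
                       renilla = 1e5) {
  rows <- list()
  for (id in names(percents)) {
    ratio <- neg + percents[[id]] / 100 * (pos - neg)
    for (r in seq_len(reps))
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = id, replicate = r,
        firefly = ratio * renilla, renilla = renilla)
  }
  for (tag in c("NEGATIVE", "POSITIVE")) {
    ratio <- if (tag == "NEGATIVE") neg else pos
    for (r in seq_len(reps))
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = tag, replicate = r,
        firefly = ratio * renilla, renilla = renilla)
  }
  do.call(rbind, rows)
}

test_that("relativeActivity anchors controls at 0 and 100 and inverts exactly", {
  w <- make_wells(c(C1 = 0, C2 = 100, C3 = 22.45, C4 = 19.69))
  act <- relativeActivity(w)
  pc <- setNames(act$percent, act$construct_id)
  expect_equal(unname(pc["NEGATIVE"]), 0, tolerance = 1e-9)
  expect_equal(unname(pc["POSITIVE"]), 100, tolerance = 1e-9)
  expect_equal(unname(pc["C1"]), 0, tolerance = 1e-9)
  expect_equal(unname(pc["C2"]), 100, tolerance = 1e-9)
  expect_equal(unname(pc["C3"]), 22.45, tolerance = 1e-9)
  expect_equal(unname(pc["C4"]), 19.69, tolerance = 1e-9)
  expect_error(relativeActivity(w[w$construct_id != "NEGATIVE", ]),
               "control")
  # positive <= negative is degenerate
  w2 <- make_wells(c(C1 = 10), neg = 1.02, pos = 0.02)
  expect_error(relativeActivity(w2), "degenerate")
})

test_that("relativeActivity is invariant to rescaling all firefly counts", {
  w <- make_wells(c(C1 = 35.2, C2 = 7.9))
  act1 <- relativeActivity(w)
  w$firefly <- w$firefly * 3.7
  act2 <- relativeActivity(w)
  expect_equal(act1$percent, act2$percent, tolerance = 1e-9)
})

test_that("perMotifEffect reproduces the printed pairwise comparisons", {
  # 4- vs 10-repeat: 22.45% vs 19.69%, 6 motifs added -> 2.76, 0.46/motif
  e1 <- perMotifEffect(22.45, 19.69, CONSTRUCT_4, CONSTRUCT_10)
  expect_identical(e1$delta, 2.76)
  expect_identical(e1$perMotif, 0.46)
  expect_identical(e1$dominantMotif, "CACA20")
  expect_identical(e1$totalAdded, 6L)
  # 12- vs 16-repeat: 17.8% vs 11.96%, 4 motifs added -> 5.84, 1.46/motif
  e2 <- perMotifEffect(17.8, 11.96, CONSTRUCT_12, CONSTRUCT_16)
  expect_identical(e2$delta, 5.84)
  expect_identical(e2$perMotif, 1.46)
  expect_identical(e2$dominantMotif, "CGCA20")
  expect_identical(e2$totalAdded, 4L)
  # identical activities
  e3 <- perMotifEffect(10, 10, CONSTRUCT_4, CONSTRUCT_10)
  expect_identical(e3$delta, 0); expect_identical(e3$perMotif, 0)
  # non-extension errors
  expect_error(perMotifEffect(10, 5, CONSTRUCT_10, CONSTRUCT_4),
               "does not extend")
})

test_that("fitMotifModel recovers exact coefficients from noise-free data", {
  truth <- c(intercept = 25, CA18 = -0.5, CACA20 = -0.5, CGCA20 = -1.5)
  structs <- list(CONSTRUCT_4, CONSTRUCT_7, CONSTRUCT_10, CONSTRUCT_12,
                  CONSTRUCT_14, CONSTRUCT_16)
  act <- do.call(rbind, lapply(structs, function(s) {
    n <- c(sum(motifs(s) == "CA18"), sum(motifs(s) == "CACA20"),
           sum(motifs(s) == "CGCA20"))
    data.frame(construct_id = alleleName(s),
               percent = truth["intercept"] + sum(truth[2:4] * n),
               nCA18 = n[1], nCACA20 = n[2], nCGCA20 = n[3])
  }))
  fit <- fitMotifModel(act)
  expect_equal(fit$intercept, 25, tolerance = 1e-9)
  expect_equal(unname(fit$betas), c(-0.5, -0.5, -1.5), tolerance = 1e-9)
  # degenerate design: identical count vectors
  bad <- act[rep(1, 4), ]; bad$construct_id <- paste0("c", 1:4)
  expect_error(fitMotifModel(bad), "distinct")
})

test_that("fitMotifModel matches perMotifEffect when one motif type is added", {
  # two constructs differing only in CACA20 count, zero noise: the fitted
  # CACA20 coefficient equals the pairwise per-motif value (sign flipped:
  # the pairwise delta is a decrease)
  act <- data.frame(construct_id = c("a", "b", "c", "d"),
                    percent = c(20, 18, 19, 16.4),
                    nCA18 = c(1, 1, 0, 2), nCACA20 = c(3, 7, 5, 3),
                    nCGCA20 = c(0, 0, 1, 1))
  fit <- fitMotifModel(act)
  pm <- perMotifEffect(20, 18, alleleStructure(c(rep("CACA20", 3), "CA18")),
                       alleleStructure(c(rep("CACA20", 7), "CA18")))
  expect_equal(unname(fit$betas["CACA20"]), -pm$perMotif, tolerance = 1e-9)
})

test_that("noisy beta recovery lands within the simulation band", {
  lds <- generateLuciferaseDataset(noiseSd = 1, replicates = 3L,
                                  nExperiments = 4L, seed = 42L)
  act <- relativeActivity(lds$wells)
  act <- act[!(act$construct_id %in% c("NEGATIVE", "POSITIVE")), ]
  act$structure <- lapply(act$construct_id, parseAlleleName)
  fit <- fitMotifModel(act)
  expect_true(all(abs(fit$betas - lds$groundTruth$betas) <= 0.5))
})

test_that("fitted activity decreases with motif count under negative betas", {
  lds <- generateLuciferaseDataset(noiseSd = 0, seed = 3L)
  act <- relativeActivity(lds$wells)
  act <- act[!(act$construct_id %in% c("NEGATIVE", "POSITIVE")), ]
  n_motifs <- vapply(act$construct_id,
                     function(s) repeatCount(parseAlleleName(s)), integer(1))
  multi <- n_motifs >= 4L  # the reporter allele series
  ord <- order(n_motifs[multi])
  expect_true(all(diff(act$percent[multi][ord]) < 0))
})

test_that("one-way ANOVA with Tukey flags planted shifts and matches t-test", {
  # two groups: F equals the squared pooled t statistic
  set.seed(61)
  g2 <- list(a = rnorm(8), b = rnorm(8, 1))
  r <- oneWayAnovaTukey(g2)
  tt <- stats::t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(r$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
  # identical groups: F ~ 0, nothing significant
  g0 <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r0 <- oneWayAnovaTukey(g0)
  expect_lt(r0$F, 1e-20)
  expect_false(any(r0$tukey$significant))
  # planted 5-sd shift at n = 12/group is detected
  set.seed(62)
  g3 <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 5))
  r3 <- oneWayAnovaTukey(g3)
  expect_lt(r3$p, 0.05)
  shifted <- grepl("c", r3$tukey$comparison)
  expect_true(all(r3$tukey$significant[shifted]))
  expect_false(any(r3$tukey$significant[!shifted]))
  expect_error(oneWayAnovaTukey(list(a = 1, b = c(1, 2))), "replicates")
})
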