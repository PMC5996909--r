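test_that("unequalCrossover splices at motif-granular breakpoints", {
  p <- alleleStructure(rep("CACA20", 7))
  # equal crossover on identical parents is a no-op
  pr <- unequalCrossover(p, p, 3, 3)
  expect_identical(alleleName(pr[[1]]), alleleName(p))
  expect_identical(alleleName(pr[[2]]), alleleName(p))
  # boundary breakpoints conserve counts into a 14- and a 0-motif product
  pr2 <- unequalCrossover(p, p, 0, 7)
  expect_identical(repeatCount(pr2[[1]]), 0L)
  expect_identical(repeatCount(pr2[[2]]), 14L)
  # splice-by-hand oracle: two 8-repeat CGCA carriers, break1=2, break2=8
  a <- alleleStructure(c("CACA20", "CGCA20", rep("CACA20", 6)))
  b <- alleleStructure(c(rep("CACA20", 4), rep("CGCA20", 4)))
  pr3 <- unequalCrossover(a, b, 2, 8)
  expect_identical(motifs(pr3[[1]]), c("CACA20", "CGCA20"))         # 2 motifs
  expect_identical(motifs(pr3[[2]]),
                   c(motifs(b), motifs(a)[3:8]))                    # 14 motifs
  expect_identical(repeatCount(pr3[[2]]), 14L)
  expect_error(unequalCrossover(a, b, 9, 0), "breakpoints")
  ai <- alleleStructure("CA18", data.frame(afterIndex = 0L, sequence = "AA"))
  expect_error(unequalCrossover(ai, b, 0, 1), "insertion")
})

test_that("crossover conserves total motif count on random events", {
  set.seed(41)
  for (k in 1:100) {
    a <- random_structure(2L, 15L); b <- random_structure(2L, 15L)
    b1 <- sample(0:repeatCount(a), 1); b2 <- sample(0:repeatCount(b), 1)
    pr <- unequalCrossover(a, b, b1, b2)
    expect_identical(repeatCount(pr[[1]]) + repeatCount(pr[[2]]),
                     repeatCount(a) + repeatCount(b))
    # multiset of motifs conserved too
    expect_identical(sort(c(motifs(pr[[1]]), motifs(pr[[2]]))),
                     sort(c(motifs(a), motifs(b))))
  }
})

test_that("with crossover rate 0 allele structures are immutable across generations", {
  founders <- list(alleleStructure(rep("CACA20", 8)),
                   parseAlleleName("4xCACA20+CA18+CACA20+CA18"))
  tr <- evolvePopulation(founders, popSize = 25L, generations = 15L,
                         crossoverRate = 0, seed = 5L)
  founder_names <- vapply(founders, alleleName, character(1))
  for (pool in tr$pools)
    expect_true(all(pool %in% founder_names))
  expect_identical(nrow(tr$events), 0L)
  # pool size constant at 2N
  expect_true(all(lengths(tr$pools) == 50L))
})

test_that("unequal crossover generates size variance and mosaic structures", {
  tr <- evolvePopulation(list(parseAlleleName("4xCACA20+CA18+CACA20+CA18"),
                              alleleStructure(rep("CACA20", 8))),
                         popSize = 40L, generations = 30L,
                         crossoverRate = 1, seed = 7L)
  count_of <- function(nm) repeatCount(parseAlleleName(nm))
  rc0 <- vapply(tr$pools[[1]], count_of, integer(1))
  rcT <- vapply(tr$pools[[31]], count_of, integer(1))
  expect_gt(stats::var(rcT), stats::var(rc0))
  # distinct structures strictly increase from the founders
  expect_gt(length(unique(tr$pools[[31]])), length(unique(tr$pools[[1]])))
  # every logged event conserves motif count
  for (r in seq_len(nrow(tr$events))) {
    e <- tr$events[r, ]
    n1 <- repeatCount(parseAlleleName(e$parent1))
    n2 <- repeatCount(parseAlleleName(e$parent2))
    np <- repeatCount(parseAlleleName(e$result))
    other <- if (e$product == 1L) e$break2 + (n1 - e$break1) else
      e$break1 + (n2 - e$break2)
    expect_identical(np + other, n1 + n2)
  }
  # expected total motif count is conserved in expectation; check the
  # realized mean stays within drift range of the founder mean (8)
  expect_lt(abs(mean(rcT) - 8), 3)
})

test_that("derivationDistance finds planted 0-, 1- and 2-event paths", {
  pool <- c("4xCACA20+CA18+CACA20+CA18",    # common 7-repeat
            "5xCACA20+CA18+CACA20+CA18",    # 8-repeat
            "2xCACA20+8xCGCA20+CA18")       # 11-repeat carrier
  # 0 events: target already in pool
  d0 <- derivationDistance(pool[1], pool)
  expect_identical(d0$minEvents, 0L)
  # 1 event: plant a single crossover product (prefix of the 8-repeat
  # allele spliced onto the CGCA-rich tail of the carrier)
  t1 <- unequalCrossover(parseAlleleName(pool[2]),
                         parseAlleleName(pool[3]), 2, 1)[[1]]
  d1 <- derivationDistance(t1, pool, maxEvents = 2L)
  expect_identical(d1$minEvents, 1L)
  expect_identical(d1$witness$result[nrow(d1$witness)], alleleName(t1))
  # the witness replays to the target
  w <- d1$witness[nrow(d1$witness), ]
  replay <- unequalCrossover(parseAlleleName(w$parent1),
                             parseAlleleName(w$parent2),
                             w$break1, w$break2)[[w$product]]
  expect_identical(alleleName(replay), alleleName(t1))
  # 2 events: stage two splices; the intermediate is not in the pool
  mid <- unequalCrossover(parseAlleleName(pool[3]),
                          parseAlleleName(pool[3]), 1, 6)[[2]]  # 16 repeats
  t2 <- unequalCrossover(mid, parseAlleleName(pool[1]), 14, 5)[[1]]
  d2 <- derivationDistance(t2, pool, maxEvents = 2L)
  expect_identical(d2$minEvents, 2L)
  expect_lte(d2$minEvents, 2L)  # never exceeds the planted construction
  # unreachable within 0 extra events
  expect_true(is.na(derivationDistance(t2, pool, maxEvents = 1L)$minEvents))
})

test_that("pathogenic-scale alleles are reachable from control pools", {
  # a 14-repeat CGCA-rich product can arise in one exchange between two
  # 11-repeat carrier alleles, mirroring the unequal-crossing-over origin
  # hypothesis for disease alleles
  carrier <- "2xCACA20+8xCGCA20+CA18"
  pr <- unequalCrossover(parseAlleleName(carrier), parseAlleleName(carrier),
                         2, 5)
  fourteen <- pr[[2]]
  expect_identical(repeatCount(fourteen), 14L)
  expect_identical(classifyAllele(fourteen), "PATHOGENIC_CANDIDATE")
  d <- derivationDistance(fourteen, c(carrier, "4xCACA20+CA18+CACA20+CA18"),
                          maxEvents = 1L)
  expect_identical(d$minEvents, 1L)
})
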