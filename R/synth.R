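## Synthetic-cohort generator.
##
## The generator produces every input the pipeline consumes — diploid repeat
## cohorts with mixed heterozygote amplicons, flanking-SNP panels in weak LD,
## luciferase plates, and bisulfite clone sets — with the planted ground
## truth serialized alongside, so every downstream recovery test can be
## scored without regeneration. Defaults emulate the published study
## conditions: 380 individuals, allele spectrum spanning 2-17 repeats with
## modal 7- and 8-repeat alleles, ~1% of alleles carrying the
## disease-associated CGCA20 motif, and maximum pairwise SNP D' <= 0.48.

#' Default SNP ref/alt alleles for the flanking panel
#' @return Named list, rs id -> c(ref, alt).
#' @export
defaultSnpAlleles <- function() {
  list(rs11150824 = c("A", "G"), rs2289534 = c("C", "T"),
       rs3829612 = c("G", "A"), rs10782008 = c("C", "T"),
       rs12943620 = c("G", "C"))
}

#' Stylized population allele spectrum
#'
#' A stylized version of the published population spectrum (exact per-allele
#' counts are figure-only and are not treated as data): repeat counts 2-17,
#' modal 7- and 8-repeat alleles near 25% and 23%, the most common allele
#' being 4xCACA20+CA18+CACA20+CA18, a single-motif-type allele, and 1% of
#' alleles carrying the CGCA20 motif (within alleles of 11+ repeats,
#' including a 17-repeat allele with 14 CGCA20).
#'
#' @param includeAtypical Add two low-frequency insertion-bearing alleles
#'   (excluded by default: insertion alleles are not deconvolvable from
#'   mixed amplicons and are exercised separately).
#' @return data.frame with columns \code{structure} (nomenclature) and
#'   \code{freq}, summing to 1.
#' @export
defaultAlleleSpectrum <- function(includeAtypical = FALSE) {
  sp <- data.frame(
    structure = c(
      "2xCACA20",                                   # 2 repeats
      "2xCACA20+CA18",                              # 3
      "3xCACA20+CA18",                              # 4 (luciferase control)
      "3xCACA20+2xCA18",                            # 5
      "4xCACA20+2xCA18",                            # 6
      "6xCA18",                                     # 6, single-motif-type
      "4xCACA20+CA18+CACA20+CA18",                  # 7, modal
      "5xCACA20+2xCA18",                            # 7
      "5xCACA20+CA18+CACA20+CA18",                  # 8, second modal
      "6xCACA20+2xCA18",                            # 8
      "6xCACA20+CA18+CACA20+CA18",                  # 9
      "7xCACA20+CA18+CACA20+CA18",                  # 10 (luciferase control)
      "8xCACA20+CA18+CACA20+CA18",                  # 11
      "8xCACA20+2xCA18+CACA20+CA18",                # 12
      # CGCA20-carrier alleles (1% of alleles in total, 11+ repeats)
      "2xCACA20+8xCGCA20+CA18",                     # 11
      "CACA20+10xCGCA20+CA18",                      # 12 (luciferase control)
      "CACA20+14xCGCA20+CACA20+CA18"                # 17, largest
    ),
    freq = c(0.010, 0.030, 0.080, 0.060, 0.070, 0.020,
             0.2546, 0.060, 0.2321, 0.060, 0.055, 0.0333,
             0.020, 0.005,
             0.004, 0.003, 0.003),
    stringsAsFactors = FALSE)
  if (includeAtypical) {
    aty <- data.frame(
      structure = c("3xCACA20+[ins:GGTTAACCGGTT]+2xCACA20+CA18",
                    "4xCACA20+[ins:AACCGGTTAACCGGTTAACC]+CA18"),
      freq = c(0.002, 0.002), stringsAsFactors = FALSE)
    sp$freq <- sp$freq * (1 - sum(aty$freq))
    sp <- rbind(sp, aty)
  }
  sp$freq <- sp$freq / sum(sp$freq)
  sp
}

#' Default SNP haplotype distribution with weak LD
#'
#' Full distribution over the 2^5 haplotypes of the flanking panel, built as
#' the product of per-SNP allele frequencies tilted by a small
#' adjacent-marker interaction, then renormalized. The tilt is fixed so that
#' the maximum pairwise D' stays below 0.48 (the weak-LD regime).
#'
#' @return data.frame with columns \code{haplotype} ("|"-joined bases in
#'   panel order) and \code{freq}.
#' @export
defaultSnpHaplotypes <- function() {
  al <- defaultSnpAlleles()
  p_alt <- c(0.30, 0.40, 0.50, 0.35, 0.45)
  eps <- 0.30
  grid <- expand.grid(rep(list(0:1), 5))[, 5:1]
  freq <- apply(grid, 1, function(g) {
    f <- prod(ifelse(g == 1, p_alt, 1 - p_alt))
    s <- ifelse(g == 1, 1, -1)
    for (j in 1:4) f <- f * (1 + eps * s[j] * s[j + 1])
    f
  })
  freq <- freq / sum(freq)
  hap <- apply(grid, 1, function(g)
    paste(vapply(1:5, function(j) al[[j]][g[j] + 1L], character(1)),
          collapse = "|"))
  data.frame(haplotype = hap, freq = freq, stringsAsFactors = FALSE)
}

## exact max pairwise D' of a haplotype distribution
.max_pairwise_dprime <- function(hapFreqs) {
  mat <- do.call(rbind, strsplit(hapFreqs$haplotype, "|", fixed = TRUE))
  m <- ncol(mat)
  best <- 0
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    ai <- sort(unique(mat[, i])); aj <- sort(unique(mat[, j]))
    if (length(ai) != 2L || length(aj) != 2L) next
    tab <- matrix(0, 2, 2)
    for (r in seq_len(nrow(mat)))
      tab[match(mat[r, i], ai), match(mat[r, j], aj)] <-
        tab[match(mat[r, i], ai), match(mat[r, j], aj)] + hapFreqs$freq[r]
    best <- max(best, dPrime(tab)$Dprime)
  }
  best
}

#' Build and validate a cohort specification
#'
#' @param nIndividuals Cohort size (default 380).
#' @param alleleSpectrum data.frame (structure, freq) summing to 1.
#' @param snpHaplotypes data.frame (haplotype, freq) summing to 1.
#' @param carrierScenarios Optional data.frame (sample, allele1, allele2)
#'   of planted genotypes, overriding the draw for those samples (1-based
#'   sample indices).
#' @param inbreeding Inbreeding coefficient F in [0, 1] (probability the two
#'   alleles are identical by descent; families at a recessive locus are
#'   consanguinity-prone, but the default is 0).
#' @param flank5,flank3 Fixed amplicon flanks shared by all alleles.
#' @param maxDprime Validation bound on the SNP haplotype distribution's
#'   maximum pairwise D'.
#' @param seed Integer seed for the whole cohort draw.
#' @return A validated list of class \code{cohortSpec}.
#' @export
cohortSpec <- function(nIndividuals = 380L,
                       alleleSpectrum = defaultAlleleSpectrum(),
                       snpHaplotypes = defaultSnpHaplotypes(),
                       carrierScenarios = NULL,
                       inbreeding = 0,
                       flank5 = "ATTGGCTAGCTTAGCCATGGTACCTTGACA",
                       flank3 = "GTCAAGGTACCATGGCTAAGCTAGCCAATT",
                       maxDprime = 0.48,
                       seed = 1L) {
  if (nIndividuals < 1L) stop("nIndividuals must be positive")
  if (abs(sum(alleleSpectrum$freq) - 1) > 1e-8)
    stop("allele spectrum frequencies must sum to 1")
  if (abs(sum(snpHaplotypes$freq) - 1) > 1e-8)
    stop("SNP haplotype frequencies must sum to 1")
  if (inbreeding < 0 || inbreeding > 1)
    stop("inbreeding must be in [0, 1]")
  md <- .max_pairwise_dprime(snpHaplotypes)
  if (md > maxDprime)
    stop(sprintf(
      "SNP haplotype distribution has max pairwise D' = %.3f > target %.2f",
      md, maxDprime))
  if (!is.null(carrierScenarios) &&
      !all(c("sample", "allele1", "allele2") %in% colnames(carrierScenarios)))
    stop("carrierScenarios needs columns sample, allele1, allele2")
  structure(list(nIndividuals = as.integer(nIndividuals),
                 alleleSpectrum = alleleSpectrum,
                 snpHaplotypes = snpHaplotypes,
                 carrierScenarios = carrierScenarios,
                 inbreeding = inbreeding,
                 flank5 = flank5, flank3 = flank3,
                 maxDprime = maxDprime, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Generate a synthetic diploid cohort
#'
#' Samples allele pairs from the spectrum under Hardy-Weinberg pairing
#' (optionally with inbreeding), SNP haplotype pairs from the weak-LD
#' haplotype distribution, applies planted carrier/affected scenarios, and
#' emits per-allele sequences plus superposed heterozygote amplicons.
#' Byte-identical under the same spec and seed.
#'
#' @param spec A \code{\link{cohortSpec}}.
#' @return List with \code{genotypes} (list of
#'   \linkS4class{DiploidGenotype}), \code{alleleSeqs} (named character,
#'   \code{sample|allele1} / \code{sample|allele2}), \code{mixedSeqs} (named
#'   character of IUPAC amplicon superpositions), \code{mixed} (list of
#'   \linkS4class{MixedSequence}), and \code{groundTruth} (per-sample true
#'   structures and SNP phases, the spec seed, and the spectrum).
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  n <- spec$nIndividuals
  sp <- spec$alleleSpectrum
  structures <- lapply(sp$structure, parseAlleleName)
  hp <- spec$snpHaplotypes

  a_idx1 <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$freq)
  ibd <- stats::runif(n) < spec$inbreeding
  a_idx2 <- ifelse(ibd, a_idx1,
                   sample.int(nrow(sp), n, replace = TRUE, prob = sp$freq))
  h_idx1 <- sample.int(nrow(hp), n, replace = TRUE, prob = hp$freq)
  h_idx2 <- sample.int(nrow(hp), n, replace = TRUE, prob = hp$freq)

  ids <- sprintf("S%04d", seq_len(n))
  genotypes <- vector("list", n)
  alleleSeqs <- character(0)
  mixedSeqs <- character(0)
  mixed <- vector("list", n)
  truth <- vector("list", n)

  for (i in seq_len(n)) {
    s1 <- structures[[a_idx1[i]]]
    s2 <- structures[[a_idx2[i]]]
    if (!is.null(spec$carrierScenarios)) {
      hit <- which(spec$carrierScenarios$sample == i)
      if (length(hit) == 1L) {
        s1 <- parseAlleleName(spec$carrierScenarios$allele1[hit])
        s2 <- parseAlleleName(spec$carrierScenarios$allele2[hit])
      }
    }
    hap1 <- strsplit(hp$haplotype[h_idx1[i]], "|", fixed = TRUE)[[1]]
    hap2 <- strsplit(hp$haplotype[h_idx2[i]], "|", fixed = TRUE)[[1]]
    snp_gt <- vapply(1:5, function(k)
      paste(sort(c(hap1[k], hap2[k])), collapse = "/"), character(1))
    genotypes[[i]] <- diploidGenotype(s1, s2, snpGenotypes = snp_gt,
                                      sampleId = ids[i])
    d1 <- composeAllele(s1); d2 <- composeAllele(s2)
    alleleSeqs[paste0(ids[i], "|allele1")] <- d1
    alleleSeqs[paste0(ids[i], "|allele2")] <- d2
    amp1 <- paste0(spec$flank5, d1, spec$flank3)
    amp2 <- paste0(spec$flank5, d2, spec$flank3)
    mx <- superpose(amp1, amp2, spec$flank5, spec$flank3)
    mixed[[i]] <- mx
    mixedSeqs[ids[i]] <- mixedIupac(mx)
    truth[[i]] <- list(sample = ids[i],
                       allele1 = alleleName(s1), allele2 = alleleName(s2),
                       snpHap1 = hp$haplotype[h_idx1[i]],
                       snpHap2 = hp$haplotype[h_idx2[i]])
  }
  list(genotypes = genotypes, alleleSeqs = alleleSeqs,
       mixedSeqs = mixedSeqs, mixed = mixed,
       groundTruth = list(samples = truth, seed = spec$seed,
                          spectrum = sp, snpHaplotypes = hp))
}

#' Generate a synthetic dual-luciferase plate
#'
#' Each construct's true activity percent is intercept + sum(beta * motif
#' count); per-well percents add Gaussian noise and are inverted through the
#' relative-activity formula to firefly/Renilla counts. Controls are emitted
#' at the exact negative/positive ratios, so with zero noise
#' \code{\link{relativeActivity}} returns the planted percents exactly.
#'
#' @param constructs Character vector of construct nomenclatures. The default
#'   mirrors the reporter construct set: control alleles of 4, 7, 10 and 12
#'   repeats, pathogenic alleles of 14 and 16 repeats, and the three
#'   single-motif constructs.
#' @param betas Named per-motif percent change per added motif (defaults to
#'   the per-motif depressions estimated from the pairwise comparisons:
#'   CA18/CACA20 about -0.46, CGCA20 about -1.46).
#' @param intercept Baseline percent for an empty construct.
#' @param noiseSd Gaussian noise sd on the percent scale.
#' @param replicates Wells per construct per experiment (assays are run in
#'   triplicate; default 3).
#' @param nExperiments Independent experiments (default 4).
#' @param negRatio,posRatio Control firefly/Renilla ratios.
#' @param renilla Renilla counts per well.
#' @param seed Integer seed.
#' @return List with \code{wells} (data.frame: construct_id, experiment,
#'   replicate, firefly, renilla), \code{groundTruth} (betas, intercept,
#'   true per-construct percents, clipped wells).
#' @export
generateLuciferaseDataset <- function(
    constructs = c("3xCACA20+CA18",
                   "4xCACA20+CA18+CACA20+CA18",
                   "7xCACA20+CA18+CACA20+CA18",
                   "CACA20+10xCGCA20+CA18",
                   "2xCACA20+10xCGCA20+CACA20+CA18",
                   "CACA20+13xCGCA20+CACA20+CA18",
                   "CA18", "CACA20", "CGCA20"),
    betas = c(CA18 = -0.46, CACA20 = -0.46, CGCA20 = -1.46),
    intercept = 24.29, noiseSd = 1, replicates = 3L, nExperiments = 4L,
    negRatio = 0.02, posRatio = 1.02, renilla = 1e5, seed = 1L) {
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  set.seed(seed)
  cnts <- t(vapply(constructs,
                   function(s) .motif_counts(parseAlleleName(s)),
                   integer(3)))
  truth_pct <- intercept + as.numeric(cnts %*% betas[colnames(cnts)])
  names(truth_pct) <- constructs

  rows <- list()
  clipped <- character(0)
  for (e in seq_len(nExperiments)) {
    for (ci in seq_along(constructs)) {
      for (r in seq_len(replicates)) {
        pct <- truth_pct[ci] + stats::rnorm(1, 0, noiseSd)
        ratio <- negRatio + pct / 100 * (posRatio - negRatio)
        if (pct <= -20 || pct >= 120) {
          clipped <- c(clipped, sprintf("%s/e%d/r%d", constructs[ci], e, r))
          warning("well percent outside (-20, 120); ratio clipped")
          ratio <- max(ratio, 1e-4)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          construct_id = constructs[ci], experiment = e, replicate = r,
          firefly = ratio * renilla, renilla = renilla,
          stringsAsFactors = FALSE)
      }
    }
    for (ctrl in c("NEGATIVE", "POSITIVE")) {
      ratio <- if (ctrl == "NEGATIVE") negRatio else posRatio
      for (r in seq_len(replicates))
        rows[[length(rows) + 1L]] <- data.frame(
          construct_id = ctrl, experiment = e, replicate = r,
          firefly = ratio * renilla, renilla = renilla,
          stringsAsFactors = FALSE)
    }
  }
  list(wells = do.call(rbind, rows),
       groundTruth = list(betas = betas, intercept = intercept,
                          percents = truth_pct, noiseSd = noiseSd,
                          clippedWells = clipped, seed = seed))
}

## deterministic planted filter violations for one reference
.planted_failure_clone <- function(reference, kind) {
  chars <- strsplit(reference, "")[[1]]
  cpg_c <- cpgSites(reference) + 1L
  c_pos <- which(chars == "C")
  non_cpg_c <- setdiff(c_pos, cpg_c)
  if (kind == "conversion") {
    # convert exactly 90% of non-CpG Cs -> conversion rate 0.90 < 0.95
    k <- floor(0.9 * length(non_cpg_c))
    chars[non_cpg_c[seq_len(k)]] <- "T"
    chars[cpg_c] <- "T"
  } else if (kind == "identity") {
    chars[non_cpg_c] <- "T"; chars[cpg_c] <- "T"
    flip <- which(chars %in% c("A", "G"))
    flip <- flip[seq(1, length(flip), by = 4)]  # ~14% of columns mismatched
    chars[flip] <- ifelse(chars[flip] == "A", "G", "A")
  } else if (kind == "n_at_c") {
    chars[non_cpg_c] <- "T"; chars[cpg_c] <- "T"
    nn <- ceiling(0.25 * length(c_pos))
    chars[c_pos[seq_len(nn)]] <- "N"
  } else if (kind == "gaps") {
    chars[non_cpg_c] <- "T"; chars[cpg_c] <- "T"
    drop <- ceiling(0.25 * length(chars))
    chars <- chars[-(seq_len(drop) + floor(length(chars) / 3))]
  } else stop("unknown planted failure kind: ", kind)
  paste(chars, collapse = "")
}

#' Generate a synthetic bisulfite clone dataset
#'
#' Draws per-CpG methylation states at the profile probabilities for each
#' clone, converts in silico, and optionally appends clones with planted
#' filter violations (conversion 90%, low identity, excess N at cytosines,
#' excess gaps), each built deterministically.
#'
#' @param reference Reference allele sequence or
#'   \linkS4class{AlleleStructure}.
#' @param perCpgProb Methylation probability per CpG site (recycled).
#' @param nSamples Number of samples.
#' @param clonesPerSample Clones sequenced per sample (default 10).
#' @param efficiency Bisulfite conversion efficiency (default 0.995).
#' @param plantedFailures Character vector among \code{"conversion"},
#'   \code{"identity"}, \code{"n_at_c"}, \code{"gaps"}; one extra clone per
#'   entry is appended.
#' @param seed Integer seed.
#' @return List with \code{clones} (named character: sample.clone ids, then
#'   \code{planted_<kind>}), \code{reference}, and \code{groundTruth}
#'   (per-clone methylation state matrix, planted clone names, parameters).
#' @export
generateBisulfiteDataset <- function(reference, perCpgProb = 0.02,
                                     nSamples = 7L, clonesPerSample = 10L,
                                     efficiency = 0.995,
                                     plantedFailures = character(0),
                                     seed = 1L) {
  if (!is.character(reference)) reference <- composeAllele(reference)
  cpg <- cpgSites(reference)
  prob <- rep_len(perCpgProb, length(cpg))
  set.seed(seed)
  clones <- character(0)
  states <- list()
  for (s in seq_len(nSamples)) {
    for (cl in seq_len(clonesPerSample)) {
      st <- stats::runif(length(cpg)) < prob
      id <- sprintf("S%02d.clone%02d", s, cl)
      clones[id] <- bisulfiteConvert(reference, st, efficiency)
      states[[id]] <- st
    }
  }
  planted <- character(0)
  for (kind in plantedFailures) {
    id <- paste0("planted_", kind)
    clones[id] <- .planted_failure_clone(reference, kind)
    planted <- c(planted, id)
  }
  list(clones = clones, reference = reference,
       groundTruth = list(
         states = do.call(rbind, states), planted = planted,
         perCpgProb = prob, efficiency = efficiency, seed = seed))
}
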