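## End-to-end orchestration: synth -> decompose -> deconvolve -> classify /
## summarize -> haplotype -> expression -> methylation -> report.
##
## All randomness flows from the single config seed; re-running with the same
## config and seed reproduces the report byte-for-byte apart from the
## timestamp field.

#' Default pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Integer master seed.
#' @param stages Stages to run, in dependency order.
#' @param nIndividuals Synthetic cohort size.
#' @param deconvolveMax Maximum samples to deconvolve (the exact search is
#'   the slow stage; a subsample measures the ambiguity rate).
#' @param alpha Significance level for the test stages.
#' @param inputs Optional named list of input paths (e.g. \code{fasta},
#'   \code{genotypes}) for runs on real data; paths are validated before any
#'   stage runs.
#' @return A list of class \code{runConfig}.
#' @export
runConfig <- function(outdir = tempfile("repeatlens_run_"), seed = 1L,
                      stages = c("synth", "decompose", "deconvolve",
                                 "summarize", "haplotype", "expression",
                                 "methylation"),
                      nIndividuals = 100L, deconvolveMax = 25L,
                      alpha = 0.05, inputs = list()) {
  known <- c("synth", "decompose", "deconvolve", "summarize", "haplotype",
             "expression", "methylation")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(outdir = outdir, seed = as.integer(seed), stages = stages,
                 nIndividuals = as.integer(nIndividuals),
                 deconvolveMax = as.integer(deconvolveMax),
                 alpha = alpha, inputs = inputs),
            class = "runConfig")
}

#' Run the analysis pipeline
#'
#' Validates the configuration (referenced input paths must exist before any
#' stage runs), executes the enabled stages in dependency order, writes
#' per-stage outputs and a machine-readable JSON report to
#' \code{config$outdir}, and returns the report. Disabled stages leave their
#' report sections absent and never alter upstream outputs.
#'
#' @param config A \code{\link{runConfig}} (or path to a JSON file with the
#'   same fields).
#' @return The report, a list with one section per executed stage plus
#'   \code{provenance} (seed, config hash, package version, timestamp).
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) {
    cfg <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- do.call(runConfig, cfg[intersect(names(cfg),
                                               names(formals(runConfig)))])
  }
  stopifnot(inherits(config, "runConfig"))
  for (p in unlist(config$inputs))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  report <- list()
  st <- config$stages
  run_stage <- function(name, fun) {
    if (!(name %in% st)) return(invisible())
    t0 <- proc.time()[["elapsed"]]
    message(sprintf("[repeatlens] stage %s ...", name))
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report[[name]] <<- res
    message(sprintf("[repeatlens] stage %s done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  }

  cohort <- NULL

  run_stage("synth", function() {
    spec <- cohortSpec(nIndividuals = config$nIndividuals, seed = config$seed)
    cohort <<- generateCohort(spec)
    writeAlleleFasta(cohort$alleleSeqs, file.path(config$outdir, "alleles.fa"))
    writeAlleleFasta(cohort$mixedSeqs, file.path(config$outdir, "mixed.fa"))
    writeGenotypesTsv(cohort$genotypes,
                      file.path(config$outdir, "genotypes.tsv"))
    writeSnpVcf(cohort$genotypes, file.path(config$outdir, "snps.vcf"))
    jsonlite::write_json(cohort$groundTruth,
                         file.path(config$outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    list(nIndividuals = length(cohort$genotypes),
         files = c("alleles.fa", "mixed.fa", "genotypes.tsv", "snps.vcf",
                   "ground_truth.json"))
  })

  run_stage("decompose", function() {
    seqs <- if (!is.null(config$inputs$fasta))
      readAlleleFasta(config$inputs$fasta)
    else if (!is.null(cohort)) cohort$alleleSeqs
    else stop("no allele FASTA available (enable synth or provide inputs$fasta)")
    tab <- do.call(rbind, lapply(names(seqs), function(id) {
      s <- decomposeSequence(seqs[[id]], allowInsertions = TRUE)
      data.frame(id = id, structure = alleleName(s),
                 repeats = repeatCount(s), cpg = countCpg(s),
                 class = classifyAllele(s), stringsAsFactors = FALSE)
    }))
    utils::write.table(tab, file.path(config$outdir, "decomposed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(nSequences = nrow(tab),
         classes = as.list(table(tab$class)))
  })

  run_stage("deconvolve", function() {
    if (is.null(cohort)) stop("deconvolve requires the synth stage")
    idx <- seq_len(min(config$deconvolveMax, length(cohort$mixed)))
    truth <- cohort$groundTruth$samples
    ok <- 0L; ambiguous <- 0L
    rows <- list()
    for (i in idx) {
      dec <- deconvolve(cohort$mixed[[i]])
      cand <- dec$candidates[dec$candidates$mismatches == 0L, , drop = FALSE]
      tp <- sort(c(truth[[i]]$allele1, truth[[i]]$allele2))
      hit <- any(cand$allele1 == tp[1] & cand$allele2 == tp[2])
      ok <- ok + hit
      ambiguous <- ambiguous + (nrow(cand) > 1L)
      rows[[i]] <- data.frame(sample = truth[[i]]$sample,
                              rank = seq_len(nrow(cand)),
                              allele1 = cand$allele1, allele2 = cand$allele2,
                              mismatches = cand$mismatches,
                              stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, rows),
                       file.path(config$outdir, "deconvolved.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(nSamples = length(idx), recovered = ok,
         recoveryRate = ok / length(idx),
         ambiguityRate = ambiguous / length(idx))
  })

  run_stage("summarize", function() {
    gts <- if (!is.null(cohort)) cohort$genotypes
    else if (!is.null(config$inputs$genotypes))
      readGenotypesTsv(config$inputs$genotypes)
    else stop("no genotypes available (enable synth or provide inputs$genotypes)")
    s <- summarizeCohort(gts)
    status <- table(vapply(gts, classifyGenotype, character(1)))
    jsonlite::write_json(s[setdiff(names(s),
                                   c("structureFreq", "repeatCountFreq"))],
                         file.path(config$outdir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    c(s[c("nIndividuals", "nDistinctAlleles", "heterozygosityPercent",
          "carrierAllelePercent", "carrierPercentWhole", "minRepeats",
          "maxRepeats")],
      list(affectionStatus = as.list(status)))
  })

  run_stage("haplotype", function() {
    gts <- if (!is.null(cohort)) cohort$genotypes
    else stop("haplotype stage requires the synth stage")
    panel <- defaultMarkerPanel()
    snp_ids <- panel$markerId[panel$type == "SNP"]
    gmat <- as.data.frame(t(vapply(gts, function(g) g@snpGenotypes,
                                   character(5))), stringsAsFactors = FALSE)
    colnames(gmat) <- snp_ids
    # repeat locus as categorical marker, in panel (plus-strand) order
    rep_gt <- vapply(gts, function(g) {
      p <- sort(vapply(alleles(g), alleleName, character(1)))
      paste(p, collapse = "/")
    }, character(1))
    gmat <- cbind(gmat[, 1:2, drop = FALSE], REPEAT = rep_gt,
                  gmat[, 3:5, drop = FALSE], stringsAsFactors = FALSE)
    em <- emPhase(gmat)
    haps <- do.call(rbind, strsplit(c(em$phase$hap1, em$phase$hap2), "|",
                                    fixed = TRUE))
    colnames(haps) <- c(snp_ids[1:2], "REPEAT", snp_ids[3:5])
    ld <- pairwiseDprime(haps)
    utils::write.table(
      data.frame(sample = vapply(gts, sampleId, character(1)),
                 hap1 = em$phase$hap1, hap2 = em$phase$hap2,
                 posterior = em$phase$posterior),
      file.path(config$outdir, "haplotypes.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    list(nHaplotypes = nrow(em$haplotypes),
         topHaplotypes = utils::head(em$haplotypes, 5),
         converged = em$converged, iterations = em$iterations,
         maxDprime = ld$maxDprime, ldTable = ld$table)
  })

  run_stage("expression", function() {
    lds <- generateLuciferaseDataset(seed = config$seed + 1L)
    writePlateTsv(lds$wells, file.path(config$outdir, "plate.tsv"))
    act <- relativeActivity(lds$wells)
    act2 <- act[!(act$construct_id %in% c("NEGATIVE", "POSITIVE")), ]
    act2$structure <- lapply(act2$construct_id, parseAlleleName)
    fit <- fitMotifModel(act2)
    ratios <- lds$wells[!(lds$wells$construct_id %in%
                            c("NEGATIVE", "POSITIVE")), ]
    groups <- split(100 * (ratios$firefly / ratios$renilla - 0.02) / 1.00,
                    ratios$construct_id)
    aov_res <- oneWayAnovaTukey(groups, alpha = config$alpha)
    list(activities = act, intercept = fit$intercept, betas = fit$betas,
         trueBetas = lds$groundTruth$betas,
         anovaF = aov_res$F, anovaP = aov_res$p,
         nSignificantPairs = sum(aov_res$tukey$significant))
  })

  run_stage("methylation", function() {
    ref16 <- composeAllele(parseAlleleName("CACA20+13xCGCA20+CACA20+CA18"))
    ref8 <- composeAllele(parseAlleleName("5xCACA20+CA18+CACA20+CA18"))
    rcps <- generateBisulfiteDataset(ref16, perCpgProb = 0.017,
                                     nSamples = 6L, seed = config$seed + 2L)
    ctrl <- generateBisulfiteDataset(ref8, perCpgProb = 0.028,
                                     nSamples = 7L, seed = config$seed + 3L)
    csA <- filterClones(rcps$clones, ref16)
    csB <- filterClones(ctrl$clones, ref8)
    qA <- quantifyMethylation(csA); qB <- quantifyMethylation(csB)
    test <- methylationGroupTest(cloneCalls(csA)[cloneTable(csA)$kept, ],
                                 cloneCalls(csB)[cloneTable(csB)$kept, ],
                                 alpha = config$alpha)
    list(cpgGain = countCpg(ref16) - countCpg(ref8),
         rcpsGlobalPercent = 100 * qA$global,
         controlGlobalPercent = 100 * qB$global,
         fisherP = test$p, significant = test$significant)
  })

  report$provenance <- list(
    seed = config$seed,
    stages = st,
    configHash = .config_hash(config),
    package = as.character(utils::packageVersion("repeatlens")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(.jsonable(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(report)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$outdir <- NULL  # location must not change the hash
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

## drop non-serializable members (model fits) before JSON serialization
.jsonable <- function(x) {
  if (is.list(x)) {
    x <- x[!vapply(x, function(e) inherits(e, c("aov", "lm")), logical(1))]
    lapply(x, .jsonable)
  } else x
}
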