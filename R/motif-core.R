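## Exact motif tiling of repeat-array sequences and allele classification.
##
## Tiling over the default alphabet is unique because all three motifs share
## the 10-nt head TCGGCAGCGG and end in GG, so motif boundaries can only fall
## at GG|TC junctions. The decomposer nevertheless backtracks, which keeps it
## correct for user alphabets where greedy longest-match can fail.

#' Compose the DNA sequence of an allele structure
#'
#' Concatenates the motif sequences in order, splicing any insertion segments
#' immediately after the motif they follow.
#'
#' @param structure An \linkS4class{AlleleStructure}.
#' @param alphabet A \linkS4class{MotifAlphabet} resolving every motif id.
#' @return Uppercase DNA string.
#' @examples
#' composeAllele(alleleStructure(c("CA18")))
#' @export
composeAllele <- function(structure, alphabet = defaultMotifAlphabet()) {
  seqs <- alphabet@entries
  unknown <- setdiff(structure@motifs, names(seqs))
  if (length(unknown))
    stop("unknown motif id(s): ", paste(unknown, collapse = ", "))
  ins <- structure@insertions
  if (nrow(ins) > 0L &&
      (any(ins$afterIndex < 0L) || any(ins$afterIndex >= length(structure@motifs))))
    stop("insertion afterIndex out of range")
  pieces <- character(0)
  for (i in seq_along(structure@motifs)) {
    pieces <- c(pieces, seqs[[structure@motifs[i]]])
    hit <- ins$sequence[ins$afterIndex == (i - 1L)]
    if (length(hit)) pieces <- c(pieces, hit)
  }
  paste(pieces, collapse = "")
}

.contains_motif <- function(segment, alphabet) {
  any(vapply(alphabet@entries, function(m) grepl(m, segment, fixed = TRUE),
             logical(1)))
}

#' Decompose a repeat-region sequence into motifs
#'
#' Finds the exact tiling of \code{dna} by alphabet motifs using an anchored
#' scan with backtracking. With \code{allowInsertions}, non-motif segments of
#' up to \code{maxInsertionLen} nt are permitted between motifs (and after the
#' last motif); such alleles are atypical and are flagged by
#' \code{\link{classifyAllele}}.
#'
#' @param dna Uppercase ACGT string.
#' @param alphabet A \linkS4class{MotifAlphabet}.
#' @param allowInsertions Permit non-motif segments between motifs.
#' @param maxInsertionLen Maximum insertion segment length (nt). The default
#'   accommodates the 12- and 20-nt inserted segments seen in atypical
#'   population alleles.
#' @param autoOrient Also try the reverse complement and keep whichever
#'   orientation tiles (the strand convention of a user's input is not fixed).
#' @return An \linkS4class{AlleleStructure}.
#' @examples
#' decomposeSequence(strrep("TCGGCAGCGGCAGCGAGG", 2))
#' @export
decomposeSequence <- function(dna, alphabet = defaultMotifAlphabet(),
                              allowInsertions = FALSE, maxInsertionLen = 20L,
                              autoOrient = FALSE) {
  if (!.is_dna(dna)) stop("dna must be a non-empty uppercase ACGT string")
  res <- .decompose_try(dna, alphabet, allowInsertions, maxInsertionLen)
  if (is.null(res$structure) && autoOrient) {
    rc <- .revcomp(dna)
    res_rc <- .decompose_try(rc, alphabet, allowInsertions, maxInsertionLen)
    if (!is.null(res_rc$structure)) return(res_rc$structure)
  }
  if (is.null(res$structure))
    stop(sprintf("sequence cannot be tiled by the alphabet (first failure at offset %d)",
                 res$failOffset))
  res$structure
}

.revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

## Depth-first tiling with backtracking. Motifs tried longest-first; insertion
## segments only where no motif fits, shortest-first, and never containing a
## full motif. Returns the first complete tiling (unique for the default
## alphabet) or the deepest offset reached.
.decompose_try <- function(dna, alphabet, allowInsertions, maxInsertionLen) {
  L <- nchar(dna)
  seqs <- alphabet@entries[order(-nchar(alphabet@entries))]
  lens <- nchar(seqs)
  best_fail <- 0L

  search <- function(pos, ids, ins) {
    # pos: 0-based offset already consumed
    if (pos == L) {
      if (length(ids) == 0L) return(NULL)  # pure-insertion input is not an allele
      return(list(ids = ids, ins = ins))
    }
    if (pos > best_fail) best_fail <<- pos
    for (k in seq_along(seqs)) {
      w <- lens[k]
      if (pos + w <= L && substr(dna, pos + 1L, pos + w) == seqs[[k]]) {
        r <- search(pos + w, c(ids, names(seqs)[k]), ins)
        if (!is.null(r)) return(r)
      }
    }
    if (allowInsertions && length(ids) > 0L) {
      for (j in seq_len(min(maxInsertionLen, L - pos))) {
        seg <- substr(dna, pos + 1L, pos + j)
        if (.contains_motif(seg, alphabet)) break
        if (pos + j == L) {
          r <- search(pos + j, ids,
                      rbind(ins, data.frame(afterIndex = length(ids) - 1L,
                                            sequence = seg)))
          if (!is.null(r)) return(r)
          next
        }
        # insertion must be followed by a motif
        follows <- any(vapply(seq_along(seqs), function(k) {
          w <- lens[k]
          pos + j + w <= L && substr(dna, pos + j + 1L, pos + j + w) == seqs[[k]]
        }, logical(1)))
        if (follows) {
          r <- search(pos + j, ids,
                      rbind(ins, data.frame(afterIndex = length(ids) - 1L,
                                            sequence = seg)))
          if (!is.null(r)) return(r)
        }
      }
    }
    NULL
  }

  hit <- search(0L, character(0), .empty_insertions())
  if (is.null(hit)) return(list(structure = NULL, failOffset = best_fail))
  list(structure = alleleStructure(hit$ids, hit$ins), failOffset = NA_integer_)
}

## ---------------------------------------------------------------------------
## Nomenclature
## ---------------------------------------------------------------------------

#' Allele-structure nomenclature
#'
#' Canonical string form of an allele: motif tokens joined by "+", runs
#' collapsed as e.g. "3xCACA20", insertion segments as "[ins:SEQ]" placed in
#' sequence order. \code{alleleName} and \code{parseAlleleName} are mutual
#' inverses.
#'
#' @param structure An \linkS4class{AlleleStructure}.
#' @return \code{alleleName}: a single string.
#' @examples
#' alleleName(alleleStructure(c("CACA20", "CACA20", "CACA20", "CA18")))
#' parseAlleleName("3xCACA20+CA18")
#' @export
alleleName <- function(structure) {
  m <- structure@motifs
  ins <- structure@insertions
  if (length(m) == 0L) return("(empty)")
  tokens <- character(0)
  run_start <- 1L
  flush_run <- function(from, to) {
    n <- to - from + 1L
    tok <- if (n > 1L) sprintf("%dx%s", n, m[from]) else m[from]
    tokens <<- c(tokens, tok)
  }
  i <- 1L
  while (i <= length(m)) {
    # a run breaks at a motif change or at an insertion boundary
    j <- i
    while (j < length(m) && m[j + 1L] == m[i] &&
           !any(ins$afterIndex == (j - 1L))) j <- j + 1L
    flush_run(i, j)
    hit <- ins$sequence[ins$afterIndex == (j - 1L)]
    for (s in hit) tokens <- c(tokens, sprintf("[ins:%s]", s))
    i <- j + 1L
  }
  paste(tokens, collapse = "+")
}

#' @rdname alleleName
#' @param name A nomenclature string.
#' @export
parseAlleleName <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a single non-empty string")
  toks <- strsplit(name, "+", fixed = TRUE)[[1]]
  motifs <- character(0)
  ins <- .empty_insertions()
  for (tok in toks) {
    if (grepl("^\\[ins:[ACGT]+\\]$", tok)) {
      if (length(motifs) == 0L)
        stop("insertion segment before any motif in '", name, "'")
      seg <- sub("^\\[ins:([ACGT]+)\\]$", "\\1", tok)
      ins <- rbind(ins, data.frame(afterIndex = length(motifs) - 1L,
                                   sequence = seg))
    } else if (grepl("^([0-9]+)x(.+)$", tok)) {
      n <- as.integer(sub("^([0-9]+)x.*$", "\\1", tok))
      id <- sub("^[0-9]+x", "", tok)
      motifs <- c(motifs, rep(id, n))
    } else if (nzchar(tok)) {
      motifs <- c(motifs, tok)
    } else {
      stop("empty token in nomenclature string '", name, "'")
    }
  }
  alleleStructure(motifs, ins)
}

## ---------------------------------------------------------------------------
## CpG accounting
## ---------------------------------------------------------------------------

#' Count CpG dinucleotides
#'
#' Number of CG dinucleotides in a DNA string or in the composed sequence of
#' an allele structure. Junction CpGs between adjacent motifs are counted
#' (none arise with the default alphabet, whose motifs end in G and start
#' with T).
#'
#' @param x A DNA string or an \linkS4class{AlleleStructure}.
#' @param alphabet Alphabet used to compose a structure.
#' @return Integer CpG count.
#' @examples
#' countCpg("TCGGCAGCGGCAGCGAGG")  # 3
#' @export
setGeneric("countCpg", function(x, alphabet = defaultMotifAlphabet())
  standardGeneric("countCpg"))

#' @rdname countCpg
setMethod("countCpg", "character", function(x, alphabet) {
  if (!.is_dna(x)) stop("x must be a non-empty uppercase ACGT string")
  length(cpgSites(x))
})

#' @rdname countCpg
setMethod("countCpg", "AlleleStructure", function(x, alphabet) {
  countCpg(composeAllele(x, alphabet))
})

#' 0-based positions of CpG cytosines in a sequence
#' @param dna Uppercase DNA string.
#' @return Integer vector of 0-based offsets of the C of each CpG.
#' @export
cpgSites <- function(dna) {
  hits <- gregexpr("(?=CG)", dna, perl = TRUE)[[1]]
  as.integer(hits[hits > 0] - 1L)
}

## ---------------------------------------------------------------------------
## Classification
## ---------------------------------------------------------------------------

#' Classify a repeat allele
#'
#' Applies the population/disease allele taxonomy: alleles with at least
#' \code{minPathogenicRepeats} repeats and at least one disease-associated
#' CGCA20 motif are pathogenic candidates; shorter CGCA20-bearing alleles are
#' carriers of the disease motif; insertion-bearing alleles are atypical;
#' everything else is control-typical. Thresholds are exposed because the
#' boundary zone (13 repeats, observed in neither patients nor controls) is
#' indeterminate; see \code{\link{summarizeCohort}}.
#'
#' @param structure An \linkS4class{AlleleStructure}.
#' @param minPathogenicRepeats Pathogenic-candidate repeat-count threshold
#'   (default 14, the smallest patient allele).
#' @param diseaseMotif Motif id of the disease-associated motif.
#' @return One of \code{"PATHOGENIC_CANDIDATE"}, \code{"DISEASE_MOTIF_CARRIER"},
#'   \code{"ATYPICAL_INSERTION"}, \code{"CONTROL_TYPICAL"}.
#' @export
classifyAllele <- function(structure, minPathogenicRepeats = 14L,
                           diseaseMotif = "CGCA20") {
  n <- repeatCount(structure)
  has_disease <- any(structure@motifs == diseaseMotif)
  if (has_disease && n >= minPathogenicRepeats) return("PATHOGENIC_CANDIDATE")
  if (has_disease) return("DISEASE_MOTIF_CARRIER")
  if (hasInsertions(structure)) return("ATYPICAL_INSERTION")
  "CONTROL_TYPICAL"
}

#' Classify a diploid genotype under the recessive model
#'
#' The syndrome is autosomal recessive: an individual is AFFECTED only when
#' both alleles are pathogenic candidates, a CARRIER with exactly one, and
#' UNAFFECTED otherwise. Symmetric in the two alleles.
#'
#' @param g A \linkS4class{DiploidGenotype}.
#' @param ... Passed to \code{\link{classifyAllele}}.
#' @return One of \code{"AFFECTED"}, \code{"CARRIER"}, \code{"UNAFFECTED"}.
#' @export
classifyGenotype <- function(g, ...) {
  k <- sum(vapply(alleles(g), classifyAllele, character(1), ...) ==
             "PATHOGENIC_CANDIDATE")
  c("UNAFFECTED", "CARRIER", "AFFECTED")[k + 1L]
}

## ---------------------------------------------------------------------------
## Cohort summary
## ---------------------------------------------------------------------------

#' Summarize a cohort of diploid repeat genotypes
#'
#' Tabulates the allele spectrum of a cohort: distinct structures, per-structure
#' and per-repeat-count allele frequencies, heterozygosity, the fraction of
#' alleles carrying the disease-associated motif, and the repeat-count range.
#' Percentages are reported to 2 decimals; \code{carrierPercentWhole} rounds
#' the carrier-allele fraction to the nearest whole percent for headline
#' reporting.
#'
#' @param genotypes List of \linkS4class{DiploidGenotype} objects.
#' @param diseaseMotif Disease-associated motif id.
#' @return A list with elements \code{nIndividuals}, \code{nAlleles},
#'   \code{nDistinctAlleles}, \code{structureFreq} (data.frame),
#'   \code{repeatCountFreq} (data.frame), \code{heterozygosity},
#'   \code{heterozygosityPercent}, \code{carrierAlleleFraction},
#'   \code{carrierAllelePercent}, \code{carrierPercentWhole},
#'   \code{minRepeats}, \code{maxRepeats}, \code{nIndeterminateZone}.
#' @export
summarizeCohort <- function(genotypes, diseaseMotif = "CGCA20") {
  if (length(genotypes) == 0L) stop("summarizeCohort requires at least one genotype")
  alle <- unlist(lapply(genotypes, alleles), recursive = FALSE)
  names_ <- vapply(alle, alleleName, character(1))
  counts <- vapply(alle, repeatCount, integer(1))
  carrier <- vapply(alle, function(a) any(a@motifs == diseaseMotif), logical(1))
  het <- vapply(genotypes, isHeterozygous, logical(1))

  st <- sort(table(names_), decreasing = TRUE)
  structureFreq <- data.frame(structure = names(st), count = as.integer(st),
                              percent = round(100 * as.integer(st) / length(alle), 2),
                              stringsAsFactors = FALSE)
  rc <- table(counts)
  repeatCountFreq <- data.frame(repeats = as.integer(names(rc)),
                                count = as.integer(rc),
                                percent = round(100 * as.integer(rc) / length(alle), 2))
  frac <- mean(carrier)
  list(
    nIndividuals = length(genotypes),
    nAlleles = length(alle),
    nDistinctAlleles = length(st),
    structureFreq = structureFreq,
    repeatCountFreq = repeatCountFreq,
    heterozygosity = mean(het),
    heterozygosityPercent = round(100 * mean(het), 2),
    carrierAlleleFraction = frac,
    carrierAllelePercent = round(100 * frac, 2),
    carrierPercentWhole = round(100 * frac),
    minRepeats = min(counts),
    maxRepeats = max(counts),
    nIndeterminateZone = sum(counts == 13L)
  )
}
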