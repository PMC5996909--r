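## Sequence-level heterozygote deconvolution.
##
## A heterozygous Sanger read of the repeat amplicon is modelled as the
## position-wise IUPAC union of the two allele amplicons, left-aligned at the
## sequencing primer (5') side. Deconvolution inverts that forward model
## exactly: it enumerates motif tilings compatible with the per-position IUPAC
## constraints for each allele, then scores candidate pairs against the
## forward model.

.IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
                 V = 7L, H = 11L, D = 13L, B = 14L, N = 15L)

.BITS_TO_CODE <- local({
  v <- character(15)
  v[.IUPAC_BITS] <- names(.IUPAC_BITS)
  v
})

.seq_bits <- function(x) {
  b <- .IUPAC_BITS[strsplit(x, "")[[1]]]
  if (anyNA(b)) stop("non-IUPAC character in sequence")
  unname(b)
}

#' Superpose two allele amplicons into a mixed IUPAC sequence
#'
#' Forward model for a heterozygote's mixed sequencing read: both amplicons are
#' aligned at their 5' ends and each position becomes the IUPAC union of the
#' bases present. Beyond the shorter amplicon, codes come from the longer
#' alone. Deterministic.
#'
#' @param seq1,seq2 Uppercase ACGT amplicon sequences (flanks included, if
#'   any).
#' @param flank5,flank3 The shared amplicon flanks (recorded for
#'   deconvolution; both sequences must contain them).
#' @return A \linkS4class{MixedSequence}.
#' @examples
#' mixedIupac(superpose("ACGT", "ACGA"))  # "ACGW"
#' @export
superpose <- function(seq1, seq2, flank5 = "", flank3 = "") {
  for (s in c(seq1, seq2))
    if (grepl("[^ACGT]", s) || !nzchar(s)) stop("amplicons must be non-empty ACGT")
  b1 <- .seq_bits(seq1); b2 <- .seq_bits(seq2)
  L <- max(length(b1), length(b2))
  length(b1) <- L; length(b2) <- L
  b1[is.na(b1)] <- 0L; b2[is.na(b2)] <- 0L
  u <- bitwOr(b1, b2)
  new("MixedSequence", iupac = paste(.BITS_TO_CODE[u], collapse = ""),
      flank5 = flank5, flank3 = flank3)
}

#' Deconvolve a mixed heterozygote sequence into allele-structure pairs
#'
#' Exact inversion of \code{\link{superpose}}: enumerates, by depth-first
#' search with backtracking, every motif tiling whose bases are compatible
#' with the IUPAC code at each position (branch-and-bound over motif choices),
#' pairs compatible tilings, and keeps pairs whose forward superposition
#' matches the mixed sequence within \code{budget} mismatched positions
#' (default 0, exact). All zero-mismatch candidates are reported; genuine
#' structural ambiguities are enumerated, never hidden.
#'
#' @param mixed A \linkS4class{MixedSequence}.
#' @param alphabet A \linkS4class{MotifAlphabet}.
#' @param maxRepeats Upper bound on motifs per allele (default 20).
#' @param budget Mismatch budget (default 0; small values mimic base-call
#'   noise).
#' @param nodeBudget Abort threshold on search states.
#' @return A list with \code{candidates} (data.frame: \code{allele1},
#'   \code{allele2} nomenclature strings with \code{allele1 <= allele2},
#'   \code{mismatches}), sorted by mismatches then lexicographically, and
#'   \code{exhaustive} (FALSE when the node budget was hit).
#' @export
deconvolve <- function(mixed, alphabet = defaultMotifAlphabet(),
                       maxRepeats = 20L, budget = 0L, nodeBudget = 200000L) {
  stopifnot(is(mixed, "MixedSequence"))
  mb <- .seq_bits(mixed@iupac)
  L <- length(mb)
  f5 <- mixed@flank5; f3 <- mixed@flank3
  n5 <- nchar(f5); n3 <- nchar(f3)
  b5 <- if (n5) .seq_bits(f5) else integer(0)
  b3 <- if (n3) .seq_bits(f3) else integer(0)

  seqs <- alphabet@entries
  mseq_bits <- lapply(seqs, .seq_bits)
  mlens <- vapply(mseq_bits, length, integer(1))

  nodes <- 0L
  overflow <- FALSE

  # cost of placing base bits bv at mixed positions pos..pos+len-1
  .cost <- function(bv, at) {
    sum(bitwAnd(bv, mb[at]) != bv)
  }

  tilings <- list()
  # DFS over one allele's tiling; l = repeat-region length consumed,
  # mis = accumulated incompatibility cost for this allele alone
  dfs <- function(l, ids, mis) {
    nodes <<- nodes + 1L
    if (nodes > nodeBudget) { overflow <<- TRUE; return(invisible()) }
    end <- n5 + l + n3
    if (end <= L && length(ids) > 0L) {
      mis3 <- if (n3) .cost(b3, (n5 + l + 1L):end) else 0L
      if (mis + mis3 <= budget)
        tilings[[length(tilings) + 1L]] <<- list(ids = ids, len = l)
    }
    if (length(ids) >= maxRepeats || overflow) return(invisible())
    for (k in seq_along(mseq_bits)) {
      w <- mlens[k]
      if (n5 + l + w + n3 > L) next
      c_k <- .cost(mseq_bits[[k]], (n5 + l + 1L):(n5 + l + w))
      if (mis + c_k <= budget)
        dfs(l + w, c(ids, names(seqs)[k]), mis + c_k)
    }
    invisible()
  }

  mis5 <- if (n5) .cost(b5, seq_len(n5)) else 0L
  if (mis5 <= budget) dfs(0L, character(0), mis5)

  if (length(tilings) == 0L) {
    return(list(candidates = data.frame(allele1 = character(0),
                                        allele2 = character(0),
                                        mismatches = integer(0)),
                exhaustive = !overflow))
  }

  ampbits <- lapply(tilings, function(t)
    c(b5, unlist(mseq_bits[t$ids], use.names = FALSE), b3))
  nom <- vapply(tilings, function(t) alleleName(alleleStructure(t$ids)),
                character(1))
  tot <- vapply(ampbits, length, integer(1))

  rows <- list()
  for (i in seq_along(tilings)) {
    for (j in i:length(tilings)) {
      if (max(tot[i], tot[j]) != L) next
      u1 <- ampbits[[i]]; u2 <- ampbits[[j]]
      length(u1) <- L; length(u2) <- L
      u1[is.na(u1)] <- 0L; u2[is.na(u2)] <- 0L
      mis <- sum(bitwOr(u1, u2) != mb)
      if (mis <= budget) {
        pair <- sort(c(nom[i], nom[j]))
        rows[[length(rows) + 1L]] <- data.frame(
          allele1 = pair[1], allele2 = pair[2], mismatches = mis,
          stringsAsFactors = FALSE)
      }
    }
  }
  cand <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(allele1 = character(0), allele2 = character(0),
               mismatches = integer(0))
  cand <- cand[order(cand$mismatches, cand$allele1, cand$allele2), ,
               drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, exhaustive = !overflow)
}
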