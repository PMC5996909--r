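## In-silico bisulfite conversion, clone filtering and methylation calling.
##
## Only the top (motif-sense) strand is modelled; CpG methylation is treated
## as symmetric, as clones of PCR products do not track strand. Clone filters
## follow the published thresholds: conversion rate >= 95%, sequence identity
## >= 90%, N at cytosine positions <= 20%, gaps <= 20%. Identity is computed
## over gap-free, N-free aligned columns and excludes C/T differences at
## reference cytosines (the bisulfite-expected change -- including an
## unmethylated CpG read as T -- is not a mismatch); that convention is
## stated here because the reference tool's is unpublished.

#' Default bisulfite clone filter thresholds
#' @return Named list: \code{minConversion} 0.95, \code{minIdentity} 0.90,
#'   \code{maxNAtC} 0.20, \code{maxGaps} 0.20.
#' @export
defaultFilterParams <- function() {
  list(minConversion = 0.95, minIdentity = 0.90, maxNAtC = 0.20,
       maxGaps = 0.20)
}

#' Simulate bisulfite conversion of one clone read
#'
#' Non-CpG cytosines convert C -> T with probability
#' \code{conversionEfficiency}; CpG cytosines convert only when unmethylated
#' (also subject to the efficiency); all other bases are untouched.
#'
#' @param reference Uppercase ACGT reference sequence.
#' @param methylationStates Logical vector, one per CpG site of the
#'   reference (TRUE = methylated).
#' @param conversionEfficiency Probability in [0, 1] that an unprotected C
#'   converts.
#' @param seed Optional integer seed.
#' @return The converted read (character string).
#' @export
bisulfiteConvert <- function(reference, methylationStates,
                             conversionEfficiency = 1, seed = NULL) {
  if (!.is_dna(reference)) stop("reference must be uppercase ACGT")
  cpg <- cpgSites(reference)
  if (length(methylationStates) != length(cpg))
    stop("methylationStates must have one entry per CpG site (",
         length(cpg), ")")
  if (conversionEfficiency < 0 || conversionEfficiency > 1)
    stop("conversionEfficiency must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  chars <- strsplit(reference, "")[[1]]
  c_pos <- which(chars == "C")
  cpg_c <- cpg + 1L
  for (p in c_pos) {
    is_cpg <- p %in% cpg_c
    protected <- is_cpg && methylationStates[match(p, cpg_c)]
    if (!protected && stats::runif(1) < conversionEfficiency)
      chars[p] <- "T"
  }
  paste(chars, collapse = "")
}

## Global alignment of a clone to the reference with match +1, mismatch -1,
## gap -2; returns aligned pattern/subject strings.
.align_clone <- function(read, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(reference),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  list(read = as.character(Biostrings::pattern(aln)),
       ref = as.character(Biostrings::subject(aln)))
}

.clone_stats <- function(read, reference, cpg0) {
  al <- .align_clone(read, reference)
  rd <- strsplit(al$read, "")[[1]]
  rf <- strsplit(al$ref, "")[[1]]
  ncol_ <- length(rd)
  cpg_c <- cpg0 + 1L  # 1-based reference positions of CpG cytosines

  ref_pos <- cumsum(rf != "-")          # reference coordinate per column
  is_ref_c <- rf == "C"
  is_cpg_col <- is_ref_c & ref_pos %in% cpg_c
  is_nonCpG_c <- is_ref_c & !is_cpg_col

  # conversion: fraction of non-CpG reference Cs read as T (of those read
  # as C or T)
  conv_den <- sum(is_nonCpG_c & rd %in% c("C", "T"))
  conv <- if (conv_den == 0L) 1 else
    sum(is_nonCpG_c & rd == "T") / conv_den

  # N at reference cytosine positions
  c_cols <- sum(is_ref_c)
  nAtC <- if (c_cols == 0L) 0 else sum(is_ref_c & rd == "N") / c_cols

  gapFrac <- sum(rd == "-" | rf == "-") / ncol_

  # identity over gap-free, N-free columns; C/T at any reference C is the
  # bisulfite-expected change, not a mismatch (an unmethylated CpG reads T)
  comp <- rd != "-" & rf != "-" & rd != "N"
  match_ <- comp & (rd == rf | (is_ref_c & rd == "T"))
  ident <- if (sum(comp) == 0L) 0 else sum(match_) / sum(comp)

  # per-CpG methylation calls: 1 = C retained, 0 = converted to T, NA else
  calls <- rep(NA_real_, length(cpg_c))
  for (k in seq_along(cpg_c)) {
    col <- which(ref_pos == cpg_c[k] & rf != "-")
    if (length(col) == 1L) {
      b <- rd[col]
      calls[k] <- if (b == "C") 1 else if (b == "T") 0 else NA_real_
    }
  }
  list(conversion = conv, identity = ident, nAtC = nAtC, gapFrac = gapFrac,
       calls = calls)
}

#' Filter bisulfite clones against a reference allele
#'
#' Aligns each clone to the (unconverted) reference with a global alignment
#' (match +1, mismatch -1, gap -2), computes per-clone conversion rate,
#' identity, N-at-cytosine fraction and gap fraction, and keeps clones
#' meeting all four thresholds. Every violated threshold is recorded in
#' \code{failReasons}; clones below 50% identity are flagged
#' \code{"unaligned"} and excluded.
#'
#' @param clones Character vector of clone reads (may contain N).
#' @param reference Uppercase ACGT reference allele sequence.
#' @param filterParams List as from \code{\link{defaultFilterParams}}.
#' @return A \linkS4class{CloneSet}.
#' @export
filterClones <- function(clones, reference,
                         filterParams = defaultFilterParams()) {
  if (!.is_dna(reference)) stop("reference must be uppercase ACGT")
  cpg0 <- cpgSites(reference)
  stats_ <- lapply(clones, function(rd) .clone_stats(rd, reference, cpg0))

  rows <- do.call(rbind, lapply(seq_along(clones), function(i) {
    s <- stats_[[i]]
    reasons <- character(0)
    if (s$identity < 0.5) {
      reasons <- "unaligned"
    } else {
      if (s$conversion < filterParams$minConversion)
        reasons <- c(reasons, "conversion")
      if (s$identity < filterParams$minIdentity)
        reasons <- c(reasons, "identity")
      if (s$nAtC > filterParams$maxNAtC) reasons <- c(reasons, "n_at_c")
      if (s$gapFrac > filterParams$maxGaps) reasons <- c(reasons, "gaps")
    }
    data.frame(read = clones[i], kept = length(reasons) == 0L,
               failReasons = paste(reasons, collapse = ","),
               conversion = s$conversion, identity = s$identity,
               nAtC = s$nAtC, gapFrac = s$gapFrac, stringsAsFactors = FALSE)
  }))
  calls <- do.call(rbind, lapply(stats_, `[[`, "calls"))
  if (is.null(calls)) calls <- matrix(numeric(0), 0, length(cpg0))
  rownames(calls) <- paste0("clone", seq_len(nrow(rows)))
  new("CloneSet", clones = rows, reference = reference,
      filterParams = filterParams, calls = calls,
      cpgPositions = cpg0)
}

#' Quantify methylation over the kept clones of a CloneSet
#'
#' Per-CpG methylation is the fraction of kept clones with a retained C at
#' that site; the global fraction is methylated calls / total readable calls
#' over kept clones (the call-count-weighted mean of the per-CpG fractions).
#'
#' @param cloneSet A \linkS4class{CloneSet}.
#' @return List with \code{perCpg} (data.frame: position, methylated, calls,
#'   fraction), \code{global}, \code{nMethylated}, \code{nCalls},
#'   \code{nKept}.
#' @export
quantifyMethylation <- function(cloneSet) {
  keep <- cloneSet@clones$kept
  if (!any(keep)) stop("no clones pass the filters")
  calls <- cloneSet@calls[keep, , drop = FALSE]
  meth <- colSums(calls == 1, na.rm = TRUE)
  tot <- colSums(!is.na(calls))
  perCpg <- data.frame(position = cloneSet@cpgPositions,
                       methylated = as.integer(meth),
                       calls = as.integer(tot),
                       fraction = ifelse(tot > 0, meth / tot, NA_real_))
  list(perCpg = perCpg,
       global = sum(meth) / sum(tot),
       nMethylated = sum(meth), nCalls = sum(tot), nKept = sum(keep))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (relative tie
#' tolerance 1e-7).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))  # 1
#' @export
fisherExact2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2L))
    stop("table must be a 2x2 matrix")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]
  m <- sum(table[1, ])          # row-1 margin
  n <- sum(table[2, ])
  k <- sum(table[, 1])          # col-1 margin
  if (m + n == 0) stop("empty table")
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Pooled and per-CpG group comparison of methylation calls
#'
#' Default mode pools methylated/unmethylated CpG calls per group into one
#' 2x2 Fisher test (the global low-methylation comparison); per-CpG mode
#' tests each site's 2x2 table with Bonferroni correction.
#'
#' @param callsA,callsB Clone x CpG call matrices (from
#'   \code{\link{cloneCalls}}, kept clones) for the two groups.
#' @param perCpg Also run per-CpG tests.
#' @param alpha Significance level (default 0.05).
#' @return List with \code{table} (pooled 2x2), \code{p}, \code{significant},
#'   group fractions, and optionally \code{perCpgTests}.
#' @export
methylationGroupTest <- function(callsA, callsB, perCpg = FALSE,
                                 alpha = 0.05) {
  mA <- sum(callsA == 1, na.rm = TRUE); uA <- sum(callsA == 0, na.rm = TRUE)
  mB <- sum(callsB == 1, na.rm = TRUE); uB <- sum(callsB == 0, na.rm = TRUE)
  tab <- matrix(c(mA, uA, mB, uB), 2, byrow = TRUE,
                dimnames = list(c("groupA", "groupB"),
                                c("methylated", "unmethylated")))
  p <- fisherExact2x2(tab)
  out <- list(table = tab, p = p, significant = p < alpha,
              fractionA = mA / (mA + uA), fractionB = mB / (mB + uB))
  if (perCpg) {
    if (ncol(callsA) != ncol(callsB))
      stop("call matrices must cover the same CpG sites")
    ps <- vapply(seq_len(ncol(callsA)), function(j) {
      t2 <- matrix(c(sum(callsA[, j] == 1, na.rm = TRUE),
                     sum(callsA[, j] == 0, na.rm = TRUE),
                     sum(callsB[, j] == 1, na.rm = TRUE),
                     sum(callsB[, j] == 0, na.rm = TRUE)), 2, byrow = TRUE)
      fisherExact2x2(t2)
    }, numeric(1))
    out$perCpgTests <- data.frame(
      cpg = seq_len(ncol(callsA)), p = ps,
      pBonferroni = pmin(1, ps * ncol(callsA)),
      significant = pmin(1, ps * ncol(callsA)) < alpha)
  }
  out
}
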