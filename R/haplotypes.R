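## Pairwise linkage disequilibrium and EM haplotype phasing over the
## five SNPs flanking the repeat locus plus the repeat allele itself
## (treated as a categorical marker).

#' The default flanking-marker panel
#'
#' Marker order follows the plus-strand genomic convention:
#' SNP1 (rs11150824) - SNP2 (rs2289534) - repeat locus - SNP3 (rs3829612) -
#' SNP4 (rs10782008) - SNP5 (rs12943620).
#'
#' @return data.frame with columns \code{markerId} and \code{type}
#'   (\code{"SNP"} or \code{"REPEAT_LOCUS"}).
#' @export
defaultMarkerPanel <- function() {
  data.frame(
    markerId = c("rs11150824", "rs2289534", "REPEAT", "rs3829612",
                 "rs10782008", "rs12943620"),
    type = c("SNP", "SNP", "REPEAT_LOCUS", "SNP", "SNP", "SNP"),
    stringsAsFactors = FALSE)
}

#' Pairwise linkage disequilibrium D and D'
#'
#' From a 2x2 table of haplotype counts (rows = alleles A/a at locus 1,
#' columns = alleles B/b at locus 2): D = pAB - pA pB and D' = |D| / Dmax,
#' where Dmax = min(pA pb, pa pB) for D > 0 and min(pA pB, pa pb) for D < 0.
#'
#' @param hapCounts 2x2 numeric matrix of haplotype counts.
#' @return List with \code{D}, \code{Dprime}, and \code{alleleFreqs}
#'   (pA, pa, pB, pb).
#' @examples
#' dPrime(matrix(c(50, 0, 0, 50), 2))  # complete LD, D' = 1
#' @export
dPrime <- function(hapCounts) {
  if (!is.matrix(hapCounts) || !all(dim(hapCounts) == 2L))
    stop("hapCounts must be a 2x2 matrix")
  if (any(hapCounts < 0) || sum(hapCounts) == 0)
    stop("hapCounts must be non-negative with at least one haplotype")
  n <- sum(hapCounts)
  p <- hapCounts / n
  pA <- sum(p[1, ]); pa <- 1 - pA
  pB <- sum(p[, 1]); pb <- 1 - pB
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1)
    stop("LD is undefined at a monomorphic locus")
  D <- p[1, 1] - pA * pB
  Dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  Dp <- if (D == 0) 0 else abs(D) / Dmax
  list(D = D, Dprime = Dp,
       alleleFreqs = c(pA = pA, pa = pa, pB = pB, pb = pb))
}

## ---------------------------------------------------------------------------
## EM haplotype phasing
## ---------------------------------------------------------------------------

.geno_pairs_for_individual <- function(geno_row, locus_alleles) {
  # per-locus ordered allele pairs compatible with the observation
  per_locus <- vector("list", length(geno_row))
  for (j in seq_along(geno_row)) {
    g <- geno_row[[j]]
    if (is.na(g)) {
      al <- locus_alleles[[j]]
      per_locus[[j]] <- expand.grid(a = al, b = al,
                                    stringsAsFactors = FALSE)
    } else {
      ab <- strsplit(g, "/", fixed = TRUE)[[1]]
      if (length(ab) != 2L)
        stop("genotype '", g, "' is not of the form a/b")
      if (ab[1] == ab[2]) {
        per_locus[[j]] <- data.frame(a = ab[1], b = ab[2],
                                     stringsAsFactors = FALSE)
      } else {
        per_locus[[j]] <- data.frame(a = c(ab[1], ab[2]),
                                     b = c(ab[2], ab[1]),
                                     stringsAsFactors = FALSE)
      }
    }
  }
  # cartesian product of per-locus choices -> ordered haplotype pairs
  idx <- expand.grid(lapply(per_locus, function(d) seq_len(nrow(d))))
  h1 <- apply(idx, 1, function(r)
    paste(vapply(seq_along(r), function(j) per_locus[[j]]$a[r[j]],
                 character(1)), collapse = "|"))
  h2 <- apply(idx, 1, function(r)
    paste(vapply(seq_along(r), function(j) per_locus[[j]]$b[r[j]],
                 character(1)), collapse = "|"))
  # unordered pairs
  key <- ifelse(h1 <= h2, paste(h1, h2, sep = "~"), paste(h2, h1, sep = "~"))
  keep <- !duplicated(key)
  data.frame(h1 = pmin(h1, h2)[keep], h2 = pmax(h1, h2)[keep],
             stringsAsFactors = FALSE)
}

#' EM haplotype frequency estimation and phasing
#'
#' Standard expectation-maximization over exhaustive haplotype-pair expansions
#' of unphased multi-locus genotypes (at most 8 loci). SNPs are biallelic;
#' the repeat locus enters as a categorical allele (its structure
#' nomenclature). Missing genotypes (NA) are marginalized over the alleles
#' observed at that locus. Initialization is uniform, so the run is
#' deterministic; the log-likelihood is non-decreasing across iterations.
#'
#' @param genotypes data.frame or matrix, individuals x loci, entries "a/b"
#'   (unordered) or NA.
#' @param maxIter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-8).
#' @return List with \code{haplotypes} (data.frame: \code{haplotype} as a
#'   "|"-joined allele vector, \code{frequency}), \code{loglik},
#'   \code{loglikTrace}, \code{iterations}, \code{converged}, and
#'   \code{phase}: per-individual most probable pair (ties broken toward the
#'   pair whose first haplotype has higher frequency) with its posterior.
#' @export
emPhase <- function(genotypes, maxIter = 1000L, tol = 1e-8) {
  genotypes <- as.data.frame(genotypes, stringsAsFactors = FALSE)
  if (ncol(genotypes) > 8L)
    stop("emPhase supports at most 8 loci (exhaustive expansion)")
  n <- nrow(genotypes)
  if (n == 0L) stop("no individuals")

  locus_alleles <- lapply(genotypes, function(col) {
    al <- unique(unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE)))
    if (length(al) == 0L) stop("a locus has no observed alleles")
    sort(al)
  })

  # collapse identical genotype rows
  rowkey <- apply(genotypes, 1, function(r) paste(r, collapse = ";"))
  ukeys <- unique(rowkey)
  counts <- as.numeric(table(rowkey)[ukeys])
  upairs <- lapply(match(ukeys, rowkey), function(i)
    .geno_pairs_for_individual(as.list(genotypes[i, , drop = FALSE]),
                               locus_alleles))
  for (i in seq_along(upairs)) if (nrow(upairs[[i]]) == 0L)
    stop("no compatible haplotype pair for individual ", ukeys[i])

  haps <- sort(unique(unlist(lapply(upairs, function(d) c(d$h1, d$h2)))))
  H <- length(haps)
  f <- rep(1 / H, H)
  names(f) <- haps

  loglik_trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    exp_counts <- setNames(numeric(H), haps)
    ll <- 0
    for (u in seq_along(upairs)) {
      d <- upairs[[u]]
      w <- f[d$h1] * f[d$h2] * ifelse(d$h1 == d$h2, 1, 2)
      tw <- sum(w)
      if (tw <= 0) {  # degenerate start; re-spread mass
        w <- rep(1 / nrow(d), nrow(d)); tw <- 1
      } else {
        ll <- ll + counts[u] * log(tw)
        w <- w / tw
      }
      for (r in seq_len(nrow(d))) {
        exp_counts[d$h1[r]] <- exp_counts[d$h1[r]] + counts[u] * w[r]
        exp_counts[d$h2[r]] <- exp_counts[d$h2[r]] + counts[u] * w[r]
      }
    }
    f <- exp_counts / (2 * n)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(prev) && abs(ll - prev) < tol) { converged <- TRUE; break }
    prev <- ll
  }

  # most probable phase per individual
  phase <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- upairs[[match(rowkey[i], ukeys)]]
    w <- f[d$h1] * f[d$h2] * ifelse(d$h1 == d$h2, 1, 2)
    if (sum(w) == 0) w <- rep(1, nrow(d))
    post <- w / sum(w)
    best <- which(post == max(post))
    if (length(best) > 1L) {
      first_f <- pmax(f[d$h1[best]], f[d$h2[best]])
      best <- best[which.max(first_f)]
    }
    # orient the reported pair so hap1 has the higher frequency
    a <- d$h1[best]; b <- d$h2[best]
    if (f[b] > f[a]) { tmp <- a; a <- b; b <- tmp }
    data.frame(individual = i, hap1 = a, hap2 = b,
               posterior = post[best], stringsAsFactors = FALSE)
  }))

  ord <- order(-f)
  list(haplotypes = data.frame(haplotype = haps[ord],
                               frequency = unname(f[ord]),
                               stringsAsFactors = FALSE),
       loglik = loglik_trace[length(loglik_trace)],
       loglikTrace = loglik_trace,
       iterations = it, converged = converged, phase = phase)
}

#' Marker sharing between two haplotypes
#'
#' @param h1,h2 Allele vectors (or "|"-joined strings) on the same marker
#'   panel.
#' @return List with \code{nMatching} and \code{identical}.
#' @export
sharedHaplotype <- function(h1, h2) {
  if (is.character(h1) && length(h1) == 1L) h1 <- strsplit(h1, "|", fixed = TRUE)[[1]]
  if (is.character(h2) && length(h2) == 1L) h2 <- strsplit(h2, "|", fixed = TRUE)[[1]]
  if (length(h1) != length(h2))
    stop("haplotypes are not on the same marker panel")
  nm <- sum(h1 == h2)
  list(nMatching = nm, identical = nm == length(h1))
}

#' All pairwise D' values between biallelic markers of a phased haplotype set
#'
#' Counts 2x2 haplotype tables from phased haplotypes (e.g. the EM phase
#' output) for every pair of biallelic markers and reports D' for each, plus
#' the maximum. Markers with more than two alleles (the repeat locus) are
#' skipped, since D' is defined for biallelic pairs; which marker pair the
#' original weak-LD summary referred to is unknowable, so all pairs are
#' reported.
#'
#' @param haps Character matrix/data.frame of phased haplotypes (rows =
#'   haplotypes, columns = markers) or vector of "|"-joined strings.
#' @return List with \code{table} (data.frame: marker1, marker2, D, Dprime)
#'   and \code{maxDprime}.
#' @export
pairwiseDprime <- function(haps) {
  if (is.character(haps) && !is.matrix(haps))
    haps <- do.call(rbind, strsplit(haps, "|", fixed = TRUE))
  haps <- as.matrix(haps)
  m <- ncol(haps)
  cols <- colnames(haps)
  if (is.null(cols)) cols <- paste0("M", seq_len(m))
  biallelic <- which(vapply(seq_len(m), function(j)
    length(unique(haps[, j])) == 2L, logical(1)))
  rows <- list()
  if (length(biallelic) >= 2L) {
    for (pair in utils::combn(biallelic, 2L, simplify = FALSE)) {
      a <- haps[, pair[1]]; b <- haps[, pair[2]]
      ta <- sort(unique(a)); tb <- sort(unique(b))
      tab <- matrix(0, 2, 2)
      for (i in 1:2) for (j in 1:2)
        tab[i, j] <- sum(a == ta[i] & b == tb[j])
      ld <- dPrime(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        marker1 = cols[pair[1]], marker2 = cols[pair[2]],
        D = ld$D, Dprime = ld$Dprime, stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker1 = character(0), marker2 = character(0),
               D = numeric(0), Dprime = numeric(0))
  list(table = tab,
       maxDprime = if (nrow(tab)) max(tab$Dprime) else NA_real_)
}
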