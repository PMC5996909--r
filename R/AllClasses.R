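#' @import methods
#' @importFrom stats aov TukeyHSD dhyper lm coef pf rnorm runif rbinom setNames
#'   qt sd var complete.cases
#' @importFrom utils write.table read.table head tail combn
NULL

.MOTIF_HEAD <- "TCGGCAGCGG"

.ALLELE_CLASSES <- c("CONTROL_TYPICAL", "DISEASE_MOTIF_CARRIER",
                     "PATHOGENIC_CANDIDATE", "ATYPICAL_INSERTION")

.AFFECTION_STATUSES <- c("UNAFFECTED", "CARRIER", "AFFECTED")

.is_dna <- function(x) {
  length(x) == 1L && !is.na(x) && nchar(x) > 0L &&
    !grepl("[^ACGT]", x)
}

## ---------------------------------------------------------------------------
## MotifAlphabet
## ---------------------------------------------------------------------------

#' Motif alphabet for repeat-array tiling
#'
#' An ordered set of repeat-unit sequences, keyed by motif identifier. The
#' default alphabet holds the three EIF4A3 5'UTR motifs, which share a common
#' 10-nt head (TCGGCAGCGG) and differ only in their central nucleotides:
#' \describe{
#'   \item{CA18}{TCGGCAGCGGCAGCGAGG (18 nt, 3 CpGs)}
#'   \item{CACA20}{TCGGCAGCGGCACAGCGAGG (20 nt, 3 CpGs)}
#'   \item{CGCA20}{TCGGCAGCGGCGCAGCGAGG (20 nt, 4 CpGs; the
#'     disease-associated motif)}
#' }
#'
#' @slot entries Named character vector, motif id -> uppercase DNA sequence.
#' @export
setClass("MotifAlphabet", representation(entries = "character"))

setValidity("MotifAlphabet", function(object) {
  e <- object@entries
  if (length(e) == 0L) return("alphabet has no entries")
  if (is.null(names(e)) || anyDuplicated(names(e)) || any(!nzchar(names(e))))
    return("motif ids must be unique non-empty names")
  if (any(grepl("[^ACGT]", e)))
    return("motif sequences must be uppercase ACGT")
  if (anyDuplicated(e))
    return("motif sequences must be distinct")
  TRUE
})

#' Construct a motif alphabet
#'
#' @param entries Named character vector of uppercase DNA motif sequences;
#'   names are the motif identifiers.
#' @return A \linkS4class{MotifAlphabet}.
#' @examples
#' motifAlphabet(c(CA18 = "TCGGCAGCGGCAGCGAGG"))
#' @export
motifAlphabet <- function(entries) {
  new("MotifAlphabet", entries = entries)
}

#' The default EIF4A3 5'UTR motif alphabet
#'
#' @return A \linkS4class{MotifAlphabet} with the CA18, CACA20 and CGCA20
#'   motifs.
#' @export
defaultMotifAlphabet <- function() {
  motifAlphabet(c(
    CA18   = "TCGGCAGCGGCAGCGAGG",
    CACA20 = "TCGGCAGCGGCACAGCGAGG",
    CGCA20 = "TCGGCAGCGGCGCAGCGAGG"
  ))
}

#' @describeIn motifAlphabet Motif ids of an alphabet.
#' @param x A \code{MotifAlphabet}.
#' @export
motifIds <- function(x) names(x@entries)

#' @describeIn motifAlphabet Named motif sequences of an alphabet.
#' @export
motifSequences <- function(x) x@entries

setMethod("show", "MotifAlphabet", function(object) {
  cat("MotifAlphabet with", length(object@entries), "motifs\n")
  for (id in names(object@entries))
    cat(sprintf("  %-8s %s (%d nt)\n", id, object@entries[[id]],
                nchar(object@entries[[id]])))
})

## ---------------------------------------------------------------------------
## AlleleStructure
## ---------------------------------------------------------------------------

.empty_insertions <- function() {
  data.frame(afterIndex = integer(0), sequence = character(0),
             stringsAsFactors = FALSE)
}

#' Motif-level structure of one repeat allele
#'
#' An ordered list of motif identifiers, optionally interrupted by non-motif
#' insertion segments. This is the unit of all downstream analysis: alleles
#' are compared, classified, recombined and modelled at motif granularity.
#'
#' @slot motifs Character vector of motif ids, 5' to 3'.
#' @slot insertions data.frame with columns \code{afterIndex} (0-based index
#'   of the motif the segment follows) and \code{sequence} (uppercase DNA).
#' @slot label Optional allele label.
#' @export
setClass("AlleleStructure",
         representation(motifs = "character", insertions = "data.frame",
                        label = "character"),
         prototype(motifs = character(0), insertions = .empty_insertions(),
                   label = NA_character_))

setValidity("AlleleStructure", function(object) {
  ins <- object@insertions
  if (!identical(sort(colnames(ins)), sort(c("afterIndex", "sequence"))))
    return("insertions must have columns afterIndex, sequence")
  if (nrow(ins) > 0L) {
    if (any(is.na(ins$afterIndex)) || any(ins$afterIndex < 0L) ||
        any(ins$afterIndex >= length(object@motifs)))
      return("insertion afterIndex out of range")
    if (any(!vapply(ins$sequence, .is_dna, logical(1))))
      return("insertion sequences must be uppercase ACGT")
  }
  if (length(object@label) != 1L) return("label must be length 1")
  TRUE
})

#' Construct an allele structure
#'
#' @param motifs Character vector of motif ids, 5' to 3'.
#' @param insertions Optional data.frame with columns \code{afterIndex}
#'   (0-based motif index the segment follows) and \code{sequence}.
#' @param label Optional label.
#' @return An \linkS4class{AlleleStructure}.
#' @examples
#' alleleStructure(c("CACA20", "CACA20", "CACA20", "CA18"))
#' @export
alleleStructure <- function(motifs, insertions = NULL, label = NA_character_) {
  if (is.null(insertions)) insertions <- .empty_insertions()
  insertions$afterIndex <- as.integer(insertions$afterIndex)
  insertions <- insertions[order(insertions$afterIndex), , drop = FALSE]
  rownames(insertions) <- NULL
  new("AlleleStructure", motifs = as.character(motifs),
      insertions = insertions, label = as.character(label))
}

#' Accessors for AlleleStructure
#'
#' @param x An \linkS4class{AlleleStructure}.
#' @return \code{motifs()} the motif id vector; \code{insertions()} the
#'   insertion table; \code{repeatCount()} the number of motifs;
#'   \code{hasInsertions()} whether any non-motif segment is present.
#' @name allele-accessors
NULL

#' @rdname allele-accessors
#' @export
motifs <- function(x) x@motifs

#' @rdname allele-accessors
#' @export
insertions <- function(x) x@insertions

#' @rdname allele-accessors
#' @export
repeatCount <- function(x) length(x@motifs)

#' @rdname allele-accessors
#' @export
hasInsertions <- function(x) nrow(x@insertions) > 0L

setMethod("show", "AlleleStructure", function(object) {
  cat("AlleleStructure:", alleleName(object), "\n")
  cat("  repeats:", repeatCount(object))
  if (hasInsertions(object))
    cat(" (+", nrow(object@insertions), "insertion segment(s))")
  cat("\n")
})

## ---------------------------------------------------------------------------
## DiploidGenotype
## ---------------------------------------------------------------------------

#' Diploid repeat-locus genotype
#'
#' Two allele structures for one individual, optionally with genotypes at the
#' five flanking SNPs (unphased, as "a/b" strings in panel order).
#'
#' @slot allele1,allele2 \linkS4class{AlleleStructure} objects.
#' @slot snpGenotypes Character vector of length 0 or 5 ("a/b" per SNP).
#' @slot sampleId Sample identifier.
#' @export
setClass("DiploidGenotype",
         representation(allele1 = "AlleleStructure",
                        allele2 = "AlleleStructure",
                        snpGenotypes = "character",
                        sampleId = "character"))

setValidity("DiploidGenotype", function(object) {
  if (!length(object@snpGenotypes) %in% c(0L, 5L))
    return("snpGenotypes must have length 0 or 5")
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  TRUE
})

#' Construct a diploid genotype
#'
#' @param allele1,allele2 \linkS4class{AlleleStructure} objects.
#' @param snpGenotypes Optional character(5) of unphased "a/b" SNP genotypes.
#' @param sampleId Sample identifier.
#' @return A \linkS4class{DiploidGenotype}.
#' @export
diploidGenotype <- function(allele1, allele2, snpGenotypes = character(0),
                            sampleId = NA_character_) {
  new("DiploidGenotype", allele1 = allele1, allele2 = allele2,
      snpGenotypes = as.character(snpGenotypes),
      sampleId = as.character(sampleId))
}

#' @describeIn diploidGenotype The two alleles as a list.
#' @param x A \code{DiploidGenotype}.
#' @export
alleles <- function(x) list(x@allele1, x@allele2)

#' @describeIn diploidGenotype Sample identifier.
#' @export
sampleId <- function(x) x@sampleId

#' @describeIn diploidGenotype TRUE when the two allele structures differ.
#' @export
isHeterozygous <- function(x) {
  !identical(alleleName(x@allele1), alleleName(x@allele2))
}

setMethod("show", "DiploidGenotype", function(object) {
  cat("DiploidGenotype", object@sampleId, "\n")
  cat("  allele1:", alleleName(object@allele1), "\n")
  cat("  allele2:", alleleName(object@allele2), "\n")
  if (length(object@snpGenotypes))
    cat("  SNPs:", paste(object@snpGenotypes, collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## MixedSequence
## ---------------------------------------------------------------------------

#' IUPAC superposition of a diploid amplicon
#'
#' The sequence-level analogue of a heterozygote's mixed Sanger trace: the
#' position-wise IUPAC union of the two allele amplicons after 5' alignment
#' (the sequencing-primer side). Beyond the shorter amplicon the codes come
#' from the longer allele alone.
#'
#' @slot iupac The mixed sequence over IUPAC codes.
#' @slot flank5,flank3 The amplicon flanks shared by both alleles.
#' @export
setClass("MixedSequence",
         representation(iupac = "character", flank5 = "character",
                        flank3 = "character"))

setValidity("MixedSequence", function(object) {
  if (length(object@iupac) != 1L || !nzchar(object@iupac))
    return("iupac must be a single non-empty string")
  if (grepl("[^ACGTMRWSYKVHDBN]", object@iupac))
    return("iupac contains non-IUPAC characters")
  TRUE
})

#' @describeIn superpose The IUPAC string of a MixedSequence.
#' @export
mixedIupac <- function(x) x@iupac

setMethod("show", "MixedSequence", function(object) {
  n_amb <- sum(strsplit(object@iupac, "")[[1]] %in%
               c("M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N"))
  cat("MixedSequence of", nchar(object@iupac), "nt with", n_amb,
      "ambiguous position(s)\n")
})

## ---------------------------------------------------------------------------
## CloneSet
## ---------------------------------------------------------------------------

#' Filtered bisulfite clone set
#'
#' Bisulfite clone reads aligned to a reference allele sequence, with per-clone
#' quality statistics, filter verdicts and per-CpG methylation calls.
#'
#' @slot clones data.frame with columns \code{read}, \code{kept},
#'   \code{failReasons}, \code{conversion}, \code{identity}, \code{nAtC},
#'   \code{gapFrac}.
#' @slot reference Reference (unconverted) allele sequence.
#' @slot filterParams Named list of the four thresholds.
#' @slot calls Clone x CpG matrix of methylation calls (1 methylated,
#'   0 unmethylated, NA unreadable).
#' @slot cpgPositions 0-based positions of CpG cytosines on the reference.
#' @export
setClass("CloneSet",
         representation(clones = "data.frame", reference = "character",
                        filterParams = "list", calls = "matrix",
                        cpgPositions = "integer"))

#' @describeIn filterClones Per-clone table (read, kept, failReasons, stats).
#' @export
cloneTable <- function(x) x@clones

#' @describeIn filterClones Clone x CpG methylation call matrix (kept and
#'   rejected clones alike; rows named by clone).
#' @export
cloneCalls <- function(x) x@calls

#' @describeIn filterClones 0-based CpG cytosine positions on the reference.
#' @export
cpgPositions <- function(x) x@cpgPositions

setMethod("show", "CloneSet", function(object) {
  cat("CloneSet:", nrow(object@clones), "clones (",
      sum(object@clones$kept), "kept ) over",
      length(object@cpgPositions), "CpG sites\n")
})
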