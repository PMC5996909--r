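## Readers and writers for the package's exchange formats: allele and mixed
## amplicon FASTA (via Biostrings), genotype and plate TSVs, a minimal
## GT-only SNP VCF (written as text, read back with vcfR), and a BED-like
## table of CpG positions.

#' Write allele sequences to FASTA
#'
#' One record per allele; ids follow the \code{sample|allele1} /
#' \code{sample|allele2} convention.
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeAlleleFasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read allele (or mixed amplicon) sequences from FASTA
#'
#' @param path FASTA file; IUPAC ambiguity codes are allowed.
#' @return Named character vector of uppercase sequences.
#' @export
readAlleleFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a cohort genotype table to TSV
#'
#' Columns: sample, allele1, allele2 (nomenclature strings) and one column
#' per SNP marker with unphased "a/b" genotypes.
#'
#' @param genotypes List of \linkS4class{DiploidGenotype} objects.
#' @param path Output file.
#' @param panel Marker panel (for SNP column names).
#' @return \code{path}, invisibly.
#' @export
writeGenotypesTsv <- function(genotypes, path, panel = defaultMarkerPanel()) {
  snp_ids <- panel$markerId[panel$type == "SNP"]
  rows <- do.call(rbind, lapply(genotypes, function(g) {
    snp <- g@snpGenotypes
    if (length(snp) == 0L) snp <- rep(NA_character_, length(snp_ids))
    d <- data.frame(sample = sampleId(g),
                    allele1 = alleleName(g@allele1),
                    allele2 = alleleName(g@allele2),
                    stringsAsFactors = FALSE)
    for (k in seq_along(snp_ids)) d[[snp_ids[k]]] <- snp[k]
    d
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort genotype table from TSV
#'
#' @param path TSV written by \code{\link{writeGenotypesTsv}}.
#' @return List of \linkS4class{DiploidGenotype} objects.
#' @export
readGenotypesTsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  snp_cols <- setdiff(colnames(d), c("sample", "allele1", "allele2"))
  lapply(seq_len(nrow(d)), function(i) {
    snp <- if (length(snp_cols)) as.character(unlist(d[i, snp_cols]))
           else character(0)
    diploidGenotype(parseAlleleName(d$allele1[i]),
                    parseAlleleName(d$allele2[i]),
                    snpGenotypes = snp, sampleId = d$sample[i])
  })
}

#' Write a minimal GT-only SNP VCF
#'
#' @param genotypes List of \linkS4class{DiploidGenotype} with 5 SNP
#'   genotypes each.
#' @param path Output file.
#' @param panel Marker panel.
#' @param snpAlleles Named list, rs id -> c(ref, alt).
#' @return \code{path}, invisibly.
#' @export
writeSnpVcf <- function(genotypes, path, panel = defaultMarkerPanel(),
                        snpAlleles = defaultSnpAlleles()) {
  snp_ids <- panel$markerId[panel$type == "SNP"]
  samples <- vapply(genotypes, sampleId, character(1))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (k in seq_along(snp_ids)) {
    ra <- snpAlleles[[snp_ids[k]]]
    gts <- vapply(genotypes, function(g) {
      ab <- strsplit(g@snpGenotypes[k], "/", fixed = TRUE)[[1]]
      paste(match(ab, ra) - 1L, collapse = "/")
    }, character(1))
    lines <- c(lines, paste(c("17", as.character(1000L * k), snp_ids[k],
                              ra[1], ra[2], ".", "PASS", ".", "GT", gts),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP genotypes from a minimal VCF
#'
#' Extracts the GT field for each record keyed by rs id and maps allele
#' indices back to bases.
#'
#' @param path VCF file (plain text).
#' @return data.frame, samples x SNPs, entries "a/b".
#' @export
readSnpVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v)
  out <- as.data.frame(matrix(NA_character_, ncol(gt), nrow(gt)),
                       stringsAsFactors = FALSE)
  colnames(out) <- fix[, "ID"]
  rownames(out) <- colnames(gt)
  for (r in seq_len(nrow(gt))) {
    alleles <- c(fix[r, "REF"], fix[r, "ALT"])
    for (s in seq_len(ncol(gt))) {
      idx <- as.integer(strsplit(gt[r, s], "[/|]")[[1]]) + 1L
      ab <- sort(alleles[idx])
      out[s, r] <- paste(ab, collapse = "/")
    }
  }
  out
}

#' Write a luciferase plate table to TSV
#' @param wells data.frame (construct_id, replicate, experiment, firefly,
#'   renilla).
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writePlateTsv <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a luciferase plate table from TSV
#' @param path TSV with columns construct_id, replicate, firefly, renilla
#'   (optionally experiment).
#' @return data.frame.
#' @export
readPlateTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write CpG positions of a composed allele as BED-like TSV
#'
#' 0-based half-open intervals covering each CG dinucleotide.
#'
#' @param structure An \linkS4class{AlleleStructure} (or DNA string).
#' @param path Output file.
#' @param name Feature name stem.
#' @return \code{path}, invisibly.
#' @export
writeCpgBed <- function(structure, path, name = "cpg") {
  dna <- if (is.character(structure)) structure else composeAllele(structure)
  pos <- cpgSites(dna)
  d <- data.frame(chrom = name, start = pos, end = pos + 2L,
                  name = paste0(name, "_", seq_along(pos)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
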