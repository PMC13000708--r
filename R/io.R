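#' @importFrom utils read.delim write.table
NULL

.dosageToGT <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a cohort to disk (VCF + sample sheet + weight tables)
#'
#' Emits \code{genotypes.vcf} (VCF v4.2, GT field, ALT-allele frequency in
#' INFO/AF), \code{samples.tsv}, one \code{weights_<trait>.tsv} per
#' weight-set, and — when the cohort carries simulation truth —
#' \code{truth_related_pairs.tsv}. Missing genotypes are encoded
#' \code{"./."}. Files round-trip bit-exactly through [readCohortVCF()],
#' [readSampleSheet()] and [readWeights()].
#'
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @param weightSets named list of \linkS4class{WeightSet} (may be empty)
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
writeCohort <- function(genotypes, weightSets = list(), dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  vi <- variantInfo(genotypes)
  d <- dosages(genotypes)
  gt <- matrix(.dosageToGT[as.character(d)], nrow(d), ncol(d))
  gt[is.na(d)] <- "./."

  vcfPath <- file.path(dir, "genotypes.vcf")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"ALT allele frequency\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", colnames(genotypes)), collapse = "\t"))
  body <- paste(vi$chrom, vi$pos, vi$variant_id, vi$ref, vi$alt, ".", "PASS",
                sprintf("AF=%.6g", vi$altFreq), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), vcfPath)

  sampPath <- file.path(dir, "samples.tsv")
  ss <- sampleSheet(genotypes)
  keep <- intersect(c("sample_id", "sex", "age", "case_status", "stratum",
                      "cohort", "true_liability", "subpop"), names(ss))
  write.table(ss[, keep, drop = FALSE], sampPath, sep = "\t",
              quote = FALSE, row.names = FALSE)

  wPaths <- character()
  for (nm in names(weightSets)) {
    wp <- file.path(dir, paste0("weights_", nm, ".tsv"))
    write.table(as.data.frame(weightSets[[nm]]), wp, sep = "\t",
                quote = FALSE, row.names = FALSE)
    wPaths <- c(wPaths, wp)
  }
  paths <- c(vcf = vcfPath, samples = sampPath, wPaths)
  rt <- metadata(genotypes)$related_truth
  if (!is.null(rt)) {
    tp <- file.path(dir, "truth_related_pairs.tsv")
    write.table(rt, tp, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth = tp)
  }
  invisible(paths)
}

#' Read a cohort VCF into a GenotypeCohort
#'
#' Parses a VCF (v4.2, GT genotypes; phased or unphased separators) via
#' \pkg{vcfR}; \code{"./."} becomes missing. If INFO carries AF it is used
#' as the stored ALT frequency, otherwise the frequency is recomputed from
#' the dosages.
#'
#' @param vcfPath path to a VCF file
#' @param samplePath optional sample sheet TSV joined into \code{colData}
#'   by \code{sample_id}
#' @return a \linkS4class{GenotypeCohort}
#' @export
readCohortVCF <- function(vcfPath, samplePath = NULL) {
  v <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  allele1 <- substr(gt, 1, 1)
  allele3 <- substr(gt, 3, 3)
  dos <- (allele1 == "1") + (allele3 == "1")
  dos[allele1 == "." | allele3 == "."] <- NA_integer_
  mode(dos) <- "integer"
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                        fix$INFO)))
  variants <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT,
                         altFreq = ifelse(is.na(af),
                                          rowMeans(dos, na.rm = TRUE) / 2,
                                          af))
  samples <- data.frame(sample_id = colnames(dos))
  if (!is.null(samplePath)) {
    ss <- readSampleSheet(samplePath)
    samples <- ss[match(colnames(dos), ss$sample_id), , drop = FALSE]
    if (anyNA(samples$sample_id))
      stop("sample sheet is missing ids present in the VCF")
  }
  GenotypeCohort(dos, variants, samples)
}

#' Read a sample sheet TSV
#'
#' @param path TSV with header containing at least \code{sample_id}
#' @return data.frame
#' @export
readSampleSheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(ss))
    stop("format error: sample sheet must have a 'sample_id' column")
  if (anyDuplicated(ss$sample_id))
    stop("duplicate sample_id in sample sheet")
  ss
}

#' Read a polygenic weight table TSV
#'
#' Requires the header columns \code{variant_id}, \code{effect_allele},
#' \code{other_allele}, \code{weight}, \code{effect_allele_freq}
#' (\code{chrom}/\code{pos} optional). Malformed rows (non-numeric weight
#' or frequency) are rejected with their line numbers.
#'
#' @param path TSV path
#' @param trait trait label (defaults to the file name stem)
#' @return a \linkS4class{WeightSet}
#' @export
readWeights <- function(path, trait = NULL) {
  if (is.null(trait))
    trait <- sub("^weights_", "", sub("\\.tsv$", "", basename(path)))
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  req <- c("variant_id", "effect_allele", "other_allele", "weight",
           "effect_allele_freq")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  w <- suppressWarnings(as.numeric(tab$weight))
  f <- suppressWarnings(as.numeric(tab$effect_allele_freq))
  bad <- which(is.na(w) | is.na(f))
  if (length(bad))
    stop("format error: malformed numeric field at line(s) ",
         paste(bad + 1L, collapse = ", "))   # +1 for the header line
  tab$weight <- w
  tab$effect_allele_freq <- f
  if ("pos" %in% names(tab)) tab$pos <- as.integer(tab$pos)
  WeightSet(tab, trait = trait)
}

#' Write per-sample scores to TSV
#'
#' @param scores a \linkS4class{PGScore} or named list of them
#' @param path output TSV (`sample_id trait raw standardized`)
#' @export
writeScores <- function(scores, path) {
  if (is(scores, "PGScore")) scores <- list(scores)
  rows <- do.call(rbind, lapply(scores, function(s)
    data.frame(sample_id = s$sample_id, trait = s@trait,
               raw = s$raw, standardized = s$standardized)))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
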