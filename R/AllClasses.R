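#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   colData<- rowRanges
NULL

#' Genotype cohort container
#'
#' A \linkS4class{RangedSummarizedExperiment} holding biallelic SNV dosages
#' for one cohort. Rows are variants (a \code{GRanges} with \code{ref},
#' \code{alt} and \code{altFreq} in its metadata columns), columns are
#' samples, and the single assay \code{"dosage"} counts ALT alleles in
#' \{0, 1, 2\} with \code{NA} for missing genotypes. Per-sample phenotype
#' fields (sex, age, case status, stratum, cohort label and, for simulated
#' cohorts, the latent liability) live in \code{colData}.
#'
#' @slot .. see \linkS4class{RangedSummarizedExperiment}; no extra slots.
#' @seealso [GenotypeCohort()] for construction, [simulateCohort()] for
#'   synthetic cohorts, [readCohortVCF()] to import a VCF.
#' @export
setClass("GenotypeCohort", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  rr <- rowRanges(object)
  if (length(rr) > 1) {
    byc <- split(GenomicRanges::start(rr), as.character(GenomicRanges::seqnames(rr)))
    if (any(vapply(byc, is.unsorted, logical(1), strictly = TRUE)))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeCohort
#'
#' @param dosage variants x samples matrix of ALT-allele counts
#'   (0/1/2, \code{NA} = missing), with variant ids as rownames and sample
#'   ids as colnames.
#' @param variants data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt} and optionally
#'   \code{altFreq}; one row per dosage row, in order.
#' @param samples data.frame of per-sample fields (at least
#'   \code{sample_id}); one row per dosage column, in order. Conventional
#'   columns: \code{sex} ("female"/"male"), \code{age} (years),
#'   \code{case_status} ("case"/"control"), \code{stratum}, \code{cohort},
#'   \code{true_liability}.
#' @return a \linkS4class{GenotypeCohort}
#' @export
GenotypeCohort <- function(dosage, variants, samples) {
  stopifnot(is.matrix(dosage),
            nrow(dosage) == nrow(variants),
            ncol(dosage) == nrow(samples))
  rr <- GRanges(variants$chrom,
                IRanges(start = variants$pos, width = 1L))
  names(rr) <- variants$variant_id
  mcols(rr)$ref <- as.character(variants$ref)
  mcols(rr)$alt <- as.character(variants$alt)
  mcols(rr)$altFreq <- if ("altFreq" %in% names(variants)) variants$altFreq
    else rowMeans(dosage, na.rm = TRUE) / 2
  rownames(dosage) <- variants$variant_id
  colnames(dosage) <- samples$sample_id
  cd <- DataFrame(samples)
  rownames(cd) <- samples$sample_id
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = rr, colData = cd)
  new("GenotypeCohort", se)
}

#' @describeIn GenotypeCohort dosage matrix accessor (variants x samples)
#' @param x a GenotypeCohort
#' @export
dosages <- function(x) assay(x, "dosage")

#' @describeIn GenotypeCohort per-sample phenotype table as a data.frame
#' @export
sampleSheet <- function(x) as.data.frame(colData(x))

#' @describeIn GenotypeCohort per-variant table (id, chrom, pos, ref, alt,
#'   altFreq) as a data.frame
#' @export
variantInfo <- function(x) {
  rr <- rowRanges(x)
  data.frame(variant_id = names(rr),
             chrom = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             ref = mcols(rr)$ref, alt = mcols(rr)$alt,
             altFreq = mcols(rr)$altFreq,
             row.names = NULL)
}

setMethod("show", "GenotypeCohort", function(object) {
  cs <- colData(object)$case_status
  cat("GenotypeCohort:", nrow(object), "variants x", ncol(object), "samples\n")
  if (!is.null(cs))
    cat("  cases:", sum(cs == "case"), " controls:", sum(cs == "control"), "\n")
  cat("  missing dosage rate:",
      signif(mean(is.na(assay(object, "dosage"))), 3), "\n")
})

#' Per-variant polygenic weight table
#'
#' A \linkS4class{DataFrame} with one row per variant and columns
#' \code{variant_id}, \code{chrom}, \code{pos}, \code{effect_allele},
#' \code{other_allele}, \code{weight} (additive per-allele effect) and
#' \code{effect_allele_freq}, plus a \code{trait} label. The weight is the
#' expected change in the trait (or liability) per copy of the effect
#' allele.
#'
#' @slot trait trait label for this weight-set
#' @export
setClass("WeightSet", contains = "DFrame",
         representation(trait = "character"))

setValidity("WeightSet", function(object) {
  req <- c("variant_id", "effect_allele", "other_allele",
           "weight", "effect_allele_freq")
  miss <- setdiff(req, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  msg <- character()
  dup <- object$variant_id[duplicated(object$variant_id)]
  if (length(dup))
    msg <- c(msg, paste("duplicate variant_id:", paste(unique(dup), collapse = ", ")))
  same <- object$effect_allele == object$other_allele
  if (any(same))
    msg <- c(msg, paste("effect_allele equals other_allele for:",
                        paste(object$variant_id[same], collapse = ", ")))
  f <- object$effect_allele_freq
  if (any(!is.finite(f) | f <= 0 | f >= 1))
    msg <- c(msg, "effect_allele_freq must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightSet
#'
#' @param table data.frame with the required weight-table columns (see
#'   \linkS4class{WeightSet}).
#' @param trait trait label.
#' @return a \linkS4class{WeightSet}
#' @export
WeightSet <- function(table, trait = "trait") {
  ws <- new("WeightSet", DataFrame(table), trait = trait)
  validObject(ws)
  ws
}

#' @describeIn WeightSet trait label accessor
#' @param x a WeightSet
#' @export
traitName <- function(x) x@trait

setMethod("show", "WeightSet", function(object) {
  cat("WeightSet for trait '", object@trait, "': ",
      nrow(object), " variants\n", sep = "")
  callNextMethod()
})

#' Per-sample polygenic score vector
#'
#' A \linkS4class{DataFrame} with columns \code{sample_id}, \code{raw}
#' (weighted dosage sum) and \code{standardized} (within-cohort z-score),
#' one row per sample, plus bookkeeping on how many weight rows were used
#' or skipped during harmonization.
#'
#' @slot trait trait label
#' @slot nUsed number of weight rows scored
#' @slot nSkipped number of weight rows skipped
#' @slot skipReasons named character vector, reason per skipped variant id
#' @export
setClass("PGScore", contains = "DFrame",
         representation(trait = "character", nUsed = "integer",
                        nSkipped = "integer", skipReasons = "character"))

setValidity("PGScore", function(object) {
  if (!all(c("sample_id", "raw", "standardized") %in% colnames(object)))
    return("columns sample_id, raw, standardized are required")
  s <- object$standardized
  if (!all(is.na(s))) {
    n <- length(s)
    if (abs(mean(s)) > 1e-8 || abs(sqrt(sum((s - mean(s))^2) / n) - 1) > 1e-8)
      return("standardized scores must have mean 0 and (population) SD 1")
  }
  TRUE
})

setMethod("show", "PGScore", function(object) {
  cat("PGScore '", object@trait, "': ", nrow(object), " samples; ",
      object@nUsed, " variants used, ", object@nSkipped, " skipped\n",
      sep = "")
  if (object@nSkipped > 0)
    print(table(object@skipReasons))
})

#' Evaluation report for one cohort
#'
#' Bundles the three result families of the evaluation battery:
#' association (odds ratio per SD of PGS from logistic models),
#' discrimination (AUC with one-tailed Z inference) and liability-scale
#' variance explained (Lee transformation with bootstrap intervals), for
#' each trait and the combined predictor, per stratum.
#'
#' @slot association data.frame: trait, model, stratum, or_per_sd, ci_lo,
#'   ci_hi, p, p_adj
#' @slot discrimination data.frame: predictor, stratum, auc, se, z, p,
#'   lb90, p_adj
#' @slot liability data.frame: predictor, stratum, r2_obs, K, P, r2_l, se,
#'   lb90, z, p, p_adj
#' @slot meta list of run metadata (seed, counts, bootstrap B, config hash)
#' @export
setClass("EvaluationReport",
         representation(association = "data.frame",
                        discrimination = "data.frame",
                        liability = "data.frame",
                        meta = "list"))

#' @describeIn EvaluationReport association results accessor
#' @param x an EvaluationReport
#' @export
associationResults <- function(x) x@association

#' @describeIn EvaluationReport AUC / discrimination results accessor
#' @export
discriminationResults <- function(x) x@discrimination

#' @describeIn EvaluationReport liability-scale variance results accessor
#' @export
liabilityResults <- function(x) x@liability

setMethod("show", "EvaluationReport", function(object) {
  m <- object@meta
  cat("EvaluationReport:", m$n_cases, "cases /", m$n_controls,
      "controls; K =", m$K, "\n")
  cat("  association rows:", nrow(object@association),
      "| discrimination rows:", nrow(object@discrimination),
      "| liability rows:", nrow(object@liability), "\n")
  sig <- object@liability$p_adj < 0.05
  if (length(sig))
    cat("  predictors with liability R2 > 0 (adj. p < 0.05):",
        paste(object@liability$predictor[sig &
              object@liability$stratum == "all"], collapse = ", "), "\n")
})
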