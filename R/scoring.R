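#' Harmonize a weight table against cohort genotypes
#'
#' Matches weight rows to cohort variants by id and aligns the effect
#' allele to the VCF ALT allele: when the effect allele is the ALT the
#' dosage is used as-is; when it is the REF the dosage is flipped to
#' \code{2 - dosage} (and the stored effect-allele frequency to
#' \code{1 - f}); any other allele pair is skipped with reason
#' \code{"allele_mismatch"}, and ids absent from the cohort with reason
#' \code{"missing_variant"}. No strand flipping is attempted: matching is
#' by id plus exact allele pair, and skips are recorded for audit.
#'
#' @param weights a \linkS4class{WeightSet}
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @return list with \code{index} (row of each used variant in the
#'   cohort), \code{weight}, \code{flip} (logical: effect allele is REF),
#'   \code{freq} (effect-allele frequency, aligned), and
#'   \code{skipReasons} (named character)
#' @export
harmonizeWeights <- function(weights, genotypes) {
  vi <- variantInfo(genotypes)
  m <- match(weights$variant_id, vi$variant_id)
  skip <- character()
  use <- !is.na(m)
  if (any(!use))
    skip[weights$variant_id[!use]] <- "missing_variant"
  idx <- m[use]
  ea <- weights$effect_allele[use]; oa <- weights$other_allele[use]
  ref <- vi$ref[idx]; alt <- vi$alt[idx]
  asIs <- ea == alt & oa == ref
  flip <- ea == ref & oa == alt
  mism <- !(asIs | flip)
  if (any(mism))
    skip[weights$variant_id[use][mism]] <- "allele_mismatch"
  keep <- which(use)[!mism]
  list(index = idx[!mism],
       weight = weights$weight[keep],
       flip = flip[!mism],
       freq = weights$effect_allele_freq[keep],
       skipReasons = skip,
       trait = traitName(weights))
}

#' Compute raw and standardized polygenic scores
#'
#' The raw score is the weighted sum of effect-allele dosages over the
#' harmonized variants. Missing dosages are mean-imputed as twice the
#' effect-allele frequency (policy \code{"mean_impute"}, the default) or
#' omitted with the per-sample sum renormalized to the full variant count
#' (policy \code{"omit"}). Scores are then z-scored within the cohort
#' (population-SD denominator \code{n}).
#'
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @param weights a \linkS4class{WeightSet} or the result of
#'   [harmonizeWeights()]
#' @param missingPolicy \code{"mean_impute"} or \code{"omit"}
#' @param standardize z-score within cohort (default TRUE)
#' @return a \linkS4class{PGScore}
#' @export
computeScores <- function(genotypes, weights,
                          missingPolicy = c("mean_impute", "omit"),
                          standardize = TRUE) {
  missingPolicy <- match.arg(missingPolicy)
  h <- if (is(weights, "WeightSet")) harmonizeWeights(weights, genotypes)
       else weights
  if (length(h$index) == 0L)
    stop("empty score: all ", length(h$skipReasons),
         " weight rows were skipped")
  d <- dosages(genotypes)[h$index, , drop = FALSE]
  # effect-allele dosage: flip REF-effect variants
  ed <- d
  if (any(h$flip)) ed[h$flip, ] <- 2L - d[h$flip, , drop = FALSE]
  w <- h$weight
  if (anyNA(ed)) {
    if (missingPolicy == "mean_impute") {
      imp <- 2 * h$freq
      naIdx <- which(is.na(ed))
      ed[naIdx] <- imp[(naIdx - 1L) %% nrow(ed) + 1L]
      raw <- as.numeric(crossprod(ed, w))
    } else {
      obs <- !is.na(ed)
      ed[!obs] <- 0
      raw <- as.numeric(crossprod(ed, w))
      nUsed <- colSums(obs)
      raw <- as.numeric(ifelse(nUsed > 0, raw * length(w) / nUsed,
                               NA_real_))
    }
  } else {
    raw <- as.numeric(crossprod(ed, w))
  }
  std <- if (standardize) standardizeValues(raw) else rep(NA_real_, length(raw))
  new("PGScore",
      DataFrame(sample_id = colnames(genotypes), raw = raw,
                standardized = std),
      trait = h$trait,
      nUsed = length(h$index),
      nSkipped = length(h$skipReasons),
      skipReasons = h$skipReasons)
}

# z-score with population-SD denominator n
standardizeValues <- function(x) {
  if (length(x) < 2L) stop("standardization needs at least 2 samples")
  mu <- mean(x)
  s <- sqrt(sum((x - mu)^2) / length(x))
  if (s == 0) stop("standardization error: zero variance in raw scores")
  (x - mu) / s
}

#' Standardize a score vector within its cohort
#'
#' Centers and scales the raw scores to mean 0 and SD 1, using the
#' population-SD denominator \code{n}; idempotent on already-standardized
#' scores.
#'
#' @param score a \linkS4class{PGScore}
#' @return the \linkS4class{PGScore} with \code{standardized} filled
#' @export
standardizeScores <- function(score) {
  new("PGScore",
      DataFrame(sample_id = score$sample_id, raw = score$raw,
                standardized = standardizeValues(score$raw)),
      trait = score@trait, nUsed = score@nUsed,
      nSkipped = score@nSkipped, skipReasons = score@skipReasons)
}

#' Score a cohort for several traits at once
#'
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @param weightSets named list of \linkS4class{WeightSet}
#' @param ... passed to [computeScores()]
#' @return named list of \linkS4class{PGScore}
#' @export
scoreCohort <- function(genotypes, weightSets, ...) {
  out <- lapply(weightSets, computeScores, genotypes = genotypes, ...)
  names(out) <- vapply(out, function(s) s@trait, "")
  out
}
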