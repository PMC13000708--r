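#' @importFrom stats rnorm rbinom runif rbeta qnorm dnorm
NULL

# Deterministic per-stage seed streams: one user seed fans out so toggling
# one stage does not perturb the draws of another. Offsets are arbitrary
# fixed constants; results stay within 32-bit integer range.
.stageOffsets <- c(freqs = 101L, effects = 211L, genotypes = 307L,
                   phenotypes = 401L, weights = 503L, related = 601L,
                   covariates = 701L, match = 809L, boot = 907L,
                   pipeline = 1009L)

fanSeed <- function(seed, stage) {
  off <- .stageOffsets[[stage]]
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + off)
}

#' Default trait specifications for the synthetic multi-trait generator
#'
#' Eight traits mirroring a cerebral-palsy PGS panel: the disorder itself
#' plus a motor-development trait, perinatal predisposing factors and
#' comorbidities. \code{n_eff} values are the discovery-GWAS effective
#' sample sizes that control weight-estimation noise; \code{rho_cp} is the
#' genetic correlation of each trait's per-variant effects with the
#' disorder liability trait (negative for protective profiles such as
#' educational attainment); \code{h2} is the liability variance
#' attributable to the simulated variant panel.
#'
#' @return data.frame with columns name, h2, rho_cp, n_eff
#' @export
defaultTraitSpecs <- function() {
  data.frame(
    name = c("cp", "walking_age", "birth_weight", "gestational_duration",
             "stroke", "asd", "epilepsy", "ea"),
    h2 = rep(0.3, 8),
    rho_cp = c(1, 0.5, -0.25, -0.25, 0.3, 0.3, 0.3, -0.4),
    n_eff = c(3465, 70560, 298142, 151987, 278028, 44367, 65124, 757277))
}

#' Simulation configuration for a synthetic case-control cohort
#'
#' Defaults emulate the smaller of the two study-like cohorts: population
#' prevalence K = 0.0032, ascertainment of 322 cases and 1610 controls
#' from a pool of 150,000, two weakly diverged subpopulations
#' (Balding-Nichols Fst = 0.01), cases on average much younger than
#' controls and with a lower female fraction, and a handful of injected
#' related pairs. \code{cohort = "australia"} switches to K = 0.0014 with
#' 525 cases / 20,410 controls (requires a much larger pool).
#'
#' @param seed integer master seed; all stages derive independent streams.
#' @param nPool individuals simulated before ascertainment.
#' @param nVariants number of independent biallelic variants.
#' @param mafRange ancestral minor-allele frequency range, within (0, 0.5].
#' @param nSubpops number of subpopulations.
#' @param fst Balding-Nichols divergence of subpopulation allele
#'   frequencies around the ancestral frequency (>= 0).
#' @param traits data.frame as [defaultTraitSpecs()].
#' @param K population prevalence of the disorder, in (0,1).
#' @param targetCases,targetControls ascertained sample sizes.
#' @param ageModel list with \code{case} and \code{control} elements, each
#'   \code{c(mean=, sd=)} in years.
#' @param sexModel named vector \code{c(case=, control=)} of female
#'   fractions.
#' @param relatedPairs named list of pair counts to inject, names among
#'   \code{duplicate}, \code{parent_offspring}, \code{full_sib}.
#' @param missingRate genotype missingness rate in [0,1).
#' @param cohortLabel label stored in the sample sheet.
#' @param chunkSize pool individuals simulated per chunk (memory bound).
#' @param cohort optional preset, \code{"mycode"} (default values) or
#'   \code{"australia"}.
#' @return a validated list of class \code{"simConfig"}
#' @export
simConfig <- function(seed = 1L, nPool = 150000L, nVariants = 2000L,
                      mafRange = c(0.05, 0.5), nSubpops = 2L, fst = 0.01,
                      traits = defaultTraitSpecs(), K = 0.0032,
                      targetCases = 322L, targetControls = 1610L,
                      ageModel = list(case = c(mean = 8.9, sd = 5.1),
                                      control = c(mean = 61.2, sd = 9.6)),
                      sexModel = c(case = 0.40, control = 0.576),
                      relatedPairs = list(duplicate = 2L,
                                          parent_offspring = 4L,
                                          full_sib = 4L),
                      missingRate = 0.002, cohortLabel = "synthetic",
                      chunkSize = 20000L, cohort = NULL) {
  if (!is.null(cohort) && cohort == "australia") {
    K <- 0.0014; targetCases <- 525L; targetControls <- 20410L
    nPool <- 600000L; cohortLabel <- "australia"
  }
  cfg <- list(seed = as.integer(seed), nPool = as.integer(nPool),
              nVariants = as.integer(nVariants), mafRange = mafRange,
              nSubpops = as.integer(nSubpops), fst = fst, traits = traits,
              K = K, targetCases = as.integer(targetCases),
              targetControls = as.integer(targetControls),
              ageModel = ageModel, sexModel = sexModel,
              relatedPairs = relatedPairs, missingRate = missingRate,
              cohortLabel = cohortLabel, chunkSize = as.integer(chunkSize))
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$nPool <= 0L || cfg$nVariants <= 0L)
    stop("configuration error: nPool and nVariants must be positive")
  if (!(cfg$K > 0 && cfg$K < 1))
    stop("configuration error: K must be in (0,1)")
  if (cfg$mafRange[1] <= 0 || cfg$mafRange[2] > 0.5 ||
      cfg$mafRange[1] > cfg$mafRange[2])
    stop("configuration error: mafRange must lie within (0, 0.5]")
  if (cfg$fst < 0) stop("configuration error: fst must be >= 0")
  if (cfg$targetCases > cfg$K * cfg$nPool)
    stop("configuration error: targetCases exceeds expected cases in pool (",
         round(cfg$K * cfg$nPool), ")")
  tr <- cfg$traits
  if (any(tr$h2 < 0 | tr$h2 > 1)) stop("configuration error: h2 outside [0,1]")
  if (any(abs(tr$rho_cp) > 1)) stop("configuration error: |rho_cp| > 1")
  if (any(tr$n_eff <= 0)) stop("configuration error: n_eff must be positive")
  if (min(eigen(traitCorrelation(tr), symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8)
    stop("configuration error: trait correlation matrix not positive semi-definite")
  invisible(cfg)
}

# Single-factor genetic correlation structure: corr(t, cp) = rho_cp and
# corr(t1, t2) = rho_1 * rho_2 for non-cp pairs; PSD whenever |rho| <= 1.
traitCorrelation <- function(traits) {
  r <- traits$rho_cp
  S <- outer(r, r)
  diag(S) <- 1
  dimnames(S) <- list(traits$name, traits$name)
  S
}

# Draw ancestral and Balding-Nichols subpopulation allele frequencies.
drawSubpopFreqs <- function(nVariants, mafRange, nSubpops, fst, seed) {
  set.seed(seed)
  pAnc <- runif(nVariants, mafRange[1], mafRange[2])
  if (fst > 0 && nSubpops > 1) {
    a <- pAnc * (1 - fst) / fst
    b <- (1 - pAnc) * (1 - fst) / fst
    pSub <- vapply(seq_len(nSubpops),
                   function(s) rbeta(nVariants, a, b),
                   numeric(nVariants))
  } else {
    pSub <- matrix(pAnc, nVariants, nSubpops)
  }
  list(pAnc = pAnc, pSub = pSub)
}

.variantTable <- function(nVariants, altFreq) {
  data.frame(variant_id = sprintf("rs%06d", seq_len(nVariants)),
             chrom = "1", pos = seq_len(nVariants) * 1000L,
             ref = "A", alt = "G", altFreq = altFreq)
}

# Hardy-Weinberg genotypes given per-subpopulation frequencies.
.drawDosages <- function(pSub, subpop, missingRate, seed) {
  set.seed(seed)
  m <- nrow(pSub); n <- length(subpop)
  d <- matrix(0L, m, n)
  for (s in unique(subpop)) {
    idx <- which(subpop == s)
    d[, idx] <- matrix(rbinom(m * length(idx), 2L, pSub[, s]),
                       m, length(idx))
  }
  if (missingRate > 0) {
    nm <- rbinom(1L, m * n, missingRate)
    if (nm > 0) d[sample.int(m * n, nm)] <- NA_integer_
  }
  d
}

#' Simulate genotypes under Balding-Nichols population structure
#'
#' Subpopulation allele frequencies are drawn around a shared ancestral
#' frequency with variance \code{fst * p * (1-p)}; genotypes are
#' Hardy-Weinberg within subpopulation and variants are independent (no
#' LD). Deterministic given the config seed.
#'
#' @param config a [simConfig()]; \code{nPool} samples are generated in one
#'   block (use [simulateCohort()] for large ascertained cohorts, which
#'   generates the pool in chunks).
#' @return a \linkS4class{GenotypeCohort}; \code{colData} records the
#'   subpopulation, \code{altFreq} is the ancestral (pool-level mean)
#'   frequency.
#' @export
simulateGenotypes <- function(config) {
  validateSimConfig(config)
  fr <- drawSubpopFreqs(config$nVariants, config$mafRange, config$nSubpops,
                        config$fst, fanSeed(config$seed, "freqs"))
  subpop <- rep_len(seq_len(config$nSubpops), config$nPool)
  d <- .drawDosages(fr$pSub, subpop, config$missingRate,
                    fanSeed(config$seed, "genotypes"))
  samples <- data.frame(sample_id = sprintf("S%06d", seq_len(config$nPool)),
                        subpop = subpop)
  gc <- GenotypeCohort(d, .variantTable(config$nVariants, fr$pAnc), samples)
  metadata(gc)$freqs <- fr
  gc
}

#' Draw correlated per-variant true effects for all traits
#'
#' Effects are drawn jointly across traits from a single-factor Gaussian
#' model in which each trait's per-variant effects correlate \code{rho_cp}
#' with the disorder-liability trait, then each trait is rescaled so the
#' variance of its genetic score (sum of weight times dosage over
#' independent variants) equals \code{h2}.
#'
#' @param config a [simConfig()]
#' @param altFreq effect-allele frequencies used for the h2 scaling
#'   (defaults to frequencies redrawn from the config seed).
#' @return matrix of true effects, variants x traits (named columns)
#' @export
simulateEffects <- function(config, altFreq = NULL) {
  validateSimConfig(config)
  if (is.null(altFreq))
    altFreq <- drawSubpopFreqs(config$nVariants, config$mafRange,
                               config$nSubpops, config$fst,
                               fanSeed(config$seed, "freqs"))$pAnc
  tr <- config$traits
  m <- config$nVariants
  set.seed(fanSeed(config$seed, "effects"))
  f <- rnorm(m)                     # shared factor
  beta <- vapply(seq_len(nrow(tr)), function(i) {
    r <- tr$rho_cp[i]
    raw <- r * f + sqrt(1 - r^2) * rnorm(m)
    v <- sum(raw^2 * 2 * altFreq * (1 - altFreq))
    if (tr$h2[i] == 0 || v == 0) rep(0, m) else raw * sqrt(tr$h2[i] / v)
  }, numeric(m))
  colnames(beta) <- tr$name
  rownames(beta) <- sprintf("rs%06d", seq_len(m))
  beta
}

# genetic score of the disorder trait, centred at its expectation
.geneticScore <- function(dosage, beta, altFreq) {
  d <- dosage
  if (anyNA(d)) {
    # mean-impute for liability construction only
    imp <- 2 * altFreq
    naIdx <- which(is.na(d))
    d[naIdx] <- imp[(naIdx - 1L) %% nrow(d) + 1L]
  }
  as.numeric(crossprod(d, beta)) - 2 * sum(beta * altFreq)
}

#' Assign liabilities, case status and covariates; ascertain the cohort
#'
#' Liability is the centred disorder-trait genetic score plus independent
#' Gaussian noise scaled so total variance is 1; an individual is a case
#' iff liability exceeds the threshold \code{qnorm(1 - K)}. The requested
#' numbers of cases and controls are then sampled at random, and ages and
#' sexes are drawn per group from the config's age and sex models (ages
#' truncated at 0).
#'
#' @param genotypes a \linkS4class{GenotypeCohort} of the pool
#' @param effects matrix from [simulateEffects()] (column \code{"cp"} used)
#' @param config a [simConfig()]
#' @param ascertain if FALSE, return the whole labelled pool (no sampling)
#' @return a \linkS4class{GenotypeCohort} with phenotype columns
#'   \code{case_status}, \code{age}, \code{sex}, \code{true_liability};
#'   \code{metadata()$pool} records pool size and pool case count.
#' @export
assignPhenotypes <- function(genotypes, effects, config, ascertain = TRUE) {
  beta <- effects[, "cp"]
  p <- mcols(rowRanges(genotypes))$altFreq
  h2 <- sum(beta^2 * 2 * p * (1 - p))
  g <- .geneticScore(dosages(genotypes), beta, p)
  set.seed(fanSeed(config$seed, "phenotypes"))
  liab <- g + rnorm(ncol(genotypes), 0, sqrt(max(0, 1 - h2)))
  status <- ifelse(liab > qnorm(1 - config$K), "case", "control")

  keep <- seq_along(liab)
  if (ascertain) {
    ic <- which(status == "case"); io <- which(status == "control")
    if (length(ic) < config$targetCases)
      stop("simulation error: pool produced ", length(ic), " cases but ",
           config$targetCases, " requested (shortfall ",
           config$targetCases - length(ic), ")")
    if (length(io) < config$targetControls)
      stop("simulation error: pool produced ", length(io),
           " controls but ", config$targetControls, " requested")
    keep <- c(sample(ic, config$targetCases),
              sample(io, config$targetControls))
  }
  out <- genotypes[, keep]
  cd <- colData(out)
  cd$case_status <- status[keep]
  cd$true_liability <- liab[keep]
  cd$genetic_score <- g[keep]
  cd$cohort <- config$cohortLabel

  set.seed(fanSeed(config$seed, "covariates"))
  nK <- length(keep)
  isCase <- cd$case_status == "case"
  age <- numeric(nK); sex <- character(nK)
  for (grp in c("case", "control")) {
    idx <- which((cd$case_status == grp))
    am <- config$ageModel[[grp]]
    age[idx] <- pmax(0, rnorm(length(idx), am[["mean"]], am[["sd"]]))
    sex[idx] <- ifelse(runif(length(idx)) < config$sexModel[[grp]],
                       "female", "male")
  }
  cd$age <- age; cd$sex <- sex
  colData(out) <- cd
  metadata(out)$pool <- list(n_pool = ncol(genotypes),
                             n_cases_pool = sum(status == "case"),
                             h2_realized = h2)
  out
}

#' Create an estimated weight-set from true effects
#'
#' Adds per-variant Gaussian estimation noise with variance
#' \code{1 / (2 p (1-p) n_eff)} — the sampling variance of a GWAS effect
#' estimate for a standardized trait — so the discovery effective sample
#' size is the single knob controlling weight accuracy.
#'
#' @param trueEffects numeric vector of per-variant true effects
#' @param nEff discovery effective sample size (> 0)
#' @param variants data.frame as from [variantInfo()] (provides ids,
#'   alleles and \code{altFreq} in (0,1))
#' @param trait trait label
#' @param seed integer seed
#' @return a \linkS4class{WeightSet} with the ALT allele as effect allele
#' @export
makeWeightSet <- function(trueEffects, nEff, variants, trait, seed = 1L) {
  if (nEff <= 0) stop("n_eff must be positive")
  p <- variants$altFreq
  if (any(p <= 0 | p >= 1)) stop("effect allele frequency outside (0,1)")
  set.seed(seed)
  w <- trueEffects + rnorm(length(trueEffects),
                           0, sqrt(1 / (2 * p * (1 - p) * nEff)))
  WeightSet(data.frame(variant_id = variants$variant_id,
                       chrom = variants$chrom, pos = variants$pos,
                       effect_allele = variants$alt,
                       other_allele = variants$ref,
                       weight = w, effect_allele_freq = p),
            trait = trait)
}

.gamete <- function(dos) rbinom(length(dos), 1L, dos / 2)

#' Append related individuals to a cohort
#'
#' Duplicates copy dosages verbatim; offspring receive one gamete from an
#' existing cohort member and one drawn from the population allele
#' frequencies; full siblings are two children of the same (existing +
#' simulated) parent pair. Appended samples copy the phenotype row of
#' their anchor sample and record the relationship; the truth table of
#' injected pairs is stored in \code{metadata()$related_truth}.
#'
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @param relatedPairs named list of counts (\code{duplicate},
#'   \code{parent_offspring}, \code{full_sib})
#' @param seed integer seed
#' @return the augmented \linkS4class{GenotypeCohort}
#' @export
injectRelatedPairs <- function(genotypes, relatedPairs, seed = 1L) {
  counts <- unlist(relatedPairs)
  if (is.null(counts) || sum(counts) == 0) return(genotypes)
  bad <- setdiff(names(counts), c("duplicate", "parent_offspring", "full_sib"))
  if (length(bad)) stop("unknown relationship: ", paste(bad, collapse = ", "))
  set.seed(seed)
  d <- dosages(genotypes)
  p <- mcols(rowRanges(genotypes))$altFreq
  anchors <- sample(colnames(genotypes),
                    sum(counts) , replace = FALSE)
  newCols <- list(); truth <- list(); anchorOf <- character(); rel <- character()
  ai <- 1L
  for (r in names(counts)) {
    for (k in seq_len(counts[[r]])) {
      a <- anchors[ai]; ai <- ai + 1L
      da <- d[, a]
      if (r == "duplicate") {
        id <- paste0(a, "_dup")
        newCols[[id]] <- da
        truth[[length(truth) + 1L]] <- c(a, id, r)
        anchorOf <- c(anchorOf, a); rel <- c(rel, r)
      } else if (r == "parent_offspring") {
        id <- paste0(a, "_child")
        daImp <- ifelse(is.na(da), rbinom(length(da), 2L, p), da)
        newCols[[id]] <- .gamete(daImp) + rbinom(length(da), 1L, p)
        truth[[length(truth) + 1L]] <- c(a, id, r)
        anchorOf <- c(anchorOf, a); rel <- c(rel, r)
      } else {                         # full_sib
        daImp <- ifelse(is.na(da), rbinom(length(da), 2L, p), da)
        other <- rbinom(length(da), 2L, p)
        s1 <- .gamete(daImp) + .gamete(other)
        s2 <- .gamete(daImp) + .gamete(other)
        id1 <- paste0(a, "_sib1"); id2 <- paste0(a, "_sib2")
        newCols[[id1]] <- s1; newCols[[id2]] <- s2
        truth[[length(truth) + 1L]] <- c(id1, id2, r)
        anchorOf <- c(anchorOf, a, a); rel <- c(rel, r, r)
      }
    }
  }
  addMat <- do.call(cbind, newCols)
  cd <- as.data.frame(colData(genotypes))
  addCd <- cd[match(anchorOf, cd$sample_id), , drop = FALSE]
  addCd$sample_id <- colnames(addMat)
  rownames(addCd) <- addCd$sample_id
  allD <- cbind(d, addMat)
  allCd <- rbind(cd, addCd)
  out <- GenotypeCohort(allD, variantInfo(genotypes), allCd)
  metadata(out) <- metadata(genotypes)
  metadata(out)$related_truth <- data.frame(
    sample_i = vapply(truth, `[`, "", 1L),
    sample_j = vapply(truth, `[`, "", 2L),
    relationship = vapply(truth, `[`, "", 3L))
  out
}

#' Simulate a full ascertained case-control cohort with weight-sets
#'
#' End-to-end generator: allele frequencies and correlated true effects
#' are drawn once; the liability pool is generated in chunks of
#' \code{chunkSize} individuals (keeping memory bounded at large pool
#' sizes), cases and the first sufficient controls are retained; related
#' pairs are appended; one noisy \linkS4class{WeightSet} per trait is
#' estimated from the true effects.
#'
#' @param config a [simConfig()]
#' @return list with elements \code{cohort} (\linkS4class{GenotypeCohort}),
#'   \code{weights} (named list of \linkS4class{WeightSet}) and
#'   \code{truth} (true effects, pool counts, realized h2, the config)
#' @export
simulateCohort <- function(config) {
  validateSimConfig(config)
  fr <- drawSubpopFreqs(config$nVariants, config$mafRange, config$nSubpops,
                        config$fst, fanSeed(config$seed, "freqs"))
  beta <- simulateEffects(config, altFreq = fr$pAnc)
  betaCP <- beta[, "cp"]
  p <- fr$pAnc
  h2 <- sum(betaCP^2 * 2 * p * (1 - p))
  thr <- qnorm(1 - config$K)

  set.seed(fanSeed(config$seed, "genotypes"))
  caseD <- list(); ctrlD <- list()
  caseG <- numeric(); ctrlG <- numeric()
  caseL <- numeric(); ctrlL <- numeric()
  caseSub <- integer(); ctrlSub <- integer()
  nDone <- 0L; nCasesPool <- 0L; nCtrlNeeded <- config$targetControls
  while (nDone < config$nPool) {
    nThis <- min(config$chunkSize, config$nPool - nDone)
    subpop <- rep_len(seq_len(config$nSubpops), nThis)
    d <- matrix(0L, config$nVariants, nThis)
    for (s in seq_len(config$nSubpops)) {
      idx <- which(subpop == s)
      d[, idx] <- matrix(rbinom(config$nVariants * length(idx), 2L,
                                fr$pSub[, s]),
                         config$nVariants, length(idx))
    }
    if (config$missingRate > 0) {
      nm <- rbinom(1L, length(d), config$missingRate)
      if (nm > 0) d[sample.int(length(d), nm)] <- NA_integer_
    }
    g <- .geneticScore(d, betaCP, p)
    liab <- g + rnorm(nThis, 0, sqrt(max(0, 1 - h2)))
    isCase <- liab > thr
    nCasesPool <- nCasesPool + sum(isCase)
    if (any(isCase)) {
      caseD[[length(caseD) + 1L]] <- d[, isCase, drop = FALSE]
      caseG <- c(caseG, g[isCase]); caseL <- c(caseL, liab[isCase])
      caseSub <- c(caseSub, subpop[isCase])
    }
    if (length(ctrlG) < nCtrlNeeded && any(!isCase)) {
      take <- which(!isCase)[seq_len(min(sum(!isCase),
                                         nCtrlNeeded - length(ctrlG)))]
      ctrlD[[length(ctrlD) + 1L]] <- d[, take, drop = FALSE]
      ctrlG <- c(ctrlG, g[take]); ctrlL <- c(ctrlL, liab[take])
      ctrlSub <- c(ctrlSub, subpop[take])
    }
    nDone <- nDone + nThis
  }
  if (length(caseG) < config$targetCases)
    stop("simulation error: pool produced ", length(caseG),
         " cases but ", config$targetCases, " requested (shortfall ",
         config$targetCases - length(caseG), ")")
  if (length(ctrlG) < config$targetControls)
    stop("simulation error: pool produced too few controls")
  pick <- sample(length(caseG), config$targetCases)
  caseMat <- do.call(cbind, caseD)[, pick, drop = FALSE]
  ctrlMat <- do.call(cbind, ctrlD)
  d <- cbind(caseMat, ctrlMat)
  n <- ncol(d)
  samples <- data.frame(
    sample_id = sprintf("S%06d", seq_len(n)),
    subpop = c(caseSub[pick], ctrlSub),
    case_status = rep(c("case", "control"),
                      c(config$targetCases, config$targetControls)),
    true_liability = c(caseL[pick], ctrlL),
    genetic_score = c(caseG[pick], ctrlG),
    cohort = config$cohortLabel)

  set.seed(fanSeed(config$seed, "covariates"))
  samples$age <- NA_real_; samples$sex <- NA_character_
  for (grp in c("case", "control")) {
    idx <- which(samples$case_status == grp)
    am <- config$ageModel[[grp]]
    samples$age[idx] <- pmax(0, rnorm(length(idx), am[["mean"]], am[["sd"]]))
    samples$sex[idx] <- ifelse(runif(length(idx)) < config$sexModel[[grp]],
                               "female", "male")
  }
  cohort <- GenotypeCohort(d, .variantTable(config$nVariants, fr$pAnc),
                           samples)
  metadata(cohort)$freqs <- fr
  metadata(cohort)$pool <- list(n_pool = config$nPool,
                                n_cases_pool = nCasesPool,
                                h2_realized = h2)
  cohort <- injectRelatedPairs(cohort, config$relatedPairs,
                               fanSeed(config$seed, "related"))

  vi <- .variantTable(config$nVariants, fr$pAnc)
  wSeed <- fanSeed(config$seed, "weights")
  weights <- lapply(seq_len(nrow(config$traits)), function(i)
    makeWeightSet(beta[, i], config$traits$n_eff[i], vi,
                  config$traits$name[i], seed = wSeed + i))
  names(weights) <- config$traits$name
  list(cohort = cohort, weights = weights,
       truth = list(effects = beta, n_pool = config$nPool,
                    n_cases_pool = nCasesPool, h2_realized = h2,
                    config = config))
}
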