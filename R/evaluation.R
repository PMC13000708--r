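#' @importFrom stats glm binomial coef pnorm qnorm dnorm pchisq pt qt
#'   chisq.test p.adjust sd var setNames complete.cases
NULL

#' Effective sample size of a case-control GWAS
#'
#' \code{4 / (1/n_cases + 1/n_controls)}: the balanced-design size with
#' equivalent power. Equals the total n for a balanced design and
#' approaches \code{4 n_cases} as controls grow without bound.
#'
#' @param nCases,nControls positive counts
#' @return effective sample size
#' @export
effectiveSampleSize <- function(nCases, nControls) {
  if (any(nCases <= 0) || any(nControls <= 0))
    stop("counts must be positive")
  4 / (1 / nCases + 1 / nControls)
}

#' Benjamini-Hochberg step-up adjustment over a family of m tests
#'
#' Step-up adjusted p-values \code{p_adj(i) = min_{j >= i} m p(j) / j}
#' capped at 1, with the family size \code{m} possibly exceeding the
#' number of p-values supplied.
#'
#' @param p p-values in [0,1]
#' @param m family size (default \code{length(p)})
#' @return adjusted p-values in the original order
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0,1]")
  if (length(p) > m) stop("more p-values than the family size m")
  p.adjust(p, method = "BH", n = m)
}

#' Pearson chi-squared test for a 2x2 table with Yates correction
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins
#' @param continuity apply the Yates continuity correction (default TRUE)
#' @return list: statistic, df (1), p.value
#' @export
chiSquare2x2 <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("a 2x2 table is required")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in 2x2 table")
  ct <- chisq.test(table, correct = continuity)
  list(statistic = unname(ct$statistic), df = 1L, p.value = ct$p.value)
}

#' Welch two-sample t-test from summary statistics
#'
#' Welch statistic and Satterthwaite degrees of freedom computed from
#' group means, SDs and sizes, with a 95 percent CI for the mean
#' difference.
#'
#' @param mean1,sd1,n1 first group summaries
#' @param mean2,sd2,n2 second group summaries
#' @return list: t, df, diff, ci (length-2), p.value (two-tailed)
#' @export
welchTFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 <= 1 || n2 <= 1 || sd1 <= 0 || sd2 <= 0)
    stop("need n > 1 and sd > 0 in both groups")
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  ci <- (mean1 - mean2) + c(-1, 1) * qt(0.975, df) * se
  list(t = t, df = df, diff = mean1 - mean2, ci = ci,
       p.value = 2 * pt(-abs(t), df))
}

#' Mann-Whitney AUC
#'
#' Probability that a random case outscores a random control, ties
#' counted 0.5 (rank-based computation, exactly the pairwise concordance).
#'
#' @param score numeric predictor
#' @param y case indicator (logical, or 0/1, or "case"/"control")
#' @return AUC in [0,1]
#' @export
aucMW <- function(score, y) {
  y <- .asCase(y)
  nP <- sum(y); nN <- sum(!y)
  if (nP == 0 || nN == 0) stop("both classes must be present")
  r <- rank(score)
  (sum(r[y]) - nP * (nP + 1) / 2) / (nP * nN)
}

.asCase <- function(y) {
  if (is.character(y) || is.factor(y)) as.character(y) == "case"
  else as.logical(y)
}

#' One-tailed Z inference for an AUC
#'
#' Hanley-McNeil standard error
#' \code{SE^2 = [A(1-A) + (n+ - 1)(Q1 - A^2) + (n- - 1)(Q2 - A^2)]/(n+ n-)}
#' with \code{Q1 = A/(2-A)}, \code{Q2 = 2A^2/(1+A)}; \code{Z = (A - 0.5)/SE}
#' against the null AUC of 0.5, one-tailed p from the standard normal, and
#' the 90 percent one-sided lower bound \code{A - 1.6449 SE}.
#'
#' @param auc AUC in (0,1)
#' @param nCases,nControls class sizes
#' @return list: auc, se, z, p.value (one-tailed), lb90
#' @export
aucInference <- function(auc, nCases, nControls) {
  if (nCases < 1 || nControls < 1) stop("degenerate class sizes")
  if (auc <= 0 || auc >= 1) stop("AUC must be in (0,1)")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nCases - 1) * (q1 - auc^2) +
              (nControls - 1) * (q2 - auc^2)) / (nCases * nControls))
  z <- (auc - 0.5) / se
  list(auc = auc, se = se, z = z, p.value = 1 - pnorm(z),
       lb90 = auc - qnorm(0.95) * se)
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Thin wrapper over \code{glm(family = binomial)} that fails loudly on
#' non-convergence or (quasi-)separation, naming the offending predictor.
#'
#' @param y case indicator
#' @param X data.frame or matrix of predictors (covariates included);
#'   an intercept is added
#' @return data.frame per predictor: estimate, se, z, p (two-tailed
#'   Wald), or, ci_lo, ci_hi (95 percent Wald, exponentiated)
#' @export
fitLogistic <- function(y, X) {
  y <- .asCase(y)
  X <- as.data.frame(X)
  const <- vapply(X, function(c) length(unique(c)) < 2, logical(1))
  if (any(const))
    stop("constant predictor: ", paste(names(X)[const], collapse = ", "))
  if (length(y) <= ncol(X) + 1) stop("more parameters than observations")
  dat <- cbind(.y = as.integer(y), X)
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  if (!fit$converged || sepWarn) {
    worst <- rownames(cf)[which.max(abs(cf[, 1]))]
    stop("logistic fit failed (separation or non-convergence); ",
         "predictor: ", worst)
  }
  data.frame(predictor = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             z = cf[, 3], p = cf[, 4], or = exp(cf[, 1]),
             ci_lo = exp(cf[, 1] - 1.959964 * cf[, 2]),
             ci_hi = exp(cf[, 1] + 1.959964 * cf[, 2]),
             row.names = NULL)
}

# Covariate design matrix: sex as indicator plus PC columns; NULL if none.
.covariateMatrix <- function(samples, pcs = NULL, useSex = TRUE) {
  out <- NULL
  if (useSex && "sex" %in% names(samples) &&
      length(unique(samples$sex)) > 1)
    out <- cbind(sexmale = as.numeric(samples$sex == "male"))
  if (!is.null(pcs)) {
    sc <- if (inherits(pcs, "pcResult")) pcs$scores else as.matrix(pcs)
    sc <- sc[match(samples$sample_id, rownames(sc)), , drop = FALSE]
    out <- cbind(out, sc)
  }
  out
}

#' Single- and multiple-PGS logistic association
#'
#' One logistic model per trait (standardized PGS + covariates) and one
#' joint model with all PGS simultaneously, reporting the odds ratio per
#' SD of PGS with 95 percent Wald CIs; Benjamini-Hochberg adjustment over
#' \code{mBH} comparisons is applied within the single-model family and
#' within the multiple-model family separately.
#'
#' @param scoreMatrix samples x traits matrix of standardized scores
#' @param samples sample sheet (provides \code{case_status} and \code{sex})
#' @param pcs \code{pcResult} or samples x k matrix of PCs, or NULL
#' @param adjust include sex + PCs as covariates (default TRUE)
#' @param mBH family size for the adjustment (default 8)
#' @return data.frame: trait, model, or_per_sd, ci_lo, ci_hi, p, p_adj
#' @export
runAssociation <- function(scoreMatrix, samples, pcs = NULL, adjust = TRUE,
                           mBH = 8L) {
  y <- .asCase(samples$case_status)
  covs <- if (adjust) .covariateMatrix(samples, pcs) else NULL
  traits <- colnames(scoreMatrix)
  single <- do.call(rbind, lapply(traits, function(tr) {
    X <- setNames(data.frame(scoreMatrix[, tr]), tr)
    if (!is.null(covs)) X <- cbind(X, covs)
    cf <- fitLogistic(y, X)
    cf[cf$predictor == tr, ]
  }))
  Xall <- as.data.frame(scoreMatrix)
  if (!is.null(covs)) Xall <- cbind(Xall, covs)
  cfm <- fitLogistic(y, Xall)
  cfm <- cfm[cfm$predictor %in% traits, ]
  res <- rbind(
    data.frame(trait = single$predictor, model = "single",
               or_per_sd = single$or, ci_lo = single$ci_lo,
               ci_hi = single$ci_hi, p = single$p,
               p_adj = bhAdjust(single$p, mBH)),
    data.frame(trait = cfm$predictor, model = "multiple",
               or_per_sd = cfm$or, ci_lo = cfm$ci_lo, ci_hi = cfm$ci_hi,
               p = cfm$p, p_adj = bhAdjust(cfm$p, mBH)))
  rownames(res) <- NULL
  res
}

# R-squared of an OLS fit via QR, with a rank check.
.r2 <- function(y, X) {
  X1 <- cbind(1, X)
  q <- qr(X1)
  if (q$rank < ncol(X1)) stop("collinear design in R2 computation")
  res <- qr.resid(q, y)
  1 - sum(res^2) / sum((y - mean(y))^2)
}

#' Observed-scale incremental R-squared of a predictor
#'
#' Difference in linear-model R-squared between the full model
#' (predictor + covariates) and the reduced model (covariates only), with
#' the binary case indicator as outcome; nonnegative by nesting.
#'
#' @param y case indicator
#' @param score numeric predictor (or samples x p matrix for a joint
#'   predictor set)
#' @param covariates matrix of covariates or NULL (reduced model =
#'   intercept only)
#' @return incremental observed-scale R-squared
#' @export
r2Observed <- function(y, score, covariates = NULL) {
  y <- as.numeric(.asCase(y))
  S <- as.matrix(score)
  if (is.null(covariates)) {
    # no reduced model: incremental R2 is the plain model R2; for a single
    # predictor that is the squared Pearson correlation
    if (ncol(S) == 1L) {
      r <- stats::cor(y, S[, 1L])
      if (is.na(r)) stop("collinear design in R2 computation")
      return(r^2)
    }
    return(.r2(y, S))
  }
  .r2(y, cbind(S, covariates)) - .r2(y, covariates)
}

#' Observed-scale to liability-scale R-squared (Lee transformation)
#'
#' Corrects the observed-scale variance explained for the binary scale
#' and for case-control ascertainment, given the population prevalence
#' \code{K} and the sample case proportion \code{P}:
#' \code{t = qnorm(1-K)}, \code{z = dnorm(t)}, \code{m = z/K},
#' \code{C = K(1-K)/z^2 * K(1-K)/(P(1-P))},
#' \code{theta = m (P-K)/(1-K) (m (P-K)/(1-K) - t)}, and
#' \code{R2_l = R2_obs C / (1 + R2_obs theta C)}. At \code{K = P} the
#' correction reduces to the scale factor alone (\code{theta = 0}); at
#' \code{K = P = 0.5} that factor is \code{pi/2}.
#'
#' @param r2Obs observed-scale R-squared in [0,1)
#' @param K population prevalence in (0,1)
#' @param P sample case proportion in (0,1)
#' @return list: r2_obs, K, P, t, z, m, C, theta, r2_l
#' @export
liabilityTransform <- function(r2Obs, K, P) {
  if (!(K > 0 && K < 1)) stop("K must be in (0,1)")
  if (!(P > 0 && P < 1)) stop("P must be in (0,1)")
  if (r2Obs < 0 || r2Obs >= 1) stop("r2Obs must be in [0,1)")
  t <- qnorm(1 - K)
  z <- dnorm(t)
  m <- z / K
  C <- (K * (1 - K) / z^2) * (K * (1 - K) / (P * (1 - P)))
  theta <- m * ((P - K) / (1 - K)) * (m * ((P - K) / (1 - K)) - t)
  list(r2_obs = r2Obs, K = K, P = P, t = t, z = z, m = m, C = C,
       theta = theta, r2_l = r2Obs * C / (1 + r2Obs * theta * C))
}

#' Bootstrap inference for liability-scale R-squared
#'
#' Individuals are resampled with replacement \code{B} times; the sample
#' case proportion, observed R-squared and liability R-squared are
#' recomputed per resample (resamples with a single class are redrawn and
#' counted). The SE is the bootstrap SD of \code{R2_l}, the 90 percent
#' one-sided lower bound is the 5th percentile, and \code{Z = R2_l / SE}
#' gives a one-tailed p against \code{R2_l = 0}.
#'
#' @param y case indicator
#' @param score predictor (vector or matrix for a joint set)
#' @param covariates covariate matrix or NULL
#' @param K population prevalence
#' @param B bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return list: r2_obs, r2_l, se, lb90, z, p.value, n_redrawn, boot
#' @export
bootstrapLiability <- function(y, score, covariates = NULL, K,
                               B = 1000L, seed = 1L) {
  if (B < 2) stop("B must be >= 2")
  y <- as.numeric(.asCase(y))
  S <- as.matrix(score)
  n <- length(y)
  point <- liabilityTransform(r2Observed(y, S, covariates), K, mean(y))
  set.seed(seed)
  boot <- numeric(B)
  redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (var(y[idx]) > 0) break
      redrawn <- redrawn + 1L
    }
    cb <- if (is.null(covariates)) NULL
          else covariates[idx, , drop = FALSE]
    r2b <- r2Observed(y[idx], S[idx, , drop = FALSE], cb)
    boot[b] <- liabilityTransform(r2b, K, mean(y[idx]))$r2_l
  }
  se <- sd(boot)
  z <- point$r2_l / se
  list(r2_obs = point$r2_obs, r2_l = point$r2_l, se = se,
       lb90 = unname(stats::quantile(boot, 0.05)), z = z,
       p.value = 1 - pnorm(z), n_redrawn = redrawn, boot = boot)
}

#' Run the full evaluation battery on a scored cohort
#'
#' For each stratum (the whole case set, plus any case strata evaluated
#' against the full control set) computes: single- and multiple-PGS
#' logistic association (OR per SD, B-H over 8 comparisons per family);
#' AUC per trait and for the combined predictor with one-tailed
#' Hanley-McNeil Z inference (B-H over 9); and observed-to-liability
#' R-squared with bootstrap intervals (B-H over 9). The combined
#' predictor is the linear predictor of a PGS-only logistic model by
#' default (set \code{rocAdjusted = TRUE} to include covariates in it);
#' combined liability R-squared uses all PGS jointly in the full model.
#'
#' @param scores named list of \linkS4class{PGScore} (or samples x traits
#'   matrix of standardized scores)
#' @param samples sample sheet data.frame aligned to the scores
#' @param pcs \code{pcResult}, PC matrix, or NULL
#' @param K population prevalence for the liability transformation
#' @param strata optional column name in \code{samples} labelling case
#'   strata; each stratum's cases are evaluated against all controls
#' @param B bootstrap replicates (default 1000)
#' @param seed integer seed
#' @param adjust include sex + PCs in the regression models (default TRUE)
#' @param rocAdjusted include covariates in the combined ROC predictor
#' @return an \linkS4class{EvaluationReport}
#' @export
evaluateCohort <- function(scores, samples, pcs = NULL, K,
                           strata = NULL, B = 1000L, seed = 1L,
                           adjust = TRUE, rocAdjusted = FALSE) {
  SM <- if (is.list(scores))
    vapply(scores, function(s) s$standardized, numeric(nrow(samples)))
  else as.matrix(scores)
  if (is.list(scores)) colnames(SM) <- names(scores)
  traits <- colnames(SM)
  y <- .asCase(samples$case_status)
  covs <- if (adjust) .covariateMatrix(samples, pcs) else NULL

  strataSets <- list(all = rep(TRUE, length(y)))
  if (!is.null(strata)) {
    levs <- unique(samples[[strata]][y])
    levs <- levs[!is.na(levs)]
    for (lv in levs) {
      keep <- !y | (!is.na(samples[[strata]]) & samples[[strata]] == lv)
      if (sum(y & keep) == 0) {
        warning("stratum '", lv, "' has no cases; skipped")
        next
      }
      strataSets[[as.character(lv)]] <- keep
    }
  }

  assoc <- disc <- liab <- list()
  for (sn in names(strataSets)) {
    keep <- strataSets[[sn]]
    yk <- y[keep]; Sk <- SM[keep, , drop = FALSE]
    ck <- if (is.null(covs)) NULL else covs[keep, , drop = FALSE]
    sk <- samples[keep, , drop = FALSE]
    nC <- sum(yk); nN <- sum(!yk)

    a <- runAssociation(Sk, sk, pcs = pcs, adjust = adjust,
                        mBH = max(8L, length(traits)))
    a$stratum <- sn
    assoc[[sn]] <- a

    Xcomb <- as.data.frame(Sk)
    if (rocAdjusted && !is.null(ck)) Xcomb <- cbind(Xcomb, ck)
    combFit <- fitLogistic(yk, Xcomb)
    est <- combFit$estimate[match(traits, combFit$predictor)]
    lp <- as.numeric(Sk %*% est)
    preds <- c(as.list(as.data.frame(Sk)), list(combined = lp))
    dRows <- lapply(names(preds), function(nm) {
      ai <- aucInference(aucMW(preds[[nm]], yk), nC, nN)
      data.frame(predictor = nm, stratum = sn, auc = ai$auc, se = ai$se,
                 z = ai$z, p = ai$p.value, lb90 = ai$lb90)
    })
    dd <- do.call(rbind, dRows)
    dd$p_adj <- bhAdjust(dd$p, max(9L, nrow(dd)))
    disc[[sn]] <- dd

    lRows <- lapply(seq_along(traits), function(i) {
      bl <- bootstrapLiability(yk, Sk[, i], ck, K, B = B,
                               seed = seed + i)
      data.frame(predictor = traits[i], stratum = sn, r2_obs = bl$r2_obs,
                 K = K, P = nC / (nC + nN), r2_l = bl$r2_l, se = bl$se,
                 lb90 = bl$lb90, z = bl$z, p = bl$p.value)
    })
    blc <- bootstrapLiability(yk, Sk, ck, K, B = B,
                              seed = seed + length(traits) + 1L)
    lRows[[length(lRows) + 1L]] <-
      data.frame(predictor = "combined", stratum = sn, r2_obs = blc$r2_obs,
                 K = K, P = nC / (nC + nN), r2_l = blc$r2_l, se = blc$se,
                 lb90 = blc$lb90, z = blc$z, p = blc$p.value)
    ll <- do.call(rbind, lRows)
    ll$p_adj <- bhAdjust(ll$p, max(9L, nrow(ll)))
    liab[[sn]] <- ll
  }

  new("EvaluationReport",
      association = do.call(rbind, c(assoc, list(make.row.names = FALSE))),
      discrimination = do.call(rbind, c(disc, list(make.row.names = FALSE))),
      liability = do.call(rbind, c(liab, list(make.row.names = FALSE))),
      meta = list(K = K, n_cases = sum(y), n_controls = sum(!y),
                  B = B, seed = seed, traits = traits,
                  strata = setdiff(names(strataSets), "all"),
                  adjusted = adjust))
}
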