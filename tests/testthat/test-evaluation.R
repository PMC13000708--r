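test_that("effective sample size follows the harmonic-mean formula", {
  expect_equal(effectiveSampleSize(1000, 1000), 2000)
  expect_equal(effectiveSampleSize(624, 495687), 2492.87, tolerance = 1e-4)
  expect_equal(effectiveSampleSize(525, 1e12), 4 * 525, tolerance = 1e-6)
  expect_error(effectiveSampleSize(0, 10), "positive")
})

test_that("BH adjustment equals the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2, 0.5, 0.7, 0.9)
  expect_equal(bhAdjust(p, 8),
               c(0.08, 0.08, 0.08, 0.08, 0.32, 2 / 3, 0.8, 0.9),
               tolerance = 1e-12)
  expect_equal(bhAdjust(rep(1, 5), 5), rep(1, 5))
  expect_equal(bhAdjust(0.031, 1), 0.031)
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0,1\\]")
  expect_error(bhAdjust(c(0.1, 0.2), m = 1), "family size")
  set.seed(7)
  for (i in 1:100) {
    n <- sample(1:12, 1); m <- n + sample(0:4, 1)
    pv <- round(runif(n), 3)
    expect_equal(bhAdjust(pv, m), stepUpBH(pv, m), tolerance = 1e-12)
  }
})

test_that("sex-by-status chi-squared tests reproduce the printed cohort
           statistics", {
  aus <- matrix(c(11750, 210, 8660, 315), 2, byrow = TRUE)
  expect_equal(chiSquare2x2(aus)$statistic, 63.80, tolerance = 0.01 / 63.8)
  myc <- matrix(c(1004, 167, 606, 155), 2, byrow = TRUE)
  expect_equal(chiSquare2x2(myc)$statistic, 11.95, tolerance = 0.01 / 11.95)
  prop <- matrix(c(20, 40, 10, 20), 2)
  expect_equal(chiSquare2x2(prop)$statistic, 0, tolerance = 1e-12)
  expect_error(chiSquare2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "margin")
})

test_that("Welch t from summary statistics matches direct computation", {
  eq <- welchTFromSummary(5, 1, 50, 5, 2, 80)
  expect_equal(eq$t, 0)
  # age contrast from rounded cohort summaries
  w <- welchTFromSummary(61.2, 9.6, 20338, 8.9, 5.1, 461)
  expect_equal(w$t, 211.8, tolerance = 0.005)
  expect_equal(w$df, 537, tolerance = 0.005)
  expect_gte(w$df, min(461 - 1, 20338 - 1))          # Welch df bounds
  expect_lte(w$df, 461 + 20338 - 2)
  expect_error(welchTFromSummary(1, 0, 10, 2, 1, 10), "sd > 0")
})

test_that("AUC equals brute-force pairwise concordance", {
  expect_equal(aucMW(c(1, 3, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(aucMW(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(aucMW(c(1, 2, 3, 1, 2, 3),
                     rep(c("case", "control"), each = 3)), 0.5)
  expect_error(aucMW(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # independent library cross-check on a non-trivial instance
  set.seed(13)
  sc <- rnorm(300); yy <- rep(c(TRUE, FALSE), c(100, 200))
  expect_equal(aucMW(sc, yy),
               as.numeric(pROC::auc(pROC::roc(yy, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  set.seed(17)
  for (i in 1:100) {
    nP <- sample(1:8, 1); nN <- sample(1:8, 1)
    s <- sample(0:5, nP + nN, replace = TRUE)       # ties likely
    y <- rep(c(TRUE, FALSE), c(nP, nN))
    expect_equal(aucMW(s, y), bruteAUC(s, y))
  }
})

test_that("AUC Z-inference uses the Hanley-McNeil standard error", {
  ai <- aucInference(0.75, 2, 2)
  expect_equal(ai$se, 0.2763, tolerance = 1e-3)
  expect_equal(ai$z, 0.905, tolerance = 1e-3)
  null <- aucInference(0.5, 100, 100)
  expect_equal(null$z, 0)
  expect_equal(null$p.value, 0.5)
  expect_equal(null$lb90, 0.5 - qnorm(0.95) * null$se)
  expect_error(aucInference(1, 5, 5), "in \\(0,1\\)")
})

test_that("logistic OR matches the 2x2 closed form and ignores orthogonal
           covariates", {
  # 30/70 exposed cases, 10/90 exposed controls -> OR 3.857
  y <- rep(c(TRUE, FALSE), c(100, 100))
  x <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f <- fitLogistic(y, data.frame(exposure = x))
  expect_equal(f$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_true(f$ci_lo < f$or & f$or < f$ci_hi)
  # a covariate balanced within every exposure-outcome cell changes nothing
  cells <- expand.grid(y = c(TRUE, FALSE), x = c(1, 0))
  counts <- c(30, 10, 70, 90)
  yy <- rep(cells$y, counts * 2)
  xx <- rep(cells$x, counts * 2)
  cc <- unlist(mapply(function(n) rep(c(1, -1), n), counts * 1,
                      SIMPLIFY = FALSE))
  f1 <- fitLogistic(yy, data.frame(exposure = xx))
  f2 <- fitLogistic(yy, data.frame(exposure = xx, cov = cc))
  expect_equal(f2$estimate[f2$predictor == "exposure"],
               f1$estimate[f1$predictor == "exposure"], tolerance = 1e-6)
  expect_error(fitLogistic(y, data.frame(k = rep(1, 200))), "constant")
  ysep <- rep(c(TRUE, FALSE), each = 50)
  xsep <- c(rnorm(50, 10), rnorm(50, -10))
  expect_error(fitLogistic(ysep, data.frame(s = xsep)), "separation")
})

test_that("null logistic CIs cover OR = 1 at the nominal rate", {
  set.seed(23)
  cover <- vapply(1:100, function(i) {
    y <- runif(5000) < 0.1
    s <- rnorm(5000)
    f <- fitLogistic(y, data.frame(pgs = s))
    f$ci_lo <= 1 && 1 <= f$ci_hi
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("observed R2 is an incremental nested-model difference", {
  set.seed(31)
  n <- 2000
  y <- runif(n) < 0.2
  s <- rnorm(n) + y
  # no covariates: equals the squared Pearson correlation
  expect_equal(r2Observed(y, s), cor(as.numeric(y), s)^2, tolerance = 1e-10)
  # orthogonal predictor adds nothing
  covs <- cbind(c1 = rnorm(n))
  expect_lt(abs(r2Observed(y, rnorm(n), covs)), 5e-3)
  # nesting keeps it nonnegative
  for (i in 1:20)
    expect_gte(r2Observed(y, rnorm(n), covs), 0)
  expect_error(r2Observed(y, s, cbind(a = s, b = s)), "collinear")
})

test_that("the liability transformation has its closed-form properties", {
  # K = P: theta = 0 and the ratio is the scale factor C; at 0.5 it is pi/2
  lt <- liabilityTransform(0.37, 0.5, 0.5)
  expect_equal(lt$theta, 0, tolerance = 1e-12)
  expect_equal(lt$r2_l / lt$r2_obs, pi / 2, tolerance = 1e-9)
  # zero maps to zero everywhere
  set.seed(41)
  for (i in 1:200) {
    K <- runif(1, 1e-4, 0.5); P <- runif(1, 0.01, 0.99)
    expect_identical(liabilityTransform(0, K, P)$r2_l, 0)
  }
  # frozen study-scale example: K = 0.0032, P = 322/1932, R2_obs = 0.05
  expect_equal(liabilityTransform(0.05, 0.0032, 322 / 1932)$r2_l,
               0.0407137, tolerance = 1e-4)
  expect_error(liabilityTransform(0.5, 0, 0.5), "K")
  expect_error(liabilityTransform(1.2, 0.1, 0.5), "r2Obs")
})

test_that("bootstrap liability inference is seeded, stable and detects
           signal", {
  set.seed(47)
  n <- 600
  y <- rep(c(1, 0), c(120, 480))
  s <- rnorm(n) + 0.8 * y
  b1 <- bootstrapLiability(y, s, NULL, K = 0.01, B = 300, seed = 5)
  b2 <- bootstrapLiability(y, s, NULL, K = 0.01, B = 300, seed = 5)
  expect_identical(b1$boot, b2$boot)
  expect_gt(b1$lb90, 0)                              # strong signal
  expect_lt(b1$p.value, 0.001)
  # SE stabilizes in B
  b3 <- bootstrapLiability(y, s, NULL, K = 0.01, B = 1500, seed = 9)
  expect_equal(b1$se, b3$se, tolerance = 0.15)
  expect_error(bootstrapLiability(y, s, NULL, K = 0.01, B = 1), "B must")
})

test_that("single- and multiple-PGS models agree for independent scores", {
  set.seed(53)
  n <- 6000
  S <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("t", 1:4)))
  eta <- -2 + S %*% c(0.4, 0.2, 0, -0.3)
  y <- runif(n) < plogis(eta)
  ss <- data.frame(sample_id = as.character(seq_len(n)),
                   case_status = ifelse(y, "case", "control"),
                   sex = sample(c("female", "male"), n, TRUE))
  res <- runAssociation(S, ss, adjust = FALSE, mBH = 8)
  sing <- res[res$model == "single", ]
  mult <- res[res$model == "multiple", ]
  expect_equal(nrow(sing), 4)
  expect_lt(max(abs(log(sing$or_per_sd) - log(mult$or_per_sd))), 0.05)
  expect_true(all(res$p_adj >= res$p))
})

test_that("the global null yields almost no adjusted discoveries", {
  set.seed(59)
  rejections <- vapply(1:20, function(i) {
    n <- 1500
    S <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(NULL, paste0("t", 1:8)))
    y <- runif(n) < 0.15
    ss <- data.frame(sample_id = as.character(seq_len(n)),
                     case_status = ifelse(y, "case", "control"))
    res <- runAssociation(S, ss, adjust = FALSE, mBH = 8)
    sum(res$p_adj[res$model == "single"] < 0.05)
  }, numeric(1))
  # FDR control under the global null: family-wise rejection rate ~ 5%
  expect_lte(mean(rejections > 0), 0.15)
})

test_that("the full battery has the expected shape and stratum logic", {
  sim <- smallSim(seed = 61, nPool = 9000, nVariants = 300, K = 0.02,
                  cases = 150, controls = 600, relatedPairs = list())
  scores <- scoreCohort(sim$cohort, sim$weights)
  ss <- sampleSheet(sim$cohort)
  set.seed(1)
  ss$stratum <- NA_character_
  ss$stratum[ss$case_status == "case"] <-
    sample(c("monogenic", "cryptogenic"), sum(ss$case_status == "case"),
           replace = TRUE)
  pcs <- computePCs(sim$cohort, k = 4)
  rep <- evaluateCohort(scores, ss, pcs, K = 0.02, strata = "stratum",
                        B = 120, seed = 2)
  nT <- length(scores)
  expect_equal(nrow(associationResults(rep)), 2 * nT * 3)
  expect_equal(nrow(discriminationResults(rep)), (nT + 1) * 3)
  expect_equal(nrow(liabilityResults(rep)), (nT + 1) * 3)
  # every stratum keeps the full control count
  lia <- liabilityResults(rep)
  expect_true(all(abs(lia$P[lia$stratum == "all"] - 150 / 750) < 1e-9))
  # exchangeable random strata agree within joint uncertainty
  comb <- lia[lia$predictor == "combined", ]
  d <- abs(diff(comb$r2_l[comb$stratum != "all"]))
  expect_lt(d, 3 * sum(comb$se[comb$stratum != "all"]))
  # control-only stratum labels are ignored
  ss2 <- ss; ss2$stratum[ss2$case_status == "case"] <- NA
  ss2$stratum[ss2$case_status == "control"] <- "ctlonly"
  rep2 <- evaluateCohort(scores, ss2, pcs, K = 0.02, strata = "stratum",
                         B = 60, seed = 3)
  expect_equal(unique(liabilityResults(rep2)$stratum), "all")
})
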