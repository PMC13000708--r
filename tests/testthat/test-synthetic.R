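test_that("genotypes are Hardy-Weinberg with the requested frequency", {
  cfg <- simConfig(seed = 3, nPool = 4000, nVariants = 300,
                   mafRange = c(0.5, 0.5), nSubpops = 1, fst = 0,
                   K = 0.01, targetCases = 10, targetControls = 50,
                   missingRate = 0)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  expect_equal(mean(d), 1.0, tolerance = 0.01)
  expect_equal(var(as.numeric(d)), 0.5, tolerance = 0.02)
})

test_that("generation is deterministic given the seed", {
  cfg <- simConfig(seed = 5, nPool = 500, nVariants = 100, K = 0.05,
                   targetCases = 10, targetControls = 40)
  expect_identical(dosages(simulateGenotypes(cfg)),
                   dosages(simulateGenotypes(cfg)))
  s1 <- simulateCohort(cfg); s2 <- simulateCohort(cfg)
  expect_identical(dosages(s1$cohort), dosages(s2$cohort))
  expect_identical(sampleSheet(s1$cohort), sampleSheet(s2$cohort))
  expect_equal(s1$weights$cp$weight, s2$weights$cp$weight)
})

test_that("Balding-Nichols divergence reproduces the target Fst", {
  cfg <- simConfig(seed = 9, nPool = 1000, nVariants = 2000,
                   nSubpops = 2, fst = 0.1, K = 0.05,
                   targetCases = 10, targetControls = 40,
                   missingRate = 0)
  g <- simulateGenotypes(cfg)
  d <- dosages(g)
  sub <- sampleSheet(g)$subpop
  n1 <- sum(sub == 1); n2 <- sum(sub == 2)
  p1 <- rowMeans(d[, sub == 1]) / 2
  p2 <- rowMeans(d[, sub == 2]) / 2
  expect_lt(abs(hudsonFst(p1, p2, 2 * n1, 2 * n2) - 0.1), 0.02)
})

test_that("trait effects carry the requested correlation structure", {
  tr <- defaultTraitSpecs()
  cfg <- simConfig(seed = 21, nPool = 200000, nVariants = 5000,
                   traits = tr, K = 0.0032,
                   targetCases = 322, targetControls = 1610)
  beta <- simulateEffects(cfg)
  # rho_cp = 0.5 trait recovers the empirical correlation
  expect_equal(cor(beta[, "cp"], beta[, "walking_age"]), 0.5,
               tolerance = 0.03)
  # h2 = 0 silences a trait entirely
  tr0 <- tr; tr0$h2[tr0$name == "asd"] <- 0
  cfg0 <- simConfig(seed = 21, nPool = 200000, nVariants = 1000,
                    traits = tr0, K = 0.0032,
                    targetCases = 322, targetControls = 1610)
  expect_true(all(simulateEffects(cfg0)[, "asd"] == 0))
  # rho_cp = 1 makes effects proportional to the disorder trait's
  tr1 <- tr; tr1$rho_cp[tr1$name == "epilepsy"] <- 1
  cfg1 <- simConfig(seed = 21, nPool = 200000, nVariants = 1000,
                    traits = tr1, K = 0.0032,
                    targetCases = 322, targetControls = 1610)
  b1 <- simulateEffects(cfg1)
  expect_equal(abs(cor(b1[, "cp"], b1[, "epilepsy"])), 1, tolerance = 1e-9)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(simConfig(K = 1.5), "K")
  expect_error(simConfig(nVariants = 0), "nVariants")
  expect_error(simConfig(fst = -0.1), "fst")
  expect_error(simConfig(mafRange = c(0, 0.6)), "mafRange")
  expect_error(simConfig(K = 0.001, nPool = 1000, targetCases = 100),
               "targetCases")
  tr <- defaultTraitSpecs(); tr$rho_cp[2] <- 1.4
  expect_error(simConfig(traits = tr), "rho_cp")
})

test_that("unascertained case fraction matches the prevalence and case
           liabilities match the truncated-normal expectation", {
  cfg <- simConfig(seed = 13, nPool = 200000, nVariants = 60,
                   K = 0.01, targetCases = 100, targetControls = 400,
                   missingRate = 0)
  tr <- cfg$traits; tr$h2 <- rep(0.2, nrow(tr)); cfg$traits <- tr
  g <- simulateGenotypes(cfg)
  beta <- simulateEffects(cfg)
  pool <- assignPhenotypes(g, beta, cfg, ascertain = FALSE)
  ss <- sampleSheet(pool)
  frac <- mean(ss$case_status == "case")
  expect_equal(frac, 0.01, tolerance = 0.15)        # relative, ~3 SEs
  # mean liability among cases: phi(t)/K with t = qnorm(0.99) -> 2.665
  mliab <- mean(ss$true_liability[ss$case_status == "case"]) /
    sd(ss$true_liability)
  expect_equal(mliab, dnorm(qnorm(0.99)) / 0.01, tolerance = 0.03)
})

test_that("null heritability gives cases and controls the same score
           distribution", {
  cfg <- simConfig(seed = 17, nPool = 6000, nVariants = 200, K = 0.02,
                   targetCases = 60, targetControls = 300,
                   relatedPairs = list())
  tr <- cfg$traits; tr$h2 <- rep(0, nrow(tr)); cfg$traits <- tr
  sim <- simulateCohort(cfg)
  sc <- computeScores(sim$cohort, sim$weights$cp)
  ss <- sampleSheet(sim$cohort)
  pv <- t.test(sc$raw[ss$case_status == "case"],
               sc$raw[ss$case_status == "control"])$p.value
  expect_gt(pv, 0.01)
})

test_that("genetic-score variance recovers the configured h2", {
  cfg <- simConfig(seed = 29, nPool = 20000, nVariants = 2000, K = 0.02,
                   targetCases = 50, targetControls = 200,
                   missingRate = 0, fst = 0)
  g <- simulateGenotypes(cfg)
  beta <- simulateEffects(cfg)
  pool <- assignPhenotypes(g, beta, cfg, ascertain = FALSE)
  ss <- sampleSheet(pool)
  ratio <- var(ss$genetic_score) / var(ss$true_liability)
  expect_equal(ratio, 0.3, tolerance = 0.1)         # within 10% relative
})

test_that("a shortfall of cases in the pool is a named error", {
  cfg <- simConfig(seed = 1, nPool = 2000, nVariants = 50, K = 0.01,
                   targetCases = 20, targetControls = 100)
  g <- simulateGenotypes(cfg)
  beta <- simulateEffects(cfg)
  cfg$targetCases <- 1900L   # bypass constructor bound to hit the runtime check
  expect_error(assignPhenotypes(g, beta, cfg, ascertain = TRUE),
               "shortfall")
})

test_that("weight noise scales as the GWAS sampling variance", {
  vi <- data.frame(variant_id = sprintf("v%d", 1:5000), chrom = "1",
                   pos = 1:5000, ref = "A", alt = "G", altFreq = 0.5)
  beta <- rnorm(5000, 0, 0.01)
  # p = 0.5, n_eff = 1000 -> noise SD sqrt(1/500)
  w <- makeWeightSet(beta, 1000, vi, "t", seed = 2)
  expect_equal(sd(w$weight - beta), sqrt(1 / 500), tolerance = 0.03)
  # enormous n_eff -> weights converge on the true effects
  wInf <- makeWeightSet(beta, 1e12, vi, "t", seed = 2)
  expect_lt(max(abs(wInf$weight - beta)), 1e-3)
  # larger discovery sample -> strictly better weight-truth correlation
  better <- vapply(1:20, function(s) {
    small <- makeWeightSet(beta, 3465, vi, "t", seed = s)
    large <- makeWeightSet(beta, 757277, vi, "t", seed = s)
    cor(large$weight, beta) > cor(small$weight, beta)
  }, logical(1))
  expect_true(all(better))
  expect_error(makeWeightSet(beta, -1, vi, "t"), "positive")
  vi$altFreq[1] <- 1
  expect_error(makeWeightSet(beta, 1000, vi, "t"), "frequency")
})

test_that("related-pair injection is truthful and optional", {
  sim <- smallSim(nVariants = 200, relatedPairs = list())
  expect_null(S4Vectors::metadata(sim$cohort)$related_truth)
  aug <- injectRelatedPairs(sim$cohort, list(duplicate = 1), seed = 4)
  truth <- S4Vectors::metadata(aug)$related_truth
  expect_equal(nrow(truth), 1)
  expect_identical(unname(dosages(aug)[, truth$sample_i]),
                   unname(dosages(aug)[, truth$sample_j]))
  # zero pairs requested -> unchanged object
  expect_identical(dosages(injectRelatedPairs(sim$cohort, list(), 1)),
                   dosages(sim$cohort))
  expect_error(injectRelatedPairs(sim$cohort, list(cousin = 1), 1),
               "unknown relationship")
})
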