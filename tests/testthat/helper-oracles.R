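# Independent oracles and tiny fixture builders shared across tests.

# Brute-force pairwise concordance AUC (ties 0.5).
bruteAUC <- function(score, isCase) {
  ca <- score[isCase]; co <- score[!isCase]
  tot <- 0
  for (a in ca) tot <- tot + sum(a > co) + 0.5 * sum(a == co)
  tot / (length(ca) * length(co))
}

# Step-up BH definition: p_adj(i) = min_{j >= i} m p(j) / j, capped at 1.
stepUpBH <- function(p, m) {
  o <- order(p)
  ps <- p[o]
  adj <- numeric(length(ps))
  run <- Inf
  for (i in rev(seq_along(ps))) {
    run <- min(run, m * ps[i] / i)
    adj[i] <- min(run, 1)
  }
  out <- numeric(length(p))
  out[o] <- adj
  out
}

# Hudson-type Fst from two subpopulation allele-frequency estimates.
hudsonFst <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# All minimum vertex covers of a small graph, by enumeration.
allMinCovers <- function(vertices, edges) {
  k <- length(vertices)
  best <- k + 1L; covers <- list()
  ei <- match(edges$sample_i, vertices); ej <- match(edges$sample_j, vertices)
  for (mask in seq_len(2^k) - 1L) {
    inSet <- bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L
    if (!all(inSet[ei] | inSet[ej])) next
    sz <- sum(inSet)
    if (sz < best) { best <- sz; covers <- list(vertices[inSet]) }
    else if (sz == best) covers[[length(covers) + 1L]] <- vertices[inSet]
  }
  covers
}

# Tiny deterministic cohort: hand-set dosages, ids, phenotypes.
tinyCohort <- function() {
  d <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L), nrow = 2, byrow = TRUE)
  variants <- data.frame(variant_id = c("v1", "v2"), chrom = "1",
                         pos = c(100L, 200L), ref = "A", alt = "G",
                         altFreq = c(0.5, 0.5))
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        sex = c("female", "male", "female"),
                        age = c(10, 20, 30),
                        case_status = c("case", "control", "control"))
  GenotypeCohort(d, variants, samples)
}

# Small simulated cohort shared by scoring / relatedness tests.
smallSim <- function(seed = 11, nPool = 8000, nVariants = 400, K = 0.02,
                     cases = 120, controls = 480, ...) {
  simulateCohort(simConfig(seed = seed, nPool = nPool,
                           nVariants = nVariants, K = K,
                           targetCases = cases, targetControls = controls,
                           chunkSize = 4000, ...))
}
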