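#' Estimate pairwise kinship from a genetic relationship matrix
#'
#' GRM-based kinship
#' \deqn{\hat\phi_{ij} = \frac{1}{2M}\sum_m \frac{(x_{im}-2p_m)(x_{jm}-2p_m)}{2p_m(1-p_m)}}
#' with allele frequencies \eqn{p_m} computed from the cohort itself;
#' monomorphic variants and, for each pair, variants missing in either
#' sample are skipped (the denominator uses the pair's non-missing
#' overlap). Expectations: 0.5 for duplicates/MZ twins, 0.25 for
#' parent-offspring and full siblings, ~0 for unrelated pairs.
#'
#' @param genotypes a \linkS4class{GenotypeCohort} (>= 2 samples)
#' @return data.frame with one row per unordered pair: \code{sample_i},
#'   \code{sample_j}, \code{phi}, \code{n_used} (0 = unusable pair)
#' @export
estimateKinship <- function(genotypes) {
  d <- dosages(genotypes)
  n <- ncol(d)
  if (n < 2L) stop("kinship needs at least 2 samples")
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  d <- d[poly, , drop = FALSE]; p <- p[poly]
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(z)
  z[!obs] <- 0
  num <- crossprod(z)                      # sum over shared variants
  nUsed <- crossprod(obs * 1)              # pairwise non-missing overlap
  phi <- num / (2 * nUsed)
  phi[nUsed == 0] <- NA_real_
  ut <- which(upper.tri(phi), arr.ind = TRUE)
  data.frame(sample_i = colnames(d)[ut[, 1]],
             sample_j = colnames(d)[ut[, 2]],
             phi = phi[ut],
             n_used = as.integer(nUsed[ut]))
}

# Exact minimum vertex cover by subset enumeration, with preference for
# covers removing more controls, then lexicographically smallest ids.
.exactCover <- function(vertices, edges, isControl) {
  k <- length(vertices)
  edgeI <- match(edges$sample_i, vertices)
  edgeJ <- match(edges$sample_j, vertices)
  best <- NULL; bestSize <- k + 1L; bestCtrl <- -1L; bestKey <- NULL
  for (mask in seq_len(2^k) - 1L) {
    inSet <- bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L
    size <- sum(inSet)
    if (size > bestSize) next
    if (!all(inSet[edgeI] | inSet[edgeJ])) next
    ctrl <- sum(isControl[inSet])
    key <- paste(sort(vertices[inSet]), collapse = "\r")
    better <- size < bestSize ||
      (size == bestSize && (ctrl > bestCtrl ||
                            (ctrl == bestCtrl && key < bestKey)))
    if (better) {
      best <- vertices[inSet]; bestSize <- size
      bestCtrl <- ctrl; bestKey <- key
    }
  }
  best
}

# Greedy max-degree cover; ties prefer controls, then smaller id.
.greedyCover <- function(vertices, edges, isControl) {
  removed <- character()
  e <- edges
  while (nrow(e) > 0) {
    deg <- table(c(e$sample_i, e$sample_j))
    cand <- names(deg)[deg == max(deg)]
    ctl <- cand[isControl[match(cand, vertices)]]
    pick <- if (length(ctl)) min(ctl) else min(cand)
    removed <- c(removed, pick)
    e <- e[e$sample_i != pick & e$sample_j != pick, , drop = FALSE]
  }
  removed
}

#' Prune related individuals
#'
#' Removes one individual per related pair with kinship above the
#' threshold so that no remaining pair exceeds it, while retaining the
#' maximally sized cohort: on each connected component of the relatedness
#' graph with at most \code{exactLimit} vertices the removal set is an
#' exact minimum vertex cover (found by enumeration); larger components
#' fall back to greedy max-degree removal. Among equally small covers,
#' covers removing more controls are preferred, then the lexicographically
#' smallest set of sample ids.
#'
#' @param kinship data.frame from [estimateKinship()]
#' @param samples sample sheet data.frame with \code{sample_id} and
#'   \code{case_status}
#' @param threshold kinship cutoff; pairs with \code{phi > threshold} are
#'   considered related (default 0.09, capturing 2nd-degree and closer)
#' @param exactLimit largest component size solved exactly (default 12)
#' @return data.frame of removed samples: \code{sample_id},
#'   \code{case_status}, \code{reason}
#' @export
pruneRelated <- function(kinship, samples, threshold = 0.09,
                         exactLimit = 12L) {
  edges <- kinship[!is.na(kinship$phi) & kinship$phi > threshold,
                   c("sample_i", "sample_j")]
  if (nrow(edges) == 0)
    return(data.frame(sample_id = character(), case_status = character(),
                      reason = character()))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  status <- samples$case_status[match(names(comp$membership),
                                      samples$sample_id)]
  removed <- character()
  for (cid in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == cid]
    isCtl <- status[comp$membership == cid] == "control"
    sub <- edges[edges$sample_i %in% vs & edges$sample_j %in% vs, ,
                 drop = FALSE]
    removed <- c(removed,
                 if (length(vs) <= exactLimit)
                   .exactCover(vs, sub, isCtl)
                 else .greedyCover(vs, sub, isCtl))
  }
  data.frame(sample_id = removed,
             case_status = samples$case_status[match(removed,
                                                     samples$sample_id)],
             reason = sprintf("kinship > %g", threshold))
}

#' Write a kinship table to TSV
#' @param kinship data.frame from [estimateKinship()]
#' @param path output path (`sample_i sample_j phi n_used`)
#' @export
writeKinship <- function(kinship, path) {
  write.table(kinship, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
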