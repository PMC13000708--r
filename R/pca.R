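#' Ancestry principal components from genotype dosages
#'
#' Standard genotype PCA: missing dosages are mean-imputed, each variant
#' is centred by twice its sample allele frequency and scaled by
#' \code{sqrt(2 p (1-p))}, monomorphic variants are dropped, and the top
#' \code{k} components are taken from the eigendecomposition of the
#' sample-sample covariance \code{crossprod(Z)/M}. Scores are the
#' eigenvectors scaled by the square root of their eigenvalues
#' (projection convention); component signs are arbitrary.
#'
#' @param genotypes a \linkS4class{GenotypeCohort}
#' @param k number of components (default 10)
#' @return list of class \code{"pcResult"}: \code{scores} (samples x k,
#'   columns \code{PC1..PCk}), \code{eigenvalues}, \code{convention}
#' @export
computePCs <- function(genotypes, k = 10L) {
  d <- dosages(genotypes)
  n <- ncol(d)
  if (n < k + 1L) stop("need at least k+1 samples for k components")
  p <- rowMeans(d, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic variants")
  d <- d[poly, , drop = FALSE]; p <- p[poly]
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  if (anyNA(z)) z[is.na(z)] <- 0          # mean-imputed after centring
  G <- crossprod(z) / nrow(z)
  eg <- eigen(G, symmetric = TRUE)
  pos <- sum(eg$values > 1e-9)
  if (k > pos)
    stop("k = ", k, " exceeds the rank of the genotype matrix (", pos, ")")
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(k)]), k)
  dimnames(scores) <- list(colnames(d), paste0("PC", seq_len(k)))
  out <- list(scores = scores, eigenvalues = eg$values[seq_len(k)],
              convention = "scores = eigenvectors * sqrt(eigenvalue)")
  class(out) <- "pcResult"
  out
}

#' @export
print.pcResult <- function(x, ...) {
  cat("pcResult:", nrow(x$scores), "samples x", ncol(x$scores),
      "components; leading eigenvalue ratio",
      signif(x$eigenvalues[1] / max(x$eigenvalues[2], 1e-12), 3), "\n")
  invisible(x)
}

#' Write principal-component scores to TSV
#' @param pcs a \code{pcResult}
#' @param path output path (`sample_id PC1..PCk`)
#' @export
writePCs <- function(pcs, path) {
  tab <- data.frame(sample_id = rownames(pcs$scores), pcs$scores,
                    row.names = NULL)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
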