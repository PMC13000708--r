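#' Greedy nearest-neighbour case-control matching without replacement
#'
#' Cases are processed in a seeded random order (processing order affects
#' greedy results, so it is randomized and reproducible); each case claims
#' its \code{ratio} nearest controls by covariate distance, without
#' replacement. With one covariate the distance is the absolute
#' difference; with several, Euclidean distance on covariates standardized
#' by their control-pool SDs. Distance ties are broken by the smaller
#' control id. Shortfalls (pool exhausted) are recorded, never filled by
#' reuse.
#'
#' @param samples sample sheet data.frame with \code{sample_id},
#'   \code{case_status} and the covariate columns; rows with missing
#'   covariates are excluded from the control pool
#' @param covariates character vector of covariate columns (default
#'   \code{"age"})
#' @param ratio controls per case (default 5)
#' @param seed integer seed for the case processing order
#' @return list of class \code{"matchResult"}: \code{matches} data.frame
#'   (\code{case_id}, \code{control_id}, \code{distance}, per-covariate
#'   case/control values), \code{unmatched} case ids with incomplete
#'   matches, \code{ratio}, \code{metric}
#' @export
matchControls <- function(samples, covariates = "age", ratio = 5L,
                          seed = 1L) {
  miss <- setdiff(covariates, names(samples))
  if (length(miss))
    stop("covariate(s) not in sample sheet: ", paste(miss, collapse = ", "))
  cases <- samples[samples$case_status == "case", , drop = FALSE]
  ctrls <- samples[samples$case_status == "control", , drop = FALSE]
  ok <- stats::complete.cases(ctrls[, covariates, drop = FALSE])
  ctrls <- ctrls[ok, , drop = FALSE]
  if (nrow(ctrls) == 0) stop("empty control pool")
  okC <- stats::complete.cases(cases[, covariates, drop = FALSE])

  X <- as.matrix(ctrls[, covariates, drop = FALSE])
  Xc <- as.matrix(cases[, covariates, drop = FALSE])
  if (length(covariates) > 1) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2, s, "/"); Xc <- sweep(Xc, 2, s, "/")
  }
  set.seed(seed)
  order_ <- sample(nrow(cases))
  avail <- rep(TRUE, nrow(ctrls))
  rows <- list(); unmatched <- character()
  for (i in order_) {
    if (!okC[i]) { unmatched <- c(unmatched, cases$sample_id[i]); next }
    dist <- sqrt(rowSums((X - matrix(Xc[i, ], nrow(X), ncol(X),
                                     byrow = TRUE))^2))
    cand <- which(avail)
    if (length(cand) == 0) { unmatched <- c(unmatched, cases$sample_id[i]); next }
    ord <- cand[order(dist[cand], ctrls$sample_id[cand])]
    take <- ord[seq_len(min(ratio, length(ord)))]
    avail[take] <- FALSE
    if (length(take) < ratio) unmatched <- c(unmatched, cases$sample_id[i])
    rows[[length(rows) + 1L]] <- data.frame(
      case_id = cases$sample_id[i],
      control_id = ctrls$sample_id[take],
      distance = dist[take],
      stats::setNames(as.data.frame(Xc[rep(i, length(take)), , drop = FALSE]),
                      paste0(covariates, "_case")),
      stats::setNames(as.data.frame(X[take, , drop = FALSE]),
                      paste0(covariates, "_control")),
      row.names = NULL)
  }
  out <- list(matches = if (length(rows)) do.call(rbind, rows)
              else data.frame(case_id = character(),
                              control_id = character(),
                              distance = numeric()),
              unmatched = unmatched, ratio = as.integer(ratio),
              metric = if (length(covariates) > 1)
                "euclidean_standardized" else "absolute_difference",
              covariates = covariates)
  class(out) <- "matchResult"
  out
}

#' @export
print.matchResult <- function(x, ...) {
  cat("matchResult: ", length(unique(x$matches$case_id)), " cases matched 1:",
      x$ratio, " on ", paste(x$covariates, collapse = "+"),
      "; ", nrow(x$matches), " controls claimed; ",
      length(x$unmatched), " cases with shortfall\n", sep = "")
  invisible(x)
}

#' Restrict a sample sheet to a match result
#'
#' Keeps the fully matched cases and their claimed controls.
#'
#' @param samples sample sheet data.frame
#' @param match a \code{matchResult}
#' @return filtered sample sheet
#' @export
applyMatch <- function(samples, match) {
  m <- match$matches
  fully <- setdiff(unique(m$case_id), match$unmatched)
  keep <- c(fully, m$control_id[m$case_id %in% fully])
  samples[samples$sample_id %in% keep, , drop = FALSE]
}

#' Standardized mean differences before and after matching
#'
#' SMD = (case mean - control mean) / pooled SD, per covariate, computed
#' on the full cohort and on the matched subset; a constant covariate has
#' SMD 0 by definition.
#'
#' @param samples full sample sheet
#' @param match a \code{matchResult}
#' @param covariates covariate columns (default: the match's covariates)
#' @return data.frame: covariate, smd_before, smd_after
#' @export
balanceDiagnostics <- function(samples, match,
                               covariates = match$covariates) {
  smd <- function(tab) {
    vapply(covariates, function(cv) {
      a <- tab[tab$case_status == "case", cv]
      b <- tab[tab$case_status == "control", cv]
      sp <- sqrt((stats::var(a) + stats::var(b)) / 2)
      if (!is.finite(sp) || sp == 0) return(0)
      (mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)) / sp
    }, numeric(1))
  }
  data.frame(covariate = covariates,
             smd_before = smd(samples),
             smd_after = smd(applyMatch(samples, match)),
             row.names = NULL)
}
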