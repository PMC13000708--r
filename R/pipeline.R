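#' @importFrom utils packageVersion
NULL

# FNV-1a hash of a character representation, for run manifests.
configHash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Read and validate a pipeline run configuration (YAML)
#'
#' Recognised fields: \code{genotypes}, \code{samples}, \code{weights}
#' (directory or list of TSVs), \code{outdir}, \code{K}, \code{seed},
#' \code{prune_threshold}, \code{n_pcs}, \code{bootstrap_B},
#' \code{match} (\code{enabled}, \code{covariates}, \code{ratio}),
#' \code{youngest_controls} (restrict controls to the youngest n, the
#' age-bias sensitivity design), \code{strata} (sample-sheet column), and
#' a \code{simulate} block forwarded to [simConfig()].
#'
#' @param path YAML file
#' @return validated list of class \code{"runConfig"}
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(K = 0.0032, seed = 1L, prune_threshold = 0.09,
                   n_pcs = 10L, bootstrap_B = 1000L,
                   match = list(enabled = FALSE, covariates = "age",
                                ratio = 5L),
                   youngest_controls = NULL, strata = NULL)
  cfg <- modifyList(defaults, cfg)
  if (!(is.numeric(cfg$K) && cfg$K > 0 && cfg$K < 1))
    stop("config error in field 'K': must be in (0,1)")
  if (cfg$bootstrap_B < 100)
    warning("bootstrap_B < 100: intervals will be unstable")
  class(cfg) <- "runConfig"
  cfg
}

#' Simulate a cohort from a run configuration and write it to disk
#'
#' @param config path to a YAML config (its \code{simulate} block is
#'   forwarded to [simConfig()]) or a \code{runConfig}/\code{simConfig}
#' @param outdir output directory (overrides the config's)
#' @param seed optional master seed override
#' @return invisibly, the written file paths
#' @export
cmdSimulate <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  simArgs <- if (inherits(config, "simConfig")) unclass(config)
             else config$simulate
  if (is.null(simArgs)) simArgs <- list()
  if (!is.null(seed)) simArgs$seed <- seed
  simArgs <- simArgs[names(simArgs) %in% names(formals(simConfig))]
  sc <- do.call(simConfig, simArgs)
  out <- if (!is.null(outdir)) outdir
         else if (!is.null(config$outdir)) config$outdir
         else stop("config error in field 'outdir': not set")
  sim <- simulateCohort(sc)
  paths <- writeCohort(sim$cohort, sim$weights, out)
  # truth file: latent liabilities and pool counts for downstream checks
  truthPath <- file.path(out, "truth_summary.tsv")
  write.table(data.frame(n_pool = sim$truth$n_pool,
                         n_cases_pool = sim$truth$n_cases_pool,
                         h2_realized = sim$truth$h2_realized),
              truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, truth_summary = truthPath))
}

.fmt6 <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Run the full evaluation pipeline from files on disk
#'
#' score -> prune related -> (optional youngest-control restriction)
#' -> (optional matching) -> ancestry PCs -> evaluation battery, writing
#' \code{association.tsv}, \code{auc.tsv}, \code{liability_r2.tsv},
#' \code{removed_related.tsv}, optional \code{matches.tsv}, and a
#' \code{manifest.yaml} recording seed, config hash and stage counts.
#'
#' @param config path to a YAML run config or a \code{runConfig}
#' @param outdir report directory (overrides the config's)
#' @return the \linkS4class{EvaluationReport}, invisibly
#' @export
cmdEvaluate <- function(config, outdir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  for (f in c("genotypes", "samples"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("config error in field '", f, "': file not found")
  out <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(out)) stop("config error in field 'outdir': not set")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cohort <- readCohortVCF(config$genotypes, config$samples)
  wfiles <- config$weights
  if (length(wfiles) == 1 && dir.exists(wfiles))
    wfiles <- list.files(wfiles, pattern = "^weights_.*\\.tsv$",
                         full.names = TRUE)
  if (length(wfiles) == 0) stop("stage scoring failed: no weight files")
  weightSets <- lapply(wfiles, readWeights)
  names(weightSets) <- vapply(weightSets, traitName, "")

  scores <- scoreCohort(cohort, weightSets)

  kin <- estimateKinship(cohort)
  removed <- pruneRelated(kin, sampleSheet(cohort),
                          threshold = config$prune_threshold)
  keep <- setdiff(colnames(cohort), removed$sample_id)
  cohort <- cohort[, keep]
  ss <- sampleSheet(cohort)

  if (!is.null(config$youngest_controls)) {
    nyc <- config$youngest_controls
    ctl <- ss[ss$case_status == "control", ]
    youngest <- ctl$sample_id[order(ctl$age)][seq_len(min(nyc, nrow(ctl)))]
    ss <- ss[ss$case_status == "case" | ss$sample_id %in% youngest, ]
  }

  matchRes <- NULL
  if (isTRUE(config$match$enabled)) {
    matchRes <- matchControls(ss, covariates = config$match$covariates,
                              ratio = config$match$ratio,
                              seed = fanSeed(config$seed, "match"))
    ss <- applyMatch(ss, matchRes)
  }
  cohort <- cohort[, ss$sample_id]
  # re-standardize raw scores within the analysis cohort
  SM <- vapply(scores, function(s)
    standardizeValues(s$raw[match(ss$sample_id, s$sample_id)]),
    numeric(nrow(ss)))
  colnames(SM) <- names(scores)

  pcs <- computePCs(cohort, k = min(config$n_pcs, ncol(cohort) - 2L))
  report <- evaluateCohort(SM, ss, pcs = pcs, K = config$K,
                           strata = config$strata, B = config$bootstrap_B,
                           seed = fanSeed(config$seed, "boot"))
  report@meta$config_hash <- configHash(unclass(config))

  write.table(.fmt6(report@association), file.path(out, "association.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(.fmt6(report@discrimination), file.path(out, "auc.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(.fmt6(report@liability), file.path(out, "liability_r2.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(removed, file.path(out, "removed_related.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matchRes))
    write.table(.fmt6(matchRes$matches), file.path(out, "matches.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(seed = config$seed,
                        config_hash = report@meta$config_hash,
                        package_version = as.character(packageVersion("pgsEval")),
                        n_cases = report@meta$n_cases,
                        n_controls = report@meta$n_controls,
                        n_removed_related = nrow(removed),
                        K = config$K, bootstrap_B = config$bootstrap_B),
                   file.path(out, "manifest.yaml"))
  invisible(report)
}

#' Render a human-readable summary of a report directory
#'
#' Reads the report TSVs written by [cmdEvaluate()] (no recomputation)
#' and prints the three result families.
#'
#' @param reportDir directory containing the report TSVs
#' @return invisibly, a list of the three tables
#' @export
cmdReport <- function(reportDir) {
  paths <- file.path(reportDir, c("association.tsv", "auc.tsv",
                                  "liability_r2.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing report file(s): ", paste(basename(missing),
                                           collapse = ", "))
  tabs <- lapply(paths, read.delim)
  names(tabs) <- c("association", "auc", "liability_r2")
  cat("== Association (OR per SD of PGS) ==\n")
  print(tabs$association, digits = 3)
  cat("\n== Discrimination (AUC, one-tailed Z vs 0.5) ==\n")
  print(tabs$auc, digits = 3)
  cat("\n== Liability-scale variance explained ==\n")
  print(tabs$liability_r2, digits = 3)
  invisible(tabs)
}
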