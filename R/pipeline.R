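#' Assemble an end-to-end run configuration
#'
#' Collects the paths and options the reporting entry points need. Paths
#' are checked at construction; the output directory is created.
#'
#' @param outputDir directory for report TSVs and the run manifest.
#' @param panel a \code{\link{DiseasePanel}} or path to a panel file.
#' @param observations a \code{\link{SiteObservations-class}} object or
#'   path to an observations TSV (the printed-table route).
#' @param vcf,manifest optional paths for the VCF ingestion route; used
#'   when \code{observations} is NULL.
#' @param reference optional prevalence-reference table (data.frame or
#'   path) for concordance reports.
#' @param qc a \code{\link{QcConfig}}.
#' @param continuity,alpha concordance-test options.
#' @param detectionP,sigmaGrid,nRange,nPoints detection-power options:
#'   carrier rate, set of error rates, cohort-size range and grid size.
#' @param seed integer seed recorded in the provenance log and used for any
#'   simulation.
#' @return a validated list of class \code{exomeCarrierConfig}.
#' @export
runConfig <- function(outputDir, panel = NULL, observations = NULL,
                      vcf = NULL, manifest = NULL, reference = NULL,
                      qc = qcConfig(), continuity = TRUE, alpha = 0.05,
                      detectionP = 0.001, sigmaGrid = c(0, 0.01, 0.1),
                      nRange = c(1, 100000), nPoints = 100, seed = 1L) {
  for (p in c(vcf, manifest))
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  if (is.character(panel)) panel <- readPanel(panel)
  if (is.character(observations))
    observations <- readObservations(observations)
  if (is.character(reference)) reference <- readPrevalenceReference(reference)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outputDir, 2) != 0L)
    stop("output directory is not writable: ", outputDir)
  structure(list(outputDir = outputDir, panel = panel,
                 observations = observations, vcf = vcf,
                 manifest = manifest, reference = reference, qc = qc,
                 continuity = continuity, alpha = alpha,
                 detectionP = detectionP, sigmaGrid = sigmaGrid,
                 nRange = nRange, nPoints = nPoints,
                 seed = as.integer(seed)),
            class = "exomeCarrierConfig")
}

writeRunManifest <- function(config, stage, extra = character(0)) {
  lines <- c(
    sprintf("stage: %s", stage),
    sprintf("package: exomeCarrier %s",
            as.character(utils::packageVersion("exomeCarrier"))),
    if (!is.null(config$panel))
      sprintf("panel: %s (version %s, build %s)", config$panel@name,
              config$panel@version, config$panel@genomeBuild),
    sprintf("seed: %d", config$seed),
    sprintf("qc: min_depth=%g min_called=%g het_alt=%s",
            config$qc@minTotalDepth, config$qc@minFractionSamplesCalled,
            paste(config$qc@hetAltFractionRange, collapse = "-")),
    extra)
  writeLines(lines, file.path(config$outputDir,
                              paste0(stage, "_manifest.txt")))
}

resolveObservations <- function(config) {
  if (!is.null(config$observations)) return(config$observations)
  if (is.null(config$vcf) || is.null(config$manifest))
    stop("config provides neither observations nor a (vcf, manifest) pair")
  countAlleles(config$vcf, config$manifest, config$panel, qc = config$qc)
}

#' Run the carrier-rate analysis stage
#'
#' Produces the per-population carrier table (one row per mutation and
#' population, with AC/AN, allele frequency, "1 in N" and validity flag),
#' pooled superpopulation rows for the cross-cohort African/European/
#' admixed-American/Asian strata where both cohort strata are present, and
#' a provenance manifest. Any stage error is surfaced with the stage name.
#'
#' @param config from \code{\link{runConfig}}; must provide a panel and
#'   either observations or a VCF + manifest pair.
#' @param pooling optional data.frame with columns \code{label} and
#'   \code{populations} (comma-separated strata to pool); defaults to the
#'   African and European cross-cohort pools.
#' @return invisible list with the estimates object and output paths.
#' @export
runCarrierAnalysis <- function(config, pooling = NULL) {
  stopifnot(inherits(config, "exomeCarrierConfig"))
  if (is.null(config$panel)) stop("carrier stage: config lacks a panel")
  if (length(config$panel) == 0L) stop("carrier stage: empty panel")
  obs <- tryCatch(resolveObservations(config),
    error = function(e) stop("counting stage: ", conditionMessage(e)))
  est <- tryCatch(suppressWarnings(estimateCarrier(obs)),
    error = function(e) stop("carrier stage: ", conditionMessage(e)))
  tab <- carrierTable(est)
  table_path <- file.path(config$outputDir, "carrier_table.tsv")
  utils::write.table(tab, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  if (is.null(pooling))
    pooling <- data.frame(
      label = c("African", "European"),
      populations = c("AA,AFR", "EA,EUR"), stringsAsFactors = FALSE)
  pooled <- list()
  for (i in seq_len(nrow(pooling))) {
    pops <- strsplit(pooling$populations[i], ",")[[1]]
    if (!all(pops %in% obs$population)) next
    pooled[[i]] <- as.data.frame(suppressWarnings(estimateCarrier(
      poolByMutation(obs, pops, label = pooling$label[i]))))
  }
  pooled_path <- NULL
  if (length(pooled)) {
    pooled_df <- do.call(rbind, pooled)
    pooled_path <- file.path(config$outputDir, "carrier_table_pooled.tsv")
    utils::write.table(
      carrierTable(new("CarrierEstimates",
                       DataFrame(pooled_df, check.names = FALSE))),
      pooled_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeRunManifest(config, "carrier",
                   sprintf("observations: %d rows, %d mutation(s)",
                           nrow(obs), length(unique(obs$mutation_key))))
  invisible(list(estimates = est, table = table_path,
                 pooled = pooled_path))
}

#' Run the concordance-report stage
#'
#' Emits one TSV per comparison family: the cohort-vs-cohort batch
#' comparisons (African- and European-ancestry pairings by default) and,
#' when a prevalence reference is configured, the per-population
#' goodness-of-fit report against clinical estimates for each mutation in
#' the reference's scope.
#'
#' @param config from \code{\link{runConfig}}.
#' @param cohorts character(2): the cohort labels to compare; defaults to
#'   the two distinct cohorts present.
#' @param populationPairs as in \code{\link{batchConcordance}}; defaults to
#'   AA-vs-AFR and EA-vs-EUR.
#' @param referenceMutation mutation_key the prevalence reference applies
#'   to; defaults to the panel's sickle-cell entry when present.
#' @return invisible list with the report objects and output paths.
#' @export
runConcordanceReport <- function(config, cohorts = NULL,
                                 populationPairs = NULL,
                                 referenceMutation = "HBB:c.20A>T") {
  stopifnot(inherits(config, "exomeCarrierConfig"))
  obs <- tryCatch(resolveObservations(config),
    error = function(e) stop("counting stage: ", conditionMessage(e)))
  if (is.null(cohorts)) {
    cohorts <- setdiff(unique(obs$cohort), "POOLED")
    if (length(cohorts) < 2L)
      stop("concordance stage: need two cohorts, found ",
           paste(cohorts, collapse = ", "))
    cohorts <- cohorts[1:2]
  }
  if (is.null(populationPairs))
    populationPairs <- data.frame(pop1 = c("AA", "EA"),
                                  pop2 = c("AFR", "EUR"),
                                  stringsAsFactors = FALSE)
  rep <- batchConcordance(obs[obs$cohort == cohorts[1], ],
                          obs[obs$cohort == cohorts[2], ],
                          populationPairs,
                          continuity = config$continuity,
                          alpha = config$alpha)
  batch_path <- file.path(config$outputDir, "concordance_cohorts.tsv")
  utils::write.table(rep@results, batch_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prev_path <- NULL; prev <- NULL
  if (!is.null(config$reference) &&
      referenceMutation %in% obs$mutation_key) {
    prev <- prevalenceConcordance(
      obs[obs$mutation_key == referenceMutation &
          obs$cohort != "POOLED", ], config$reference)
    prev_path <- file.path(config$outputDir, "concordance_prevalence.tsv")
    utils::write.table(prev, prev_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  writeRunManifest(config, "concordance",
                   sprintf("cohorts: %s vs %s; alpha=%g; continuity=%s",
                           cohorts[1], cohorts[2], config$alpha,
                           config$continuity))
  invisible(list(batch = rep, prevalence = prev, batch_path = batch_path,
                 prevalence_path = prev_path))
}

#' Run the detection-power stage
#'
#' Emits one (n, D) curve per configured error rate over the configured
#' cohort-size range, plus a combined long-format table.
#'
#' @param config from \code{\link{runConfig}}.
#' @return invisible list with the combined curve data.frame and its path.
#' @export
runPowerReport <- function(config) {
  stopifnot(inherits(config, "exomeCarrierConfig"))
  if (config$nRange[1] > config$nRange[2] || config$nPoints < 1)
    stop("power stage: invalid cohort-size grid")
  curves <- lapply(config$sigmaGrid, function(s) {
    cv <- detectionCurve(config$detectionP, s, config$nRange[1],
                         config$nRange[2], config$nPoints)
    cv$sigma <- s
    cv$p <- config$detectionP
    cv
  })
  combined <- do.call(rbind, curves)
  path <- file.path(config$outputDir, "detection_power.tsv")
  utils::write.table(combined, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeRunManifest(config, "power",
                   sprintf("p=%g; sigma=%s; n=%d..%d",
                           config$detectionP,
                           paste(config$sigmaGrid, collapse = ","),
                           config$nRange[1], config$nRange[2]))
  invisible(list(curves = combined, path = path))
}
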