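#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

PANEL_COLUMNS <- c("disease_name", "omim_id", "gene_symbol", "refseq_gene",
                   "mrna_id", "hgvs_c", "hgvs_p", "rsid", "chrom", "pos",
                   "ref", "alt", "inheritance")

OBS_COLUMNS <- c("mutation_key", "population", "cohort", "ac", "an")

#' DiseasePanel: a curated recessive-disease mutation panel
#'
#' Holds one row per causative mutation: disease, OMIM id, gene, RefSeqGene
#' and mRNA accessions, HGVS c./p. descriptions, dbSNP rsID, and (optionally)
#' an explicit genomic locus (chrom, pos, ref, alt). Every entry must carry at
#' least one of \{rsID, locus\} so it can be matched against observed
#' variants. A derived \code{mutation_key} column (\code{gene:hgvs_c})
#' identifies mutations throughout the package.
#'
#' @slot entries data.frame of mutation records (see \code{\link{readPanel}}
#'   for the column contract).
#' @slot name character(1) panel name.
#' @slot version character(1) panel version label.
#' @slot genomeBuild character(1) opaque genome-build metadata; no liftover
#'   is ever attempted.
#' @aliases DiseasePanel
#' @seealso \code{\link{readPanel}}, \code{\link{matchVariant}}
#' @exportClass DiseasePanel
setClass("DiseasePanel",
  representation(entries = "data.frame", name = "character",
                 version = "character", genomeBuild = "character"))

validPanelEntries <- function(df) {
  msgs <- character(0)
  missing_cols <- setdiff(PANEL_COLUMNS, names(df))
  if (length(missing_cols))
    return(sprintf("missing panel column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0L)
    return("panel has no entries")
  has_rsid <- !is.na(df$rsid) & nzchar(df$rsid)
  has_locus <- !is.na(df$chrom) & nzchar(df$chrom) & !is.na(df$pos)
  bad <- which(!(has_rsid | has_locus))
  if (length(bad))
    msgs <- c(msgs, sprintf(
      "row %d (%s): neither rsid nor genomic locus present",
      bad, df$hgvs_c[bad]))
  loci <- which(has_locus)
  bad_allele <- loci[!grepl("^[ACGT]+$", df$ref[loci]) |
                     !grepl("^[ACGT]+$", df$alt[loci])]
  if (length(bad_allele))
    msgs <- c(msgs, sprintf(
      "row %d (%s): field ref/alt must be a non-empty string over {A,C,G,T}",
      bad_allele, df$hgvs_c[bad_allele]))
  dup <- duplicated(df[, c("disease_name", "hgvs_c")])
  if (any(dup))
    msgs <- c(msgs, sprintf(
      "row %d: duplicate (disease_name, hgvs_c) pair (%s, %s)",
      which(dup), df$disease_name[dup], df$hgvs_c[dup]))
  # the same rsid listed twice must point at one locus
  for (id in unique(df$rsid[has_rsid & duplicated(df$rsid) &
                            df$rsid %in% df$rsid[has_locus]])) {
    sub <- df[df$rsid %in% id & has_locus, c("chrom", "pos", "ref", "alt")]
    if (nrow(unique(sub)) > 1L)
      msgs <- c(msgs, sprintf("rsid %s maps to more than one locus", id))
  }
  msgs
}

setValidity("DiseasePanel", function(object) {
  msgs <- validPanelEntries(object@entries)
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DiseasePanel", function(object) {
  cat(sprintf("DiseasePanel '%s' (version %s, build %s)\n",
              object@name, object@version, object@genomeBuild))
  cat(sprintf("  %d mutation(s) across %d disease(s), %d gene(s)\n",
              nrow(object@entries),
              length(unique(object@entries$disease_name)),
              length(unique(object@entries$gene_symbol))))
})

#' @describeIn DiseasePanel number of mutation records in the panel.
#' @param x a \code{DiseasePanel}.
#' @export
setMethod("length", "DiseasePanel", function(x) nrow(x@entries))

#' SiteObservations: per-(mutation, population, cohort) allele counts
#'
#' A \code{DataFrame} subclass with one row per observation of a panel
#' mutation in a population: \code{mutation_key}, \code{population},
#' \code{cohort}, \code{ac} (alternate alleles observed) and \code{an}
#' (called alleles; twice the genotyped diploid samples minus missing
#' alleles, so it varies per site with missingness). An optional
#' \code{disease_name} column carries the disease label through to
#' carrier-rate reports.
#'
#' @aliases SiteObservations-class
#' @seealso \code{\link{countAlleles}}, \code{\link{readObservations}},
#'   \code{\link{poolObservations}}
#' @exportClass SiteObservations
setClass("SiteObservations", contains = "DFrame")

setValidity("SiteObservations", function(object) {
  msgs <- character(0)
  missing_cols <- setdiff(OBS_COLUMNS, colnames(object))
  if (length(missing_cols))
    return(sprintf("missing observation column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  ac <- object$ac; an <- object$an
  if (any(ac < 0)) msgs <- c(msgs, "ac must be non-negative")
  if (any(an <= 0)) msgs <- c(msgs, "an must be positive")
  bad <- which(ac > an)
  if (length(bad))
    msgs <- c(msgs, sprintf("row %d (%s, %s): ac (%d) exceeds an (%d)",
                            bad, object$mutation_key[bad],
                            object$population[bad], ac[bad], an[bad]))
  if (length(msgs)) msgs else TRUE
})

#' Construct a SiteObservations object
#'
#' @param df data.frame (or DataFrame) with columns \code{mutation_key},
#'   \code{population}, \code{cohort}, \code{ac}, \code{an}; extra columns
#'   (e.g. \code{disease_name}) are carried along.
#' @return a \code{\link{SiteObservations-class}} object.
#' @examples
#' SiteObservations(data.frame(mutation_key = "HBB:c.20A>T",
#'   population = "ALL", cohort = "POOLED", ac = 228L, an = 15182L))
#' @export
SiteObservations <- function(df) {
  df <- as.data.frame(df)
  df$ac <- as.integer(df$ac)
  df$an <- as.integer(df$an)
  new("SiteObservations", DataFrame(df, check.names = FALSE))
}

#' CarrierEstimates: carrier-rate statistics derived from allele counts
#'
#' A \code{DataFrame} subclass extending \code{\link{SiteObservations}}
#' columns with: \code{af} (allele frequency ac/an), \code{carrier_rate}
#' (equal to \code{af} under the rare-allele approximation, see
#' \code{\link{estimateCarrier}}), \code{het_frequency} (textbook
#' heterozygote frequency 2p(1-p)), \code{one_in} (1/af, \code{Inf} when
#' ac = 0) and \code{hwe_valid} (TRUE while af < 0.05, the regime in which
#' the approximation is justified).
#'
#' @aliases CarrierEstimates-class
#' @exportClass CarrierEstimates
setClass("CarrierEstimates", contains = "DFrame")

setValidity("CarrierEstimates", function(object) {
  need <- c(OBS_COLUMNS, "af", "carrier_rate", "het_frequency", "one_in",
            "hwe_valid")
  missing_cols <- setdiff(need, colnames(object))
  if (length(missing_cols))
    return(sprintf("missing estimate column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (any(object$carrier_rate != object$af))
    return("carrier_rate must equal af (rare-allele convention)")
  if (any(object$het_frequency < 0 | object$het_frequency > 0.5))
    return("het_frequency must lie in [0, 0.5]")
  TRUE
})

#' QcConfig: site-level quality-control thresholds for allele counting
#'
#' The four filter dimensions applied before a site contributes counts:
#' total read depth, fraction of samples with a called genotype, the
#' alternate-read fraction in heterozygotes, and the average position of
#' alternate alleles along the read. Each filter applies only when the
#' corresponding VCF field is present (DP, GT, AD, MPOS respectively); the
#' read-position filter is disabled by default because site-level VCFs
#' rarely carry it.
#'
#' @slot minTotalDepth integer(1) minimum INFO/DP at the site.
#' @slot minFractionSamplesCalled numeric(1) in [0,1]; minimum fraction of
#'   manifest samples with a non-missing genotype.
#' @slot hetAltFractionRange numeric(2) in [0,1]; admissible range for the
#'   mean alt-read fraction across heterozygous calls (from FORMAT/AD).
#' @slot meanReadPositionRange numeric(2) or NA; admissible range for
#'   INFO/MPOS; NA disables the filter.
#' @aliases QcConfig
#' @seealso \code{\link{qcConfig}}, \code{\link{countAlleles}}
#' @exportClass QcConfig
setClass("QcConfig",
  representation(minTotalDepth = "numeric",
                 minFractionSamplesCalled = "numeric",
                 hetAltFractionRange = "numeric",
                 meanReadPositionRange = "numeric"))

setValidity("QcConfig", function(object) {
  msgs <- character(0)
  p <- object@minFractionSamplesCalled
  if (length(p) != 1L || p < 0 || p > 1)
    msgs <- c(msgs, "minFractionSamplesCalled must be a proportion in [0,1]")
  r <- object@hetAltFractionRange
  if (length(r) != 2L || any(r < 0 | r > 1) || r[1] > r[2])
    msgs <- c(msgs, "hetAltFractionRange must be (low, high) in [0,1], low <= high")
  m <- object@meanReadPositionRange
  if (!all(is.na(m)) && (length(m) != 2L || m[1] > m[2]))
    msgs <- c(msgs, "meanReadPositionRange must be (low, high) or NA")
  if (length(msgs)) msgs else TRUE
})

#' Create a quality-control configuration
#'
#' @param minTotalDepth minimum total read depth (INFO/DP) at a site;
#'   default 10.
#' @param minFractionSamplesCalled minimum fraction of samples with a called
#'   genotype; default 0.8.
#' @param hetAltFractionRange admissible range of the mean alternate-read
#'   fraction among heterozygotes; default c(0.25, 0.75).
#' @param meanReadPositionRange admissible range for the mean read position
#'   of alternate alleles (INFO/MPOS), or NA (default) to disable.
#' @return a \code{\link{QcConfig}} object.
#' @examples
#' qcConfig(minTotalDepth = 20)
#' @export
qcConfig <- function(minTotalDepth = 10,
                     minFractionSamplesCalled = 0.8,
                     hetAltFractionRange = c(0.25, 0.75),
                     meanReadPositionRange = NA_real_) {
  new("QcConfig", minTotalDepth = minTotalDepth,
      minFractionSamplesCalled = minFractionSamplesCalled,
      hetAltFractionRange = hetAltFractionRange,
      meanReadPositionRange = as.numeric(meanReadPositionRange))
}

setMethod("show", "QcConfig", function(object) {
  mrp <- if (all(is.na(object@meanReadPositionRange))) "disabled" else
    paste(object@meanReadPositionRange, collapse = "-")
  cat("QcConfig:",
      sprintf("min DP %s;", object@minTotalDepth),
      sprintf("min called fraction %s;", object@minFractionSamplesCalled),
      sprintf("het alt fraction %s;",
              paste(object@hetAltFractionRange, collapse = "-")),
      sprintf("mean read position %s\n", mrp))
})

#' CohortSpec: parameters of a synthetic exome cohort
#'
#' Describes the statistical structure the carrier-rate analysis assumes:
#' per-population true allele frequencies, Hardy-Weinberg genotype sampling
#' (per-individual alternate-allele count ~ Binomial(2, af)), a
#' false-negative allele dropout rate \code{sigma} (each true alternate
#' allele is observed with probability 1 - sigma), and per-genotype
#' missingness. One master seed drives deterministic per-(population, site)
#' substreams so any subset regenerates identically.
#'
#' @slot populations data.frame with columns \code{code},
#'   \code{superpopulation}, \code{cohort}, \code{n_individuals}.
#' @slot truthAf data.frame with columns \code{mutation_key},
#'   \code{population}, \code{af}: the true alternate-allele frequencies.
#' @slot sigma numeric(1) per-allele false-negative rate.
#' @slot missingRate numeric(1) per-genotype missingness probability.
#' @slot seed integer(1) master seed.
#' @aliases CohortSpec
#' @seealso \code{\link{cohortSpec}}, \code{\link{generateCohort}}
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(populations = "data.frame", truthAf = "data.frame",
                 sigma = "numeric", missingRate = "numeric",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msgs <- character(0)
  pops <- object@populations
  need <- c("code", "superpopulation", "cohort", "n_individuals")
  if (length(setdiff(need, names(pops))))
    return(sprintf("populations must have columns %s",
                   paste(need, collapse = ", ")))
  if (any(pops$n_individuals < 1))
    msgs <- c(msgs, "n_individuals must be >= 1")
  if (anyDuplicated(pops$code))
    msgs <- c(msgs, "population codes must be unique")
  ta <- object@truthAf
  if (length(setdiff(c("mutation_key", "population", "af"), names(ta))))
    return("truthAf must have columns mutation_key, population, af")
  if (any(ta$af < 0 | ta$af > 1))
    msgs <- c(msgs, "truth allele frequencies must lie in [0,1]")
  if (!all(ta$population %in% pops$code))
    msgs <- c(msgs, "truthAf refers to populations absent from the spec")
  for (rate in c(object@sigma, object@missingRate))
    if (rate < 0 || rate > 1)
      msgs <- c(msgs, "sigma and missingRate must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d population(s), %d individuals, %d site x population truths\n",
    nrow(object@populations), sum(object@populations$n_individuals),
    nrow(object@truthAf)))
  cat(sprintf("  sigma = %g, missing rate = %g, seed = %d\n",
              object@sigma, object@missingRate, object@seed))
})

#' ProportionTestResult: pooled two-proportion z-test outcome
#'
#' @slot p1Hat,p2Hat observed proportions ac/an in each cohort.
#' @slot n1,n2 allele denominators.
#' @slot pooledPHat pooled proportion (ac1 + ac2) / (an1 + an2).
#' @slot z z statistic (difference standardized by the pooled variance).
#' @slot pValue two-sided p-value from the standard normal.
#' @slot continuityCorrected logical; whether the Yates-style continuity
#'   correction (1/an1 + 1/an2)/2 was subtracted from |p1 - p2|.
#' @slot degenerate logical; TRUE when the pooled proportion is 0 or 1 so
#'   the statistic is undefined (reported as z = 0, p = 1).
#' @aliases ProportionTestResult
#' @seealso \code{\link{twoProportionTest}}
#' @exportClass ProportionTestResult
setClass("ProportionTestResult",
  representation(p1Hat = "numeric", p2Hat = "numeric",
                 n1 = "numeric", n2 = "numeric",
                 pooledPHat = "numeric", z = "numeric", pValue = "numeric",
                 continuityCorrected = "logical", degenerate = "logical"))

setValidity("ProportionTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value outside [0,1]")
  if (!object@degenerate && !is.finite(object@z)) return("non-finite z")
  TRUE
})

setMethod("show", "ProportionTestResult", function(object) {
  cat("Two-proportion z-test",
      if (object@continuityCorrected) "(continuity-corrected)" else
        "(uncorrected)", "\n")
  cat(sprintf("  p1 = %.6g (n1 = %d), p2 = %.6g (n2 = %d), pooled = %.6g\n",
              object@p1Hat, object@n1, object@p2Hat, object@n2,
              object@pooledPHat))
  if (object@degenerate)
    cat("  degenerate (pooled proportion 0 or 1): z = 0, p = 1\n")
  else
    cat(sprintf("  z = %.4f, two-sided p = %.4g\n", object@z, object@pValue))
})

#' GofTestResult: one-sample goodness-of-fit chi-square outcome
#'
#' Compares an observed allele count against an externally specified
#' expected allele frequency.
#'
#' @slot observedAc observed alternate-allele count.
#' @slot an called-allele denominator.
#' @slot expectedAf the reference allele frequency tested against.
#' @slot chi2 chi-square statistic (1 df, no continuity correction).
#' @slot df degrees of freedom (always 1).
#' @slot pValue upper-tail chi-square p-value.
#' @slot exactAgreement TRUE for the degenerate expected_af = 0, ac = 0 case
#'   (reported as chi2 = 0, p = 1; tabulated "NA" in prevalence reports).
#' @aliases GofTestResult
#' @seealso \code{\link{gofTest}}
#' @exportClass GofTestResult
setClass("GofTestResult",
  representation(observedAc = "numeric", an = "numeric",
                 expectedAf = "numeric", chi2 = "numeric", df = "numeric",
                 pValue = "numeric", exactAgreement = "logical"))

setValidity("GofTestResult", function(object) {
  if (object@pValue < 0 || object@pValue > 1) return("p-value outside [0,1]")
  if (is.finite(object@chi2) && object@chi2 < 0) return("negative chi-square")
  TRUE
})

setMethod("show", "GofTestResult", function(object) {
  cat("Goodness-of-fit chi-square (1 df, no continuity correction)\n")
  cat(sprintf("  observed %d/%d (af = %.6g) vs expected af = %.6g\n",
              object@observedAc, object@an, object@observedAc / object@an,
              object@expectedAf))
  if (object@exactAgreement)
    cat("  exact agreement (both frequencies zero)\n")
  else
    cat(sprintf("  chi2 = %.4f, p = %.4g\n", object@chi2, object@pValue))
})

#' ConcordanceReport: batch cohort-vs-cohort comparison summary
#'
#' @slot results data.frame with one row per (mutation, population-pair)
#'   comparison: counts, z, p-value, significance and degeneracy flags.
#' @slot skipped data.frame of unpaired comparisons that could not be run.
#' @slot alpha significance threshold used.
#' @slot continuityCorrected logical.
#' @aliases ConcordanceReport
#' @seealso \code{\link{batchConcordance}}
#' @exportClass ConcordanceReport
setClass("ConcordanceReport",
  representation(results = "data.frame", skipped = "data.frame",
                 alpha = "numeric", continuityCorrected = "logical"))

setMethod("show", "ConcordanceReport", function(object) {
  res <- object@results
  cat(sprintf("ConcordanceReport: %d comparison(s) at alpha = %g (%s)\n",
              nrow(res), object@alpha,
              if (object@continuityCorrected) "continuity-corrected"
              else "uncorrected"))
  cat(sprintf("  significant: %d; degenerate (0 vs 0): %d; skipped: %d\n",
              sum(res$significant), sum(res$degenerate),
              nrow(object@skipped)))
})
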