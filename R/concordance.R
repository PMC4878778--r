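#' Pooled two-proportion z-test for allele-frequency equality
#'
#' Tests H0: the two cohorts share one allele frequency, using the pooled
#' statistic
#' \deqn{Z = (\hat p_1 - \hat p_2) /
#'   \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with the pooled estimate \eqn{\hat p = (ac_1 + ac_2)/(an_1 + an_2)} and
#' a two-sided p-value from the standard normal. With
#' \code{continuity = TRUE} the absolute difference is reduced by
#' \eqn{(1/an_1 + 1/an_2)/2} (floored at zero) before standardization,
#' matching the classical corrected two-sample proportion test. Without the
#' correction, \eqn{Z^2} is algebraically the 2x2 contingency chi-square.
#'
#' When both counts are zero (or both equal their denominators) the pooled
#' variance vanishes; the result is flagged \code{degenerate} with z = 0
#' and p = 1 rather than crashing.
#'
#' @param ac1,an1 alternate-allele count and called-allele number, cohort 1.
#' @param ac2,an2 likewise for cohort 2.
#' @param continuity apply the continuity correction? Default TRUE.
#' @return a \code{\link{ProportionTestResult}}.
#' @examples
#' # African-ancestry sickle-cell comparison between two exome cohorts
#' twoProportionTest(177, 4402, 45, 492, continuity = FALSE)
#' @export
twoProportionTest <- function(ac1, an1, ac2, an2, continuity = TRUE) {
  if (an1 <= 0 || an2 <= 0) stop("denominators must be positive")
  if (ac1 < 0 || ac2 < 0 || ac1 > an1 || ac2 > an2)
    stop("counts must satisfy 0 <= ac <= an")
  p1 <- ac1 / an1
  p2 <- ac2 / an2
  pooled <- (ac1 + ac2) / (an1 + an2)
  if (pooled == 0 || pooled == 1) {
    return(new("ProportionTestResult", p1Hat = p1, p2Hat = p2,
               n1 = an1, n2 = an2, pooledPHat = pooled, z = 0,
               pValue = 1, continuityCorrected = continuity,
               degenerate = TRUE))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / an1 + 1 / an2))
  d <- p1 - p2
  if (continuity) {
    adj <- max(0, abs(d) - (1 / an1 + 1 / an2) / 2)
    z <- sign(d) * adj / se
  } else {
    z <- d / se
  }
  new("ProportionTestResult", p1Hat = p1, p2Hat = p2, n1 = an1, n2 = an2,
      pooledPHat = pooled, z = z,
      pValue = 2 * stats::pnorm(-abs(z)),
      continuityCorrected = continuity, degenerate = FALSE)
}

#' Goodness-of-fit chi-square of observed counts against a reference
#' frequency
#'
#' One-sample comparison of an observed allele count against an externally
#' specified (e.g. clinically surveyed) allele frequency:
#' \deqn{\chi^2 = (ac - e)^2/e + ((an - ac) - (an - e))^2/(an - e)}
#' with \eqn{e = expectedAf \cdot an}, 1 degree of freedom, and no
#' continuity correction. The degenerate case expectedAf = 0 with ac = 0 is
#' exact agreement (chi2 = 0, p = 1, flagged); expectedAf = 0 with ac > 0
#' yields an infinite statistic, reported as p = 0 with a warning.
#'
#' @param ac observed alternate-allele count.
#' @param an called-allele number (> 0).
#' @param expectedAf reference allele frequency in [0, 1).
#' @return a \code{\link{GofTestResult}}.
#' @examples
#' gofTest(23, 176, 0.171)   # p = 0.155
#' gofTest(0, 178, 0.009)    # p = 0.204
#' @export
gofTest <- function(ac, an, expectedAf) {
  if (an <= 0) stop("an must be positive")
  if (ac < 0 || ac > an) stop("counts must satisfy 0 <= ac <= an")
  if (expectedAf < 0 || expectedAf >= 1)
    stop("expectedAf must lie in [0, 1)")
  if (expectedAf == 0) {
    if (ac == 0)
      return(new("GofTestResult", observedAc = ac, an = an,
                 expectedAf = 0, chi2 = 0, df = 1, pValue = 1,
                 exactAgreement = TRUE))
    warning("expected allele frequency is 0 but ", ac, " allele(s) ",
            "observed: statistic is infinite, p reported as 0")
    return(new("GofTestResult", observedAc = ac, an = an, expectedAf = 0,
               chi2 = Inf, df = 1, pValue = 0, exactAgreement = FALSE))
  }
  e <- expectedAf * an
  chi2 <- (ac - e)^2 / e + ((an - ac) - (an - e))^2 / (an - e)
  new("GofTestResult", observedAc = ac, an = an, expectedAf = expectedAf,
      chi2 = chi2, df = 1,
      pValue = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      exactAgreement = FALSE)
}

#' Batch cohort-vs-cohort concordance of carrier estimates
#'
#' Runs \code{\link{twoProportionTest}} for every mutation across a set of
#' population pairings (e.g. the African-American stratum of one cohort
#' against the African superpopulation of another, and likewise for
#' Europeans). Mutations lacking an observation on either side of a pairing
#' are listed as skipped, never silently dropped. Degenerate comparisons
#' (zero alleles in both cohorts) are labeled and not counted as
#' significant.
#'
#' @param obs1,obs2 \code{\link{SiteObservations-class}} objects for the
#'   two cohorts.
#' @param populationPairs data.frame with columns \code{pop1}, \code{pop2}:
#'   which population of \code{obs1} is compared against which of
#'   \code{obs2}.
#' @param continuity apply the continuity correction (default TRUE, the
#'   convention for cohort comparisons).
#' @param alpha significance threshold; default 0.05.
#' @param bonferroni divide alpha by the number of comparisons? Off by
#'   default (no multiple-testing adjustment).
#' @return a \code{\link{ConcordanceReport}}.
#' @export
batchConcordance <- function(obs1, obs2, populationPairs,
                             continuity = TRUE, alpha = 0.05,
                             bonferroni = FALSE) {
  stopifnot(is(obs1, "SiteObservations"), is(obs2, "SiteObservations"))
  stopifnot(all(c("pop1", "pop2") %in% names(populationPairs)))
  d1 <- as.data.frame(obs1)
  d2 <- as.data.frame(obs2)
  keys <- sort(unique(c(d1$mutation_key, d2$mutation_key)))
  rows <- list(); skipped <- list()
  for (pi in seq_len(nrow(populationPairs))) {
    pop1 <- populationPairs$pop1[pi]; pop2 <- populationPairs$pop2[pi]
    for (key in keys) {
      a <- d1[d1$mutation_key == key & d1$population == pop1, , drop = FALSE]
      b <- d2[d2$mutation_key == key & d2$population == pop2, , drop = FALSE]
      if (nrow(a) != 1L || nrow(b) != 1L) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          mutation_key = key, pop1 = pop1, pop2 = pop2,
          reason = "unpaired", stringsAsFactors = FALSE)
        next
      }
      t <- twoProportionTest(a$ac, a$an, b$ac, b$an,
                             continuity = continuity)
      rows[[length(rows) + 1L]] <- data.frame(
        mutation_key = key, pop1 = pop1, pop2 = pop2,
        ac1 = a$ac, an1 = a$an, ac2 = b$ac, an2 = b$an,
        z = t@z, p_value = t@pValue, degenerate = t@degenerate,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mutation_key = character(0), pop1 = character(0),
               pop2 = character(0), ac1 = integer(0), an1 = integer(0),
               ac2 = integer(0), an2 = integer(0), z = numeric(0),
               p_value = numeric(0), degenerate = logical(0))
  thr <- if (bonferroni && nrow(res)) alpha / nrow(res) else alpha
  res$significant <- !res$degenerate & res$p_value < thr
  skp <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(mutation_key = character(0), pop1 = character(0),
               pop2 = character(0), reason = character(0))
  new("ConcordanceReport", results = res, skipped = skp, alpha = thr,
      continuityCorrected = continuity)
}

#' Read an external clinical-prevalence reference table
#'
#' TSV with columns \code{population}, \code{expected_af_low},
#' \code{expected_af_high}, \code{source}. A point estimate has
#' low = high; a literature range keeps both endpoints, and concordance
#' reports then carry a p-value interval.
#'
#' @param path reference TSV path.
#' @return validated data.frame.
#' @export
readPrevalenceReference <- function(path) {
  if (!file.exists(path)) stop("reference file does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("population", "expected_af_low", "expected_af_high")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("reference table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(df$expected_af_low > df$expected_af_high))
    stop("expected_af_low exceeds expected_af_high")
  df
}

#' Concordance of observed carrier rates with clinical prevalence
#'
#' For each population present in both the observations and the reference
#' table, runs \code{\link{gofTest}} against the reference allele frequency
#' -- both endpoints when the reference is a range -- and reports the
#' p-value (interval). Populations where both the observed count and the
#' reference frequency are zero are exact agreement, reported with
#' \code{p_low}/\code{p_high} = NA (printed "NA" in prevalence tables).
#'
#' @param obs \code{\link{SiteObservations-class}} rows for one mutation.
#' @param reference data.frame from \code{\link{readPrevalenceReference}}.
#' @return data.frame: population, ac, an, af, expected_af_low/high,
#'   chi2_low/high, p_low, p_high, exact_agreement.
#' @examples
#' obs <- readObservations(system.file("extdata",
#'   "carrier_observations_24x23.tsv", package = "exomeCarrier"))
#' sca <- obs[obs$mutation_key == "HBB:c.20A>T", ]
#' ref <- readPrevalenceReference(system.file("extdata",
#'   "sca_prevalence_reference.tsv", package = "exomeCarrier"))
#' head(prevalenceConcordance(sca, ref))
#' @export
prevalenceConcordance <- function(obs, reference) {
  stopifnot(is(obs, "SiteObservations"))
  if (length(unique(obs$mutation_key)) > 1L)
    stop("prevalenceConcordance expects observations of a single mutation")
  d <- as.data.frame(obs)
  rows <- lapply(seq_len(nrow(reference)), function(i) {
    popn <- reference$population[i]
    o <- d[d$population == popn, , drop = FALSE]
    if (nrow(o) != 1L) return(NULL)
    lo <- reference$expected_af_low[i]; hi <- reference$expected_af_high[i]
    tl <- gofTest(o$ac, o$an, lo)
    th <- if (hi == lo) tl else gofTest(o$ac, o$an, hi)
    exact <- tl@exactAgreement && th@exactAgreement
    ps <- sort(c(tl@pValue, th@pValue))
    data.frame(population = popn, ac = o$ac, an = o$an, af = o$ac / o$an,
               expected_af_low = lo, expected_af_high = hi,
               chi2_low = min(tl@chi2, th@chi2),
               chi2_high = max(tl@chi2, th@chi2),
               p_low = if (exact) NA_real_ else ps[1],
               p_high = if (exact) NA_real_ else ps[2],
               exact_agreement = exact, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
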