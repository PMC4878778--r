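#' Closed-form mutation detection probability
#'
#' Probability that at least one carrier of a mutation is observed in a
#' cohort of N exomes:
#' \deqn{D = 1 - \{1 - p(1-\sigma)\}^N}
#' where p is the per-individual carrier rate in the population, sigma the
#' per-observation error rate of exome sequencing (probability a true
#' carrier allele is missed), and N the number of individuals sequenced.
#' The power is evaluated in log space (\code{expm1}/\code{log1p}) so that
#' values indistinguishable from 1 at large N remain exact in their
#' complement; use \code{\link{undetectedRate}} for that complement.
#'
#' @param p carrier rate in [0,1] (vectorized).
#' @param sigma per-observation miss probability in [0,1]; default 0.
#' @param n number of exomes (non-negative integer; vectorized).
#' @return detection probability D in [0,1].
#' @examples
#' detectionRate(0.001, 0.01, 7595)   # 0.9995
#' @export
detectionRate <- function(p, sigma = 0, n) {
  checkDetectionSpec(p, sigma, n)
  eff <- p * (1 - sigma)
  out <- -expm1(n * log1p(-eff))   # log1p(-1) = -Inf handles eff = 1
  out[rep_len(n, length(out)) == 0] <- 0   # 0 * -Inf would be NaN
  out
}

#' Probability of complete non-detection
#'
#' The complement 1 - D of \code{\link{detectionRate}}, computed directly
#' in log space so it does not underflow to zero at biobank scale (it can
#' be of order 1e-27 and smaller).
#'
#' @inheritParams detectionRate
#' @param percent return the value as a percentage? Default FALSE.
#' @return probability (or percentage) that zero carriers are detected.
#' @examples
#' undetectedRate(0.001, 0.01, 60706, percent = TRUE)  # 7.70e-25
#' @export
undetectedRate <- function(p, sigma = 0, n, percent = FALSE) {
  checkDetectionSpec(p, sigma, n)
  eff <- p * (1 - sigma)
  out <- exp(n * log1p(-eff))
  out[rep_len(n, length(out)) == 0] <- 1
  if (percent) 100 * out else out
}

checkDetectionSpec <- function(p, sigma, n) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0,1]")
  if (any(n < 0)) stop("n must be non-negative")
  invisible(TRUE)
}

#' Detection-probability curve over a cohort-size grid
#'
#' Evaluates \code{\link{detectionRate}} on a log-spaced integer grid of
#' cohort sizes including both endpoints (study-size sweeps conventionally
#' run n = 1 to 100,000).
#'
#' @param p carrier rate.
#' @param sigma per-observation miss probability.
#' @param nMin,nMax grid endpoints, 0 <= nMin <= nMax.
#' @param nPoints requested number of grid points (>= 1); duplicates from
#'   integer rounding are collapsed.
#' @return data.frame with columns \code{n} and \code{D}, non-decreasing in
#'   \code{n}.
#' @examples
#' head(detectionCurve(0.001, 0.01, 1, 100000, 50))
#' @export
detectionCurve <- function(p, sigma = 0, nMin = 1, nMax = 100000,
                           nPoints = 100) {
  if (nMin < 0 || nMin > nMax) stop("need 0 <= nMin <= nMax")
  if (nPoints < 1) stop("empty grid: nPoints must be >= 1")
  if (nMin == nMax) {
    grid <- as.integer(nMin)
  } else {
    lo <- max(nMin, 1)
    grid <- unique(as.integer(round(exp(seq(log(lo), log(nMax),
                                            length.out = nPoints)))))
    grid <- sort(unique(c(if (nMin < 1) as.integer(nMin), grid,
                          as.integer(nMax))))
  }
  data.frame(n = grid, D = detectionRate(p, sigma, grid))
}

#' Smallest cohort achieving a target detection probability
#'
#' Direct inversion of the closed form:
#' \eqn{n = \lceil \ln(1 - D^*) / \ln(1 - p(1-\sigma)) \rceil}, with an
#' exactness adjustment so that the detection probability at n reaches the
#' target and at n - 1 does not.
#'
#' @param p carrier rate; \code{p * (1 - sigma)} must be positive, else the
#'   target is unattainable.
#' @param sigma per-observation miss probability.
#' @param targetD target detection probability in (0, 1).
#' @return integer n.
#' @examples
#' requiredN(0.5, 0, 0.75)   # 2
#' @export
requiredN <- function(p, sigma = 0, targetD) {
  checkDetectionSpec(p, sigma, 1)
  if (targetD <= 0 || targetD >= 1) stop("targetD must lie in (0,1)")
  eff <- p * (1 - sigma)
  if (eff == 0)
    stop("unattainable target: p * (1 - sigma) == 0, no cohort size ",
         "can detect the mutation")
  if (eff == 1) return(1L)
  n <- ceiling(log1p(-targetD) / log1p(-eff))
  n <- max(1, n)
  while (detectionRate(p, sigma, n) < targetD) n <- n + 1
  while (n > 1 && detectionRate(p, sigma, n - 1) >= targetD) n <- n - 1
  as.integer(n)
}

#' Monte-Carlo twin of the closed-form detection probability
#'
#' Simulates, per replicate, a cohort of n individuals each carrying the
#' mutation with probability p and each carrier allele surviving the
#' sequencing error with probability 1 - sigma; reports the fraction of
#' replicates in which at least one carrier was detected, with its binomial
#' standard error. Reproducible under a fixed seed.
#'
#' @param p carrier rate.
#' @param sigma per-observation miss probability.
#' @param n cohort size.
#' @param replicates number of simulated cohorts (>= 1).
#' @param seed optional integer seed (applied locally; the caller's RNG
#'   state is restored on exit).
#' @return list with \code{estimate}, \code{se}, \code{replicates}.
#' @examples
#' mc <- monteCarloDetection(0.05, 0, 100, replicates = 5000, seed = 1)
#' abs(mc$estimate - detectionRate(0.05, 0, 100)) < 3 * mc$se
#' @export
monteCarloDetection <- function(p, sigma = 0, n, replicates, seed = NULL) {
  checkDetectionSpec(p, sigma, n)
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  carriers <- stats::rbinom(replicates, n, p)
  detected <- stats::rbinom(replicates, carriers, 1 - sigma) > 0
  est <- mean(detected)
  list(estimate = est, se = sqrt(est * (1 - est) / replicates),
       replicates = replicates)
}
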