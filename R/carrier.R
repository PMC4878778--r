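#' Carrier-rate estimates under the rare-allele Hardy-Weinberg approximation
#'
#' Under Hardy-Weinberg equilibrium with causal-allele frequency p and
#' wild-type frequency q = 1 - p, the fraction of individuals carrying at
#' least one causal allele that matters for recessive-disease screening is
#' p^2 + 2pq x 0.5 = p^2 + pq = p. In the rare-allele regime (p < 0.05,
#' implied disease prevalence p^2 < 0.25\%) this equals the allele frequency
#' itself, which is the operational "carrier rate" reported here. The
#' textbook heterozygote frequency 2p(1 - p) is exposed alongside as
#' \code{het_frequency} so users can choose either convention. When
#' p >= 0.05 the approximation degrades; such estimates keep their numeric
#' values but are flagged \code{hwe_valid = FALSE} with a warning.
#'
#' @param obs a \code{\link{SiteObservations-class}} object; every row must
#'   have an > 0.
#' @return a \code{\link{CarrierEstimates-class}} object with columns
#'   \code{af}, \code{carrier_rate}, \code{het_frequency}, \code{one_in},
#'   \code{hwe_valid} appended to the observation columns.
#' @examples
#' obs <- SiteObservations(data.frame(mutation_key = "HBB:c.20A>T",
#'   population = "ALL", cohort = "POOLED", ac = 228L, an = 15182L))
#' est <- estimateCarrier(obs)
#' est$one_in          # 66.6: "1 in 66.6", i.e. 1.50%
#' @export
estimateCarrier <- function(obs) {
  stopifnot(is(obs, "SiteObservations"))
  if (any(obs$an == 0L))
    stop("undefined estimate: an == 0 for ",
         paste(obs$mutation_key[obs$an == 0L], collapse = ", "))
  df <- as.data.frame(obs)
  df$af <- df$ac / df$an
  df$carrier_rate <- df$af
  df$het_frequency <- 2 * df$af * (1 - df$af)
  df$one_in <- oneIn(df$af)
  df$hwe_valid <- df$af < 0.05
  if (any(!df$hwe_valid))
    warning(sum(!df$hwe_valid), " estimate(s) with af >= 0.05 (implied ",
            "prevalence >= 0.25%): rare-allele carrier approximation is ",
            "flagged invalid (hwe_valid = FALSE); numeric values are still ",
            "reported")
  new("CarrierEstimates", DataFrame(df, check.names = FALSE))
}

#' Reciprocal "1 in N" carrier-burden statistic
#'
#' @param af allele frequency (vectorized). Zero maps to \code{Inf}, never a
#'   division error.
#' @return 1/af at full precision; display formatting conventionally rounds
#'   to one decimal.
#' @examples
#' oneIn(56 / 14226)   # 254.0
#' oneIn(0)            # Inf
#' @export
oneIn <- function(af) {
  if (any(af < 0 | af > 1)) stop("af must lie in [0,1]")
  ifelse(af > 0, 1 / af, Inf)
}

#' Rank mutations of one disease by carrier rate for screening priority
#'
#' Orders a disease's mutations by descending allele frequency in the named
#' population. Ties are grouped at display precision (3 significant
#' figures) and share the minimum rank, since screening panels are drawn up
#' from reported (rounded) frequencies.
#'
#' @param estimates a \code{\link{CarrierEstimates-class}} object carrying a
#'   \code{disease_name} column.
#' @param disease disease name to rank within.
#' @param population population code.
#' @return data.frame with columns \code{rank}, \code{mutation_key},
#'   \code{af}, \code{percent}, ordered by decreasing af; zero rows for
#'   empty input.
#' @export
rankMutations <- function(estimates, disease, population) {
  stopifnot(is(estimates, "CarrierEstimates"))
  if (!"disease_name" %in% colnames(estimates))
    stop("estimates carry no disease_name column")
  sel <- as.data.frame(estimates[
    estimates$disease_name == disease &
    estimates$population == population, ])
  if (nrow(sel) == 0L)
    return(data.frame(rank = integer(0), mutation_key = character(0),
                      af = numeric(0), percent = numeric(0)))
  sel <- sel[order(-sel$af, sel$mutation_key), ]
  af_disp <- signif(sel$af, 3)
  rank <- match(af_disp, af_disp)  # sorted desc, so first index = min rank
  out <- data.frame(rank = rank, mutation_key = sel$mutation_key,
                    af = sel$af, percent = 100 * sel$af,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Aggregate per-mutation carrier rates into a disease-level burden
#'
#' Sums the per-mutation allele frequencies for one disease and population.
#' Summation assumes the causal alleles are rare and independent (no
#' compound carriers double-counted), so the result is explicitly flagged
#' as an approximation.
#'
#' @param estimates a \code{\link{CarrierEstimates-class}} object with a
#'   \code{disease_name} column.
#' @param disease disease name.
#' @param population population code.
#' @return one-row data.frame: \code{disease_name}, \code{population},
#'   \code{burden} (sum of afs), \code{n_mutations}, \code{approximate}
#'   (always TRUE).
#' @export
diseaseBurden <- function(estimates, disease, population) {
  stopifnot(is(estimates, "CarrierEstimates"))
  if (!"disease_name" %in% colnames(estimates))
    stop("estimates carry no disease_name column")
  sel <- estimates[estimates$disease_name == disease &
                   estimates$population == population, ]
  data.frame(disease_name = disease, population = population,
             burden = sum(sel$af), n_mutations = nrow(sel),
             approximate = TRUE, stringsAsFactors = FALSE)
}

#' Format carrier estimates as a publication-style table
#'
#' Mirrors the layout of per-population carrier tables: one row per
#' (mutation, population) with the allele frequency at 3 significant
#' figures, the AC/AN counts, the "1 in N" reciprocal at one decimal and
#' the validity flag. Stored estimates keep full precision; only this
#' display layer rounds.
#'
#' @param estimates a \code{\link{CarrierEstimates-class}} object.
#' @return data.frame ready for writing with
#'   \code{\link[utils]{write.table}}.
#' @export
carrierTable <- function(estimates) {
  stopifnot(is(estimates, "CarrierEstimates"))
  df <- as.data.frame(estimates)
  out <- data.frame(
    mutation_key = df$mutation_key,
    population = df$population, cohort = df$cohort,
    af = signif(df$af, 3), ac = df$ac, an = df$an,
    one_in = round(df$one_in, 1), percent = signif(100 * df$af, 3),
    hwe_valid = df$hwe_valid, stringsAsFactors = FALSE)
  if ("disease_name" %in% names(df))
    out <- cbind(disease_name = df$disease_name, out)
  out
}
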