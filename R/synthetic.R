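#' Specify a synthetic exome cohort
#'
#' @param populations data.frame with columns \code{code},
#'   \code{superpopulation}, \code{cohort}, \code{n_individuals}.
#' @param truthAf data.frame with columns \code{mutation_key},
#'   \code{population}, \code{af}: true alternate-allele frequencies per
#'   panel mutation and population. Omitted (mutation, population)
#'   combinations are monomorphic reference.
#' @param sigma per-allele false-negative dropout rate (each true alternate
#'   allele is independently observed with probability 1 - sigma); default 0.
#' @param missingRate per-genotype missingness probability; default 0.
#' @param seed master seed; per-(population, site) substreams are derived
#'   from it deterministically, so subsets regenerate identically.
#' @return a \code{\link{CohortSpec}}.
#' @examples
#' cohortSpec(
#'   populations = data.frame(code = "POP1", superpopulation = "SYN",
#'                            cohort = "SIM", n_individuals = 50),
#'   truthAf = data.frame(mutation_key = "GENE1:c.1A>T",
#'                        population = "POP1", af = 0.1))
#' @export
cohortSpec <- function(populations, truthAf, sigma = 0, missingRate = 0,
                       seed = 1L) {
  new("CohortSpec", populations = as.data.frame(populations),
      truthAf = as.data.frame(truthAf), sigma = sigma,
      missingRate = missingRate, seed = as.integer(seed))
}

# deterministic substream seed for (population index, site index);
# kept below 2^31 so it is a valid R integer seed
substreamSeed <- function(master, popIdx, siteIdx) {
  as.integer((as.double(master) * 1000003 + popIdx * 7919 + siteIdx) %%
               2147483647)
}

# Draw true and observed genotypes for every (site, population).
# Returns a list keyed by population code; each element holds integer
# matrices `true` and `observed` (sites x individuals; observed has NA for
# missing genotypes) plus the site table.
simulateCohortGenotypes <- function(spec, panel) {
  stopifnot(is(spec, "CohortSpec"), is(panel, "DiseasePanel"))
  entries <- panel@entries
  keys <- unique(spec@truthAf$mutation_key)
  unknown <- setdiff(keys, entries$mutation_key)
  if (length(unknown))
    stop("truthAf refers to mutation(s) absent from the panel: ",
         paste(unknown, collapse = ", "))
  sites <- entries[entries$mutation_key %in% keys, , drop = FALSE]
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  pops <- spec@populations
  out <- list()
  for (pi in seq_len(nrow(pops))) {
    n <- pops$n_individuals[pi]
    g_true <- matrix(0L, nrow = nrow(sites), ncol = n)
    g_obs <- matrix(0L, nrow = nrow(sites), ncol = n)
    for (si in seq_len(nrow(sites))) {
      af <- spec@truthAf$af[
        spec@truthAf$mutation_key == sites$mutation_key[si] &
        spec@truthAf$population == pops$code[pi]]
      af <- if (length(af)) af[1] else 0
      old <- globalenv()$.Random.seed
      set.seed(substreamSeed(spec@seed, pi, si))
      gt <- stats::rbinom(n, 2L, af)              # Hardy-Weinberg sampling
      go <- stats::rbinom(n, gt, 1 - spec@sigma)  # allele dropout
      miss <- stats::runif(n) < spec@missingRate
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      go[miss] <- NA_integer_
      g_true[si, ] <- gt
      g_obs[si, ] <- go
    }
    out[[pops$code[pi]]] <- list(true = g_true, observed = g_obs)
  }
  list(sites = sites, populations = pops, genotypes = out)
}

#' Tally a synthetic cohort without VCF round-tripping
#'
#' Draws the cohort's genotypes and sums them directly into per-population
#' AC/AN observations, together with the pre-error truth. This is the fast
#' path for simulation studies; \code{\link{generateCohort}} emits the same
#' genotypes (same seed substreams) through a VCF + manifest for testing
#' the file-based pipeline.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param panel a \code{\link{DiseasePanel}} containing the truth
#'   mutations.
#' @return list with \code{observations} (a
#'   \code{\link{SiteObservations-class}} of observed counts) and
#'   \code{truth} (data.frame of true af, true AC and sample sizes).
#' @export
drawCohortCounts <- function(spec, panel) {
  sim <- simulateCohortGenotypes(spec, panel)
  obs <- list(); truth <- list()
  for (pi in seq_len(nrow(sim$populations))) {
    code <- sim$populations$code[pi]
    g <- sim$genotypes[[code]]
    for (si in seq_len(nrow(sim$sites))) {
      go <- g$observed[si, ]
      af <- spec@truthAf$af[
        spec@truthAf$mutation_key == sim$sites$mutation_key[si] &
        spec@truthAf$population == code]
      obs[[length(obs) + 1L]] <- data.frame(
        mutation_key = sim$sites$mutation_key[si],
        disease_name = sim$sites$disease_name[si],
        population = code, cohort = sim$populations$cohort[pi],
        ac = sum(go, na.rm = TRUE), an = 2L * sum(!is.na(go)),
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        mutation_key = sim$sites$mutation_key[si], population = code,
        true_af = if (length(af)) af[1] else 0,
        true_ac = sum(g$true[si, ]),
        n_individuals = ncol(g$true), stringsAsFactors = FALSE)
    }
  }
  list(observations = SiteObservations(do.call(rbind, obs)),
       truth = do.call(rbind, truth))
}

#' Generate a synthetic cohort as VCF + manifest + truth record
#'
#' Writes a VCF 4.2 (GT genotypes, optional constant INFO/DP for
#' exercising depth filters), a sample manifest TSV and a truth JSON
#' holding the generator parameters and the pre-error genotype matrix.
#' Genotypes are identical to those tallied by
#' \code{\link{drawCohortCounts}} under the same spec.
#'
#' @param spec a \code{\link{CohortSpec}}.
#' @param panel a \code{\link{DiseasePanel}}; every truth mutation must
#'   carry an explicit genomic locus.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; default "cohort".
#' @param infoDepth optional integer: write \code{DP=infoDepth} on every
#'   record so depth-based QC can be exercised.
#' @return list with paths \code{vcf}, \code{manifest}, \code{truth}.
#' @export
generateCohort <- function(spec, panel, dir, prefix = "cohort",
                           infoDepth = NULL) {
  sim <- simulateCohortGenotypes(spec, panel)
  sites <- sim$sites
  no_locus <- !nzchar(sites$chrom) | is.na(sites$pos)
  if (any(no_locus))
    stop("cannot write VCF: panel entr(ies) without genomic locus: ",
         paste(sites$mutation_key[no_locus], collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pops <- sim$populations

  sample_ids <- unlist(lapply(seq_len(nrow(pops)), function(pi)
    sprintf("%s_%03d", pops$code[pi], seq_len(pops$n_individuals[pi]))))
  manifest <- data.frame(
    sample_id = sample_ids,
    population = rep(pops$code, pops$n_individuals),
    superpopulation = rep(pops$superpopulation, pops$n_individuals),
    cohort = rep(pops$cohort, pops$n_individuals),
    sex = "unknown", stringsAsFactors = FALSE)

  gt_string <- function(g) {
    ifelse(is.na(g), "./.", c("0/0", "0/1", "1/1")[g + 1L])
  }
  geno_block <- do.call(cbind, lapply(pops$code, function(code)
    sim$genotypes[[code]]$observed))
  body <- vapply(seq_len(nrow(sites)), function(si) {
    info <- if (is.null(infoDepth)) "." else sprintf("DP=%d", infoDepth)
    paste(c(sites$chrom[si], sites$pos[si],
            if (is.na(sites$rsid[si])) "." else sites$rsid[si],
            sites$ref[si], sites$alt[si], ".", "PASS", info, "GT",
            gt_string(geno_block[si, ])), collapse = "\t")
  }, character(1))

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=exomeCarrier synthetic cohort (seed %d)", spec@seed),
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    if (!is.null(infoDepth))
      "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"))

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  writeLines(c(header, body), vcf_path)
  manifest_path <- file.path(dir, paste0(prefix, "_manifest.tsv"))
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth_path <- file.path(dir, paste0(prefix, "_truth.json"))
  truth <- list(
    seed = spec@seed, sigma = spec@sigma, missingRate = spec@missingRate,
    populations = pops, truth_af = spec@truthAf,
    sites = sites[, c("mutation_key", "chrom", "pos", "ref", "alt")],
    true_genotypes = lapply(sim$genotypes, function(g) g$true))
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  list(vcf = vcf_path, manifest = manifest_path, truth = truth_path)
}
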