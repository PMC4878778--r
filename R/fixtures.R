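#' Bundled 24-mutation disease panel
#'
#' The panel of causative mutations for 15 recessive disorders that were
#' observed in at least one of the two population exome cohorts, as
#' published: disease, OMIM id, gene, RefSeqGene/mRNA accessions, HGVS c.
#' and p. descriptions, and dbSNP rsID. The published table prints no
#' genomic coordinates, so entries carry rsIDs only -- except the SERAC1
#' insertion, whose dbSNP cell is "-" and which therefore carries a
#' SYNTHETIC placeholder locus (6:158571000 A>ATC) solely to satisfy the
#' one-of-\{rsID, locus\} record invariant; that locus is not a dbSNP or
#' genome-browser coordinate.
#'
#' @return a \code{\link{DiseasePanel}} of 24 mutations.
#' @examples
#' table1Panel()
#' @export
table1Panel <- function() {
  readPanel(system.file("extdata", "mutation_panel_24.tsv",
                        package = "exomeCarrier"),
            name = "recessive-24", version = "1")
}

#' Bundled per-population allele counts for the 24-mutation panel
#'
#' The published AC/AN counts for every mutation in
#' \code{\link{table1Panel}} across 23 population strata: the pooled total
#' (ALL), per-cohort totals, the NHLBI EA/AA and 1000 Genomes
#' superpopulation strata, and 16 country-level populations. Two
#' transcription notes: the RAB23:c.434T>A pooled denominator is kept as
#' printed (15190) although the printed cohort denominators sum to 15178;
#' the ADAR:c.577C>A NHLBI count (printed only as a frequency) is carried
#' as 41/13006, the difference of the printed pooled and 1000 Genomes
#' counts.
#'
#' @return a \code{\link{SiteObservations-class}} object (552 rows).
#' @examples
#' obs <- table1Observations()
#' obs[obs$mutation_key == "HBB:c.20A>T" & obs$population == "ALL", ]
#' @export
table1Observations <- function() {
  readObservations(system.file("extdata", "carrier_observations_24x23.tsv",
                               package = "exomeCarrier"))
}

#' Bundled clinical prevalence reference for the sickle-cell allele
#'
#' Literature allele-frequency estimates (point values or ranges) for the
#' HBB sickle-cell allele per population, against which exome-derived
#' carrier rates are tested with \code{\link{prevalenceConcordance}}.
#'
#' @return data.frame (see \code{\link{readPrevalenceReference}}).
#' @export
scaPrevalenceReference <- function() {
  readPrevalenceReference(system.file("extdata",
    "sca_prevalence_reference.tsv", package = "exomeCarrier"))
}

#' Bundled ExAC-style summary counts
#'
#' Published six-race AC/AN summaries for the two highest-burden panel
#' sites (HBB sickle-cell and CLEC7A), used to demonstrate that printed
#' aggregate tables flow through the same observation interface as VCF
#' cohorts.
#'
#' @return a \code{\link{SiteObservations-class}} object.
#' @export
exacObservations <- function() {
  readObservations(system.file("extdata", "exac_observations.tsv",
                               package = "exomeCarrier"))
}
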