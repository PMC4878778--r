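#' Read a sample-to-population manifest
#'
#' TSV with header \code{sample_id, population, superpopulation, cohort,
#' sex}. Sample identifiers must be unique within a cohort and every
#' population must map to exactly one superpopulation.
#'
#' @param path manifest TSV path.
#' @return validated data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest file does not exist: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("sample_id", "population", "superpopulation", "cohort", "sex")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  validateManifest(df)
}

validateManifest <- function(df) {
  dup <- df[duplicated(df[, c("sample_id", "cohort")]), , drop = FALSE]
  if (nrow(dup))
    stop("duplicate sample_id within a cohort: ",
         paste(unique(dup$sample_id), collapse = ", "))
  map <- unique(df[, c("population", "superpopulation")])
  multi <- map$population[duplicated(map$population)]
  if (length(multi))
    stop("population(s) mapped to more than one superpopulation: ",
         paste(unique(multi), collapse = ", "))
  bad_sex <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad_sex))
    stop("sex must be male/female/unknown, found: ",
         paste(bad_sex, collapse = ", "))
  df
}

#' Load per-population allele counts from a tabular file
#'
#' Lets published AC/AN summary tables act as cohort inputs with the same
#' downstream behavior as VCF-derived counts. Expects a TSV with header
#' \code{mutation_key, population, cohort, ac, an}; an optional
#' \code{disease_name} column is carried along.
#'
#' @param path observations TSV path.
#' @return a \code{\link{SiteObservations-class}} object.
#' @examples
#' obs <- readObservations(system.file("extdata",
#'   "carrier_observations_24x23.tsv", package = "exomeCarrier"))
#' obs[obs$population == "ALL" & obs$mutation_key == "HBB:c.20A>T", ]
#' @export
readObservations <- function(path) {
  if (!file.exists(path)) stop("observations file does not exist: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(OBS_COLUMNS, names(df))
  if (length(missing_cols))
    stop("observations table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(df$ac > df$an)
  if (length(bad))
    stop("invalid observations (ac > an) at row(s): ",
         paste(bad, collapse = ", "))
  SiteObservations(df)
}

#' Write observations to a TSV
#'
#' @param obs a \code{\link{SiteObservations-class}} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeObservations <- function(obs, path) {
  stopifnot(is(obs, "SiteObservations"))
  utils::write.table(as.data.frame(obs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pool allele counts for one mutation across cohorts or populations
#'
#' Sums AC and AN over observations of the same mutation, e.g. to combine
#' an African-American stratum of one cohort with the African
#' superpopulation of another into a single cross-cohort estimate. The
#' pooled allele frequency is therefore the count-weighted average and
#' always lies within the range of the component frequencies.
#'
#' @param obs a \code{\link{SiteObservations-class}} object whose rows all
#'   refer to the same mutation.
#' @param population label for the pooled stratum.
#' @param cohort label for the pooled cohort; default "POOLED".
#' @return a one-row \code{\link{SiteObservations-class}} object.
#' @examples
#' sca <- SiteObservations(data.frame(
#'   mutation_key = "HBB:c.20A>T",
#'   population = c("AA", "AFR"), cohort = c("NHLBI", "1000G"),
#'   ac = c(177L, 45L), an = c(4402L, 492L)))
#' poolObservations(sca, population = "African")  # 222/4894
#' @export
poolObservations <- function(obs, population, cohort = "POOLED") {
  stopifnot(is(obs, "SiteObservations"))
  if (nrow(obs) == 0L) stop("no observations to pool")
  keys <- unique(obs$mutation_key)
  if (length(keys) != 1L)
    stop("cannot pool observations of different mutations: ",
         paste(keys, collapse = ", "))
  out <- data.frame(mutation_key = keys, population = population,
                    cohort = cohort, ac = sum(obs$ac), an = sum(obs$an),
                    stringsAsFactors = FALSE)
  if ("disease_name" %in% colnames(obs))
    out$disease_name <- obs$disease_name[1L]
  SiteObservations(out)
}

#' Pool every mutation across a set of population strata
#'
#' Convenience wrapper over \code{\link{poolObservations}}: for each
#' mutation present, sums AC/AN over the rows whose population is in
#' \code{populations}.
#'
#' @param obs a \code{\link{SiteObservations-class}} object.
#' @param populations character vector of population codes to pool.
#' @param label pooled stratum label.
#' @param cohort pooled cohort label.
#' @return a \code{\link{SiteObservations-class}} object, one row per
#'   mutation.
#' @export
poolByMutation <- function(obs, populations, label, cohort = "POOLED") {
  stopifnot(is(obs, "SiteObservations"))
  sel <- obs[obs$population %in% populations, ]
  if (nrow(sel) == 0L)
    stop("no observations in populations: ",
         paste(populations, collapse = ", "))
  parts <- split(as.data.frame(sel), sel$mutation_key)
  pooled <- do.call(rbind, lapply(parts, function(p)
    as.data.frame(poolObservations(SiteObservations(p), population = label,
                                   cohort = cohort))))
  rownames(pooled) <- NULL
  SiteObservations(pooled)
}
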