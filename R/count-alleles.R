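#' Count panel alleles per population from a cohort VCF
#'
#' Reads a cohort VCF (plain or bgzipped), applies site-level quality
#' filters, decomposes multi-allelic records into biallelic variants,
#' normalizes alleles (shared prefix/suffix trimming) and matches them
#' against the disease panel, then tallies alternate-allele counts (AC) and
#' called-allele numbers (AN) per population of the sample manifest.
#'
#' Missing genotypes (\code{./.}) contribute nothing to AN; half-called
#' genotypes (e.g. \code{./1}) contribute their single called allele. AN
#' counts all called alleles at the site (ExAC-style denominator), so it
#' varies per site with missingness. Sites failing a quality filter are
#' excluded entirely and logged with the reason in
#' \code{metadata(result)$qc_log}. Each filter applies only when the
#' corresponding VCF field exists (INFO/DP, FORMAT/GT, FORMAT/AD,
#' INFO/MPOS).
#'
#' @param vcf path to the cohort VCF.
#' @param manifest data.frame from \code{\link{readManifest}} (or a path to
#'   a manifest TSV). Every VCF sample must appear in it.
#' @param panel a \code{\link{DiseasePanel}}; only autosomal loci are
#'   admissible.
#' @param qc a \code{\link{QcConfig}}; defaults to \code{qcConfig()}.
#' @param contigAliases optional named character vector mapping VCF contig
#'   names to panel contig names (e.g. \code{c(chr11 = "11")}). The
#'   \code{chr} prefix dialect is resolved automatically.
#' @return a \code{\link{SiteObservations-class}} object with one row per
#'   (matched mutation, population); QC exclusions in
#'   \code{metadata(.)$qc_log}.
#' @seealso \code{\link{generateCohort}} for producing test cohorts.
#' @export
countAlleles <- function(vcf, manifest, panel, qc = qcConfig(),
                         contigAliases = NULL) {
  stopifnot(is(panel, "DiseasePanel"), is(qc, "QcConfig"))
  if (is.character(manifest)) manifest <- readManifest(manifest)
  manifest <- validateManifest(manifest)

  entries <- panel@entries
  has_locus <- nzchar(entries$chrom) & !is.na(entries$pos)
  canon <- function(x) {
    x <- as.character(x)
    if (!is.null(contigAliases)) {
      hit <- match(x, names(contigAliases))
      x[!is.na(hit)] <- contigAliases[hit[!is.na(hit)]]
    }
    sub("^chr", "", x)
  }
  autosomes <- as.character(1:22)
  bad_chrom <- which(has_locus & !(canon(entries$chrom) %in% autosomes))
  if (length(bad_chrom))
    stop("non-autosomal panel entr(ies) rejected: ",
         paste(entries$mutation_key[bad_chrom], collapse = ", "),
         " (chromosome ",
         paste(unique(entries$chrom[bad_chrom]), collapse = ", "),
         "); the carrier model assumes autosomal diploid genotypes")

  v <- VariantAnnotation::readVcf(vcf, genome = panel@genomeBuild)
  vcf_samples <- colnames(v)
  unknown <- setdiff(vcf_samples, manifest$sample_id)
  if (length(unknown))
    stop("VCF sample(s) absent from the manifest: ",
         paste(unknown, collapse = ", "))
  if (!"GT" %in% names(VariantAnnotation::geno(v)))
    stop("VCF carries no GT genotypes; nothing to count")

  rr <- SummarizedExperiment::rowRanges(v)
  vcf_contigs <- unique(canon(as.character(GenomeInfoDb::seqnames(rr))))
  panel_contigs <- unique(canon(entries$chrom[has_locus]))
  if (length(rr) && length(panel_contigs) &&
      !length(intersect(vcf_contigs, panel_contigs)))
    stop("no VCF contig matches any panel contig (",
         paste(vcf_contigs, collapse = ","), " vs ",
         paste(panel_contigs, collapse = ","),
         "); configure contigAliases to resolve naming dialects")

  gt <- VariantAnnotation::geno(v)$GT
  info <- VariantAnnotation::info(v)
  ad <- if ("AD" %in% names(VariantAnnotation::geno(v)))
    VariantAnnotation::geno(v)$AD else NULL
  ids <- rownames(v)

  # population grouping of the VCF's samples
  mf <- manifest[manifest$sample_id %in% vcf_samples, , drop = FALSE]
  groups <- split(mf$sample_id,
                  paste(mf$population, mf$cohort, sep = "\r"))

  qc_log <- list()
  tallies <- list()
  n_samples <- length(vcf_samples)

  for (i in seq_along(rr)) {
    chrom <- canon(as.character(GenomeInfoDb::seqnames(rr)[i]))
    pos0 <- GenomicRanges::start(rr)[i]
    refa <- as.character(rr$REF[i])
    alts <- as.character(rr$ALT[[i]])
    # allele calls per sample: list of character vectors over {0,1,2,...,.}
    row_gt <- stats::setNames(as.character(gt[i, vcf_samples]), vcf_samples)
    calls <- strsplit(row_gt, "[/|]")
    called <- vapply(calls, function(a) sum(a != "."), integer(1))
    an_site <- sum(called)

    fail <- NULL
    if ("DP" %in% names(info) && !is.na(info$DP[i]) &&
        info$DP[i] < qc@minTotalDepth)
      fail <- "low_depth"
    if (is.null(fail) &&
        mean(called > 0) < qc@minFractionSamplesCalled)
      fail <- "low_call_rate"
    if (is.null(fail) && !all(is.na(qc@meanReadPositionRange)) &&
        "MPOS" %in% names(info) && !is.na(info$MPOS[i]) &&
        (info$MPOS[i] < qc@meanReadPositionRange[1] ||
         info$MPOS[i] > qc@meanReadPositionRange[2]))
      fail <- "read_position"

    for (k in seq_along(alts)) {
      if (alts[k] %in% c(".", "*", "")) next
      site_fail <- fail
      if (is.null(site_fail) && !is.null(ad)) {
        hets <- which(vapply(calls, function(a)
          sum(a == as.character(k)) == 1L && sum(a != ".") == 2L,
          logical(1)))
        if (length(hets)) {
          frac <- vapply(hets, function(s) {
            counts <- unlist(ad[i, vcf_samples[s]])
            if (length(counts) < k + 1L || anyNA(counts)) return(NA_real_)
            counts[k + 1L] / sum(counts)
          }, numeric(1))
          mfrac <- mean(frac, na.rm = TRUE)
          if (is.finite(mfrac) &&
              (mfrac < qc@hetAltFractionRange[1] ||
               mfrac > qc@hetAltFractionRange[2]))
            site_fail <- "het_alt_fraction"
        }
      }
      norm <- normalizeAllelePair(pos0, refa, alts[k])
      if (!is.null(site_fail)) {
        qc_log[[length(qc_log) + 1L]] <- data.frame(
          variant = ids[i], chrom = chrom, pos = norm$pos, ref = norm$ref,
          alt = norm$alt, reason = site_fail, stringsAsFactors = FALSE)
        next
      }
      rsid <- if (grepl("^rs[0-9]+$", ids[i])) ids[i] else NULL
      rec <- matchVariant(panel, chrom = chrom, pos = norm$pos,
                          ref = norm$ref, alt = norm$alt, rsid = rsid)
      if (is.null(rec)) next
      for (g in names(groups)) {
        s <- groups[[g]]
        ac <- sum(vapply(calls[s], function(a)
          sum(a == as.character(k)), integer(1)))
        an <- sum(called[s])
        if (an == 0L) next
        pc <- strsplit(g, "\r", fixed = TRUE)[[1]]
        tallies[[length(tallies) + 1L]] <- data.frame(
          mutation_key = rec$mutation_key, disease_name = rec$disease_name,
          population = pc[1], cohort = pc[2], ac = ac, an = an,
          stringsAsFactors = FALSE)
      }
    }
  }

  out <- if (length(tallies)) do.call(rbind, tallies) else
    data.frame(mutation_key = character(0), disease_name = character(0),
               population = character(0), cohort = character(0),
               ac = integer(0), an = integer(0))
  rownames(out) <- NULL
  obs <- SiteObservations(out)
  metadata(obs)$qc_log <- if (length(qc_log)) do.call(rbind, qc_log) else
    data.frame(variant = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0),
               reason = character(0))
  obs
}
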