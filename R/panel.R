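#' Read a disease-mutation panel
#'
#' Loads a panel from TSV (one column per record field) or JSON and
#' validates it. The TSV contract is a header row
#' \code{disease_name, omim_id, gene_symbol, refseq_gene, mrna_id, hgvs_c,
#' hgvs_p, rsid, chrom, pos, ref, alt} with an optional \code{inheritance}
#' column (defaults to "autosomal recessive"). A dbSNP cell of \code{"-"} or
#' empty is treated as absent; every record must then carry an explicit
#' genomic locus. Records failing validation abort the load with row-level
#' diagnostics naming the row and field.
#'
#' @param path path to the panel file.
#' @param format "tsv" or "json".
#' @param name,version panel metadata; default to values stored in the file
#'   (JSON) or the file name.
#' @param genomeBuild opaque genome-build label carried as metadata.
#' @return a \code{\link{DiseasePanel}}.
#' @examples
#' p <- readPanel(system.file("extdata", "mutation_panel_24.tsv",
#'                            package = "exomeCarrier"))
#' length(p)
#' @export
readPanel <- function(path, format = c("tsv", "json"), name = NULL,
                      version = "1", genomeBuild = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("panel file does not exist: ", path)
  if (format == "tsv") {
    df <- tryCatch(
      utils::read.delim(path, colClasses = "character"),
      error = function(e) stop("malformed panel TSV: ", conditionMessage(e)))
    if (nrow(df) == 0L) stop("panel file is empty: ", path)
  } else {
    parsed <- tryCatch(jsonlite::fromJSON(path),
      error = function(e) stop("malformed panel JSON: ", conditionMessage(e)))
    df <- as.data.frame(parsed$entries, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("panel file is empty: ", path)
    for (col in names(df)) df[[col]] <- as.character(df[[col]])
    if (is.null(name) && !is.null(parsed$name)) name <- parsed$name
    if (!is.null(parsed$version)) version <- parsed$version
    if (!is.null(parsed$genome_build)) genomeBuild <- parsed$genome_build
  }
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  DiseasePanel(df, name = name, version = version, genomeBuild = genomeBuild)
}

#' Construct a DiseasePanel from a data.frame of records
#'
#' @param entries data.frame with the panel columns (see
#'   \code{\link{readPanel}}).
#' @param name,version,genomeBuild panel metadata.
#' @return a validated \code{\link{DiseasePanel}}.
#' @export
DiseasePanel <- function(entries, name = "panel", version = "1",
                         genomeBuild = "unknown") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"inheritance" %in% names(entries))
    entries$inheritance <- "autosomal recessive"
  if (!"hgvs_p" %in% names(entries)) entries$hgvs_p <- ""
  for (col in c("chrom", "ref", "alt", "rsid", "omim_id"))
    if (!col %in% names(entries)) entries[[col]] <- ""
  if (!"pos" %in% names(entries)) entries$pos <- NA_integer_
  for (col in setdiff(PANEL_COLUMNS, "pos"))
    entries[[col]] <- trimws(as.character(entries[[col]]))
  # "-" and "" both denote an absent dbSNP identifier
  entries$rsid[entries$rsid %in% c("-", "")] <- NA_character_
  entries$pos <- suppressWarnings(as.integer(entries$pos))
  has_locus <- nzchar(entries$chrom) & !is.na(entries$pos)
  # warn (not error) when a record's rsid and locus will disagree at match
  # time; dbSNP merges drift over time, and the locus wins during matching
  entries$mutation_key <- paste(entries$gene_symbol, entries$hgvs_c, sep = ":")
  msgs <- validPanelEntries(entries)
  if (length(msgs))
    stop("invalid panel:\n  ", paste(msgs, collapse = "\n  "))
  new("DiseasePanel", entries = entries, name = name, version = version,
      genomeBuild = genomeBuild)
}

#' @describeIn DiseasePanel accessor for the mutation-record table.
#' @param panel a \code{DiseasePanel}.
#' @export
panelEntries <- function(panel) {
  stopifnot(is(panel, "DiseasePanel"))
  panel@entries
}

#' @describeIn DiseasePanel accessor for panel name, version and build.
#' @export
panelMetadata <- function(panel) {
  stopifnot(is(panel, "DiseasePanel"))
  list(name = panel@name, version = panel@version,
       genomeBuild = panel@genomeBuild)
}

#' Write a panel back to disk
#'
#' Serializes losslessly so that \code{readPanel(writePanel(p))} returns an
#' identical panel.
#'
#' @param panel a \code{\link{DiseasePanel}}.
#' @param path output path.
#' @param format "tsv" or "json".
#' @return \code{path}, invisibly.
#' @export
writePanel <- function(panel, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- panel@entries[, PANEL_COLUMNS]
  if (format == "tsv") {
    out <- df
    out$rsid[is.na(out$rsid)] <- "-"
    out$pos[is.na(out$pos)] <- ""
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(name = panel@name, version = panel@version,
           genome_build = panel@genomeBuild, entries = df),
      path, auto_unbox = TRUE, na = "null", null = "null", digits = NA)
  }
  invisible(path)
}

#' Normalize a (pos, ref, alt) allele pair
#'
#' Produces the canonical minimal representation of a variant: shared
#' trailing and leading bases are trimmed, and -- when the surrounding
#' reference sequence is supplied -- indels are left-aligned by repeatedly
#' extending into the reference and re-trimming until a fixed point is
#' reached (the standard variant-normalization algorithm). The result keeps
#' the VCF convention of non-empty alleles (an anchor base precedes a pure
#' insertion or deletion). The operation is idempotent.
#'
#' @param pos 1-based position of the first base of \code{ref}.
#' @param ref,alt reference and alternate alleles (non-identical strings
#'   over A,C,G,T).
#' @param context optional reference sequence covering the variant;
#'   required for left-alignment across repeat runs.
#' @param contextStart 1-based coordinate of the first base of
#'   \code{context}; defaults to 1.
#' @return list with elements \code{pos}, \code{ref}, \code{alt}.
#' @examples
#' normalizeAllelePair(5, "TCGA", "TCA")          # right-trim + anchor
#' normalizeAllelePair(11, "AAG", "AG")           # shared-prefix trim
#' @export
normalizeAllelePair <- function(pos, ref, alt, context = NULL,
                                contextStart = 1L) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (identical(ref, alt))
    stop("ref and alt are identical ('", ref, "'): not a variant")
  if (!nzchar(ref) || !nzchar(alt))
    stop("ref and alt must be non-empty")
  ctx_at <- function(p) {
    i <- p - contextStart + 1L
    if (i < 1L || i > nchar(context))
      stop("reference context does not cover position ", p)
    substr(context, i, i)
  }
  if (!is.null(context)) {
    # consistency: ref must equal the context at [pos, pos + nchar(ref))
    i <- pos - contextStart + 1L
    if (i < 1L || i + nchar(ref) - 1L > nchar(context))
      stop("reference context does not cover the ref allele")
    if (substr(context, i, i + nchar(ref) - 1L) != ref)
      stop("ref allele '", ref, "' is inconsistent with the reference ",
           "context at position ", pos)
  }
  last <- function(x) substr(x, nchar(x), nchar(x))
  drop_last <- function(x) substr(x, 1L, nchar(x) - 1L)
  repeat {
    can_trim <- nzchar(ref) && nzchar(alt) && last(ref) == last(alt) &&
      (nchar(ref) > 1L || nchar(alt) > 1L)
    if (!can_trim) break
    would_empty <- nchar(ref) == 1L || nchar(alt) == 1L
    # left extension across a repeat run needs the reference sequence;
    # without it the trailing-anchored spelling is already minimal
    if (would_empty && is.null(context)) break
    ref <- drop_last(ref); alt <- drop_last(alt)
    if (!nzchar(ref) || !nzchar(alt)) {
      base <- ctx_at(pos - 1L)
      ref <- paste0(base, ref)
      alt <- paste0(base, alt)
      pos <- pos - 1L
    }
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Match an observed variant against the panel
#'
#' Locus match (chromosome, position, ref, alt -- assumed already
#' normalized with \code{\link{normalizeAllelePair}}) takes precedence;
#' an rsID match is the fallback when no locus match exists. Two panel
#' entries matching one variant is an error, never a silent pick.
#'
#' @param panel a \code{\link{DiseasePanel}}.
#' @param chrom,pos,ref,alt the observed variant locus (any may be NULL
#'   when only an rsID is known).
#' @param rsid optional dbSNP identifier.
#' @return the matching mutation record as a one-row data.frame, or NULL
#'   when nothing matches.
#' @examples
#' p <- readPanel(system.file("extdata", "mutation_panel_24.tsv",
#'                            package = "exomeCarrier"))
#' matchVariant(p, rsid = "rs77121243")$hgvs_c
#' @export
matchVariant <- function(panel, chrom = NULL, pos = NULL, ref = NULL,
                         alt = NULL, rsid = NULL) {
  stopifnot(is(panel, "DiseasePanel"))
  df <- panel@entries
  hit <- integer(0)
  if (!is.null(chrom) && !is.null(pos)) {
    hit <- which(!is.na(df$pos) & nzchar(df$chrom) &
                 df$chrom == as.character(chrom) &
                 df$pos == as.integer(pos) &
                 df$ref == toupper(ref) & df$alt == toupper(alt))
  }
  if (length(hit) == 0L && !is.null(rsid) && nzchar(rsid)) {
    hit <- which(!is.na(df$rsid) & df$rsid == rsid)
  }
  if (length(hit) == 0L) return(NULL)
  if (length(hit) > 1L)
    stop("ambiguous match: panel entries ",
         paste(df$mutation_key[hit], collapse = ", "),
         " all match the query variant")
  df[hit, , drop = FALSE]
}
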