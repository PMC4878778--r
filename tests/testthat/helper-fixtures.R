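# Shared builders for in-code fixtures: tiny panels, VCF text, oracles.

toyPanelDf <- function(n = 1L, chrom = "1", start_pos = 100L) {
  data.frame(
    disease_name = paste0("Toy disease ", seq_len(n)),
    omim_id = paste0("#", 100000 + seq_len(n)),
    gene_symbol = paste0("GENE", seq_len(n)),
    refseq_gene = paste0("NG_", seq_len(n)),
    mrna_id = paste0("NM_", seq_len(n)),
    hgvs_c = paste0("c.", seq_len(n), "A>T"),
    hgvs_p = paste0("p.Xaa", seq_len(n)),
    rsid = paste0("rs", 1000 + seq_len(n)),
    chrom = chrom,
    pos = start_pos + 10L * (seq_len(n) - 1L),
    ref = "A", alt = "T",
    stringsAsFactors = FALSE)
}

toyPanel <- function(n = 1L, ...) DiseasePanel(toyPanelDf(n, ...))

toyManifest <- function(samples, population = "POP1",
                        superpopulation = "SYN", cohort = "SIM") {
  data.frame(sample_id = samples, population = population,
             superpopulation = superpopulation, cohort = cohort,
             sex = "unknown", stringsAsFactors = FALSE)
}

# Write a minimal VCF: `records` is a data.frame with chrom, pos, id, ref,
# alt, info; `gt` a matrix (records x samples) of GT strings.
writeToyVcf <- function(path, records, gt, samples = colnames(gt),
                        extra_header = character(0)) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(records$chrom)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    extra_header,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(records)), function(i)
    paste(c(records$chrom[i], records$pos[i], records$id[i], records$ref[i],
            records$alt[i], ".", "PASS", records$info[i], "GT",
            gt[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}

# Independent tally of alt-allele counts from GT strings (brute force).
tallyGt <- function(gt_strings, alt_index = 1L) {
  alleles <- unlist(strsplit(gt_strings, "[/|]"))
  c(ac = sum(alleles == as.character(alt_index)),
    an = sum(alleles != "."))
}

# Brute-force oracle for allele normalization: enumerate every spelling of
# the variant consistent with the haplotype it induces on `context`
# (non-empty alleles, ref != alt), then pick the spelling with minimal
# total allele length, leftmost position on ties.
bruteNormalize <- function(pos, ref, alt, context) {
  L <- nchar(context)
  hap <- paste0(substr(context, 1, pos - 1), alt,
                substr(context, pos + nchar(ref), L))
  best <- NULL
  for (p in seq_len(L)) {
    for (rl in 0:(L - p + 1)) {
      r <- substr(context, p, p + rl - 1)
      al <- nchar(hap) - (L - rl)
      if (al < 1 || rl < 1) next
      a <- substr(hap, p, p + al - 1)
      cand_hap <- paste0(substr(context, 1, p - 1), a,
                         substr(context, p + rl, L))
      if (cand_hap != hap || r == a) next
      size <- rl + al
      if (is.null(best) || size < best$size ||
          (size == best$size && p < best$pos)) {
        best <- list(pos = p, ref = r, alt = a, size = size)
      }
    }
  }
  best[c("pos", "ref", "alt")]
}
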