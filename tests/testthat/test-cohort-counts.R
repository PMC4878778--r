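test_that("allele counting matches a hand tally with missing genotypes", {
  panel <- toyPanel(1)
  gt <- matrix(c("0/1", "0/0", "1/1", "0/1", "./."), nrow = 1,
               dimnames = list(NULL, paste0("S", 1:5)))
  rec <- data.frame(chrom = "1", pos = 100L, id = ".", ref = "A",
                    alt = "T", info = ".")
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  obs <- countAlleles(vcf, toyManifest(paste0("S", 1:5)), panel,
                      qc = qcConfig(minFractionSamplesCalled = 0))
  expect_equal(obs$ac, 4L)
  expect_equal(obs$an, 8L)
  # half-called genotype contributes its single called allele
  gt2 <- matrix(c("0/1", "./1", "0/0", "0|1", "./."), nrow = 1,
                dimnames = list(NULL, paste0("S", 1:5)))
  vcf2 <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt2)
  obs2 <- countAlleles(vcf2, toyManifest(paste0("S", 1:5)), panel,
                       qc = qcConfig(minFractionSamplesCalled = 0))
  expect_equal(obs2$ac, 3L)
  expect_equal(obs2$an, 7L)
})

test_that("counts from a synthetic cohort equal a brute-force VCF tally", {
  panel <- toyPanel(4)
  spec <- cohortSpec(
    populations = data.frame(
      code = c("POP1", "POP2"), superpopulation = "SYN", cohort = "SIM",
      n_individuals = c(40L, 25L)),
    truthAf = expand.grid(mutation_key = panelEntries(panel)$mutation_key,
                          population = c("POP1", "POP2"),
                          stringsAsFactors = FALSE) |>
      transform(af = c(0.1, 0.3, 0, 0.5, 0.2, 0.05, 0.4, 0)),
    sigma = 0.1, missingRate = 0.1, seed = 42)
  paths <- generateCohort(spec, panel, tempdir(), prefix = "oracle")
  obs <- countAlleles(paths$vcf, paths$manifest, panel,
                      qc = qcConfig(minFractionSamplesCalled = 0))
  # independent tally straight from the VCF text
  lines <- readLines(paths$vcf)
  hdr <- strsplit(grep("^#CHROM", lines, value = TRUE), "\t")[[1]]
  samples <- hdr[-(1:9)]
  manifest <- utils::read.delim(paths$manifest)
  body <- strsplit(grep("^#", lines, value = TRUE, invert = TRUE), "\t")
  for (row in body) {
    key <- matchVariant(panel, chrom = row[1], pos = as.integer(row[2]),
                        ref = row[4], alt = row[5])$mutation_key
    for (popn in unique(manifest$population)) {
      idx <- which(samples %in%
                     manifest$sample_id[manifest$population == popn])
      tally <- tallyGt(row[9 + idx])
      got <- obs[obs$mutation_key == key & obs$population == popn, ]
      expect_equal(got$ac, unname(tally["ac"]))
      expect_equal(got$an, unname(tally["an"]))
    }
  }
  # same counts via the direct (no-VCF) simulation path
  direct <- drawCohortCounts(spec, panel)
  m <- merge(as.data.frame(obs), as.data.frame(direct$observations),
             by = c("mutation_key", "population"))
  expect_equal(m$ac.x, m$ac.y)
  expect_equal(m$an.x, m$an.y)
})

test_that("an equals 2N without missingness and ac = 0 for reference-only
          cohorts", {
  panel <- toyPanel(2)
  spec <- cohortSpec(
    populations = data.frame(code = "POP1", superpopulation = "SYN",
                             cohort = "SIM", n_individuals = 35L),
    truthAf = data.frame(mutation_key = panelEntries(panel)$mutation_key,
                         population = "POP1", af = 0),
    seed = 3)
  paths <- generateCohort(spec, panel, tempdir(), prefix = "allref")
  obs <- countAlleles(paths$vcf, paths$manifest, panel)
  expect_equal(obs$ac, c(0L, 0L))
  expect_equal(obs$an, c(70L, 70L))
})

test_that("counting is invariant to record and sample order", {
  panel <- toyPanel(2)
  samples <- paste0("S", 1:6)
  gt <- matrix(c("0/1", "0/0", "1/1", "./.", "0/1", "0/0",
                 "0/0", "0/1", "0/1", "1/1", "./.", "0/0"),
               nrow = 2, byrow = TRUE, dimnames = list(NULL, samples))
  rec <- data.frame(chrom = "1", pos = c(100L, 110L), id = ".",
                    ref = "A", alt = "T", info = ".")
  mf <- toyManifest(samples)
  v1 <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  perm <- c(4, 2, 6, 1, 3, 5)
  v2 <- writeToyVcf(tempfile(fileext = ".vcf"), rec[2:1, ],
                    gt[2:1, perm], samples = samples[perm])
  qc <- qcConfig(minFractionSamplesCalled = 0)
  o1 <- as.data.frame(countAlleles(v1, mf, panel, qc = qc))
  o2 <- as.data.frame(countAlleles(v2, mf, panel, qc = qc))
  o1 <- o1[order(o1$mutation_key), ]; o2 <- o2[order(o2$mutation_key), ]
  expect_equal(o1$ac, o2$ac)
  expect_equal(o1$an, o2$an)
})

test_that("multi-allelic records are decomposed before matching", {
  panel <- toyPanel(1)  # expects 1:100 A>T
  gt <- matrix(c("0/1", "1/2", "2/2", "0/2", "0/0"), nrow = 1,
               dimnames = list(NULL, paste0("S", 1:5)))
  rec <- data.frame(chrom = "1", pos = 100L, id = ".", ref = "A",
                    alt = "G,T", info = ".")
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  obs <- countAlleles(vcf, toyManifest(paste0("S", 1:5)), panel,
                      qc = qcConfig(minFractionSamplesCalled = 0))
  # T is ALT index 2; its AC is 4; AN counts all called alleles
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$ac, 4L)
  expect_equal(obs$an, 10L)
})

test_that("QC filters exclude sites with logged reasons", {
  panel <- toyPanel(2)
  samples <- paste0("S", 1:5)
  gt <- matrix(c("0/1", "0/0", "0/1", "0/0", "0/0",
                 "0/1", "./.", "./.", "./.", "./."),
               nrow = 2, byrow = TRUE, dimnames = list(NULL, samples))
  rec <- data.frame(chrom = "1", pos = c(100L, 110L), id = ".",
                    ref = "A", alt = "T", info = c("DP=5", "DP=100"))
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  mf <- toyManifest(samples)
  obs <- countAlleles(vcf, mf, panel,
                      qc = qcConfig(minTotalDepth = 10,
                                    minFractionSamplesCalled = 0.8))
  expect_equal(nrow(obs), 0L)
  log <- S4Vectors::metadata(obs)$qc_log
  expect_setequal(log$reason, c("low_depth", "low_call_rate"))
  # with filters relaxed both sites are counted
  obs2 <- countAlleles(vcf, mf, panel,
                       qc = qcConfig(minTotalDepth = 0,
                                     minFractionSamplesCalled = 0))
  expect_equal(nrow(obs2), 2L)
})

test_that("unknown samples and contig dialects are handled explicitly", {
  panel <- toyPanel(1)
  gt <- matrix("0/1", nrow = 1, dimnames = list(NULL, "S1"))
  rec <- data.frame(chrom = "chr1", pos = 100L, id = ".", ref = "A",
                    alt = "T", info = ".")
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  qc <- qcConfig(minFractionSamplesCalled = 0)
  expect_error(countAlleles(vcf, toyManifest("OTHER"), panel, qc = qc),
               "absent from the manifest")
  # chr-prefixed VCF contig resolves against the unprefixed panel
  obs <- countAlleles(vcf, toyManifest("S1"), panel, qc = qc)
  expect_equal(obs$ac, 1L)
  # an unrelated contig naming scheme needs explicit aliasing
  rec2 <- rec; rec2$chrom <- "NC_000001.10"
  vcf2 <- writeToyVcf(tempfile(fileext = ".vcf"), rec2, gt)
  expect_error(countAlleles(vcf2, toyManifest("S1"), panel, qc = qc),
               "contigAliases")
  obs2 <- countAlleles(vcf2, toyManifest("S1"), panel, qc = qc,
                       contigAliases = c("NC_000001.10" = "1"))
  expect_equal(obs2$ac, 1L)
})

test_that("non-autosomal panel entries are rejected, not mis-counted", {
  bad <- toyPanelDf(1); bad$chrom <- "X"
  panel <- DiseasePanel(bad)
  gt <- matrix("0/1", nrow = 1, dimnames = list(NULL, "S1"))
  rec <- data.frame(chrom = "X", pos = 100L, id = ".", ref = "A",
                    alt = "T", info = ".")
  vcf <- writeToyVcf(tempfile(fileext = ".vcf"), rec, gt)
  expect_error(countAlleles(vcf, toyManifest("S1"), panel),
               "non-autosomal")
})

test_that("pooling conserves counts and bounds the pooled frequency", {
  sca <- SiteObservations(data.frame(
    mutation_key = "HBB:c.20A>T", population = c("AA", "AFR"),
    cohort = c("NHLBI", "1000G"), ac = c(177L, 45L), an = c(4402L, 492L)))
  pooled <- poolObservations(sca, population = "African")
  expect_equal(pooled$ac, 222L)
  expect_equal(pooled$an, 4894L)
  # identity on a single observation
  one <- poolObservations(sca[1, ], population = "AA")
  expect_equal(one$ac, sca$ac[1])
  expect_equal(one$an, sca$an[1])
  # mixed mutations refuse to pool
  mixed <- SiteObservations(data.frame(
    mutation_key = c("A:c.1A>T", "B:c.2A>T"), population = "P",
    cohort = "X", ac = c(1L, 2L), an = c(10L, 10L)))
  expect_error(poolObservations(mixed, population = "P"), "different")
  # property: conservation + pooled AF within component range
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    an <- sample(50:500, k, replace = TRUE)
    ac <- vapply(an, function(n) sample(0:n, 1), integer(1))
    obs <- SiteObservations(data.frame(
      mutation_key = "G:c.1A>T", population = paste0("P", seq_len(k)),
      cohort = "X", ac = ac, an = an))
    pl <- poolObservations(obs, population = "ALL")
    expect_equal(pl$ac, sum(ac))
    expect_equal(pl$an, sum(an))
    af <- pl$ac / pl$an
    expect_gte(af, min(ac / an))
    expect_lte(af, max(ac / an))
  }
})

test_that("printed AC/AN tables load with row-level validation", {
  exac <- exacObservations()
  afr <- exac[exac$mutation_key == "CLEC7A:c.714T>G" &
              exac$population == "African", ]
  expect_equal(afr$ac, 253L)
  expect_equal(afr$an, 10404L)
  t1 <- table1Observations()
  sca <- t1[t1$mutation_key == "HBB:c.20A>T" & t1$population == "ALL", ]
  expect_equal(sca$ac, 228L)
  expect_equal(sca$an, 15182L)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("mutation_key\tpopulation\tcohort\tac\tan",
               "A:c.1A>T\tP\tX\t5\t4"), bad)
  expect_error(readObservations(bad), "row")
})

test_that("manifest validation enforces unique samples and one
          superpopulation per population", {
  mf <- toyManifest(c("S1", "S1"))
  path <- tempfile(fileext = ".tsv")
  utils::write.table(mf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readManifest(path), "duplicate")
  mf2 <- toyManifest(c("S1", "S2"))
  mf2$superpopulation <- c("AFR", "EUR")
  utils::write.table(mf2, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(readManifest(path), "superpopulation")
})
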