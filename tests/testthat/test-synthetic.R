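synSpec <- function(panel, af, n = 50L, sigma = 0, missing = 0, seed = 1,
                    pops = "POP1") {
  cohortSpec(
    populations = data.frame(code = pops, superpopulation = "SYN",
                             cohort = "SIM", n_individuals = n),
    truthAf = expand.grid(mutation_key = panelEntries(panel)$mutation_key,
                          population = pops, stringsAsFactors = FALSE) |>
      transform(af = af),
    sigma = sigma, missingRate = missing, seed = seed)
}

test_that("generation is deterministic under a fixed seed", {
  panel <- toyPanel(3)
  spec <- synSpec(panel, af = 0.2, sigma = 0.1, missing = 0.05, seed = 99)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  p1 <- generateCohort(spec, panel, d1)
  p2 <- generateCohort(spec, panel, d2)
  expect_identical(readLines(p1$vcf), readLines(p2$vcf))
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  # direct tallies agree run to run as well
  expect_identical(as.data.frame(drawCohortCounts(spec, panel)$observations),
                   as.data.frame(drawCohortCounts(spec, panel)$observations))
  # a different seed produces different genotypes
  spec2 <- synSpec(panel, af = 0.2, sigma = 0.1, missing = 0.05, seed = 100)
  p3 <- generateCohort(spec2, panel, file.path(tempdir(), "det3"))
  expect_false(identical(readLines(p1$vcf), readLines(p3$vcf)))
})

test_that("monomorphic truth produces an all-reference cohort", {
  panel <- toyPanel(2)
  spec <- synSpec(panel, af = 0, n = 20L, seed = 5)
  counts <- drawCohortCounts(spec, panel)
  expect_true(all(counts$observations$ac == 0L))
  expect_true(all(counts$observations$an == 40L))
})

test_that("sampled frequencies track the truth within binomial error", {
  panel <- toyPanel(1)
  n <- 400L
  spec <- synSpec(panel, af = 0.5, n = n, seed = 17)
  counts <- drawCohortCounts(spec, panel)
  af_hat <- counts$observations$ac / counts$observations$an
  expect_lt(abs(af_hat - 0.5), 3 * sqrt(0.25 / (2 * n)))
})

test_that("allele dropout biases recovered frequencies by 1 - sigma", {
  panel <- toyPanel(10)
  af <- 0.2; sigma <- 0.3
  acs <- ans <- 0
  for (seed in 1:10) {
    spec <- synSpec(panel, af = af, n = 200L, sigma = sigma, seed = seed)
    counts <- drawCohortCounts(spec, panel)
    acs <- acs + sum(counts$observations$ac)
    ans <- ans + sum(counts$observations$an)
  }
  # 100 site replicates: recovered af ~ (1 - sigma) * af
  expect_equal(acs / ans, (1 - sigma) * af, tolerance = 0.03)
})

test_that("missingness shrinks AN and the truth record keeps pre-error
          genotypes", {
  panel <- toyPanel(2)
  spec <- synSpec(panel, af = 0.3, n = 100L, missing = 0.25, seed = 23)
  paths <- generateCohort(spec, panel, file.path(tempdir(), "miss"))
  truth <- jsonlite::fromJSON(paths$truth)
  expect_equal(truth$sigma, 0)
  expect_equal(truth$missingRate, 0.25)
  g <- truth$true_genotypes$POP1
  expect_equal(dim(g), c(2L, 100L))
  expect_true(all(g %in% 0:2))
  obs <- countAlleles(paths$vcf, paths$manifest, panel,
                      qc = qcConfig(minFractionSamplesCalled = 0))
  expect_true(all(obs$an < 200L))
  expect_true(all(obs$an > 100L))  # 25% missing leaves most genotypes
  # with no dropout the truth matrix tallies to the VCF counts exactly,
  # restricted to non-missing genotypes
  direct <- drawCohortCounts(spec, panel)
  expect_equal(obs$ac[order(obs$mutation_key)],
               direct$observations$ac[order(direct$observations$mutation_key)])
})

test_that("cohort-level detection frequency matches the closed-form power", {
  panel <- toyPanel(1)
  af <- 0.02; n <- 30L
  detected <- vapply(1:300, function(seed) {
    counts <- drawCohortCounts(synSpec(panel, af = af, n = n, seed = seed),
                               panel)
    counts$observations$ac > 0L
  }, logical(1))
  p_carrier <- 1 - (1 - af)^2   # per-individual carrier probability
  D <- detectionRate(p_carrier, 0, n)
  se <- sqrt(D * (1 - D) / length(detected))
  expect_lt(abs(mean(detected) - D), 3 * se)
})

test_that("specs are validated against the panel and parameter ranges", {
  panel <- toyPanel(1)
  spec <- cohortSpec(
    populations = data.frame(code = "POP1", superpopulation = "SYN",
                             cohort = "SIM", n_individuals = 10L),
    truthAf = data.frame(mutation_key = "NOPE:c.9A>T",
                         population = "POP1", af = 0.1))
  expect_error(drawCohortCounts(spec, panel), "absent from the panel")
  expect_error(cohortSpec(
    populations = data.frame(code = "POP1", superpopulation = "SYN",
                             cohort = "SIM", n_individuals = 10L),
    truthAf = data.frame(mutation_key = "G:c.1A>T", population = "POP1",
                         af = 1.2)), "\\[0,1\\]")
  # VCF generation demands explicit loci
  nolocus <- toyPanelDf(1); nolocus$chrom <- ""; nolocus$pos <- NA
  p2 <- DiseasePanel(nolocus)
  spec2 <- synSpec(p2, af = 0.1, n = 5L)
  expect_error(generateCohort(spec2, p2, tempdir()), "locus")
})
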