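test_that("the pooled z-test agrees with the classical proportion test", {
  set.seed(21)
  for (i in 1:30) {
    an1 <- sample(50:5000, 1); an2 <- sample(50:5000, 1)
    ac1 <- rbinom(1, an1, 0.05); ac2 <- rbinom(1, an2, 0.05)
    if (ac1 + ac2 == 0) next
    t_un <- twoProportionTest(ac1, an1, ac2, an2, continuity = FALSE)
    ct <- suppressWarnings(stats::prop.test(c(ac1, ac2), c(an1, an2),
                                            correct = FALSE))
    expect_equal(t_un@z^2, unname(ct$statistic), tolerance = 1e-9)
    expect_equal(t_un@pValue, ct$p.value, tolerance = 1e-9)
    t_cc <- twoProportionTest(ac1, an1, ac2, an2, continuity = TRUE)
    cc <- suppressWarnings(stats::prop.test(c(ac1, ac2), c(an1, an2),
                                            correct = TRUE))
    expect_equal(t_cc@pValue, cc$p.value, tolerance = 1e-9)
  }
})

test_that("z-test reproduces the cohort comparisons and their boundary
          behavior", {
  # the significant African sickle-cell discrepancy between cohorts
  sca <- twoProportionTest(177, 4402, 45, 492, continuity = FALSE)
  expect_equal(abs(sca@z), 5.18, tolerance = 0.005)
  expect_lt(sca@pValue, 1e-6)
  # a non-significant African comparison
  ns <- twoProportionTest(116, 4406, 7, 492, continuity = FALSE)
  expect_equal(ns@pValue, 0.10, tolerance = 0.05)
  expect_gt(ns@pValue, 0.05)
  # identical proportions
  eq <- twoProportionTest(5, 100, 5, 100, continuity = FALSE)
  expect_equal(eq@z, 0)
  expect_equal(eq@pValue, 1)
  # antisymmetry
  a <- twoProportionTest(30, 400, 10, 300, continuity = FALSE)
  b <- twoProportionTest(10, 300, 30, 400, continuity = FALSE)
  expect_equal(a@z, -b@z)
  expect_equal(a@pValue, b@pValue)
  # degenerate 0-vs-0 never crashes, with or without correction
  for (cc in c(TRUE, FALSE)) {
    d <- twoProportionTest(0, 100, 0, 200, continuity = cc)
    expect_true(d@degenerate)
    expect_equal(d@pValue, 1)
  }
  expect_error(twoProportionTest(1, 0, 1, 10), "positive")
})

test_that("goodness-of-fit test reproduces the published prevalence
          p-values", {
  # each (ac, an, literature af) -> printed p-value
  rows <- list(
    list(23, 176, 0.171, 0.155),
    list(0, 178, 0.009, 0.204),
    list(1, 120, 0.008, 0.967),
    list(0, 196, 0.005, 0.321),
    list(0, 132, 0.007, 0.335),
    list(0, 28, 0.007, 0.657),
    list(3, 110, 0.004, 0.0001))
  for (r in rows) {
    g <- gofTest(r[[1]], r[[2]], r[[3]])
    expect_equal(signif(g@pValue, 3), r[[4]], tolerance = 0.005)
    # independent cross-check against the generic chi-square machinery
    ct <- suppressWarnings(stats::chisq.test(
      c(r[[1]], r[[2]] - r[[1]]), p = c(r[[3]], 1 - r[[3]])))
    expect_equal(g@chi2, unname(ct$statistic), tolerance = 1e-9)
  }
})

test_that("goodness-of-fit handles degenerate references and is monotone", {
  exact <- gofTest(0, 178, 0)
  expect_true(exact@exactAgreement)
  expect_equal(exact@pValue, 1)
  expect_warning(inf <- gofTest(3, 110, 0), "infinite")
  expect_equal(inf@pValue, 0)
  expect_error(gofTest(5, 100, 1), "expectedAf")
  # p decreases as the observed count moves away from expectation
  ps <- vapply(0:20, function(ac) gofTest(ac, 200, 0.02)@pValue,
               numeric(1))
  e <- 0.02 * 200
  dev <- abs(0:20 - e)
  ord <- order(dev)
  expect_true(all(diff(ps[ord]) <= 1e-12))
})

test_that("batch concordance pairs cohorts per ancestry and labels
          degenerates", {
  t1 <- table1Observations()
  nhlbi <- t1[t1$cohort == "NHLBI", ]
  g1000 <- t1[t1$cohort == "1000G", ]
  pairs <- data.frame(pop1 = c("AA", "EA"), pop2 = c("AFR", "EUR"))
  rep <- batchConcordance(nhlbi, g1000, pairs, continuity = FALSE)
  expect_equal(nrow(rep@results), 48L)
  expect_equal(nrow(rep@skipped), 0L)
  sca <- rep@results[rep@results$mutation_key == "HBB:c.20A>T" &
                     rep@results$pop1 == "AA", ]
  expect_true(sca$significant)
  expect_false(any(rep@results$degenerate & rep@results$significant))
  # two identical cohorts disagree nowhere
  same <- batchConcordance(nhlbi, nhlbi,
                           data.frame(pop1 = c("AA", "EA"),
                                      pop2 = c("AA", "EA")))
  expect_equal(sum(same@results$significant), 0L)
  # unpaired mutations are listed as skipped, never dropped
  rep2 <- batchConcordance(nhlbi[nhlbi$mutation_key != "HBB:c.20A>T", ],
                           g1000, pairs, continuity = FALSE)
  expect_equal(nrow(rep2@results), 46L)
  expect_equal(nrow(rep2@skipped), 2L)
  expect_true(all(rep2@skipped$mutation_key == "HBB:c.20A>T"))
})

test_that("prevalence concordance reports p-value intervals and exact
          agreement", {
  t1 <- table1Observations()
  sca <- t1[t1$mutation_key == "HBB:c.20A>T" & t1$cohort != "POOLED", ]
  ref <- scaPrevalenceReference()
  out <- prevalenceConcordance(sca, ref)
  yri <- out[out$population == "YRI", ]
  expect_equal(signif(yri$p_low, 3), 0.155)
  # literature range gives an ordered p interval
  aa <- out[out$population == "AA", ]
  expect_lte(aa$p_low, aa$p_high)
  # zero observed vs zero expected is exact agreement (reported NA)
  asn <- out[out$population %in% c("CHB", "CHS", "JPT", "FIN"), ]
  expect_true(all(asn$exact_agreement))
  expect_true(all(is.na(asn$p_low)))
})
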