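---
title: "Carrier-rate epidemiology from population exomes: models and methods"
author: "exomeCarrier maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier-rate epidemiology from population exomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeCarrier)
```

## The problem

Reliable epidemiological figures for rare recessive disorders are scarce:
clinical registries cover few countries, and case ascertainment varies
widely. Population exome resources offer an alternative route. If the
causative mutations of a disorder are known, the alternate-allele counts at
those sites in a population cohort estimate how common carriers are in each
population — without any patient registry. `exomeCarrier` implements that
pipeline: a curated mutation panel, per-population allele counting from
cohort VCFs, carrier-rate estimation, statistical concordance checks, and a
power model for how large a cohort must be before a mutation of given
frequency becomes visible at all.

## The carrier-rate model

At a biallelic site with causal-allele frequency $p$ and wild-type
frequency $q = 1 - p$, Hardy–Weinberg equilibrium gives genotype
frequencies $p^2$, $2pq$, $q^2$. The screening-relevant quantity

$$p^2 + 2pq \times 0.5 \;=\; p^2 + pq \;=\; p$$

is simply the allele frequency: each allele carried contributes one half of
a potential homozygous offspring. The package therefore reports the
**carrier rate as the allele frequency** $\widehat{p} = AC/AN$, where $AC$
is the alternate-allele count and $AN$ the number of called alleles at the
site. This is an approximation that holds in the rare-allele regime; the
`hwe_valid` flag marks estimates with $\widehat{p} \ge 0.05$ (implied
disease prevalence $\ge 0.25\%$) where it degrades. The textbook
heterozygote frequency $2p(1-p)$ is exposed alongside as `het_frequency`
so users can apply either convention; the two agree as $p \to 0$.

Denominators follow the aggregation-database convention: $AN$ counts
*called* alleles, so it varies site by site with missingness and is
generally below twice the number of enrolled individuals. Reported
summaries include the reciprocal "1 in $N$" ($1/\widehat{p}$, `Inf` for
zero counts) because that is how screening burden is communicated
clinically.

Disease-level burden (`diseaseBurden`) sums per-mutation allele
frequencies. That assumes causal alleles are rare and independent (no
compound-carrier double counting), so the output carries an explicit
`approximate` flag. Screening ranks (`rankMutations`) order mutations by
descending frequency, grouping ties at three significant figures — the
precision at which screening panels quote frequencies; two counts such as
1/8586 and 1/8600 are operationally the same carrier rate even though they
differ in the tenth decimal.

## Panel matching and allele normalization

Panel records identify mutations by dbSNP rsID and/or an explicit genomic
locus. Locus matching takes precedence; rsID is a fallback (dbSNP merges
drift over time, so a conflict between a record's rsID and locus is
resolved in favor of the locus). Because published panels mix HGVS-style
indels with VCF loci, both sides of a match are normalized first: shared
leading/trailing bases are trimmed and, when reference sequence is
available, indels are left-aligned across repeat runs to a canonical
minimal spelling (the standard variant-normalization fixed point, verified
in tests against a brute-force enumeration of equivalent spellings). Two
panel entries matching one observed variant is always an error, never a
silent pick.

The genome build is carried as opaque metadata; no liftover is attempted.
Non-autosomal panel entries are rejected outright, since the
carrier model assumes autosomal diploid genotypes.

## Quality control

Site-level filters mirror the four dimensions exome pipelines typically
apply: total read depth, fraction of samples with a called genotype,
alternate-read fraction in heterozygotes, and mean position of alternate
alleles along the read. Published analyses rarely state their cutoffs, so
the defaults here are deliberately conventional and fully configurable:

| filter | field | default |
|---|---|---|
| minimum total depth | `INFO/DP` | 10 |
| minimum fraction of samples called | `FORMAT/GT` | 0.8 |
| mean het alternate-read fraction | `FORMAT/AD` | 0.25–0.75 |
| mean read position of alt alleles | `INFO/MPOS` | disabled |

Each filter applies only when its field is present in the VCF (site-level
VCFs usually lack per-read position data, hence that filter is off by
default). A failed site is excluded entirely and logged with its reason;
nothing is silently dropped.

## Concordance tests

Two cohorts are compared per mutation and ancestry with the pooled
two-proportion z-test

$$Z = \frac{\hat p_1 - \hat p_2}
     {\sqrt{\hat p(1-\hat p)\left(\tfrac{1}{n_1}+\tfrac{1}{n_2}\right)}},
\qquad \hat p = \frac{ac_1 + ac_2}{an_1 + an_2},$$

two-sided against the standard normal. Both the Yates-corrected and
uncorrected variants are implemented: the corrected form is the default
for cohort comparisons, while the uncorrected form satisfies the algebraic
identity $Z^2 = \chi^2_{2\times 2}$ (checked numerically to $10^{-9}$) and
is what reproduces published comparison statistics. When both counts are
zero the pooled variance vanishes; such comparisons are flagged degenerate
(p = 1), not counted as significant, and never crash batch runs.

Observed rates are compared against external clinical prevalence with a
one-sample goodness-of-fit chi-square (1 df, expected count
$e = AF_{ref} \cdot AN$), **without** continuity correction — validation
against the published prevalence table showed that the uncorrected
statistic reproduces its printed p-values exactly at printed precision
(0.155, 0.204, 0.967, 0.321, 0.335, 0.657, 0.0001 across seven
populations), while the corrected one does not. One published value
(0.000346 for the Kenyan population) is not reproduced by the construction
that matches every other row — the same construction gives
$1.3\times10^{-5}$ — and is treated as a probable inconsistency in the
source rather than something to fit. Literature frequencies given as
ranges are evaluated at both endpoints, yielding a p-value interval; a
zero observed count against a zero reference frequency is exact agreement,
reported as NA. The significance level defaults to 0.05 with no
multiple-testing adjustment (a Bonferroni option exists but is off by
default, matching how such comparisons are conventionally reported).

## Detection power

The probability that a cohort of $N$ individuals reveals at least one
carrier of a mutation with per-individual carrier rate $p$, when each
observation is missed with probability $\sigma$, is

$$D = 1 - \{1 - p(1-\sigma)\}^N.$$

$N$ counts **individuals**, not haploid exomes: the model's own worked
value — 99.95% detection at $p = 0.001$, $\sigma = 0.01$ — is obtained at
$N = 7{,}595$ individuals (using haploid-exome counts would give
99.99997%). All evaluation is in log space (`log1p`/`expm1`): the
undetected probability at consortium scale ($N = 60{,}706$) is of order
$10^{-27}$, far below double-precision resolution of $1 - D$. The
`requiredN` inverse is exact — $D(n) \ge$ target $> D(n-1)$ — which means
inverting a *rounded* published percentage can need slightly more samples
than the cohort that produced it ($D(7595) = 0.999459$ rounds to 99.95%,
but the exact target 0.9995 needs 7,674).

$\sigma$ is a single per-observation false-negative probability; the
underlying data give no basis for a richer error model (e.g. genotype-
dependent dropout), so none is offered. A Monte-Carlo twin
(`monteCarloDetection`) simulates the same process and agrees with the
closed form within three binomial standard errors in the test suite; it
exists to validate, not replace, the formula.

## The synthetic-cohort generator

`generateCohort` emulates exactly the statistical structure the analysis
assumes, so every pipeline stage is testable without downloads:

* genotypes per individual drawn as alternate-allele count
  $\sim \mathrm{Binomial}(2, af)$ — individual-level Hardy–Weinberg
  sampling, so heterozygote/homozygote structure exists for QC testing;
* each true alternate allele independently dropped to reference with
  probability $\sigma$ (false negatives only, matching the power model;
  false-positive calls are outside the model);
* genotypes set missing with a per-genotype probability, which is what
  makes $AN$ vary per site as in real aggregation tables;
* one master seed, with per-(population, site) substreams derived
  deterministically, so any subset of a cohort regenerates byte-identically.

What it does **not** emulate: linkage disequilibrium, consanguinity or
other inbreeding structure, batch effects between sequencing centers, and
site-specific coverage variation. Passing tests on synthetic cohorts
therefore demonstrate the counting and estimation machinery, not
robustness to those real-data complications.

Default study conditions in the test suite follow the real cohorts'
scale where that is affordable (hundreds of individuals per population,
rare-allele frequencies around $10^{-2}$ to $10^{-3}$), and problem sizes
are chosen so the full suite runs in well under a minute of simulation:
parameter recovery uses 500 replicate sites of 200 individuals, type-I
calibration 1,000 replicate cohort pairs of 500 individuals at allele
frequency 0.05 (large enough that the normal approximation behind the
z-test is exact territory), and Monte-Carlo power checks 10,000
replicates.

## Numerical and design choices

* **Carrier rate = allele frequency** is the operational convention
  throughout, because it is what per-population carrier tables print; the
  heterozygote frequency is a separate column, never silently substituted.
* Display rounding (frequencies to 3 significant figures, "1 in N" to one
  decimal) lives only in `carrierTable`; stored values keep full
  precision.
* Pooling is exact integer addition of AC and AN; the pooled frequency is
  the count-weighted mean and provably lies within the component range.
* The published table transcribed as the bundled fixture has two internal
  inconsistencies, kept as printed and documented in `?table1Observations`
  rather than corrected.
* The bundled panel carries rsIDs only (its source prints no genomic
  coordinates); the single entry whose dbSNP cell is empty carries a
  synthetic placeholder locus, clearly labelled as such.
* Degenerate inputs (zero denominators, zero-vs-zero comparisons,
  unattainable power targets) return flagged results or informative
  errors; no statistic is ever produced by division that can overflow or
  crash.

## Limitations

The package estimates carrier rates among *sequenced, reportedly healthy*
cohort members; ascertainment of cohorts from disease-specific studies,
penetrance differences, prenatal screening effects and consanguinity all
shift true population burden in ways the model does not capture. Dominant
disorders are out of scope: cohorts of unaffected adults are depleted for
dominant causal alleles, so their frequencies do not estimate carrier
burden. Panel curation itself — deciding which mutations are causal — is
an input, not something the package re-derives.
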