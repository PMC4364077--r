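---
title: "Combinatorial conflicting homozygosity: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combinatorial conflicting homozygosity: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cch)
```

## The problem and the principle

Mapping a dominant trait in an extended family conventionally requires
haplotype reconstruction and parametric linkage analysis, which is
computationally heavy for large pedigrees and loses power when some
affected individuals are phenocopies — they share the phenotype but not
the causal variant, so the true locus fails to co-segregate in the full
affected set.

Conflicting homozygosity (CH) turns the problem into an exclusion test
that needs no haplotypes and no pedigree. At a biallelic SNP, two
individuals homozygous for opposite alleles (AA and BB; identical by
state for zero alleles, IBS0) cannot both carry a shared haplotype
spanning that marker. For a set of individuals, a marker shows CH when
both homozygote classes occur among their non-missing genotypes. Short
stretches free of CH arise constantly by chance, but the probability of a
long CH-free stretch without identity by descent (IBD) decays
geometrically with its marker count, so runs beyond a genetic-length
threshold are strong evidence that at least one haplotype is shared IBD
by the whole set. Missing genotypes conflict with nothing: they can only
lengthen runs, which is conservative in the direction of calling IBD,
and the same holds for linkage disequilibrium and for low marker
diversity.

The combinatorial layer handles phenocopies: if only an unknown subset of
the n affected individuals carries the variant, the scan is repeated for
every subset of size k, descending from k = n until loci appear. The
subset(s) sharing a locus identify exactly which individuals carry the
variant there — information linkage analysis does not provide directly.

## Runs, thresholds and the single-error tolerance

`find_runs()` computes the CH track per chromosome, takes maximal
CH-free stretches as raw runs, and reports runs that span at least
`min_cm` centimorgans **and** contain at least `min_snps` markers. The
defaults, 4 cM and 100 SNPs, belong together: they assume an array of
roughly 100 SNPs per cM, at which density the SNP floor stops sparse
marker coverage from masquerading as long CH-free regions. If your data
are much sparser, scale `min_snps` accordingly or expect degraded
calibration (see below).

A single genotyping error inside a genuine IBD region manufactures one
spurious CH marker and would split an otherwise qualifying run, so an
isolated CH marker — one flanked by CH-free markers on both sides — that
directly separates two runs is ignored whenever the merged span reaches
`min_cm`. Two consecutive CH markers always terminate a run. Merging is
applied deterministically left to right and may repeat, so one run can
absorb several isolated CH markers; each run reports how many were
tolerated (`tolerated_ch_count`). The run length of a single-marker run
is 0 cM, so such runs can never qualify.

Two consequences of iterated merging are worth knowing. First, it is
exactly what rescues IBD runs hit by several scattered errors (at an
error rate of 0.002 a 4 cM window of a dozen individuals expects more
than one). Second, once a run exceeds `min_cm` it will absorb *any*
isolated CH marker at its edge, so with error-free genotypes the rule
only extends runs past their true boundaries; the gene-dropping
evaluation below therefore disables it, and at marker densities far
below ~100 SNPs/cM it can chain through ordinary chance runs — another
reason the thresholds and density belong together.

## The exhaustive subset scan

`cch_scan()` runs the genome scan for every k-subset of the group,
descending from `k_max` to `k_min`. The number of analyses, nCk =
n!/(k!(n−k)!), is recorded because it is the Bonferroni denominator:
`count_subsets(17, 11)` = 12,376 analyses for the level k = 11 of a
17-member group. Each analysis is a pure function of its inputs;
`enumerate_subsets()` splits the lexicographic enumeration into
contiguous blocks whose sizes differ by at most one, so work can be
chunked across processes or cluster jobs (`--chunk i/N`) and results
merged by concatenation. The hot loop — OR-ing bit-packed homozygote
planes and extracting runs — is compiled, which keeps an exhaustive scan
of 10^5 subsets over tens of thousands of markers in the minutes range
on one core.

`aggregate_max_k()` reduces the retained runs to the per-marker maximum
number of individuals sharing a haplotype ("max-k profile"), the
genome-wide summary a scan is usually read from.

## The exponential null and significance

Among unrelated individuals, CH-free run lengths in cM are
well-described by an exponential distribution: the CH track is close to
independent Bernoulli per marker, so run lengths in markers are
geometric, and a geometric sum of near-exponential marker spacings is
exponential. `fit_exponential()` estimates the rate by maximum
likelihood (1/mean) after dropping runs below a SNP floor (default 20
SNPs; single-marker runs have length 0 by construction and would distort
the fit), and reports a quantile-quantile correlation as a
goodness-of-fit summary. A left-truncated variant
(`truncate_at`) is available for sensitivity analysis.

`run_pvalue()` gives the tail probability exp(−rate × length) that a run
at least this long arises without recent shared ancestry, Bonferroni
corrected by the number of genome-wide subset analyses performed — not
by the number of runs, because the unit of testing is the analysis. The
p-value attaches to IBD inheritance of the locus by those individuals,
not to causation of any trait: a locus can be IBD in a subset and
irrelevant to the phenotype.

The phenocopy side of the example workflow is plain binomial arithmetic:
`binom_expected(48, 0.16)` = 7.7 expected phenotype-positive relatives
among 48 at a 16% population prevalence, and
`min_prevalence_exceeding(48, 5, 0.05)` = 0.056 — above a 5.6%
prevalence, observing more than 5 affected among 48 is unsurprising at
the 0.05 level. The grid resolution (0.1%) matches the reporting
precision of such prevalence figures; note the search can always
terminate, since the tail reaches 1 as prevalence approaches 1.

## What the simulator emulates

`simulate_unrelated()` draws per-marker minor-allele frequencies from
Uniform(0.05, 0.5) — mirroring routine QC that removes rarer markers —
and genotypes under Hardy–Weinberg equilibrium with independent markers.
No linkage disequilibrium is modelled: LD only lengthens chance CH-free
runs, so a no-LD null is conservative for calibrating the run-length
threshold; with real array data the same thresholds are, if anything,
slightly anti-conservative and the 100-SNP floor is what absorbs that
gap. Maps from `make_map()` place markers uniformly at a target density
(defaulting to the ~100 SNPs/cM regime with bp at 1 Mb/cM).

`gene_drop()` provides exact IBD ground truth: founder haplotypes carry
globally unique labels, each meiosis recombines under the Haldane model
(crossover count Poisson with mean cM-length/100, uniform positions, no
interference — the standard gene-dropping model, fully specified by the
cM map), and the truth track records both labels of every individual at
every marker. `truth_max_k()` counts, per marker, the largest number of
members carrying the same founder label; by construction, members
sharing a label can never show CH among themselves — an exact invariant
the test suite asserts marker by marker.

`default_pedigree()` is a four-generation family with 17 genotyped
affected members (twelve first cousins and five of their children)
connected through ungenotyped relatives. The published structure of such
families is rarely fully recoverable, so this pedigree is a synthetic
stand-in chosen for its sharing regime rather than a reproduction:
top-founder haplotypes are carried with probability 1/4 or 1/8 per
member, so segments shared IBD by seven or more members arise
intermittently with cM-scale lengths, rather than saturating the genome
(a shallower, sibship-heavy design was rejected because it left
essentially every marker in a ≥7-sharing segment, which no real mapping
family resembles).

## Evaluation design

The sensitivity/specificity experiment gene-drops the default pedigree
over 5 chromosomes × 100 cM at 100 SNPs/cM (50,000 markers), scans all
subsets of size 7–17 at the 4 cM / 100 SNP threshold, and scores the
detected max-k profile against truth at k = 7 across 50 replicates;
problem sizes were chosen so the whole experiment runs in minutes on one
core while each replicate still contains several multi-cM truth
segments. Three choices deserve explicit statement:

* **Tolerance off.** Gene-dropped genotypes carry no genotyping errors,
  and the single-error tolerance exists solely to absorb them; with
  error-free inputs iterated merging only drags run boundaries past the
  truth, inflating false calls at segment edges. The error-injection
  path (`inject_errors()`) is exercised separately, where tolerance
  demonstrably rescues fragmented runs.
* **Thresholded truth.** Detection is, by construction, blind to
  sharing segments shorter than the cM threshold, so the truth profile
  is first reduced to its threshold-detectable form
  (`truth_detectable_max_k()`): per level, only stretches spanning at
  least `min_cm` count. Scoring raw truth would penalise the method for
  sub-threshold fluctuations no run-based detector could resolve.
* **Level matching.** Sensitivity asks whether a marker inside a true
  ≥k segment is identified as shared at level k
  (`score_detection(match = "level")`), matching an analysis of
  "regions inherited IBD by k or more individuals". The strict variant
  (`match = "exact"`, the default) additionally requires the detected
  maximum to equal the true maximum at every marker and is reported
  alongside; it is systematically harder wherever nested sub-segments
  change the truth level by ±1. Specificity is strict in either case: a
  called marker counts only if the truth supports at least the detected
  level.

Passing this experiment shows the combinatorial machinery, the
thresholds and the truth tracking are mutually consistent under the
simulator's assumptions (no LD, uniform marker spacing, Haldane
recombination, random mating). It does not by itself demonstrate
performance on real arrays, where LD, allele-frequency structure and
genotyping error are present — the null-calibration experiment and the
error-injection tests cover those mechanisms separately, and real-data
behaviour ultimately depends on the array's density matching the
threshold pair.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive bp internally; BED export converts
  to 0-based half-open. Genetic positions are interpolated linearly from
  anchor maps, extrapolated at a fallback rate (default 1 cM/Mb) beyond
  terminal anchors, clamped non-negative and made non-decreasing.
* Duplicate bp positions on a chromosome keep the first marker; sex
  chromosomes are excluded by default (hemizygous males would fabricate
  homozygosity), with an opt-in for X.
* Allele coding is per-marker first-observed; CH depends only on "both
  homozygote classes present", so coding cannot affect results (tested
  by recoding). Binomial coefficients use the exact multiplicative
  scheme (exact below 2^53, with a warning beyond).
* Empty subsets are errors; subsets of one cannot show CH and are
  rejected; a run comparison with an empty denominator reports NA, never
  0.
* All randomness flows through explicit seeds; every simulation
  function restores the caller's RNG state.

## Known limitations

* The method detects sharing of *at least one* haplotype; it cannot
  distinguish which haplotype, nor phase, nor recessive architectures
  (opposite-homozygote exclusion is the wrong primitive there).
* Thresholds are array-density dependent; the defaults assume ~100
  SNPs/cM and should be rescaled for sparser panels.
* The exhaustive scan is practical up to roughly 10^7–10^8 subset
  analyses; beyond that, power also degrades through the Bonferroni
  denominator. `analysis_budget` warns rather than forbids.
* The built-in pedigree is a synthetic approximation used for
  evaluation, not a reproduction of any published family.
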