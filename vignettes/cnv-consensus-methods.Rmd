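---
title: "Methods: multi-algorithm CNV consensus, enrichment, trait association and qPCR validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-algorithm CNV consensus, enrichment, trait association and qPCR validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicnv)
```

## The problem

Copy-number variants (CNVs) called from SNP-array intensity data are
notoriously algorithm-dependent: hidden-Markov-model callers such as PennCNV
and QuantiSNP and segmentation tools such as CNVPartition produce call sets
that differ several-fold in yield on the same arrays, with very different
false-negative profiles. A standard defence is to run several callers and
analyse their intersection. `equicnv` implements that comparative workflow
for a breed-structured horse cohort genotyped on a ~50k equine SNP chip:
per-sample and per-call quality control, merging of calls into CNV regions
(CNVRs), a three-level multi-caller consensus, per-chromosome enrichment,
breed-sharing summaries, association of CNV genotypes with withers height,
and copy-number validation from qPCR Ct values.

All user-facing functions take plain data frames (tibbles) and return
tibbles, so each stage can be inspected, piped, and written to TSV.

## Coordinates and interval algebra

Internal coordinates are 1-based inclusive with `size = end - start + 1`,
the Illumina/PennCNV convention; a published consensus interval of
155,487,276–155,656,642 bp spans 169,367 bp under this rule, which is the
reported median CNV size, so the convention is self-consistent with the
numbers the workflow is meant to reproduce. BED import/export converts
to and from 0-based half-open coordinates at the file boundary only.

Two calls hit the same locus under an `overlap_spec()`: `"any"` (at least
1 bp shared; adjacency is not overlap) or `"reciprocal"` (shared bp at
least a fraction *f* of **each** interval). Any-overlap is the default
because the source workflow states no reciprocal fraction; reciprocal mode
exists because external-list comparisons are sensitive to it. A CNVR is a
connected component of the overlap graph (transitive closure), and its
envelope is the union of its members; components are found by a sorted
sweep for any-overlap and by union–find over sweep candidates for
reciprocal mode. The test suite checks both against brute-force per-base
set arithmetic on random instances with coordinates below 10,000.

One caveat discovered while testing: tightening the overlap specification
does **not** monotonically reduce consensus locus counts. A tighter spec
splits components, and both halves of a split component can retain
three-caller support. Monotonicity does hold for per-pair overlap
decisions, and that is what the property tests assert.

## Quality control

Defaults follow common SNP-array practice: samples are kept only when the
call rate is strictly above 0.90 and SD(LRR) ≤ 0.3 and |GCWF| ≤ 0.02;
calls need ≥ 3 probes; QuantiSNP calls additionally need a Log Bayes
Factor ≥ 10 and CNVPartition calls a confidence ≥ 35. Comparisons are
boundary-inclusive for keeping (a call *at* the threshold survives),
matching the usual phrasing of these rules ("less than three were
omitted"). Missing per-sample metrics skip that rule for that sample and
are logged, because merged caller exports often lack them. Records with
copy number 2 are dropped with a counter rather than an error for the same
reason. The SD(LRR)/GCWF exclusions are applied globally (to all callers'
samples), the simpler of the two readings of the source workflow.

## Three-level consensus

A locus (overlap-graph component across all callers' calls) is a consensus
CNV when every caller supports it:

* **population** — each caller has ≥ 1 call at the locus in any sample;
* **breed** — some single breed contains supporting calls from all
  callers;
* **individual** — some single animal was called by all callers.

Distinct consensus loci are nested across levels (individual ⊆ breed ⊆
population), and the suite asserts this on random call sets against a
triple-loop oracle. Published breed-level counts can exceed the
population-level locus count because they are (locus × breed) pair counts;
`consensus()` therefore returns one row per locus with the qualifying
breeds/samples in a list column and the pair multiplicity as `n_pairs`, so
both conventions are available. State is `loss` if every member copy
number is below 2, `gain` if all are above, else `both`.

## Chromosomal enrichment

For each autosome, the number of SNPs covered by CNVRs divided by the
chromosome length, with the genome-wide ratio (total covered SNPs / total
autosome length) as the standard; a chromosome is flagged enriched when
its ratio strictly exceeds the genome's. The bp-coverage percentage is
reported alongside because published per-chromosome tables often read as
coverage percentages, but the flag follows the SNP-density rule; both
totals are emitted. An optional permutation test (off by default, since
the original rule is a point comparison with no null) preserves region
lengths, reassigns chromosomes proportionally to length among those the
region fits on, draws uniform starts, and reports the add-one-corrected
fraction of placements reaching the observed density.

## Trait association

Replacing a mixed-model/PLINK quantitative-trait step: per CNVR, ordinary
least squares of height (cm) on copy-number dosage (0–4, capped; an
optional deletion-indicator coding exists because published tables report
deletion copy numbers) with breed fixed effects. Breeds are the
stratification axis and no variance components are available to copy, so
fixed effects plus **within-breed** permutation are used instead of a
mixed model. The fit uses Frisch–Waugh residualisation (centering both
trait and dosage within breed), which is numerically identical to the full
design and lets the permutation null be computed as one matrix product per
scan: family-wise p-values are `(1 + #{max |t| over regions ≥ observed})
/ (n_perm + 1)` genome-wide, and analogously over the region's chromosome.
A breed with a single sample is warned about: its indicator is saturated,
so the sample carries no information and never permutes. Regions with
fewer than `min_carriers` (default 5) non-diploid samples are skipped and
logged. With dosage coding a deletion that increases the trait yields a
*negative* coefficient; the output therefore also carries an explicit
`direction` column ("deletion-increases-trait").

Default `n_perm` is 1,000 in the bundled pipeline and tests (add-one
resolution ~0.001); 10,000 is appropriate for production scans.

## qPCR validation

Relative quantification uses the standard 2^−ΔΔCt model with amplification
efficiency exactly 2: replicate Ct values are averaged, ΔCt = Ct_target −
Ct_reference per sample, ΔΔCt is taken against a diploid calibrator, and
rq = 2^−ΔΔCt, so 0.5 / 1 / 1.5 correspond to 1 / 2 / 3 copies. Copy
numbers are classified to the nearest theoretical level with bin edges at
0.25 / 0.75 / 1.25 — midpoints between levels, chosen because the source
material defines the classes only graphically; rq above 1.75 implies more
than 3 copies and is reported as 3 with a flag. Concordance is computed
per (sample, region) pair — whether published validation rates counted
samples or pairs is ambiguous, and the pair convention is documented here
as the package's choice. Accuracy is the fraction of pairs where the
caller's copy number (diploid where it made no call) equals the qPCR call;
the false-negative rate is the fraction of non-diploid qPCR calls the
caller left diploid.

## The synthetic-data generator

No raw genotypes were ever deposited for the study this workflow targets,
so the generator is the package's study stand-in, and its defaults *are*
the study conditions:

* **Genome**: 5 autosomes × 10 Mb with 2,000 markers (deterministic
  length-proportional allocation, uniform placement). A paper-scale preset
  (31 autosomes, 48,860 markers, 717 samples across 8 breeds) exists for
  slow runs; the default keeps every test in seconds.
* **Cohort**: Arabian (n = 60, 148 cm), Hanoverian (n = 100, 168 cm),
  Lusitano (n = 40, 160 cm); within-breed height sd 3 cm (no published
  per-breed variance was available; 3 cm is a realistic within-breed
  spread for withers height). 2% of samples get a failing QC metric.
* **CNV landscape**: 20 disjoint loci, each spanning ≥ 3 markers; sizes
  log-normal parameterised by median 169,367 bp and mean 487,562 bp (the
  published size statistics; meanlog = log(median), sdlog² =
  2·log(mean/median)); 60% losses; carrier frequencies 0.05–0.40
  rank-coupled to size so that sharing correlates with length, as observed
  in real cohorts.
* **Callers**: sensitivities 0.2 / 0.7 / 0.8 and false-positive rates
  0.1 / 0.4 / 0.6 per sample for CNVPartition / PennCNV / QuantiSNP, with
  5 kb breakpoint jitter snapped to keep ≥ 3 markers — reproducing the
  observed low/mid/high yield ordering and CNVPartition's high miss rate.
  False positives never overlap true loci, keeping sensitivity and FP rate
  identifiable. Scores are Normal (LBF ~ N(30, 12²), confidence ~
  N(55, 15²)) so the score filters have something to cut.
* **Trait**: height = breed mean + β·(2 − cn at the causal loss locus) +
  noise, with β = +4 cm and 15% carriers by default — a deletion that
  makes horses taller.
* **qPCR**: Ct_target = 25 − log2(cn/2) + noise, censored at Ct 38 for
  homozygous deletions, reference gene at Ct 20, two replicates.

What the generator does **not** emulate: raw LRR/BAF signal, linkage
disequilibrium between CNVs, relatedness within breeds, batch/plate
effects, and probe-density heterogeneity along chromosomes. Passing tests
therefore demonstrate that the algebra, statistics and error handling are
correct under a realistic error model — not that any particular biological
conclusion transfers to a specific real cohort.

## Numerical choices and degenerate inputs

* Seeds are mandatory for every stochastic operation; each generator
  derives a distinct sub-seed from the config seed, so the full bundle is
  a pure function of (config, seed) and pipeline reruns are byte-identical.
* Reciprocal-fraction comparisons use a 1e-12 tolerance so exact fractions
  (50/100 at f = 0.5) are not lost to floating point.
* Zero-region chromosomes appear in the enrichment table with density 0;
  zero regions give permutation p = 1 by the add-one correction.
* Degenerate dosage columns (constant within every breed) get t = 0
  rather than NaN and never reach the permutation null's maximum.
* Ties in the genotype matrix (several calls overlapping one region for
  one sample) resolve to the minimum copy number.
* Empty call sets propagate as empty tibbles, not errors; empty sample
  tables are errors.

## Problem sizes

The shipped tests and the acceptance script use the default scaled genome
(2,000 markers, 200–400 samples, 20 loci), 1,000 permutations, and 100
replicate seeds for the parameter-recovery and type-I studies; these sizes
give Monte-Carlo error around 2 percentage points on power and FWER
estimates while the whole suite runs in a few minutes.

## Worked example

```{r example, eval = FALSE}
library(equicnv)

cfg <- sim_config(seed = 42)
bundle <- simulate_cohort(cfg)

kept <- filter_calls(bundle$calls)$calls
cons <- consensus(kept, bundle$samples, level = "population")
cov <- coverage_table(cons, bundle$snp_map)

g <- build_genotypes(cons, kept, bundle$samples)
fit <- assoc_scan(g, bundle$samples, n_perm = 1000, seed = 43)
tidy(fit)
glance(fit)
autoplot(fit)
```

## Known limitations

* The consensus treats a whole overlap component as one locus; two
  distinct variants bridged by a long spanning call merge into one CNVR.
* Breed fixed effects control stratification only at the breed label
  level; cryptic within-breed structure is not modelled.
* qPCR classification assumes a perfectly diploid calibrator and
  efficiency exactly 2; efficiency-corrected variants are out of scope.
* The permutation enrichment null ignores marker-density autocorrelation
  within chromosomes.
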