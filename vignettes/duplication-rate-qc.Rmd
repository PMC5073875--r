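---
title: "Profiling per-gene duplication rates for RNA-Seq quality control"
author: "dupscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling per-gene duplication rates for RNA-Seq quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupscope)
```

## Why a per-gene view of duplication

A duplicate read is one that maps to exactly the same coordinates as another
read (same chromosome, strand-adjusted 5′ start, and mate coordinates for
paired data). Two very different processes produce them. *Natural*
duplicates arise because a highly expressed transcript contributes so many
independent molecules that identical mappings become unavoidable — certain
once coverage approaches one read per exonic base. *Technical* duplicates
arise when PCR re-amplifies the same library molecule, which happens across
the whole expression range when library complexity is low (little input
material, single cells, too many PCR cycles). A single global duplication
percentage confounds the two; the per-gene duplication rate as a function of
expression separates them, because technical duplication lifts the whole
profile while natural duplication only bends its highly expressed end.

## The statistics

For each annotated gene the package computes four counts from a
duplicate-marked alignment file: all and duplicate-filtered reads, each for
uniquely mapping reads (NH = 1) and for the tier that also includes
multi-mappers. From the unique tier:

* `dupRate = (allCounts − filteredCounts)/allCounts`, undefined (`NA`) for
  genes without reads;
* `RPK = allCounts/(geneLength/1000)` with `geneLength` the number of
  distinct exonic bases (union of all transcripts' exons) — the expression
  proxy;
* `RPKM = RPK/(librarySize/10⁶)`.

`librarySize` is the sum of per-gene assigned counts of the corresponding
tier, not the total number of records in the file. This choice keeps
`RPK/RPKM` an exact constant across genes, which is also the observable
property of published example tables; using raw record totals would only
rescale RPKM by a constant and affects nothing downstream (the fit uses
RPK).

The dependency of duplication on expression is modelled as

$$\mathrm{dupRate}_g = \mathrm{expit}\!\left(\alpha + \beta \log_{10}
\mathrm{RPK}_g\right)$$

fitted by iteratively reweighted least squares under a quasi-binomial
likelihood, each gene contributing one unweighted observation. Genes with
zero counts or non-positive RPK are excluded. The reported
**baseline duplication rate** is $\mathrm{expit}(\alpha)$: the model's
prediction at RPK = 1 (log10 RPK = 0), i.e. for lowly expressed genes,
where natural duplication is essentially impossible and any signal is
technical.

Design choices that were genuinely open:

* **Predictor scale.** Expression enters as log10(RPK), matching how such
  profiles are plotted and keeping the intercept interpretable at a round
  expression level (RPK = 1).
* **Unweighted fractional response.** Weighting genes by their read counts
  would let the highly expressed (naturally duplicated) genes dominate the
  fit, which is exactly the signal the baseline must *not* absorb. The
  count-weighted binomial variant (successes = `dupsPerId`,
  trials = `allCounts`) is available via `fit_duprate(weighted = TRUE)` for
  users who want it; on data simulated from the model both estimators agree.
* **Baseline anchor.** "Lowly expressed" is operationalized as RPK = 1
  (one read per kilobase of model): low enough that natural duplication is
  negligible, high enough to be inside the observed range of real data.
* **No fixed threshold.** The baseline is a comparative diagnostic; sample
  preparations, depths and protocols shift what "acceptable" means, so the
  package deliberately reports a number rather than a verdict.

Numerical details: IRLS runs at most 50 iterations with a deviance-change
tolerance of 1e-8; non-convergence is flagged on the returned object and the
last iterate is kept. An all-zero (or all-one) duplication-rate vector is a
perfect-separation case and is rejected with a pointer to the usual cause
(an unmarked BAM). Fewer than 10 genes with reads is an error. All table
values are stored at full precision; the 2-decimal rendering used in
reports is applied only at formatting time.

## Read counting

Counting re-implements the featureCounts default gene-level rules so no
external counter is needed: a counting unit (read, or fragment in
paired-end mode) is assigned to a gene iff exactly one gene's merged exons
overlap any of the unit's aligned blocks by at least one base; units hitting
several genes are ambiguous and discarded; secondary (0x100) and
supplementary (0x800) records are never counted. CIGAR M/=/X/D consume
reference within a block and N splits a read into separate blocks, so
spliced reads can only be assigned once per gene. Strandedness 0/1/2
mirrors the `-s` convention (unstranded / stranded / reversely stranded),
with the first mate defining fragment orientation.

Multi-mapper accounting is not standardized anywhere: here a unit with
NH > 1 counts once, on its primary alignment, in the `Multi` tier; NH is
used only to separate the unique tier. This whole-count-on-primary rule is
deterministic and order-independent; fractional weighting was rejected
because it makes `filtered ≤ all` bookkeeping and the duplicate OR-rule for
pairs ambiguous. A fragment is a duplicate if either mate carries the flag
(markers set both; OR tolerates inconsistent inputs). The MAPQ threshold
defaults to 0, i.e. no filtering.

Internal coordinates are 0-based half-open everywhere; GTF input (1-based
inclusive, quoted or unquoted attributes) is converted on read. Genes whose
annotation spans several chromosomes or strands are reduced, with a
warning, to the combination holding the most exonic bases — a graceful
degradation preferred over failing on real-world annotation pathologies.

## What the simulator emulates — and what it does not

`simulate_library()` generates gene models laid out along two synthetic
chromosomes (1–3 exons per gene, intron gaps of 0.1–2 kb) and places reads
uniformly within exons, with per-gene counts drawn multinomially with
probabilities proportional to expression × length. Expression is log-normal
(default median 50 RPK, sdlog 1.2, spanning roughly 2–1000 RPK — the
dynamic range a bulk mRNA-Seq experiment shows after filtering). Defaults:
200 genes of 0.5–5 kb, 1e5 single-end 50 bp reads, 3 % intergenic reads, 2 %
multi-mappers (NH = 2 with a decoy secondary alignment). Every stochastic
step takes an explicit seed and leaves the caller's RNG stream untouched.

`pcr_amplify(f, λ)` implements amplification as: keep each template
independently with probability `f`, then emit every kept template
`1 + Poisson(λ)` times. With the default `λ = 1/f − 1` the expected output
depth equals the input depth, and when input templates occupy distinct
coordinates the expected coordinate-duplicate fraction of the output is
exactly `1 − f` — 50 % at f = 0.5, 90 % at f = 0.1. The per-template copy
count is the simplest Poisson reading of PCR stochasticity; cycle-by-cycle
branching or per-molecule efficiency variation would change higher moments
of the copy-count distribution but not this first-moment contract, which is
what the validation asserts.

The simulator intentionally omits: sequencing errors and base calls
entirely (duplicate marking and counting never read sequence), optical
duplicate geometry, UMIs, fragment-length biases, and positional coverage
bias along transcripts. Consequently, passing tests demonstrate the
correctness of the counting/statistics/fitting machinery and the internal
consistency of the PCR model — not that real libraries obey the model.
In real data duplicate marks come from external markers on real aligners'
output, and the baseline should be read comparatively across samples.

Validation problem sizes: the simulation contract uses libraries of 1e5
distinct reads averaged over 10 seeds (estimated duplicate percentages are
then accurate to ~0.05 %); counting is checked against a brute-force
per-unit overlap loop on 20-gene/1e4-read libraries across all strandedness
and pairing modes; end-to-end, the fitted baseline of an amplified library
must exceed its pristine counterpart in every seeded run, mirroring the
good-vs-degraded contrast the diagnostic is designed to reveal.

## Degenerate inputs and edge behaviour

* Zero-count genes stay in the table (`dupRate = NA`) and are excluded from
  fitting and plotting.
* An empty annotation or an annotation without the requested feature type is
  an explicit error, as is a missing grouping attribute.
* An alignment file with a header but no reads yields an all-zero count set,
  not an error; a file with no duplicate flags is refused by the CLI unless
  `--assume-marked` is passed.
* Ambiguity ties are not broken: a unit overlapping two genes is discarded
  (featureCounts default), keeping counting order-independent.
* Duplicate marking breaks coordinate-group ties deterministically by input
  order (first record unmarked).

## Limitations

The baseline is a *diagnostic*, not a correction: the package deliberately
does not attempt to remove or down-weight duplicates, as naive removal
biases expression estimates of highly expressed genes. Gene-level union
counting inherits featureCounts' known blind spots (overlapping genes
generate ambiguity, transcript-level resolution is out of scope). The
plots report 2-D binned densities rather than kernel estimates — a
deterministic choice that renders identically across platforms.
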