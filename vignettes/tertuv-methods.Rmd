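---
title: "Two-step UV mutagenesis of the TERT promoter: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step UV mutagenesis of the TERT promoter: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tertuv)
```

## The scientific model

Somatic TERT promoter (TERTp) driver mutations — C>T at −124 bp (C228T) and
−146 bp (C250T) upstream of the translation start, plus the rarer CC>TT
dinucleotide drivers at −125/−124 and −139/−138 — create de novo binding
sites for ETS-family transcription factors, each reading `CCCCTTCCGG` on the
C-rich strand. Bound ETS factors deform DNA in a way that promotes
cyclobutane pyrimidine dimer (CPD) formation under UV light, primarily at
the CC dipyrimidine immediately 5′ of the `TTCCK` core and, more weakly, at
the first central cytosine. The package implements the resulting *two-step*
model of atypical TERTp mutations: a driver mutation first creates (or, for
the native ETS site near −100 bp, licenses) an occupied ETS site; UV damage
at the occupied site then produces secondary C>T passenger mutations — at
−149/−148 (next to a −146 driver), −126/−125 (next to −124), and
−101/−100/−97 (the native site) — in *cis* with the driver, with a frequency
that tracks the sample's UV mutation burden.

Every module is testable end-to-end against seeded synthetic data because
the cohort-scale inputs the model was originally fitted to are access
controlled.

## Coordinates and the synthetic promoter

All offsets are strictly negative, −1 being the base immediately upstream of
the ATG anchor, and all sequences live on the *reporting strand* — the
strand on which the mutant driver motif reads `CCCCTTCCGG`. For a gene on
the genomic minus strand (TERT), upstream means higher genomic coordinate:
with the default hg19 anchor 1,295,104, offsets −124 and −146 map to
chr5:1,295,228 and chr5:1,295,250. The bundled wild-type promoter is not a
copy of any reference genome; it is *constructed* to satisfy, jointly, every
motif constraint the mutant and native sequences impose (C>T at −124 and at
−146 each yield `CCCCTTCCGG`; CC>TT at −139/−138 yields a CC-flanked core;
the native region carries `CCTTCCG` at −101..−95; a second native core sits
5 bp downstream). Remaining positions are a fixed G/C alternation, which
contains no A or T and therefore cannot harbour or create a `TTCCK` core
(nor its reverse complement, which requires `GGAA`): the catalogue's motif
content is exactly its designed content, which the test suite verifies by
exhaustive single-edit scanning against a regular-expression oracle.

Hotspot prediction is deliberately mechanical: an *occupied* core yields
strong hotspots at its two 5′-flanking bases only when both are cytosines
(CPDs need a dipyrimidine) and a weak hotspot at the first central cytosine;
an unoccupied core yields nothing. Which cores count as occupied is the
caller's statement (e.g. driver present), not sequence inference.

## Cohort statistics

Cohort ingestion accepts MAF-style tables (1-based, length-preserving
substitutions) with sample metadata. Filters run in a fixed order — assay
coverage and ≥300,000 bp capture, first sample per patient, cancer types
with ≥40 samples and ≥500 mutations, then a ≥1% driver-frequency floor —
each logged with removal counts; the composite is idempotent. ONVs (span ≥3)
are split into their changed-base SNV components, DNVs kept whole.

The two-sided Fisher's exact test is implemented as summation of
hypergeometric point probabilities not exceeding the observed table's (the
"point probability" convention; two-sided definitions differ, so this is
stated normatively). The test suite checks equality against an independent
log-factorial enumeration on every 2×2 table with total ≤60 (635,375
tables). The odds ratio is the unconditional `ad/bc`, with `Inf`
representable. No multiple-testing correction is applied by default.

For burden–frequency analysis the cohort is split into five bins by UV
burden (C>T SNVs in dipyrimidine contexts after recurrent-driver removal),
and Pearson's r between bin-mean burden and binned mutation frequency is
tested against a t distribution on k−2 df, with 80% normal-approximation
error bars on each binned proportion. Two numerical choices matter here and
were made after observing their failure modes:

* **Bin edges.** Default bins are burden *quantiles* (roughly equal
  occupancy). Equal-width bins on log10(burden+1) — available via
  `method = "logwidth"` — leave their extreme bins nearly empty under a
  long-tailed burden distribution; a ~30-sample bin is then a high-leverage
  point whose noisy frequency drags five-point |r| toward 1 and breaks the
  calibration of the correlation test (we measured ~40% false rejection at
  α = 0.05 under independence, versus the nominal 5%, restored by quantile
  binning).
* **Minimum bin occupancy.** Bins with fewer than `min_bin_n = 10` samples
  are reported but excluded from the correlation — a proportion estimated
  from a handful of samples is not a data point.

## Signature fitting

Spectra use the standard pyrimidine-strand SBS-96 classes and
strand-collapsed DBS-78 classes (both generated programmatically, with the
canonical reference-doublet set and reverse-complement palindrome rule).
Recurrent sites (SNVs in ≥4 samples, DNVs in ≥2, per cancer type) are
removed before spectra and burden, so that selection-driven recurrences do
not contaminate the mutational-process estimate.

Fitting is greedy forward selection with a joint non-negative least-squares
refit (inner solver: Lawson–Hanson NNLS via `pracma::lsqnonneg`) at each
candidate step, stopping at `max_k = 5` signatures or when the SSE
improvement on the normalized spectrum falls below `stop_delta`. Ties are
broken by signature name order, weights below 1e-6 are dropped, and the
procedure is fully deterministic. `stop_delta` defaults to **1e-5**: on the
normalized scale the total sum of squares of a flat 96-bin spectrum is about
1e-2 and a genuine 20–50% mixture component improves the SSE by only ~1e-4,
so a coarser threshold (an earlier candidate default of 1e-3) terminates
after a single signature and cannot recover mixtures; 1e-5 sits an order of
magnitude below real-component improvements and an order above the
multinomial noise floor at the mutation counts this package targets
(thousands per fit). Reference signature matrices are user-supplied TSVs; a
small built-in toy set (UV-like `SBS7`/`DBS1` among them) ships so that
tests and simulations need no downloads, and an optional strictly positive
per-class scaling vector stands in for context-frequency (exome-to-genome)
adjustment without reproducing any external tool's internals.

Per-sample UV attribution combines the two spectra:
(SBS7-attributed SNVs + DBS1-attributed DNVs) / (SNVs + DNVs). Subcohort
labels follow fixed thresholds: driver frequency ≥20% splits high- from
low-TERTp types, UV fraction ≥10% splits UV from non-UV, aggregated per type
by unweighted mean over samples (pooled weighting is available; the
aggregation choice is not forced by anything upstream, and the unweighted
mean is the neutral default).

## Read-backed phasing

Phasing consumes text SAM. Reads flagged duplicate/secondary/supplementary
are excluded; a read qualifies only if a CIGAR walk lands an aligned query
base (M/=/X) on *every* target position — a deletion or reference skip over
any target disqualifies the read, while insertions elsewhere do not. Calls
below base quality Q20 (configurable; the source data's quality model is
unknown, so a standard threshold is used) are masked. Reads are partitioned
by the driver allele; per secondary position the mutant support in each
partition gives cis/trans counts, allele fractions, and a per-sample verdict
(`cis`/`trans`/`mixed`/`indeterminate`) governed by `min_support = 3` mutant
reads and a `max_leak = 2` tolerance for stray reads on the opposite axis —
the leak tolerance exists precisely because at per-base error ε a run with
N informative reads expects ~Nε spurious mutant calls.

That same arithmetic fixes what "recovering" a planted cis fraction can
mean: the estimator x/n (mutant reads on the driver axis over all mutant
reads) is checked against the exact binomial 95% interval *of the true
fraction* at the observed n. Checking instead that the truth lies inside the
Clopper–Pearson interval of the estimate is impossible at cis fractions 0
and 1 for any nonzero error rate — one spurious read on the empty axis
yields a CI excluding the boundary — and would measure the error model, not
the phasing.

## UMI consensus

The amplicon analysis is deliberately simple: reads carry a fixed-length UMI
followed by a locus primer and the target window; anchoring is an exact
primer match with ≤1 mismatch (alignment is out of scope — the locus is
fixed), and a remainder whose length deviates from the window marks the read
as indel-bearing. Families group by exact UMI (optional 1-mismatch collapse
into the larger family, off by default since hairpin-protected UMIs have low
tag error). A family needs ≥3 reads to emit a consensus; per position the
base supported by ≥2/3 of members wins, otherwise `N`. The 2/3 agreement is
the natural majority rule at the minimum family size and is configurable;
the upstream tool the protocol normally uses does not publish its rule, so
2/3 is a declared choice, not an inference. Indel-flagged consensus reads
are removed and counted. Subclonal calls partition consensus reads by the
driver base (−146 by default), tally per-position alternative-base support
on each axis, and report only sites supported by >1 consensus read. With
family size ≥3 and agreement 2/3, two same-base errors must coincide for a
consensus miscall, so the consensus error rate is O(ε²); the suite measures
it at ε = 1e-3 over more than a million consensus bases.

## Paired ETS sites

Upstream regions (1 kb 5′ of the coding start, X/Y excluded by default)
are scanned on both strands for the 7-mer `NNTTCCK` — since `NNTTCCG` is a
subset, the union is just the `TTCCK` scan — requiring the NN prefix to lie
inside the region; ambiguous bases never match. Hits are reported at the
leftmost plus-strand coordinate of the 7-mer with a strand flag; same-strand
pairs with start-to-start distance 7–100 bp (non-overlap guaranteed by the
lower bound) are enumerated, a hit participating in any number of pairs.
Mutation classes are *per-site*: `ge2_per_site` needs ≥2 overlapping
(donor-deduplicated, SNV-only by default) mutations at *both* 7-mer
footprints, `ge1_per_site` needs ≥1 at both; an either-site mode exists but
is non-default. Spacing distributions are counts over 7..100, smoothed by a
centred window-3 moving average (edges averaged over available neighbours,
so smoothing conserves mass up to the two edge bins) and normalized to sum
1. ChIP co-occupancy keeps, per experiment, the top quartile of broadPeak
records by enrichment score (column 7) and requires both site starts inside
*one* retained peak in at least one experiment; experiments with <4 peaks
have no quartile and are skipped with a warning. The helical-period score is
this package's own construction (none is published for this analysis): the
normalized autocorrelation of the mean-subtracted smoothed distribution,
maximized over lags 8–14 bp; a perfectly uniform distribution scores
amplitude 0, and a single-spacing distribution is undefined.

## What the generators emulate — and what they do not

Each generator is a pure function of (config, seed) and emits a truth
record sufficient to score every downstream stage.

* **Cohort** (`simulate_cohort`): per sample, a log-normal UV burden
  (default meanlog log 10, sdlog 1 — tens of panel mutations, the scale at
  which burden binning is informative); a driver with probability 0.674
  (the printed UV-subcohort prevalence), *independent* of burden, split
  45/45/5/5 between −124, −146 and the two DNV drivers (skin cancers show
  the two canonical drivers at near-equal frequency; DNV drivers are rare);
  secondary hotspots drawn *only when their core is occupied* by the
  matching driver, with probability min(1, rate × burden) — linear with
  saturation, the weakest assumption consistent with proportionality. The
  default per-unit-burden rates (−149: 2e-3, −148: 4e-4, −126: 1.2e-3,
  −101: 1.6e-3, −100: 8e-4, −97: 1e-4) put expected prevalences at the mean
  burden near the printed 1.4%/0.9%/2.8% figures, with −101 twice −100 and
  −97 nearly absent (negative selection at the central position).
  Passenger SNVs/DNVs arrive at 1 (resp. 0.05) per unit burden, drawn from
  the UV-like toy signature with weight 0.8 and a flat one otherwise. An
  option merges a −146 driver with a co-occurring −149 hotspot into a
  single ONV record to exercise ONV splitting.
* **Promoter reads** (`simulate_promoter_reads`): a diploid locus, driver
  on one homolog; each read picks a homolog 50/50 and, through its cell of
  origin, carries the secondary variants on the driver haplotype with
  probability `cis_fraction`; uniform start positions, fixed Q30 bases,
  symmetric substitution errors, all-match CIGARs.
* **UMI reads** (`simulate_umi_reads`): heterozygous driver (≈50% of
  molecules), subclones placed on their configured haplotype at their cell
  fraction, family sizes 1 + NB(mu = 5, size = 2) (no amplification model
  is published; a shifted negative binomial gives realistic overdispersion
  and ~80% of families reaching the ≥3 threshold), per-read errors, UMIs
  drawn without collision, optional 1-bp deletions and UMI tag errors.
* **Pair-scan world** (`simulate_pairscan_world`): two 120 kb contigs, a
  gene every 2 kb, 50 "bound" pairs planted at helical spacings
  (round(10.5k), k = 2..8) under high-score synthetic ChIP peaks with
  Poisson(3) mutations per hotspot prefix, 50 unbound pairs at uniform
  spacings, uniform background mutations and low-score decoy peaks.

None of the generators model PCR chimeras, GC-content or strand bias,
quality miscalibration, alignment artefacts, tumour purity or copy number,
or the CPD photochemistry itself; and the real promoter's sequence context
diversity is replaced by a GC filler. Passing tests therefore demonstrate
that the *pipeline logic* — filtering order, conditional hotspot structure,
phasing arithmetic, consensus thresholds, scan/pair/overlap bookkeeping —
behaves as specified under the stated statistical conditions, not that the
methods are robust to every artefact of real sequencing data.

## Problem sizes and determinism

The shipped tests and the acceptance script use: the full promoter window
(300 bp) with exhaustive single-edit motif scans; all 635,375 2×2 tables
with N ≤ 60 for the Fisher oracle; 5,000-sample cohorts (50 seeds for the
burden-contrast property); depth-1,000 read sets at error 1e-3 (4 cis
fractions × 50 seeds); 10,000–16,000 UMI molecules (over 1e6 consensus
bases for the error-rate bound); and 10 kb sequences for the scan oracles.
These sizes make every statistical check well-powered while the whole suite
runs in a few minutes. All randomness flows through explicit seeds;
`scripts/acceptance.R --seed N` derives per-component seeds from `N` and is
reproducible run-to-run.

## Known limitations

* The native ETS site's occupancy is modelled as requiring *any* driver;
  residual GABP binding to the wild-type promoter, reported in cell-free
  systems, is out of scope.
* Rare, mechanistically unclear co-occurrences of −126 hotspot mutations
  with −146 drivers are not generated by the simulator, whose −126
  hotspot requires the −124 core.
* Phasing requires single reads covering all targets; mate-pair merging is
  noted as an extension but not implemented.
* The periodicity score has no significance test attached, by design.
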