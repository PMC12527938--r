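---
title: "codonflux: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonflux: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonflux)
library(data.table)
```

# Scope

codonflux implements three connected analyses around codon-resolution
translation and whole-body metabolite fluxes:

1. a **ribosome-profiling workflow** from transcript-space footprint
   alignments to per-codon relative ribosome dwelling occupancy (RDO),
   pausing tracks, third-base pausing sums, metagenes and wobble-base
   codon composition;
2. a **steady-state isotope-tracing calculus**: circulatory turnover
   fluxes, atom-labeling fractions, non-negative deconvolution of tissue
   metabolite sources with bootstrap errors, and inter-nutrient flux
   networks;
3. an **integration layer** connecting codon composition to proteome fold
   changes (mixed imputation, pathway summaries, correlation).

A seeded synthetic-data generator with known ground truth accompanies all
three, so every stage is validated by parameter recovery rather than by
eyeballing real data.

# The ribosome-profiling model

## From reads to P-sites

Footprints are expected at 28–29 nt after trimming; `filter_reads()`
retains that window and reports the length histogram. The P-site of a
read — the codon being decoded at lysis — sits a fixed offset downstream
of the 5' end, with the offset depending on read length.
`estimate_psite_offsets()` estimates it per length from the start-codon
metagene: initiating ribosomes accumulate over the start codon, so the 5'
ends of their footprints pile up at exactly one candidate offset upstream
of annotated CDS starts. The argmax over candidates 9–15 nt is taken, with
ties broken toward the canonical 12 nt; length classes with fewer than
1,000 start-proximal reads fall back to a configurable default with a
warning. The estimator is validated on simulations with known offsets
(12/12 and 12/13 for 28/29-mers are both recovered exactly). A- and
E-site profiles are the P-site shifted by +3 and −3 nt.

Coordinates are 0-based and half-open throughout; codon *i* of a CDS
occupies nucleotides [3i, 3i+3). SAM input is converted from its 1-based
convention at the boundary only.

## Normalization and occupancy

Per-transcript expression is quantified as PPKM (P-sites per kilobase of
CDS per million mapped P-sites); downstream analyses are restricted to
transcripts with PPKM > 1 in **every** sample, which removes
low-coverage transcripts whose normalized profiles would be dominated by
shot noise. Within each retained CDS, per-nucleotide P-site depths are
divided by the CDS mean depth, so each transcript contributes a profile
with mean exactly 1 regardless of its expression level.

A codon instance's occupancy is the mean of its three normalized
per-nucleotide values; the per-codon-type occupancy is the mean over all
instances (instances with no signal count as zero). RDO between
conditions is the log2 ratio of these means. Zero-mean codons are flagged
`NA`, never ±Inf. Replicates are handled by computing occupancy per
sample and averaging with equal weight; the package makes no attempt to
weight samples by depth, since CDS-mean normalization already removes
depth differences within expressed transcripts.

For pausing, per-position normalized depths of two conditions are
compared as log2((a+1)/(b+1)); the +1 pseudocount keeps tracks finite at
empty positions. A codon's pausing value is the sum of the track over its
3 nt — the only reduction under which the four third-base bucket sums add
exactly to the whole-CDS pausing sum, which is asserted in tests.

## Codon composition

`third_base_fraction()` counts the wobble (third) base of every codon of
the annotated CDS. The start codon and the terminal stop **are included
by default**: the CDS is taken verbatim, and a flag
(`include_start_stop = FALSE`) covers the alternative convention. The
choice moves per-gene fractions by at most 2/K for a K-codon gene and
does not affect comparisons made with a consistent setting. Pathway-level
fractions are unweighted means over member genes; genes in several
pathways contribute to each.

Of the 61 sense codons, 14 end in A and 15 in G (TAA/TGA and TAG are
stops); rank-separation checks between A- and G-ending codons use these
counts.

# The synthetic generator

The generator is a forward model of the analyses above, not of
sequencing chemistry. It emulates:

* **Transcriptomes** — one canonical transcript per gene; CDS lengths
  uniform over a configurable range of multiples of 3 (default 150–600
  nt); internal codons drawn third-base-first from per-gene-set weight
  vectors, with the first two bases uniform over prefixes that keep the
  codon sense. This makes the wobble-base composition of sense codons
  match the configured weights exactly in expectation. Defaults encode an
  A-rich "cc" set (A weight 0.4) versus an A-poor "neuro" set (A weight
  0.1). Each transcript carries fixed UTRs (36 nt 5', 30 nt 3') so that
  footprints whose P-site sits on terminal codons have valid transcript
  coordinates and the start-codon metagene needed for offset estimation
  exists.
* **Expression** — log-normal across genes (meanlog 0, sdlog 1), the
  standard heavy-tailed approximation for expression levels.
* **Footprints** — the P-site lands on codon *j* of gene *g* with
  probability ∝ expr(g) × w(codon_j, condition); dwell weights are
  multiplicative per matching stall pattern (exact codon, `NNA`-style
  wildcard, or the `STOP`/`START` classes) and renormalized within each
  gene, which matches the relative, CDS-mean-normalized read-out of the
  analysis. Counts are Poisson; lengths follow a 50/50 mixture of 28 and
  29 nt with offset 12 for both. The start codon carries a default dwell
  multiplier of 3 to reproduce the initiation peak of real profiles (and
  to make the offset estimator's argmax well defined). The Poisson dwell
  model is the module's assumption; real elongation-time distributions
  are not claimed to be Poisson.
* **Labeling experiments** — tissue labeling vectors L = M·f + Gaussian
  noise clipped to [0, 1], from a known interconversion matrix M (unit
  diagonal) and known direct contributions f; serum MIDs are generated by
  inverting the turnover-flux relation (fully-labeled fraction
  R/(R+F)); self-consistent interconversion matrices for flux-network
  truths are obtained by solving the steady-state labeling balance of a
  known contribution network.

What the generator does **not** emulate: rRNA/tRNA contamination,
multi-mapping, soft clipping, nucleotide-level sequence bias of nuclease
digestion, uneven 5'-end precision, isotopic natural abundance, or
compartmental kinetics. Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated generative assumptions,
not robustness to every artefact of real libraries.

# The tracing calculus

At isotopic pseudo-steady state, infusing a [U-13C] tracer at rate R
(nmol min⁻¹ g⁻¹) gives the circulatory turnover flux

F_circ = R × (1 − L[M+C]) / L[M+C],

with L[M+C] the fully-labeled serum fraction. The carbon-atom analogue is
F_circ_atom = C × R × (1 − L)/L with L = Σᵢ i·L[M+i]/C the atom-labeling
fraction. Normalized labeling of a downstream metabolite Y under tracer X
is L_Y/L_X. Pseudo-steady state is taken as given; no time-course
modelling is attempted.

Direct contributions of circulating nutrients to a tissue metabolite
solve min‖M·f − L‖₂ subject to f ≥ 0 (Lawson–Hanson NNLS via
`pracma::lsqnonneg`). Contributions are **not** forced to sum to 1; the
shortfall is reported as `unexplained`, since the constraint set contains
only non-negativity. Bootstrap standard errors re-solve the NNLS on 100
draws with every entry of M and L perturbed by its measurement sd;
draws are clipped at 0 by default because labeling fractions cannot be
negative (a flag disables clipping). For the circulating flux network,
each nutrient's row of the contribution matrix N is estimated with the
self-source excluded (row and column dropped), and the edge flux from j
to i is N[i,j] × F_circ_atom(i). This single-solve treatment follows the
verbal definition of the network computation; in degenerate (collinear)
interconversion matrices a multi-hop treatment could differ, which is why
the implementation is validated on self-consistent synthetic networks
where the answer is exact.

# Proteomics preprocessing

Intensities are log2-transformed; proteins with less than 70% valid
values in every group are removed. Missing values are imputed per group:
k-nearest-neighbour (k = 10, Euclidean distance on shared valid entries,
neighbours over proteins within the group) where the group holds at
least 60% valid values for that protein, and otherwise random draws from
a down-shifted Gaussian parameterized per sample (mean − 1.8·sd,
width 0.2·sd) — missing-not-at-random values are assumed to sit near the
detection limit. Observed values are never altered, and draws are seeded.
k = 10 is fixed and recorded; with the group sizes this package targets
(3–10 samples) the imputation is insensitive to k in the 5–20 range.

# Numerical choices and degenerate inputs

* Transcripts with zero total depth are skipped by normalization with a
  message, not imputed.
* Metagenes exclude out-of-CDS positions from each instance's average and
  report per-position instance counts; a window of 0 degenerates to the
  anchor-codon occupancy.
* Offset ties go to 12 nt; insufficient start-proximal coverage falls
  back to the configured default with a warning.
* RDO/correlation outputs are `NA` (with a warning or reported field)
  whenever a denominator or variance is exactly zero.
* All generators and stochastic steps take explicit integer seeds; fixed
  seeds give byte-identical outputs, which is asserted in tests.

# Validation strategy and problem sizes

Every operation has an independent brute-force oracle (plain loops over
instances, grid search for the NNLS) that must agree exactly on small
instances (≤10 transcripts). Parameter-recovery checks run at moderate
scale chosen to make the expected estimation error an order of magnitude
smaller than the asserted tolerance: 200 genes at 10⁶ P-sites per
condition for the NNA-stalling recovery (complete A/G rank separation;
mean RDO within 0.05 log2 units of the closed-form expectation), 40
genes at 4×10⁵ reads for the stop- and CCA-stalling metagene signatures,
and 3-metabolite systems with noise sd 0.01 and 100 bootstrap draws for
the deconvolution (per-component bias < 0.02).

# Known limitations

* The codon census is validated against generator-built synthetic
  sequences with prescribed composition; comparisons against specific
  public reference transcripts require the user to supply those sequences
  as FASTA.
* Reads are unique transcript-space placements; multi-mapping and
  soft-clipping are outside the data model.
* The flux network's single-solve contract may differ from multi-hop
  treatments when the interconversion matrix is nearly singular.
* GSEA-style enrichment statistics are intentionally not reimplemented;
  the integration layer exposes ranked tables for export instead.
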