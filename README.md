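# codonflux

Codon-resolution ribosome-occupancy analysis, steady-state isotope-tracing
flux calculus, and codon-composition/proteome integration — with a seeded
synthetic-data generator so every estimator is testable by parameter
recovery.

## The scientific problem

Translational stress does not slow all codons equally. Under metabolic
perturbations such as polyamine depletion, ribosomes can stall
preferentially at codons distinguished only by their third (wobble)
base — for example codons with adenosine in the third position — while
synonymous codons ending in guanosine speed up. Because gene programmes
differ systematically in wobble-base composition (proliferation genes are
A-rich at the third position, neuronal differentiation genes A-poor),
such codon-specific stalling rewires the proteome without any
transcriptional change. Detecting this requires codon-resolution analysis
of ribosome profiling (Ribo-seq), and connecting it to whole-body
metabolism requires in vivo stable-isotope tracing.

codonflux provides both halves for analysts working with:

* **Ribo-seq in transcript space** — P-site offset estimation from the
  start-codon metagene, PPKM expression filtering, CDS-mean
  normalization, per-codon occupancy, and the relative ribosome dwelling
  occupancy between two conditions,
  `RDO(codon) = log2(occ_a / occ_b)`,
  plus per-position pausing tracks `log2((a+1)/(b+1))`, pausing sums
  bucketed by codon third base, codon/start/stop metagenes, and
  polyproline-tract handling.
* **Tracer infusions at pseudo-steady state** — circulatory turnover flux
  `F_circ = R (1 − L[M+C]) / L[M+C]`, its carbon-atom analogue
  `F_atom = C·R(1−L)/L` with `L = Σ i·L[M+i] / C`, normalized labeling
  `L_{Y←X} = L_Y / L_X`, non-negative deconvolution of tissue metabolite
  sources `min ‖M·f − L‖₂ s.t. f ≥ 0` with 100-draw bootstrap errors, and
  inter-nutrient flux networks.
* **Integration** — proteomics filtering (70% valid rule) with mixed
  imputation (within-group kNN + down-shifted Gaussian), wobble-base
  composition per gene and per pathway, and composition-versus-fold-change
  correlation.

## Worked example

Simulate a two-condition experiment in which every codon ending in A
dwells 1.5× longer in the treated condition, then recover that signal as
RDO:

```r
library(codonflux)

cfg <- sim_config(n_genes = 100, read_depth = 5e5,
                  stall_multipliers = list(treated = c(NNA = 1.5)), seed = 7)
ts  <- gen_transcriptome(cfg)

run <- function(cond, s) {
  reads <- filter_reads(gen_footprints(ts, cfg, cond, seed = s))
  off   <- estimate_psite_offsets(reads, ts)   # recovers 12/12 from data
  psite_profiles(reads, off, ts, sample_id = cond)
}
p_t <- run("treated", 8); p_c <- run("control", 9)

expressed <- filter_expressed(list(ppkm(p_t), ppkm(p_c)))  # PPKM > 1 everywhere
r <- rdo(codon_occupancy(normalize_profiles(p_t, expressed), ts, expressed),
         codon_occupancy(normalize_profiles(p_c, expressed), ts, expressed))
r <- r[r$codon %in% sense_codons(), ]
head(r[order(-r$rdo), ], 5)
#>     codon    occ_a     occ_b       rdo
#> 1:    ACA 1.270268 0.9591216 0.4053477
#> 2:    AAA 1.308005 1.0007517 0.3862844
#> 3:    CCA 1.288125 0.9875135 0.3833998
#> 4:    GCA 1.266208 0.9718944 0.3816427
#> 5:    CTA 1.259528 0.9669643 0.3813492

round(tapply(r$rdo, substr(r$codon, 3, 3), mean), 3)
#>      A      C      G      T
#>  0.355 -0.158 -0.137 -0.148
```

All top-ranked codons end in A, and the mean RDO of A-ending codons is
positive while every other ending base is pushed slightly negative — the
within-CDS renormalization makes condition effects relative, so a slowdown
at A-ending codons appears as an apparent speedup elsewhere. The measured
mean RDO is checked against the closed-form expectation from the
generative dwell weights (`expected_codon_occupancy()`).

The flux calculus inverts exactly on generated data:

```r
mid <- gen_serum_mid(F_true = 90, R = 10, C = 6)  # serum MID with L[M+6] = 0.1
fcirc(10, mid)
#> [1] 90
```

A thin command-line front end over the same functions is installed at
`inst/cli/codonflux.R` (subcommands `simulate`, `occupancy`, `rdo`,
`codonfrac`, `flux`).

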