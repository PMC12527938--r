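#' Simulation configuration for the synthetic ribosome-profiling generator
#'
#' Bundles every knob of the forward model: transcriptome composition,
#' expression law, condition-specific dwell (stall) multipliers, and the
#' footprint/read model. Defaults encode the study conditions the generators
#' emulate: 28/29-nt footprints mixed 50/50 with P-site offset 12 for both
#' lengths, a log-normal expression law, a third-base composition bias
#' between a "cc" (cell-cycle-like, A-rich wobble base) and a "neuro"
#' (neuronal-like, A-poor) gene set, and an elevated start-codon dwell that
#' reproduces the initiation peak of real ribosome profiles.
#'
#' @param n_genes number of genes (one canonical transcript each)
#' @param cds_length_range min/max CDS length in nt; both multiples of 3
#' @param codon_bias named list, one entry per gene set, each a named numeric
#'   weight vector over third bases `c(A=,C=,G=,T=)` (normalized internally)
#' @param expression_law `c(meanlog=, sdlog=)` of the per-gene log-normal
#'   expression law
#' @param stall_multipliers named list, one entry per condition; each entry a
#'   named numeric vector mapping a codon pattern (exact codon such as
#'   `"CCA"`, wildcard such as `"NNA"`, or the classes `"STOP"`/`"START"`) to
#'   a positive dwell multiplier. Conditions absent from the list use
#'   baseline weights.
#' @param read_depth expected number of footprints per sample
#' @param footprint_lengths footprint lengths emitted by the read model
#' @param footprint_weights mixture weights over `footprint_lengths`
#' @param psite_offset named integer vector, P-site offset (nt from the 5'
#'   end) per footprint length
#' @param utr5,utr3 fixed UTR lengths (nt) flanking each CDS so that
#'   footprints whose P-site sits on terminal codons have valid transcript
#'   coordinates
#' @param init_weight dwell multiplier of the start codon in every condition
#'   (initiation peak)
#' @param seed integer seed; fixed seed gives byte-identical outputs
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_genes = 200L,
                       cds_length_range = c(150L, 600L),
                       codon_bias = list(
                         cc    = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2),
                         neuro = c(A = 0.1, C = 0.3, G = 0.3, T = 0.3)
                       ),
                       expression_law = c(meanlog = 0, sdlog = 1),
                       stall_multipliers = list(),
                       read_depth = 1e5,
                       footprint_lengths = c(28L, 29L),
                       footprint_weights = c(0.5, 0.5),
                       psite_offset = c(`28` = 12L, `29` = 12L),
                       utr5 = 36L, utr3 = 30L,
                       init_weight = 3,
                       seed = 1L) {
  if (any(cds_length_range %% 3L != 0L))
    stop("cds_length_range must contain multiples of 3")
  if (cds_length_range[1] < 9L)
    stop("minimum CDS length is 9 nt (start + one sense codon + stop)")
  if (cds_length_range[1] > cds_length_range[2])
    stop("cds_length_range must be increasing")
  if (is.null(names(codon_bias)) || any(!nzchar(names(codon_bias))))
    stop("codon_bias must be a named list (one entry per gene set)")
  for (w in codon_bias) {
    if (!all(c("A", "C", "G", "T") %in% names(w)) || any(w < 0) || sum(w) <= 0)
      stop("each codon_bias entry needs non-negative A/C/G/T weights")
  }
  for (cond in names(stall_multipliers)) {
    m <- stall_multipliers[[cond]]
    if (length(m) && (is.null(names(m)) || any(m <= 0)))
      stop("stall multipliers must be named and strictly positive")
  }
  if (length(footprint_weights) != length(footprint_lengths))
    stop("footprint_weights must match footprint_lengths")
  missing_off <- setdiff(as.character(footprint_lengths), names(psite_offset))
  if (length(missing_off))
    stop("psite_offset missing for footprint length(s): ",
         paste(missing_off, collapse = ", "))
  if (init_weight <= 0) stop("init_weight must be positive")
  structure(list(
    n_genes = as.integer(n_genes),
    cds_length_range = as.integer(cds_length_range),
    codon_bias = lapply(codon_bias, function(w) w[c("A", "C", "G", "T")] / sum(w)),
    expression_law = expression_law,
    stall_multipliers = stall_multipliers,
    read_depth = read_depth,
    footprint_lengths = as.integer(footprint_lengths),
    footprint_weights = footprint_weights / sum(footprint_weights),
    psite_offset = psite_offset,
    utr5 = as.integer(utr5), utr3 = as.integer(utr3),
    init_weight = init_weight,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes, CDS",
      paste(x$cds_length_range, collapse = "-"), "nt, depth",
      format(x$read_depth, big.mark = ","), "reads\n")
  cat("  gene sets:", paste(names(x$codon_bias), collapse = ", "), "\n")
  cat("  conditions with stalling:",
      if (length(x$stall_multipliers)) paste(names(x$stall_multipliers), collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
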