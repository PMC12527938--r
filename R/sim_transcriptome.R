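# Forward model, part 1: the transcriptome. Each gene draws a CDS length
# (multiple of 3), a third-base-biased codon sequence, and a log-normal
# expression level. Internal codons are sampled third-base-first so the
# wobble-base composition of sense codons matches the configured weights
# exactly in expectation; stop codons are never produced internally.

#' Generate a synthetic transcriptome with controlled wobble-base bias
#'
#' Genes are split evenly (round robin) across the gene sets named in
#' `config$codon_bias`. Every CDS starts with ATG, ends with a stop codon,
#' and has length divisible by 3; internal sense codons draw their third
#' base from the set's weight vector and their first two bases uniformly
#' from the prefixes that keep the codon a sense codon. Transcripts carry
#' fixed-length UTRs so edge codons are reachable by footprints.
#'
#' @param config a [sim_config()]
#' @return a `transcriptome` (subclass `sim_transcriptome`) whose
#'   `transcripts` table carries the per-gene expression level `expr`
#' @export
gen_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  sets <- names(config$codon_bias)
  gene_set <- sets[((seq_len(n) - 1L) %% length(sets)) + 1L]
  n_codons_rng <- config$cds_length_range / 3L
  n_codons <- sample(seq.int(n_codons_rng[1], n_codons_rng[2]), n, replace = TRUE)
  expr <- rlnorm(n, config$expression_law[["meanlog"]],
                 config$expression_law[["sdlog"]])
  bases <- c("A", "C", "G", "T")
  # prefixes (first two bases) that keep a codon with third base b sense
  sense_prefix <- lapply(setNames(bases, bases), function(b) {
    cand <- codons_ending_in(b, sense_only = TRUE)
    cand <- setdiff(cand, "ATG")  # ATG reserved for the start codon
    substr(cand, 1, 2)
  })
  stops <- stop_codons()
  ids <- sprintf("t%04d", seq_len(n))
  seqs <- character(n)
  for (i in seq_len(n)) {
    w <- config$codon_bias[[gene_set[i]]]
    k <- n_codons[i] - 2L  # internal sense codons
    third <- sample(bases, k, replace = TRUE, prob = w)
    pref <- vapply(third, function(b) sample(sense_prefix[[b]], 1L), "")
    cds <- paste0("ATG", paste0(pref, third, collapse = ""),
                  sample(stops, 1L))
    utr5 <- paste(sample(bases, config$utr5, replace = TRUE), collapse = "")
    utr3 <- paste(sample(bases, config$utr3, replace = TRUE), collapse = "")
    seqs[i] <- paste0(utr5, cds, utr3)
  }
  tr <- data.table(transcript_id = ids, gene_id = ids,
                   gene_set = gene_set, seq = seqs,
                   utr5 = config$utr5, cds_length = 3L * n_codons,
                   expr = expr)
  gs <- data.table(pathway = gene_set, gene_id = ids)
  out <- transcriptome(tr, gs)
  class(out) <- c("sim_transcriptome", class(out))
  out
}
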