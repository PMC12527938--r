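# Forward model, part 2: ribosome footprints. A footprint's P-site lands on
# codon j of gene g with probability proportional to expr_g x w(codon_j,
# condition), where the dwell weights w are multiplicative per matching
# stall pattern and renormalized within each gene (so condition effects are
# relative, matching a CDS-mean-normalized read-out). Counts per codon are
# Poisson; footprint lengths follow the configured mixture and the 5' end is
# placed at (P-site nucleotide - offset(length)).

#' Per-instance dwell weights under a condition
#'
#' @param ts a `transcriptome` from [gen_transcriptome()]
#' @param config the [sim_config()]
#' @param condition condition label; conditions without an entry in
#'   `config$stall_multipliers` use baseline weights
#' @return data.table (transcript_id, codon_index, codon, weight)
#' @export
dwell_weights <- function(ts, config, condition = "control") {
  ct <- codon_table(ts)
  ct[, weight := 1]
  mult <- config$stall_multipliers[[condition]]
  for (pat in names(mult)) {
    hit <- codon_matches(ct$codon, pat)
    ct[hit, weight := weight * mult[[pat]]]
  }
  ct[codon_index == 0L, weight := weight * config$init_weight]
  ct[, .(transcript_id, codon_index, codon, weight)]
}

#' Simulate ribosome footprints for one condition
#'
#' @inheritParams dwell_weights
#' @param seed integer seed for this draw (default: the config seed)
#' @return data.table (transcript_id, five_prime_pos, length) with 0-based
#'   transcript-space 5' positions
#' @export
gen_footprints <- function(ts, config, condition = "control",
                           seed = config$seed) {
  stopifnot(inherits(ts, "transcriptome"), inherits(config, "sim_config"))
  if (nrow(ts$transcripts) == 0L) stop("empty transcriptome")
  missing_off <- setdiff(as.character(config$footprint_lengths),
                         names(config$psite_offset))
  if (length(missing_off))
    stop("psite_offset missing for length(s): ",
         paste(missing_off, collapse = ", "))
  empty <- data.table(transcript_id = character(),
                      five_prime_pos = integer(), length = integer())
  if (config$read_depth <= 0) return(empty)
  set.seed(seed)
  w <- dwell_weights(ts, config, condition)
  tr <- copy(ts$transcripts)
  if (!"expr" %in% names(tr)) tr[, expr := 1]  # equal expression fallback
  anno <- tr[, .(transcript_id, utr5, expr)]
  w <- merge(w, anno, by = "transcript_id", sort = FALSE)
  w[, weight := weight / sum(weight), by = transcript_id]   # within-gene dwell
  gene_p <- tr$expr / sum(tr$expr)                          # across genes
  w[, expr := gene_p[match(transcript_id, tr$transcript_id)]]
  lambda <- config$read_depth * w$expr * w$weight
  counts <- rpois(length(lambda), lambda)
  if (sum(counts) == 0L) return(empty)
  idx <- rep.int(seq_along(counts), counts)
  lens <- sample(config$footprint_lengths, sum(counts), replace = TRUE,
                 prob = config$footprint_weights)
  off <- config$psite_offset[as.character(lens)]
  reads <- data.table(
    transcript_id = w$transcript_id[idx],
    five_prime_pos = w$utr5[idx] + 3L * w$codon_index[idx] - as.integer(off),
    length = as.integer(lens)
  )
  setorder(reads, transcript_id, five_prime_pos, length)
  reads[]
}

#' Analytic expected codon occupancy under the forward model
#'
#' Closed-form large-depth limit of the per-codon-type mean CDS-normalized
#' occupancy: an instance of codon c in gene g contributes
#' K_g * w(c) / W_g, where K_g is the gene's codon count and W_g the gene's
#' total dwell weight. This is the independent oracle against which measured
#' occupancy and RDO are validated.
#'
#' @inheritParams dwell_weights
#' @param transcripts optional character vector restricting to a transcript
#'   subset (e.g. the expressed set)
#' @param sense_only drop stop codons from the summary (default TRUE)
#' @return data.table (codon, occupancy, n_instances)
#' @export
expected_codon_occupancy <- function(ts, config, condition = "control",
                                     transcripts = NULL, sense_only = TRUE) {
  w <- dwell_weights(ts, config, condition)
  if (!is.null(transcripts)) w <- w[transcript_id %in% transcripts]
  w[, n_codons := .N, by = transcript_id]
  w[, value := n_codons * weight / sum(weight), by = transcript_id]
  out <- w[, .(occupancy = mean(value), n_instances = .N), by = codon]
  if (sense_only) out <- out[codon %in% sense_codons()]
  setorder(out, codon)
  out[]
}
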