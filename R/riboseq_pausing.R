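# Relative pausing between conditions and third-base (wobble) composition.

#' Per-position relative pausing track for one transcript
#'
#' log2((a + 1) / (b + 1)) of the CDS-mean-normalized depths of two
#' conditions at every CDS nucleotide; the +1 pseudocount keeps the track
#' finite everywhere. Condition inputs should already be replicate means
#' (see [average_profiles()]).
#'
#' @param norm_a,norm_b `norm_profiles` of the two conditions
#' @param tid transcript id (must be expressed in both conditions)
#' @return numeric vector of length cds_length
#' @export
pausing_track <- function(norm_a, norm_b, tid) {
  a <- profile_vector(norm_a, tid)
  b <- profile_vector(norm_b, tid)
  if (length(a) != length(b))
    stop("CDS length mismatch between conditions for ", tid)
  log2((a + 1) / (b + 1))
}

#' Pausing sums bucketed by codon third base
#'
#' A codon's pausing value is the sum of the track over its 3 nt; each
#' value is added to the bucket of the codon's third (wobble) base. The
#' four bucket sums add up exactly to the whole-CDS pausing sum.
#'
#' @param track per-nucleotide pausing track (from [pausing_track()])
#' @param cds the transcript's CDS sequence (length = length(track))
#' @return named numeric vector of sums for ending bases A, C, G, T
#' @export
pausing_sum_by_base <- function(track, cds) {
  codons <- split_codons(cds)
  if (length(track) != 3L * length(codons))
    stop("track length does not match the CDS")
  per_codon <- colSums(matrix(track, nrow = 3L))
  third <- substr(codons, 3, 3)
  out <- vapply(c("A", "C", "G", "T"),
                function(b) sum(per_codon[third == b]), numeric(1))
  out
}

#' Per-transcript pausing sums between two conditions
#'
#' Convenience wrapper building the pausing track of every shared expressed
#' transcript and bucketing by ending base.
#'
#' @param norm_a,norm_b `norm_profiles` of the two conditions
#' @param ts the `transcriptome`
#' @param transcripts optional transcript subset
#' @return data.table (transcript_id, gene_id, A, C, G, T, total)
#' @export
pausing_sums <- function(norm_a, norm_b, ts, transcripts = NULL) {
  shared <- intersect(norm_a$anno$transcript_id, norm_b$anno$transcript_id)
  if (!is.null(transcripts)) shared <- intersect(shared, transcripts)
  cds <- cds_sequences(ts)
  out <- rbindlist(lapply(shared, function(tid) {
    s <- pausing_sum_by_base(pausing_track(norm_a, norm_b, tid), cds[[tid]])
    data.table(transcript_id = tid, A = s[["A"]], C = s[["C"]],
               G = s[["G"]], T = s[["T"]], total = sum(s))
  }))
  if (nrow(out) == 0) return(out)
  merge(ts$transcripts[, .(transcript_id, gene_id)], out,
        by = "transcript_id")
}

#' Third-base (wobble position) composition of a CDS
#'
#' Fraction of codons ending in each of A, C, G, T. By default all codons
#' of the annotated CDS are counted, including the start and the terminal
#' stop codon; set `include_start_stop = FALSE` to drop the first codon and
#' any stop codons.
#'
#' @param cds CDS sequence (length divisible by 3) or a codon vector
#' @param include_start_stop count the start codon and stop codons
#'   (default TRUE)
#' @return named fractions over A, C, G, T summing to 1
#' @export
third_base_fraction <- function(cds, include_start_stop = TRUE) {
  codons <- if (length(cds) == 1L && nchar(cds[1]) > 3L)
    split_codons(cds) else cds
  if (!include_start_stop) {
    codons <- codons[-1]
    codons <- codons[!codons %in% stop_codons()]
  }
  if (length(codons) == 0) stop("no codons left to count")
  third <- factor(substr(codons, 3, 3), levels = c("A", "C", "G", "T"))
  prop <- table(third) / length(codons)
  setNames(as.numeric(prop), levels(third))
}

#' Per-gene third-base fractions of a transcriptome
#'
#' @param ts the `transcriptome`
#' @param include_start_stop see [third_base_fraction()]
#' @return data.table (transcript_id, gene_id, gene_set, A, C, G, T)
#' @export
gene_third_base_table <- function(ts, include_start_stop = TRUE) {
  cds <- cds_sequences(ts)
  fr <- t(vapply(cds, third_base_fraction, numeric(4),
                 include_start_stop = include_start_stop))
  out <- data.table(transcript_id = rownames(fr),
                    A = fr[, "A"], C = fr[, "C"], G = fr[, "G"],
                    T = fr[, "T"])
  merge(ts$transcripts[, .(transcript_id, gene_id, gene_set)], out,
        by = "transcript_id")
}
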