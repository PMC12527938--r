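# The shared transcriptome container: one canonical transcript per gene,
# with 0-based CDS coordinates inside the (possibly UTR-flanked) transcript
# sequence. Codon i of a CDS occupies CDS nucleotides [3i, 3i+3).

#' Construct a transcriptome object
#'
#' @param transcripts data.frame/data.table with columns `transcript_id`,
#'   `gene_id`, `seq` (transcript sequence, ACGT), `utr5` (0-based CDS start
#'   offset in nt) and `cds_length` (nt, multiple of 3); optional `gene_set`
#'   and `expr` columns
#' @param gene_sets optional data.frame with columns `pathway`, `gene_id`
#' @return object of class `transcriptome`
#' @export
transcriptome <- function(transcripts, gene_sets = NULL) {
  tr <- as.data.table(transcripts)
  need <- c("transcript_id", "gene_id", "seq", "utr5", "cds_length")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("transcripts is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(tr$cds_length %% 3L != 0L))
    stop("all cds_length values must be multiples of 3")
  if (any(tr$utr5 + tr$cds_length > nchar(tr$seq)))
    stop("CDS extends past transcript end for some records")
  if (anyDuplicated(tr$transcript_id))
    stop("duplicate transcript_id")
  if (!"gene_set" %in% names(tr)) tr[, gene_set := NA_character_]
  setkey(tr, transcript_id)
  gs <- if (is.null(gene_sets)) {
    data.table(pathway = character(), gene_id = character())
  } else as.data.table(gene_sets)
  structure(list(transcripts = tr, gene_sets = gs), class = "transcriptome")
}

#' @export
print.transcriptome <- function(x, ...) {
  cat("transcriptome:", nrow(x$transcripts), "transcripts,",
      length(unique(x$gene_sets$pathway)), "gene sets\n")
  invisible(x)
}

#' CDS sequences of a transcriptome
#' @param ts a `transcriptome`
#' @return named character vector of CDS sequences
#' @export
cds_sequences <- function(ts) {
  tr <- ts$transcripts
  setNames(substr(tr$seq, tr$utr5 + 1L, tr$utr5 + tr$cds_length),
           tr$transcript_id)
}

#' Per-instance codon table of a transcriptome
#'
#' One row per codon instance: transcript, 0-based codon index, codon.
#'
#' @param ts a `transcriptome`
#' @return data.table (transcript_id, gene_id, gene_set, codon_index, codon)
#' @export
codon_table <- function(ts) {
  cds <- cds_sequences(ts)
  tr <- ts$transcripts
  out <- lapply(seq_along(cds), function(i) {
    cod <- split_codons(cds[[i]])
    data.table(transcript_id = names(cds)[i],
               codon_index = seq_along(cod) - 1L,
               codon = cod)
  })
  out <- rbindlist(out)
  out <- merge(out, tr[, .(transcript_id, gene_id, gene_set)],
               by = "transcript_id", sort = FALSE)
  setkey(out, transcript_id, codon_index)
  out[]
}
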