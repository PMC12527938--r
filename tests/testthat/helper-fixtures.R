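# Tiny hand-built fixtures. All coordinates 0-based half-open; codon i of a
# CDS occupies nucleotides [3i, 3i+3).

# a transcriptome of hand-written CDSs (no UTRs unless utr5 > 0)
tiny_transcriptome <- function(cds_list, utr5 = 0L, gene_set = NULL) {
  n <- length(cds_list)
  ids <- names(cds_list)
  if (is.null(ids)) ids <- sprintf("tx%02d", seq_len(n))
  pad5 <- strrep("G", utr5)
  tr <- data.table::data.table(
    transcript_id = ids, gene_id = ids,
    seq = paste0(pad5, unlist(cds_list)),
    utr5 = as.integer(utr5),
    cds_length = nchar(unlist(cds_list))
  )
  if (!is.null(gene_set)) tr$gene_set <- gene_set
  transcriptome(tr)
}

# reads that put exactly `depth[i]` P-sites on CDS nucleotide i-1 of each
# transcript, using read length 30 with offset 0
reads_from_depths <- function(depths, ts) {
  anno <- ts$transcripts
  out <- lapply(names(depths), function(tid) {
    d <- depths[[tid]]
    u5 <- anno$utr5[anno$transcript_id == tid]
    pos <- rep.int(seq_along(d) - 1L, d)
    if (!length(pos)) return(NULL)
    data.table::data.table(transcript_id = tid,
                           five_prime_pos = u5 + pos, length = 30L)
  })
  data.table::rbindlist(out)
}

fixed_offsets <- c(`30` = 0L)

# profiles straight from explicit per-nucleotide depth vectors
profiles_from_depths <- function(depths, ts, sample_id = "s1") {
  psite_profiles(reads_from_depths(depths, ts), fixed_offsets, ts,
                 sample_id = sample_id)
}

norm_from_depths <- function(depths, ts, ...) {
  normalize_profiles(profiles_from_depths(depths, ts, ...))
}

# a small random instance (<= 10 transcripts) with strictly positive depths,
# used for exact brute-force oracle comparisons
make_small_case <- function(seed = 101, n = 8) {
  set.seed(seed)
  cds <- lapply(seq_len(n), function(i) {
    k <- sample(10:25, 1)
    internal <- sample(setdiff(sense_codons(), "ATG"), k, replace = TRUE)
    paste0("ATG", paste(internal, collapse = ""), sample(stop_codons(), 1))
  })
  names(cds) <- sprintf("tx%02d", seq_len(n))
  depths <- lapply(cds, function(s) rpois(nchar(s), 2) + 1L)
  list(cds = cds, depths = depths, ts = tiny_transcriptome(cds))
}
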