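# Readers and writers for the package's external formats. Internal
# coordinates are 0-based half-open everywhere; SAM's 1-based convention is
# converted at the boundary only.

#' Read coding sequences from FASTA
#'
#' Sequences are upper-cased; records containing non-ACGT characters or
#' with length not divisible by 3 are skipped with a warning (counts
#' reported). Without an annotation table the FASTA records are taken as
#' bare CDSs (no UTRs).
#'
#' @param path FASTA file of CDS (or full transcript) sequences
#' @param annotation optional data.frame (transcript_id, utr5, cds_length)
#'   giving CDS coordinates inside each record; also may carry `gene_id`
#'   and `gene_set`
#' @param gene_sets optional data.frame (pathway, gene_id)
#' @return a `transcriptome`
#' @export
read_cds_fasta <- function(path, annotation = NULL, gene_sets = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  seqc <- toupper(as.character(seqs))
  names(seqc) <- ids
  bad_alpha <- grepl("[^ACGT]", seqc)
  if (any(bad_alpha))
    warning(sum(bad_alpha), " record(s) with non-ACGT characters skipped")
  seqc <- seqc[!bad_alpha]
  if (is.null(annotation)) {
    bad_len <- nchar(seqc) %% 3L != 0L
    if (any(bad_len))
      warning(sum(bad_len), " record(s) with length not divisible by 3 skipped")
    seqc <- seqc[!bad_len]
    tr <- data.table(transcript_id = names(seqc), gene_id = names(seqc),
                     seq = unname(seqc), utr5 = 0L,
                     cds_length = nchar(unname(seqc)))
  } else {
    anno <- as.data.table(annotation)
    anno <- anno[transcript_id %in% names(seqc)]
    bad_len <- anno$cds_length %% 3L != 0L
    if (any(bad_len))
      warning(sum(bad_len), " record(s) with CDS length not divisible by 3 skipped")
    anno <- anno[!bad_len]
    tr <- copy(anno)
    if (!"gene_id" %in% names(tr)) tr[, gene_id := transcript_id]
    tr[, seq := unname(seqc[transcript_id])]
    tr[, utr5 := as.integer(utr5)]
    tr[, cds_length := as.integer(cds_length)]
  }
  transcriptome(tr, gene_sets)
}

#' Write transcript sequences to FASTA
#'
#' @param ts a `transcriptome`
#' @param path output FASTA path
#' @param cds_only write bare CDS sequences instead of full transcripts
#' @return `path`, invisibly
#' @export
write_cds_fasta <- function(ts, path, cds_only = FALSE) {
  seqs <- if (cds_only) cds_sequences(ts)
          else setNames(ts$transcripts$seq, ts$transcripts$transcript_id)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write/read the transcript annotation table (TSV)
#'
#' @param ts a `transcriptome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_annotation <- function(ts, path) {
  cols <- intersect(c("transcript_id", "gene_id", "gene_set", "utr5",
                      "cds_length", "expr"), names(ts$transcripts))
  fwrite(ts$transcripts[, ..cols], path, sep = "\t")
  invisible(path)
}

#' Read a footprint read table (TSV)
#'
#' Expected columns: transcript_id, five_prime_pos (0-based), length.
#'
#' @param path TSV path
#' @return data.table of reads
#' @export
read_reads_tsv <- function(path) {
  r <- fread(path, sep = "\t")
  need <- c("transcript_id", "five_prime_pos", "length")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop("read table missing column(s): ",
                         paste(miss, collapse = ", "))
  r[, five_prime_pos := as.integer(five_prime_pos)]
  r[, length := as.integer(length)]
  r[, ..need]
}

#' Write a footprint read table (TSV)
#' @param reads read table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_reads_tsv <- function(reads, path) {
  fwrite(as.data.table(reads)[, .(transcript_id, five_prime_pos, length)],
         path, sep = "\t")
  invisible(path)
}

#' Read transcript-space footprint alignments from SAM/BAM
#'
#' SAM text is converted to BAM on the fly (Rsamtools). POS is converted
#' from SAM's 1-based to the package's 0-based convention. Reverse-strand
#' and unmapped records are dropped (transcript space is stranded);
#' records on transcripts absent from `ts` are dropped and counted in
#' attribute `n_dropped_unknown`.
#'
#' @param path SAM (or BAM) file with transcript-space alignments
#' @param ts optional `transcriptome` used to reject unknown transcripts
#' @return data.table (transcript_id, five_prime_pos, length)
#' @export
read_reads_sam <- function(path, ts = NULL) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  aln <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("rname", "pos", "qwidth", "strand", "flag")))[[1]]
  keep <- !is.na(aln$pos) & aln$strand != "-"
  out <- data.table(transcript_id = as.character(aln$rname)[keep],
                    five_prime_pos = aln$pos[keep] - 1L,
                    length = aln$qwidth[keep])
  n_unknown <- 0L
  if (!is.null(ts)) {
    known <- out$transcript_id %in% ts$transcripts$transcript_id
    n_unknown <- sum(!known)
    out <- out[known]
  }
  setattr(out, "n_dropped_unknown", n_unknown)
  out[]
}

#' Read gene sets from GMT or two-column TSV
#'
#' GMT: one pathway per line (name, description, genes...). TSV: columns
#' `pathway`, `gene_id`.
#'
#' @param path GMT or TSV path
#' @return data.table (pathway, gene_id)
#' @export
read_gene_sets <- function(path) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    out <- rbindlist(lapply(lines[nzchar(lines)], function(l) {
      f <- strsplit(l, "\t")[[1]]
      if (length(f) < 3) return(NULL)
      data.table(pathway = f[1], gene_id = f[-(1:2)])
    }))
    return(out[])
  }
  gs <- fread(path, sep = "\t")
  if (!all(c("pathway", "gene_id") %in% names(gs)))
    stop("gene set TSV needs columns pathway, gene_id")
  gs[, .(pathway, gene_id)]
}

#' Read natural-abundance-corrected MIDs from CSV
#'
#' Expected columns: metabolite, compartment, tracer, isotopomer (`M+i`),
#' fraction.
#'
#' @param path CSV path
#' @return named list (by metabolite/compartment/tracer) of [mid_vector()]s
#' @export
read_mids <- function(path) {
  x <- fread(path)
  need <- c("metabolite", "compartment", "tracer", "isotopomer", "fraction")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("mids CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, idx := as.integer(sub("^M\\+", "", isotopomer))]
  sp <- split(x, by = c("metabolite", "compartment", "tracer"), sep = "|")
  lapply(sp, function(d) {
    d <- d[order(idx)]
    if (!identical(d$idx, 0:max(d$idx)))
      stop("incomplete MID for ", d$metabolite[1])
    mid_vector(d$fraction, metabolite = d$metabolite[1])
  })
}

#' Read infusion parameters from CSV
#'
#' Expected columns: tracer, conc_mM, pump_ul_min_g (and optionally
#' duration_h, carbons). The infusion rate R = conc_mM x pump_ul_min_g in
#' nmol min^-1 g^-1 is derived.
#'
#' @param path CSV path
#' @return data.table with derived column `R`
#' @export
read_infusions <- function(path) {
  x <- fread(path)
  need <- c("tracer", "conc_mM", "pump_ul_min_g")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("infusions CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  x[, R := conc_mM * pump_ul_min_g]
  if (any(x$R <= 0)) stop("infusion rate R must be > 0")
  x[]
}

#' Write a machine-readable run manifest
#'
#' Records package version, seeds, parameter list, input checksums and
#' output file list as JSON.
#'
#' @param path output JSON path
#' @param seeds named list/vector of seeds used
#' @param params named list of parameters
#' @param inputs character vector of input file paths (md5-summed)
#' @param outputs character vector of output file paths
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(path, seeds = list(), params = list(),
                           inputs = character(), outputs = character()) {
  manifest <- list(
    package = "codonflux",
    version = as.character(utils::packageVersion("codonflux")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    params = params,
    inputs = if (length(inputs))
      setNames(as.list(tools::md5sum(inputs)), inputs) else list(),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
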