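# From footprint reads to P-site depth profiles. Coordinates are 0-based
# half-open throughout: a read's 5' end is a transcript coordinate, its
# P-site nucleotide is five_prime_pos + offset(length), and CDS positions
# run 0 .. cds_length-1. Codon i occupies CDS nucleotides [3i, 3i+3).

#' Filter footprint reads by length
#'
#' Retains reads whose length lies in [min_len, max_len] and attaches the
#' pre-filter length histogram as attribute `length_histogram`.
#'
#' @param reads data.table (transcript_id, five_prime_pos, length)
#' @param min_len,max_len retained length bounds (defaults 28 and 29 nt)
#' @return filtered read table
#' @export
filter_reads <- function(reads, min_len = 28L, max_len = 29L) {
  reads <- as.data.table(reads)
  hist <- if (nrow(reads)) table(reads$length) else table(integer())
  out <- reads[length >= min_len & length <= max_len]
  setattr(out, "length_histogram", hist)
  out[]
}

#' Estimate P-site offsets from the start-codon metagene
#'
#' For each read length, counts reads whose 5' end lies a candidate offset
#' upstream of an annotated start codon and takes the candidate with the
#' highest count (the initiation peak), searching offsets 9..15 nt and
#' breaking ties toward 12. Lengths with fewer than `min_reads` start-
#' proximal reads fall back to `default` with a warning.
#'
#' @param reads read table (transcript_id, five_prime_pos, length)
#' @param ts a `transcriptome` (provides CDS start coordinates)
#' @param search candidate offsets in nt (default 9:15)
#' @param default fallback offset (default 12)
#' @param min_reads minimum start-proximal reads per length class
#' @return named integer vector, offset per read length
#' @export
estimate_psite_offsets <- function(reads, ts, search = 9:15,
                                   default = 12L, min_reads = 1000L) {
  reads <- as.data.table(reads)
  anno <- ts$transcripts[, .(transcript_id, utr5)]
  r <- merge(reads, anno, by = "transcript_id")
  r[, psite := utr5 - five_prime_pos]  # candidate offset if P-site at start
  lens <- sort(unique(reads$length))
  out <- setNames(integer(length(lens)), lens)
  for (l in as.character(lens)) {
    d <- r[length == as.integer(l) & psite %in% search, psite]
    if (length(d) < min_reads) {
      warning("length ", l, ": only ", length(d),
              " start-proximal reads; falling back to default offset ",
              default)
      out[l] <- as.integer(default)
      next
    }
    cnt <- table(factor(d, levels = search))
    best <- search[cnt == max(cnt)]
    out[l] <- best[which.min(abs(best - 12L))]  # tie toward 12
  }
  out
}

#' P-site (or A-/E-site) depth profiles over CDSs
#'
#' Assigns each read's ribosomal-site nucleotide (P = 5' end + offset,
#' A = P + 3, E = P - 3) and accumulates per-CDS-nucleotide depths.
#' Positions outside the CDS and reads on unknown transcripts are dropped
#' and counted in the `dropped` field.
#'
#' @param reads read table (transcript_id, five_prime_pos, length)
#' @param offsets named offset vector per read length (nt)
#' @param ts a `transcriptome`
#' @param site ribosomal site, one of "P", "A", "E"
#' @param sample_id sample label carried on the result
#' @return object of class `psite_profiles`: sparse per-nucleotide counts
#'   (`counts`: transcript_id, pos, depth), CDS lengths (`anno`), `site`,
#'   `sample_id`, `dropped`
#' @export
psite_profiles <- function(reads, offsets, ts, site = c("P", "A", "E"),
                           sample_id = "sample") {
  site <- match.arg(site)
  reads <- as.data.table(reads)
  miss_off <- setdiff(as.character(unique(reads$length)), names(offsets))
  if (length(miss_off))
    stop("no offset for read length(s): ", paste(miss_off, collapse = ", "))
  anno <- ts$transcripts[, .(transcript_id, utr5, cds_length)]
  known <- reads$transcript_id %in% anno$transcript_id
  n_unknown <- sum(!known)
  r <- merge(reads[known], anno, by = "transcript_id")
  shift <- c(P = 0L, A = 3L, E = -3L)[[site]]
  r[, pos := five_prime_pos + as.integer(offsets[as.character(length)]) +
        shift - utr5]
  inside <- r$pos >= 0L & r$pos < r$cds_length
  n_outside <- sum(!inside)
  counts <- r[inside, .(depth = .N), by = .(transcript_id, pos)]
  setkey(counts, transcript_id, pos)
  structure(list(counts = counts,
                 anno = ts$transcripts[, .(transcript_id, cds_length)],
                 site = site, sample_id = sample_id,
                 dropped = c(unknown_transcript = n_unknown,
                             outside_cds = n_outside)),
            class = "psite_profiles")
}

#' @export
print.psite_profiles <- function(x, ...) {
  cat("psite_profiles [", x$sample_id, ", ", x$site, "-site]: ",
      sum(x$counts$depth), " P-sites on ",
      length(unique(x$counts$transcript_id)), " transcripts (dropped: ",
      paste(names(x$dropped), x$dropped, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' P-sites per kilobase of CDS per million mapped P-sites
#'
#' PPKM = CDS count / (CDS length / 1000) / (sample total / 10^6).
#' Transcripts without counts get PPKM 0; a zero sample total is an error.
#'
#' @param profiles a `psite_profiles`
#' @return data.table (transcript_id, count, ppkm) over all annotated
#'   transcripts
#' @export
ppkm <- function(profiles) {
  stopifnot(inherits(profiles, "psite_profiles"))
  total <- sum(profiles$counts$depth)
  if (total == 0) stop("sample has zero mapped P-sites")
  per_tr <- profiles$counts[, .(count = sum(depth)), by = transcript_id]
  out <- merge(profiles$anno, per_tr, by = "transcript_id", all.x = TRUE)
  out[is.na(count), count := 0L]
  out[, ppkm := count / (cds_length / 1000) / (total / 1e6)]
  out[, .(transcript_id, count, ppkm)]
}

#' Expressed-transcript filter
#'
#' Keeps a transcript only if its PPKM exceeds the threshold in every
#' sample.
#'
#' @param ppkm_tables a single [ppkm()] table or a list of them (one per
#'   sample)
#' @param threshold PPKM threshold (default 1)
#' @return character vector of retained transcript ids
#' @export
filter_expressed <- function(ppkm_tables, threshold = 1) {
  if (is.data.frame(ppkm_tables)) ppkm_tables <- list(ppkm_tables)
  kept <- lapply(ppkm_tables, function(p) p$transcript_id[p$ppkm > threshold])
  Reduce(intersect, kept)
}

#' Normalize P-site profiles to their CDS mean
#'
#' Divides each per-nucleotide depth by the mean depth over the CDS (zeros
#' included), so the mean normalized value of every retained transcript is
#' exactly 1. Transcripts with zero total depth are skipped and recorded in
#' the `skipped` field.
#'
#' @param profiles a `psite_profiles`
#' @param transcripts optional subset of transcript ids (e.g. the expressed
#'   set from [filter_expressed()])
#' @return object of class `norm_profiles` with sparse `values`
#'   (transcript_id, pos, value) and `anno`
#' @export
normalize_profiles <- function(profiles, transcripts = NULL) {
  stopifnot(inherits(profiles, "psite_profiles"))
  anno <- profiles$anno
  if (!is.null(transcripts)) anno <- anno[transcript_id %in% transcripts]
  cnt <- profiles$counts[transcript_id %in% anno$transcript_id]
  tot <- cnt[, .(total = sum(depth)), by = transcript_id]
  covered <- merge(anno, tot, by = "transcript_id", all.x = TRUE)
  skipped <- covered[is.na(total) | total == 0, transcript_id]
  if (length(skipped))
    message(length(skipped), " transcript(s) with zero depth skipped")
  keep <- setdiff(covered$transcript_id, skipped)
  cnt <- merge(cnt[transcript_id %in% keep], covered,
               by = "transcript_id", sort = FALSE)
  cnt[, value := depth * cds_length / total]
  values <- cnt[, .(transcript_id, pos, value)]
  setkey(values, transcript_id, pos)
  structure(list(values = values,
                 anno = anno[transcript_id %in% keep],
                 sample_id = profiles$sample_id, site = profiles$site,
                 skipped = skipped),
            class = "norm_profiles")
}

#' Average normalized profiles across replicate samples
#'
#' Equal-weight per-position mean of normalized depths over samples;
#' missing positions count as 0. Only transcripts present in every sample's
#' annotation are retained.
#'
#' @param nps list of `norm_profiles`
#' @return a `norm_profiles` whose values are sample means
#' @export
average_profiles <- function(nps) {
  stopifnot(length(nps) >= 1, all(vapply(nps, inherits, TRUE, "norm_profiles")))
  if (length(nps) == 1L) return(nps[[1]])
  shared <- Reduce(intersect, lapply(nps, function(x) x$anno$transcript_id))
  vals <- rbindlist(lapply(nps, function(x)
    x$values[transcript_id %in% shared]))
  out <- vals[, .(value = sum(value) / length(nps)),
              by = .(transcript_id, pos)]
  setkey(out, transcript_id, pos)
  structure(list(values = out,
                 anno = nps[[1]]$anno[transcript_id %in% shared],
                 sample_id = paste(vapply(nps, `[[`, "", "sample_id"),
                                   collapse = "+"),
                 site = nps[[1]]$site, skipped = character()),
            class = "norm_profiles")
}

#' Dense per-nucleotide vector of one transcript's profile
#'
#' @param np a `norm_profiles` (or `psite_profiles`)
#' @param tid transcript id
#' @return numeric vector of length cds_length (zeros where no signal)
#' @export
profile_vector <- function(np, tid) {
  anno <- np$anno[transcript_id == tid]
  if (nrow(anno) == 0) stop("unknown transcript: ", tid)
  v <- numeric(anno$cds_length)
  tab <- if (inherits(np, "norm_profiles")) np$values else np$counts
  col <- if (inherits(np, "norm_profiles")) "value" else "depth"
  sub <- tab[transcript_id == tid]
  v[sub$pos + 1L] <- sub[[col]]
  v
}
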