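# Codon-type occupancy, between-condition RDO, and codon-anchored
# metagenes, all computed on CDS-mean-normalized profiles of the expressed
# transcript set.

#' Mean normalized occupancy per codon type
#'
#' Each codon instance's occupancy is the mean of the normalized
#' per-nucleotide depths over its 3 nt; the table reports, per codon type,
#' the mean over all instances (instances without signal count as 0) and
#' the instance census.
#'
#' @param np a `norm_profiles`
#' @param ts the `transcriptome`
#' @param transcripts optional transcript subset (defaults to the profile's
#'   annotation)
#' @param exclude optional data.table (transcript_id, codon_index) of
#'   instances to leave out, e.g. polyproline tracts from
#'   [polypro_instances()]
#' @return data.table (codon, mean_occ, n_instances) over all 64 codons
#'   present in the subset (stop codons included; filter as needed)
#' @export
codon_occupancy <- function(np, ts, transcripts = NULL, exclude = NULL) {
  stopifnot(inherits(np, "norm_profiles"))
  if (is.null(transcripts)) transcripts <- np$anno$transcript_id
  transcripts <- intersect(transcripts, np$anno$transcript_id)
  ct <- codon_table(ts)[transcript_id %in% transcripts]
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- as.data.table(exclude)[, .(transcript_id, codon_index)]
    ct <- ct[!ex, on = c("transcript_id", "codon_index")]
  }
  vals <- np$values[transcript_id %in% transcripts]
  vals[, codon_index := pos %/% 3L]
  per_codon <- vals[, .(value = sum(value) / 3), by = .(transcript_id, codon_index)]
  ct <- merge(ct, per_codon, by = c("transcript_id", "codon_index"),
              all.x = TRUE)
  ct[is.na(value), value := 0]
  out <- ct[, .(mean_occ = mean(value), n_instances = .N), by = codon]
  setorder(out, codon)
  out[]
}

#' Average occupancy tables across replicate samples
#'
#' @param occ_list list of [codon_occupancy()] tables (one per sample)
#' @return data.table with the equal-weight mean occupancy per codon
#' @export
average_occupancy <- function(occ_list) {
  stopifnot(length(occ_list) >= 1)
  all <- rbindlist(occ_list)
  out <- all[, .(mean_occ = mean(mean_occ),
                 n_instances = n_instances[1]), by = codon]
  setorder(out, codon)
  out[]
}

#' Relative ribosome dwelling occupancy (RDO) between two conditions
#'
#' RDO(codon) = log2(mean_occ_a / mean_occ_b). Codons with a zero mean
#' occupancy in either condition are flagged undefined (NA) rather than
#' reported as +/-Inf.
#'
#' @param occ_a,occ_b [codon_occupancy()] tables over the same transcript
#'   subset
#' @return data.table (codon, occ_a, occ_b, rdo)
#' @export
rdo <- function(occ_a, occ_b) {
  m <- merge(occ_a[, .(codon, occ_a = mean_occ)],
             occ_b[, .(codon, occ_b = mean_occ)], by = "codon")
  m[, rdo := ifelse(occ_a > 0 & occ_b > 0, log2(occ_a / occ_b), NA_real_)]
  n_undef <- sum(is.na(m$rdo))
  if (n_undef) warning(n_undef, " codon(s) undefined (zero mean occupancy)")
  setorder(m, codon)
  m[]
}

# shared metagene engine over a table of anchors (transcript_id, anchor =
# 0-based CDS nucleotide of the anchor codon's first base)
metagene_at <- function(np, anchors, window) {
  anchors <- as.data.table(anchors)
  anchors <- merge(anchors, np$anno, by = "transcript_id", sort = FALSE)
  if (nrow(anchors) == 0)
    return(data.table(rel = integer(), mean_value = numeric(),
                      n_instances = integer()))
  anchors[, instance := .I]
  rels <- seq.int(-window, window)
  grid <- anchors[, .(rel = rels, pos = anchor + rels),
                  by = .(instance, transcript_id, cds_length)]
  grid <- grid[pos >= 0L & pos < cds_length]  # CDS-edge-aware
  grid <- merge(grid, np$values, by = c("transcript_id", "pos"),
                all.x = TRUE)
  grid[is.na(value), value := 0]
  out <- grid[, .(mean_value = mean(value), n_instances = .N), by = rel]
  setorder(out, rel)
  out[]
}

#' Codon-anchored metagene of normalized occupancy
#'
#' Mean normalized depth at each position within `window` nt of every
#' instance of the given codon(s); positions outside a CDS are excluded
#' from that instance's average, and the per-position instance counts are
#' reported.
#'
#' @param np a `norm_profiles` (expressed transcripts)
#' @param ts the `transcriptome`
#' @param codons codon or codon set to anchor on (e.g. "CCA" or
#'   [proline_codons()])
#' @param window half-window in nt (default 90)
#' @param transcripts optional transcript subset
#' @param exclude optional (transcript_id, codon_index) instances to skip
#' @return data.table (rel, mean_value, n_instances), rel = nt relative to
#'   the anchor codon's first nucleotide
#' @export
metagene_codon <- function(np, ts, codons, window = 90L,
                           transcripts = NULL, exclude = NULL) {
  if (is.null(transcripts)) transcripts <- np$anno$transcript_id
  ct <- codon_table(ts)[transcript_id %in% transcripts & codon %in% codons]
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- as.data.table(exclude)[, .(transcript_id, codon_index)]
    ct <- ct[!ex, on = c("transcript_id", "codon_index")]
  }
  if (nrow(ct) == 0) {
    warning("no instances of ", paste(codons, collapse = "/"),
            " in the transcript subset")
    return(data.table(rel = integer(), mean_value = numeric(),
                      n_instances = integer()))
  }
  anchors <- ct[, .(transcript_id, anchor = 3L * codon_index)]
  metagene_at(np, anchors, window)
}

#' Start- and stop-anchored metagenes
#'
#' @param np a `norm_profiles`
#' @param ts the `transcriptome`
#' @param window half-window in nt
#' @param transcripts optional transcript subset
#' @return list with `start` and `stop` metagene tables (as in
#'   [metagene_codon()]); anchor 0 is the first nucleotide of the start /
#'   stop codon
#' @export
metagene_start_stop <- function(np, ts, window = 90L, transcripts = NULL) {
  if (is.null(transcripts)) transcripts <- np$anno$transcript_id
  anno <- np$anno[transcript_id %in% transcripts]
  list(
    start = metagene_at(np, anno[, .(transcript_id, anchor = 0L)], window),
    stop = metagene_at(np, anno[, .(transcript_id,
                                    anchor = cds_length - 3L)], window)
  )
}

#' Find polyproline tracts
#'
#' Maximal runs of `min_run` or more consecutive proline codons
#' (CCA/CCC/CCG/CCT), reported as 0-based half-open codon intervals.
#'
#' @param ts the `transcriptome`
#' @param min_run minimum run length in codons (default 3)
#' @return data.table (transcript_id, start, end) in codon coordinates
#' @export
find_polypro_tracts <- function(ts, min_run = 3L) {
  pro <- proline_codons()
  cds <- cds_sequences(ts)
  out <- lapply(names(cds), function(tid) {
    is_pro <- split_codons(cds[[tid]]) %in% pro
    r <- rle(is_pro)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values & r$lengths >= min_run
    if (!any(sel)) return(NULL)
    data.table(transcript_id = tid, start = starts[sel] - 1L,
               end = ends[sel])
  })
  out <- rbindlist(out)
  if (nrow(out) == 0)
    out <- data.table(transcript_id = character(), start = integer(),
                      end = integer())
  out[]
}

#' Expand tract intervals to per-instance rows
#'
#' @param tracts a [find_polypro_tracts()] table
#' @return data.table (transcript_id, codon_index), one row per codon
#'   inside a tract; suitable for the `exclude` argument of
#'   [codon_occupancy()]
#' @export
polypro_instances <- function(tracts) {
  tracts <- as.data.table(tracts)
  if (nrow(tracts) == 0)
    return(data.table(transcript_id = character(), codon_index = integer()))
  tracts[, .(codon_index = seq.int(start, end - 1L)),
         by = .(transcript_id, start)][, .(transcript_id, codon_index)]
}
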