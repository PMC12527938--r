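# Independent brute-force re-implementations used as oracles. Plain loops,
# no shared code with the package internals.

bf_split_codons <- function(cds) {
  vapply(seq_len(nchar(cds) / 3), function(i)
    substr(cds, 3 * i - 2, 3 * i), "")
}

bf_normalize <- function(depth) depth / mean(depth)

# mean normalized occupancy per codon type over a list of depth vectors
bf_codon_occupancy <- function(depths, cds_list) {
  vals <- list()
  for (tid in names(depths)) {
    norm <- bf_normalize(depths[[tid]])
    codons <- bf_split_codons(cds_list[[tid]])
    for (j in seq_along(codons)) {
      v <- mean(norm[(3 * j - 2):(3 * j)])
      vals[[codons[j]]] <- c(vals[[codons[j]]], v)
    }
  }
  sapply(vals, mean)
}

bf_rdo <- function(occ_a, occ_b) {
  shared <- intersect(names(occ_a), names(occ_b))
  out <- log2(occ_a[shared] / occ_b[shared])
  out[!(occ_a[shared] > 0 & occ_b[shared] > 0)] <- NA
  out
}

bf_pausing_track <- function(norm_a, norm_b) log2((norm_a + 1) / (norm_b + 1))

bf_pausing_sums <- function(track, cds) {
  codons <- bf_split_codons(cds)
  sums <- c(A = 0, C = 0, G = 0, T = 0)
  for (j in seq_along(codons)) {
    v <- sum(track[(3 * j - 2):(3 * j)])
    b <- substr(codons[j], 3, 3)
    sums[b] <- sums[b] + v
  }
  sums
}

bf_third_base_fraction <- function(cds) {
  codons <- bf_split_codons(cds)
  third <- substr(codons, 3, 3)
  c(A = sum(third == "A"), C = sum(third == "C"),
    G = sum(third == "G"), T = sum(third == "T")) / length(codons)
}

# metagene around every instance of `codon`: mean of normalized values at
# each offset, skipping out-of-CDS positions
bf_metagene <- function(depths, cds_list, codon, window) {
  acc <- matrix(NA_real_, 0, 2 * window + 1)
  for (tid in names(depths)) {
    norm <- bf_normalize(depths[[tid]])
    codons <- bf_split_codons(cds_list[[tid]])
    for (j in which(codons == codon)) {
      p0 <- 3 * (j - 1) + 1  # 1-based anchor nt
      row <- rep(NA_real_, 2 * window + 1)
      for (k in -window:window) {
        p <- p0 + k
        if (p >= 1 && p <= length(norm)) row[k + window + 1] <- norm[p]
      }
      acc <- rbind(acc, row)
    }
  }
  colMeans(acc, na.rm = TRUE)
}

# grid-search oracle for 2-source non-negative deconvolution
bf_nnls_grid <- function(M, L, step = 1e-3, upper = 1) {
  grid <- seq(0, upper, by = step)
  best <- c(NA, NA); best_val <- Inf
  for (f1 in grid) for (f2 in grid) {
    r <- M %*% c(f1, f2) - L
    v <- sum(r^2)
    if (v < best_val) { best_val <- v; best <- c(f1, f2) }
  }
  list(f = best, value = best_val)
}
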