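# Codon vocabulary used across the package. Built from Biostrings' standard
# genetic code so stop/sense classification is never hand-typed.

#' All 64 codons in lexicographic order
#' @return character vector of 64 codons over {A,C,G,T}
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Stop codons of the standard genetic code
#' @return character vector (TAA, TAG, TGA)
#' @export
stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  cod <- names(gc)[gc == "*"]
  gsub("U", "T", cod)
}

#' Sense (non-stop) codons
#' @return character vector of 61 codons
#' @export
sense_codons <- function() setdiff(all_codons(), stop_codons())

#' Proline codons
#' @return character vector (CCA, CCC, CCG, CCT)
#' @export
proline_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  gsub("U", "T", names(gc)[gc == "P"])
}

#' Codons with a given third (wobble) base
#'
#' @param base one of "A", "C", "G", "T"
#' @param sense_only drop stop codons (default TRUE)
#' @return character vector of codons ending in `base`
#' @export
codons_ending_in <- function(base, sense_only = TRUE) {
  base <- match.arg(base, c("A", "C", "G", "T"))
  set <- if (sense_only) sense_codons() else all_codons()
  set[substr(set, 3, 3) == base]
}

#' Split a coding sequence into codons
#'
#' @param seq nucleotide string over {A,C,G,T}; length must be a multiple of 3
#' @return character vector of codons
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

# TRUE where a codon matches a dwell-weight pattern: an exact codon ("CCA"),
# an N-wildcard pattern ("NNA"), or the classes "STOP" / "START".
codon_matches <- function(codons, pattern) {
  if (pattern == "STOP") return(codons %in% stop_codons())
  if (pattern == "START") return(codons == "ATG")
  if (nchar(pattern) != 3L)
    stop("dwell pattern must be a 3-letter codon pattern, 'STOP' or 'START': ",
         pattern)
  pat <- strsplit(pattern, "")[[1]]
  hit <- rep(TRUE, length(codons))
  for (i in 1:3) {
    if (pat[i] != "N")
      hit <- hit & substr(codons, i, i) == pat[i]
  }
  hit
}
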