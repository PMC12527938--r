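# Proteomics preprocessing (filter + mixed imputation), pathway-level
# codon-composition summaries, and composition-versus-fold-change
# correlation.

#' Filter and impute a protein intensity table (mixed imputation)
#'
#' Intensities are log2-transformed (unless already logged). Proteins with
#' fewer than `min_valid` (70%) valid values in every group are dropped.
#' Remaining missing values are imputed per group: k-nearest-neighbour over
#' proteins where the group has at least `knn_valid` (60%) valid values for
#' that protein, and otherwise random draws from a down-shifted Gaussian
#' (per sample: mean = observed mean - downshift * sd, sd = width * sd).
#' Observed values are never altered; draws are seeded.
#'
#' @param intensities numeric matrix, proteins x samples (NA = missing);
#'   rownames are protein/gene ids
#' @param groups character/factor of group labels, one per column; at least
#'   2 groups with >= 2 samples each
#' @param log2_transform apply log2 to the raw intensities (default TRUE)
#' @param min_valid minimum valid fraction in at least one group (0.7)
#' @param knn_valid minimum valid fraction in a group for kNN (0.6)
#' @param k neighbours for kNN (default 10)
#' @param width,downshift MinProb Gaussian parameters in units of the
#'   per-sample observed sd (defaults 0.2 and 1.8)
#' @param seed integer seed for the random draws
#' @return list: `data` (complete matrix), `kept` (protein ids),
#'   `dropped` (ids failing the valid filter), `imputed` (logical matrix,
#'   TRUE where a value was imputed)
#' @export
filter_and_impute <- function(intensities, groups, log2_transform = TRUE,
                              min_valid = 0.7, knn_valid = 0.6, k = 10L,
                              width = 0.2, downshift = 1.8, seed = 1L) {
  x <- as.matrix(intensities)
  groups <- as.character(groups)
  if (length(groups) != ncol(x))
    stop("one group label per sample column required")
  if (length(unique(groups)) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 samples")
  if (log2_transform) x <- log2(x)
  glev <- unique(groups)
  valid_frac <- matrix(
    unlist(lapply(glev, function(g)
      rowMeans(!is.na(x[, groups == g, drop = FALSE])))),
    nrow = nrow(x), dimnames = list(rownames(x), glev))
  keep <- apply(valid_frac >= min_valid, 1, any)
  dropped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  valid_frac <- valid_frac[keep, , drop = FALSE]
  imputed <- is.na(x)
  set.seed(seed)
  for (g in glev) {
    cols <- which(groups == g)
    xg <- x[, cols, drop = FALSE]
    knn_rows <- which(valid_frac[, g] >= knn_valid & rowSums(is.na(xg)) > 0)
    for (i in knn_rows)
      xg[i, ] <- knn_impute_row(xg, i, k)
    x[, cols] <- xg
  }
  # remaining gaps: per-sample down-shifted Gaussian draws
  for (j in seq_len(ncol(x))) {
    miss <- which(is.na(x[, j]))
    if (!length(miss)) next
    obs <- x[!imputed[, j], j]
    mu <- mean(obs, na.rm = TRUE)
    s <- sd(obs, na.rm = TRUE)
    x[miss, j] <- rnorm(length(miss), mu - downshift * s, width * s)
  }
  list(data = x, kept = rownames(x), dropped = dropped, imputed = imputed)
}

# impute the NAs of row i of xg from the k nearest complete-enough rows
# (Euclidean distance on shared valid entries, scaled to full length)
knn_impute_row <- function(xg, i, k) {
  target <- xg[i, ]
  miss <- is.na(target)
  if (!any(miss)) return(target)
  cand <- which(seq_len(nrow(xg)) != i)
  d <- rep(Inf, length(cand))
  for (jj in seq_along(cand)) {
    other <- xg[cand[jj], ]
    sh <- !is.na(target) & !is.na(other)
    if (!any(sh) || any(is.na(other[miss]))) next
    d[jj] <- sqrt(sum((target[sh] - other[sh])^2) / sum(sh))
  }
  ok <- which(is.finite(d))
  if (!length(ok)) return(target)  # left for the Gaussian fallback
  nb <- cand[ok[order(d[ok])][seq_len(min(k, length(ok)))]]
  target[miss] <- colMeans(xg[nb, miss, drop = FALSE])
  target
}

#' Pathway-level mean of per-gene fractions
#'
#' Unweighted mean of the member genes' values; genes in several pathways
#' contribute to each. Pathway genes without a computed fraction are
#' skipped with a message; empty pathways are dropped with a warning.
#'
#' @param gene_fractions data.frame with columns `gene_id` and `value`
#'   (e.g. the A column of [gene_third_base_table()])
#' @param gene_sets data.frame with columns `pathway`, `gene_id`
#' @return data.table (pathway, value, n_genes)
#' @export
pathway_fraction <- function(gene_fractions, gene_sets) {
  gf <- as.data.table(gene_fractions)[, .(gene_id, value)]
  gs <- as.data.table(gene_sets)[, .(pathway, gene_id)]
  miss <- setdiff(gs$gene_id, gf$gene_id)
  if (length(miss))
    message(length(miss), " pathway gene(s) without a computed fraction skipped")
  m <- merge(gs, gf, by = "gene_id")
  empty <- setdiff(unique(gs$pathway), unique(m$pathway))
  if (length(empty))
    warning("empty pathway(s) skipped: ", paste(empty, collapse = ", "))
  out <- m[, .(value = mean(value), n_genes = .N), by = pathway]
  setorder(out, pathway)
  out[]
}

#' Correlate pathway codon composition with protein fold change
#'
#' Pearson correlation and ordinary least-squares line of per-pathway mean
#' protein log2 fold change on per-pathway codon fraction. A negative slope
#' indicates that pathways rich in the focal wobble base lose protein under
#' treatment.
#'
#' @param fractions numeric vector of pathway fractions
#' @param log2fc numeric vector of pathway mean protein log2 fold changes
#' @return list: `r`, `p_value`, `slope`, `intercept`, `n`
#' @export
fraction_foldchange_correlation <- function(fractions, log2fc) {
  ok <- is.finite(fractions) & is.finite(log2fc)
  x <- fractions[ok]; y <- log2fc[ok]
  if (length(x) < 3L) stop("need at least 3 pathways")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(x)))
  ct <- cor.test(x, y, method = "pearson")
  fit <- lm(y ~ x)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = length(x))
}

#' Joined per-gene pausing / composition / protein report
#'
#' Joins per-gene pausing sums (A and G buckets), third-base fractions and
#' protein log2 fold changes on the shared gene universe and reports the
#' correlation between the A-bucket pausing sum and the fold change.
#'
#' @param pausing a [pausing_sums()] table (columns gene_id, A, G, ...)
#' @param fractions a [gene_third_base_table()] (gene_id and A fraction)
#' @param protein_fc data.frame with columns `gene_id`, `log2fc`
#' @return list: `table` (data.table ranked by A-bucket pausing sum,
#'   descending) and `correlation` (Pearson r of pausing A-sum vs log2fc,
#'   NA when either side is constant)
#' @export
gene_pausing_protein_report <- function(pausing, fractions, protein_fc) {
  p <- as.data.table(pausing)[, .(gene_id, pausing_A = A, pausing_G = G)]
  fr <- as.data.table(fractions)[, .(gene_id, frac_A = A)]
  pf <- as.data.table(protein_fc)[, .(gene_id, log2fc)]
  out <- merge(merge(p, fr, by = "gene_id"), pf, by = "gene_id")
  if (nrow(out) == 0) stop("no shared genes between pausing and protein tables")
  setorder(out, -pausing_A)
  r <- if (sd(out$pausing_A) == 0 || sd(out$log2fc) == 0) NA_real_
       else cor(out$pausing_A, out$log2fc)
  list(table = out[], correlation = r)
}
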