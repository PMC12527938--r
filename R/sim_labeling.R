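# Forward models for the tracing calculus: serum mass-isotopomer
# distributions consistent with a known turnover flux, tissue labeling
# vectors generated from a known interconversion matrix and known direct
# contributions, and self-consistent interconversion matrices derived from a
# known circulating contribution network.

#' Ground truth for a labeling simulation
#'
#' @param metabolites ordered character vector of metabolite names
#' @param M_true interconversion matrix, entry (X, Y) = normalized labeling
#'   of Y when X is infused; diagonal exactly 1, entries in [0, 1]
#' @param f_true non-negative direct-contribution fractions of each
#'   circulating metabolite to the tissue metabolite (same order)
#' @param noise_sd additive Gaussian noise sd on labeling measurements
#' @param F_true true circulatory turnover flux per metabolite
#'   (nmol min^-1 g^-1), optional
#' @return object of class `labeling_truth`
#' @export
labeling_truth <- function(metabolites, M_true, f_true, noise_sd = 0,
                           F_true = NULL) {
  n <- length(metabolites)
  M_true <- as.matrix(M_true)
  stopifnot(nrow(M_true) == n, ncol(M_true) == n)
  if (any(abs(diag(M_true) - 1) > 1e-12))
    stop("M_true must have unit diagonal")
  if (any(M_true < 0 | M_true > 1)) stop("M_true entries must be in [0, 1]")
  if (any(f_true < 0)) stop("f_true must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  dimnames(M_true) <- list(metabolites, metabolites)
  structure(list(metabolites = metabolites, M_true = M_true,
                 f_true = setNames(as.numeric(f_true), metabolites),
                 noise_sd = noise_sd, F_true = F_true),
            class = "labeling_truth")
}

#' Generate noisy labeling measurements from known ground truth
#'
#' Tissue labeling is `M_true %*% f_true` plus Gaussian noise; serum
#' interconversion measurements are `M_true` plus noise. All values are
#' clipped to [0, 1] (labeling fractions cannot leave the unit interval).
#'
#' @param truth a [labeling_truth()]
#' @param seed integer seed
#' @return list with `M` (noisy interconversion matrix) and `L_tissue`
#'   (noisy tissue labeling vector)
#' @export
gen_labeling <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "labeling_truth"))
  set.seed(seed)
  n <- length(truth$metabolites)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  L0 <- as.numeric(truth$M_true %*% truth$f_true)
  L <- clip01(L0 + rnorm(n, 0, truth$noise_sd))
  M <- truth$M_true + matrix(rnorm(n * n, 0, truth$noise_sd), n, n)
  M <- clip01(M)
  diag(M) <- 1  # infusing X trivially labels X fully
  dimnames(M) <- dimnames(truth$M_true)
  list(M = M, L_tissue = setNames(L, truth$metabolites))
}

#' Generate a serum MID consistent with a known turnover flux
#'
#' Inverts the turnover-flux relation: at pseudo-steady state the
#' fully-labeled serum fraction is R / (R + F_true); the remainder is
#' assigned to M+0. Optional Gaussian noise is applied to the fully-labeled
#' fraction before renormalization.
#'
#' @param F_true true turnover flux (nmol min^-1 g^-1), >= 0
#' @param R tracer infusion rate (nmol min^-1 g^-1), > 0
#' @param C carbon count of the metabolite
#' @param noise_sd Gaussian noise sd on the labeled fraction
#' @param seed integer seed (used when `noise_sd > 0`)
#' @return a [mid_vector()] with fractions summing to 1
#' @export
gen_serum_mid <- function(F_true, R, C, noise_sd = 0, seed = 1L) {
  if (F_true < 0) stop("F_true must be >= 0")
  if (R <= 0) stop("infusion rate R must be > 0")
  lab <- R / (R + F_true)
  if (noise_sd > 0) {
    set.seed(seed)
    lab <- min(max(lab + rnorm(1, 0, noise_sd), 0), 1)
  }
  fractions <- c(1 - lab, rep(0, C - 1L), lab)
  mid_vector(fractions, metabolite = "synthetic")
}

#' Interconversion matrix implied by a circulating contribution network
#'
#' Given a matrix of true direct contributions among circulating nutrients
#' (entry (i, j) = fraction of i derived directly from j; zero diagonal),
#' solves the steady-state labeling balance for each tracer X
#' (l_i = sum_j f_ij l_j for i != X, with l_X = 1) and returns the implied
#' interconversion matrix M with entry (X, Y) = normalized labeling of Y
#' under infusion of X. Used to build self-consistent flux-network truths.
#'
#' @param f_mat n x n matrix of direct contributions, zero diagonal,
#'   row sums <= 1
#' @return n x n interconversion matrix with unit diagonal
#' @export
interconversion_from_contributions <- function(f_mat) {
  f_mat <- as.matrix(f_mat)
  n <- nrow(f_mat)
  stopifnot(ncol(f_mat) == n)
  if (any(diag(f_mat) != 0)) stop("f_mat must have zero diagonal")
  if (any(f_mat < 0)) stop("f_mat must be non-negative")
  M <- diag(1, n)
  dimnames(M) <- dimnames(f_mat)
  for (x in seq_len(n)) {
    others <- setdiff(seq_len(n), x)
    # l_i - sum_{j in others} f_ij l_j = f_ix * 1
    A <- diag(1, n - 1) - f_mat[others, others, drop = FALSE]
    b <- f_mat[others, x]
    l <- solve(A, b)
    M[x, others] <- l
  }
  M
}
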