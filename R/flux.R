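# Steady-state isotope-tracing calculus: turnover fluxes from serum MIDs,
# atom-labeling fractions, normalized labeling, non-negative deconvolution
# of tissue metabolite sources with bootstrap errors, and the circulating
# flux network. All fluxes are per gram body weight at isotopic
# pseudo-steady state; natural-abundance correction of MIDs is assumed done
# upstream.

#' Mass-isotopomer distribution of one metabolite
#'
#' @param fractions numeric vector of length C+1 with fractions of the
#'   M+0 .. M+C forms; must be in [0, 1] and sum to 1 (tolerance 1e-6)
#' @param metabolite metabolite name
#' @return object of class `mid_vector` with fields `fractions` (named
#'   `M+0` ..) and `C` (carbon count)
#' @export
mid_vector <- function(fractions, metabolite = "metabolite") {
  fractions <- as.numeric(fractions)
  C <- length(fractions) - 1L
  if (C < 1L) stop("a MID needs at least M+0 and M+1 entries")
  if (any(fractions < -1e-9 | fractions > 1 + 1e-9))
    stop("MID fractions must lie in [0, 1]")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("MID fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(list(metabolite = metabolite, C = C,
                 fractions = setNames(fractions, paste0("M+", 0:C))),
            class = "mid_vector")
}

#' @export
print.mid_vector <- function(x, ...) {
  cat("MID of", x$metabolite, "(C =", x$C, "):",
      paste(sprintf("%s=%.3f", names(x$fractions), x$fractions),
            collapse = " "), "\n")
  invisible(x)
}

#' Circulatory turnover flux from a fully-labeled tracer infusion
#'
#' F_circ = R * (1 - L_M+C) / L_M+C, where L_M+C is the fully-labeled serum
#' fraction of the infused nutrient at pseudo-steady state and R the tracer
#' infusion rate.
#'
#' @param R infusion rate (nmol min^-1 g^-1), > 0
#' @param mid serum [mid_vector()] of the infused metabolite
#' @return turnover flux (nmol min^-1 g^-1), >= 0
#' @export
fcirc <- function(R, mid) {
  stopifnot(inherits(mid, "mid_vector"))
  if (R <= 0) stop("infusion rate R must be > 0")
  LMC <- unname(mid$fractions[mid$C + 1L])
  if (LMC <= 0)
    stop("fully-labeled fraction is 0: turnover flux is undefined (infinite)")
  R * (1 - LMC) / LMC
}

#' Fraction of labeled carbon atoms in a metabolite
#'
#' L = sum_i i * L_M+i / C. Invariant to renormalization of the MID.
#'
#' @param mid a [mid_vector()]
#' @return atom-labeling fraction in [0, 1]
#' @export
atom_fraction <- function(mid) {
  stopifnot(inherits(mid, "mid_vector"))
  i <- 0:mid$C
  sum(i * mid$fractions) / (mid$C * sum(mid$fractions))
}

#' Carbon-atom circulatory turnover flux
#'
#' F_circ_atom = C * R * (1 - L) / L with L the atom-labeling fraction.
#'
#' @param R infusion rate (nmol min^-1 g^-1)
#' @param C carbon count of the metabolite
#' @param L atom-labeling fraction, in (0, 1]
#' @return atom turnover flux (nmolC min^-1 g^-1)
#' @export
fcirc_atom <- function(R, C, L) {
  if (R <= 0) stop("infusion rate R must be > 0")
  if (L <= 0 || L > 1) stop("atom-labeling fraction must be in (0, 1]")
  C * R * (1 - L) / L
}

#' Normalized labeling of a downstream metabolite
#'
#' L_{Y<-X} = L_Y / L_X, the atom-labeling fraction of Y divided by that of
#' the infused tracer X.
#'
#' @param L_Y atom-labeling fraction of the downstream metabolite
#' @param L_X atom-labeling fraction of the infused tracer, > 0
#' @return unitless normalized labeling
#' @export
normalized_labeling <- function(L_Y, L_X) {
  if (L_X <= 0) stop("tracer did not enrich (L_X = 0)")
  L_Y / L_X
}

#' Non-negative deconvolution of direct metabolite contributions
#'
#' Solves f = argmin || M f - L ||_2 subject to f >= 0 (Lawson-Hanson
#' NNLS), where M is the circulating interconversion matrix (entry (X, i) =
#' normalized labeling of source i under tracer X) and L the normalized
#' tissue labeling vector across tracers. Contributions are not forced to
#' sum to 1; the shortfall 1 - sum(f) is reported as `unexplained`.
#'
#' @param M interconversion matrix (rows = tracers, columns = sources)
#' @param L_k numeric vector of tissue normalized labelings, one per tracer
#' @return object of class `contribution_estimate`: fields `f` (named
#'   non-negative fractions), `residual` (L2 norm), `unexplained`
#' @export
direct_contributions <- function(M, L_k) {
  M <- as.matrix(M)
  if (length(L_k) != nrow(M))
    stop("length(L_k) must equal nrow(M)")
  fit <- pracma::lsqnonneg(M, as.numeric(L_k))
  f <- setNames(fit$x, colnames(M))
  structure(list(f = f,
                 residual = sqrt(sum((M %*% f - L_k)^2)),
                 unexplained = 1 - sum(f),
                 se = NULL),
            class = "contribution_estimate")
}

#' @export
print.contribution_estimate <- function(x, ...) {
  cat("direct contributions (residual", format(x$residual, digits = 4), "):\n")
  tab <- data.frame(f = x$f)
  if (!is.null(x$se)) tab$se <- x$se
  print(tab)
  invisible(x)
}

#' Bootstrap standard errors for direct contributions
#'
#' Repeats the non-negative deconvolution on perturbed inputs: every entry
#' of M and L is drawn from a Normal with the measured mean and standard
#' deviation, clipped at 0 by default (labeling cannot be negative), and the
#' NNLS is re-solved. The SE of each contribution is the standard deviation
#' across simulations. Seeded and reproducible.
#'
#' @param M_mean,M_sd matrices of entrywise means and sds of M
#' @param L_mean,L_sd vectors of means and sds of the tissue labeling
#' @param n_sims number of bootstrap draws
#' @param seed integer seed
#' @param clip clip negative draws at 0 (default TRUE)
#' @return a `contribution_estimate` fitted at the means, with `se` and the
#'   per-draw matrix in `draws`
#' @export
bootstrap_contributions <- function(M_mean, M_sd, L_mean, L_sd,
                                    n_sims = 100L, seed = 1L, clip = TRUE) {
  M_mean <- as.matrix(M_mean); M_sd <- as.matrix(M_sd)
  if (any(M_sd < 0) || any(L_sd < 0)) stop("sds must be >= 0")
  stopifnot(all(dim(M_mean) == dim(M_sd)), length(L_mean) == length(L_sd))
  est <- direct_contributions(M_mean, L_mean)
  set.seed(seed)
  n <- length(est$f)
  draws <- matrix(NA_real_, n_sims, n)
  for (s in seq_len(n_sims)) {
    Mi <- M_mean + matrix(rnorm(length(M_mean), 0, 1), nrow(M_mean)) * M_sd
    Li <- L_mean + rnorm(length(L_mean), 0, 1) * L_sd
    if (clip) { Mi[Mi < 0] <- 0; Li[Li < 0] <- 0 }
    draws[s, ] <- direct_contributions(Mi, Li)$f
  }
  colnames(draws) <- names(est$f)
  est$se <- apply(draws, 2, sd)
  est$draws <- draws
  est
}

#' Circulating nutrient flux network
#'
#' For each circulating nutrient i, the direct contributions from every
#' other nutrient j are estimated by non-negative deconvolution with the
#' self-source excluded (column and row i of M dropped), filling row i of
#' the contribution matrix N. The direct flux from j to i is then
#' N[i, j] * F_circ_atom(i), in nmolC min^-1 g^-1.
#'
#' @param M interconversion matrix among circulating nutrients (unit
#'   diagonal; entry (X, Y) = normalized labeling of Y under tracer X)
#' @param fcirc_atom named vector of carbon-atom turnover fluxes, one per
#'   nutrient (same order as M)
#' @return list with `N` (direct-contribution matrix, zero diagonal) and
#'   `edges` (data.table source, target, flux with positive fluxes only)
#' @export
flux_network <- function(M, fcirc_atom) {
  M <- as.matrix(M)
  n <- nrow(M)
  mets <- colnames(M)
  if (is.null(mets)) mets <- paste0("met", seq_len(n))
  if (length(fcirc_atom) != n)
    stop("need one atom turnover flux per nutrient")
  if (any(is.na(fcirc_atom))) stop("missing atom turnover flux")
  N <- matrix(0, n, n, dimnames = list(mets, mets))
  if (n > 1) {
    for (i in seq_len(n)) {
      keep <- setdiff(seq_len(n), i)
      # rows = tracers X != i, columns = candidate sources j != i,
      # target labeling = L_{i <- X}
      est <- direct_contributions(M[keep, keep, drop = FALSE], M[keep, i])
      N[i, keep] <- est$f
    }
  }
  edges <- rbindlist(lapply(seq_len(n), function(i) {
    data.table(source = mets, target = mets[i],
               flux = N[i, ] * as.numeric(fcirc_atom)[i])
  }))
  edges <- edges[flux > 0 & source != target]
  setorder(edges, -flux)
  list(N = N, edges = edges[])
}
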