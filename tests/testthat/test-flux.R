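# Turnover fluxes, atom fractions, normalized labeling, non-negative
# deconvolution and the circulating flux network.

test_that("fcirc follows its closed form and monotonicity", {
  expect_equal(fcirc(10, mid_vector(c(0, 1))), 0)          # fully labeled
  expect_equal(fcirc(10, mid_vector(c(0.5, 0.5))), 10)     # symmetry point
  # round trip with the generator inversion
  expect_equal(fcirc(10, gen_serum_mid(F_true = 90, R = 10, C = 6)), 90,
               tolerance = 1e-9)
  # strictly decreasing in the fully-labeled fraction
  lmc <- seq(0.05, 1, by = 0.05)
  f <- vapply(lmc, function(l) fcirc(5, mid_vector(c(1 - l, 0, l))), 1)
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 0))
  expect_error(fcirc(10, mid_vector(c(1, 0))), "undefined")
})

test_that("atom fraction: limits, hand example, renormalization invariance", {
  expect_equal(atom_fraction(mid_vector(c(1, 0, 0))), 0)
  expect_equal(atom_fraction(mid_vector(c(0, 0, 1))), 1)
  expect_equal(atom_fraction(mid_vector(c(0.5, 0.2, 0.2, 0.1))), 0.3)
  # invariance: scaling fractions (pre-normalization) leaves L unchanged
  m <- mid_vector(c(0.5, 0.2, 0.2, 0.1))
  m2 <- m; m2$fractions <- m$fractions * 2   # bypass constructor on purpose
  expect_equal(atom_fraction(m2), atom_fraction(m))
  # bounded by min/max isotopomer index over C
  expect_true(atom_fraction(m) >= 0 && atom_fraction(m) <= 1)
})

test_that("atom turnover flux reduces to fcirc for binary MIDs", {
  expect_equal(fcirc_atom(2, 5, 0.2), 40)
  expect_equal(fcirc_atom(3, 4, 1), 0)
  mid <- mid_vector(c(0.7, 0.3))  # C = 1: binary by construction
  expect_equal(fcirc_atom(6, 1, atom_fraction(mid)), fcirc(6, mid))
  expect_error(fcirc_atom(2, 5, 0), "fraction")
})

test_that("normalized labeling is the tracer-relative ratio", {
  expect_equal(normalized_labeling(0.2, 0.2), 1)
  expect_equal(normalized_labeling(0, 0.2), 0)
  expect_equal(normalized_labeling(0.04, 0.2), 0.2)
  expect_error(normalized_labeling(0.1, 0), "enrich")
})

test_that("non-negative deconvolution attains the grid-search optimum", {
  M <- matrix(c(1, 0.4, 0.25, 1), 2, 2)
  L <- as.numeric(M %*% c(0.35, 0.48))
  est <- direct_contributions(M, L)
  grid <- bf_nnls_grid(M, L, step = 1e-3)
  expect_equal(unname(est$f), grid$f, tolerance = 2e-3)
  # a case where the unconstrained optimum is infeasible
  L2 <- c(0.1, 0.6)
  est2 <- direct_contributions(M, L2)
  expect_true(all(est2$f >= 0))
  grid2 <- bf_nnls_grid(M, L2, step = 1e-3)
  expect_lte(est2$residual^2, grid2$value + 1e-9)
  # NNLS residual never beats projected unconstrained least squares
  proj <- pmax(solve(M, L2), 0)
  expect_lte(est2$residual, sqrt(sum((M %*% proj - L2)^2)) + 1e-12)
})

test_that("identity mixing and zero labeling are recovered trivially", {
  est <- direct_contributions(diag(2), c(0.3, 0.7))
  expect_equal(unname(est$f), c(0.3, 0.7))
  expect_equal(direct_contributions(diag(3), rep(0, 3))$f, rep(0, 3),
               ignore_attr = TRUE)
  expect_error(direct_contributions(diag(2), c(1, 2, 3)), "nrow")
})

test_that("noiseless synthetic labeling recovers contributions exactly", {
  M <- matrix(c(1, 0.3, 0.15, 0.2, 1, 0.4, 0.1, 0.25, 1), 3, 3)
  f_true <- c(0.5, 0.2, 0.1)
  truth <- labeling_truth(c("pro", "arg", "gln"), M, f_true, noise_sd = 0)
  lab <- gen_labeling(truth, seed = 1)
  est <- direct_contributions(lab$M, lab$L_tissue)
  expect_equal(unname(est$f), f_true, tolerance = 1e-8)
  expect_equal(est$unexplained, 1 - sum(f_true), tolerance = 1e-8)
})

test_that("bootstrap SEs are zero without noise, reproducible, and unbiased", {
  M <- matrix(c(1, 0.3, 0.15, 0.2, 1, 0.4, 0.1, 0.25, 1), 3, 3)
  f_true <- c(0.5, 0.2, 0.1)
  L <- as.numeric(M %*% f_true)
  b0 <- bootstrap_contributions(M, M * 0, L, rep(0, 3), seed = 3)
  expect_equal(unname(b0$se), rep(0, 3))
  sdm <- matrix(0.01, 3, 3); sdl <- rep(0.01, 3)
  b1 <- bootstrap_contributions(M, sdm, L, sdl, n_sims = 100, seed = 5)
  b2 <- bootstrap_contributions(M, sdm, L, sdl, n_sims = 100, seed = 5)
  expect_identical(b1$se, b2$se)
  bias <- abs(colMeans(b1$draws) - f_true)
  expect_true(all(bias < 0.02))
  expect_error(bootstrap_contributions(M, -sdm, L, sdl), "sds")
})

test_that("flux network recovers a three-node synthetic truth", {
  f_true <- matrix(c(0, 0.30, 0.20,
                     0.45, 0, 0.25,
                     0.20, 0.25, 0), 3, 3, byrow = TRUE,
                   dimnames = list(c("pro", "arg", "gln"),
                                   c("pro", "arg", "gln")))
  M <- interconversion_from_contributions(f_true)
  fa <- c(pro = 120, arg = 80, gln = 300)
  net <- flux_network(M, fa)
  expect_equal(net$N, f_true, tolerance = 1e-8)
  # edge flux j -> i = N[i, j] * F_atom(i)
  edge <- net$edges[net$edges$source == "arg" & net$edges$target == "pro", ]
  expect_equal(edge$flux, 0.30 * 120, tolerance = 1e-6)
  # noisy inputs: recovery within 5% at noise sd 0.005
  set.seed(11)
  Mn <- pmin(pmax(M + matrix(rnorm(9, 0, 0.005), 3, 3), 0), 1); diag(Mn) <- 1
  netn <- flux_network(Mn, fa)
  rel_err <- abs(netn$N[f_true > 0] - f_true[f_true > 0]) / f_true[f_true > 0]
  expect_true(all(rel_err < 0.05))
  # unit coherence: fluxes scale linearly with the turnover fluxes
  net2 <- flux_network(M, fa * 2)
  expect_equal(net2$edges$flux, net$edges$flux * 2, tolerance = 1e-9)
  # degenerate sizes
  expect_identical(nrow(flux_network(matrix(1, 1, 1,
    dimnames = list("pro", "pro")), c(pro = 10))$edges), 0L)
  M0 <- diag(2); dimnames(M0) <- list(c("a", "b"), c("a", "b"))
  expect_identical(nrow(flux_network(M0, c(a = 1, b = 1))$edges), 0L)
  expect_error(flux_network(M, fa[1:2]), "per nutrient")
})
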