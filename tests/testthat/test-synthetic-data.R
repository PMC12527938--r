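# The generators are the ground truth for every downstream recovery test,
# so their own guarantees (determinism, composition, generative law) are
# checked first.

test_that("sim_config validates its invariants", {
  expect_error(sim_config(cds_length_range = c(100L, 600L)), "multiples of 3")
  expect_error(sim_config(stall_multipliers = list(t = c(NNA = -1))),
               "positive")
  expect_error(sim_config(footprint_lengths = c(28L, 30L),
                          psite_offset = c(`28` = 12L)), "psite_offset")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("generated CDSs are well-formed and match degenerate bias", {
  cfg <- sim_config(n_genes = 30, codon_bias = list(cc = c(A = 1, C = 0, G = 0, T = 0)),
                    seed = 7)
  ts <- gen_transcriptome(cfg)
  cds <- cds_sequences(ts)
  for (s in cds) {
    expect_identical(nchar(s) %% 3L, 0L)
    expect_identical(substr(s, 1, 3), "ATG")
    expect_true(substr(s, nchar(s) - 2, nchar(s)) %in% stop_codons())
    internal <- split_codons(s)
    internal <- internal[-c(1, length(internal))]
    expect_true(all(substr(internal, 3, 3) == "A"))  # degenerate A weight
    expect_false(any(internal %in% stop_codons()))
  }
})

test_that("same seed gives byte-identical transcriptomes and reads", {
  cfg <- sim_config(n_genes = 20, read_depth = 5e3, seed = 7)
  t1 <- gen_transcriptome(cfg); t2 <- gen_transcriptome(cfg)
  expect_identical(t1$transcripts, t2$transcripts)
  r1 <- gen_footprints(t1, cfg, seed = 99)
  r2 <- gen_footprints(t2, cfg, seed = 99)
  expect_identical(r1, r2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_cds_fasta(t1, f1, cds_only = TRUE); write_cds_fasta(t2, f2, cds_only = TRUE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("third-base bias difference between gene sets matches the weights", {
  cfg <- sim_config(n_genes = 300, cds_length_range = c(300L, 600L),
                    codon_bias = list(cc = c(A = 0.4, C = 0.2, G = 0.2, T = 0.2),
                                      neuro = c(A = 0.1, C = 0.3, G = 0.3, T = 0.3)),
                    seed = 11)
  ts <- gen_transcriptome(cfg)
  # exclude the fixed start/stop codons so the multinomial expectation is exact
  tb <- gene_third_base_table(ts, include_start_stop = FALSE)
  mean_a <- tapply(tb$A, tb$gene_set, mean)
  # per-gene sd ~ sqrt(p(1-p)/K) <= 0.05; mean over 150 genes: sd < 0.005
  expect_equal(unname(mean_a["cc"] - mean_a["neuro"]), 0.3, tolerance = 0.02)
})

test_that("footprint P-site marginal follows the generative law (chi-square GOF)", {
  cfg <- sim_config(n_genes = 10, cds_length_range = c(150L, 300L),
                    read_depth = 2e5, init_weight = 1, seed = 5)
  ts <- gen_transcriptome(cfg)
  reads <- gen_footprints(ts, cfg, "control", seed = 21)
  off <- cfg$psite_offset
  prof <- psite_profiles(reads, off, ts)
  w <- dwell_weights(ts, cfg, "control")
  anno <- ts$transcripts
  w$p <- anno$expr[match(w$transcript_id, anno$transcript_id)] /
    sum(anno$expr)
  w$p <- w$p * stats::ave(w$weight, w$transcript_id,
                          FUN = function(x) 1 / sum(x)) * w$weight
  cnt <- prof$counts
  cnt$codon_index <- cnt$pos %/% 3L
  obs <- merge(w[, c("transcript_id", "codon_index", "p")],
               cnt[, .(depth = sum(depth)), by = .(transcript_id, codon_index)],
               by = c("transcript_id", "codon_index"), all.x = TRUE)
  obs$depth[is.na(obs$depth)] <- 0L
  gof <- suppressWarnings(
    chisq.test(obs$depth, p = obs$p / sum(obs$p)))
  expect_gt(gof$p.value, 1e-3)
  expect_identical(sort(unique(reads$length)), c(28L, 29L))
})

test_that("injected stalling raises occupancy at matching codons only", {
  cfg <- sim_config(n_genes = 60, read_depth = 4e5,
                    stall_multipliers = list(trt = c(NNA = 2.0)), seed = 13)
  ts <- gen_transcriptome(cfg)
  occ <- function(cond, seed) {
    reads <- gen_footprints(ts, cfg, cond, seed = seed)
    np <- normalize_profiles(psite_profiles(reads, cfg$psite_offset, ts))
    codon_occupancy(np, ts)
  }
  r <- rdo(occ("trt", 31), occ("control", 32))
  r <- r[r$codon %in% sense_codons() & r$codon != "ATG", ]
  third <- substr(r$codon, 3, 3)
  ratio_a <- mean(2^r$rdo[third == "A"])
  ratio_g <- mean(2^r$rdo[third == "G"])
  # analytic: occupancy ratio at NNA ~ 2x the NNG ratio (both shrunk by the
  # per-gene renormalization); compare against the closed-form oracle
  exp_t <- expected_codon_occupancy(ts, cfg, "trt")
  exp_c <- expected_codon_occupancy(ts, cfg, "control")
  m <- merge(exp_t, exp_c, by = "codon")
  m <- m[m$codon != "ATG", ]
  third_m <- substr(m$codon, 3, 3)
  exp_ratio_a <- mean(m$occupancy.x[third_m == "A"] / m$occupancy.y[third_m == "A"])
  exp_ratio_g <- mean(m$occupancy.x[third_m == "G"] / m$occupancy.y[third_m == "G"])
  expect_equal(ratio_a / ratio_g, exp_ratio_a / exp_ratio_g, tolerance = 0.05)
  expect_equal(ratio_a / ratio_g, 2, tolerance = 0.1)
})

test_that("read_depth = 0 yields an empty read table", {
  cfg <- sim_config(n_genes = 5, read_depth = 0, seed = 2)
  ts <- gen_transcriptome(cfg)
  reads <- gen_footprints(ts, cfg)
  expect_identical(nrow(reads), 0L)
  expect_named(reads, c("transcript_id", "five_prime_pos", "length"))
})

test_that("labeling generator honours its closed forms and determinism", {
  tr <- labeling_truth(c("pro", "arg"), diag(2), c(0.3, 0.7), noise_sd = 0)
  lab <- gen_labeling(tr, seed = 4)
  expect_equal(unname(lab$L_tissue), c(0.3, 0.7))
  M <- matrix(c(1, 0.3, 0.2, 1), 2, 2)
  tr2 <- labeling_truth(c("pro", "arg"), M, c(0.5, 0.2), noise_sd = 0)
  expect_equal(unname(gen_labeling(tr2, 1)$L_tissue),
               as.numeric(M %*% c(0.5, 0.2)))
  tr3 <- labeling_truth(c("pro", "arg"), M, c(0.5, 0.2), noise_sd = 0.05)
  expect_identical(gen_labeling(tr3, 8), gen_labeling(tr3, 8))
  expect_true(all(gen_labeling(tr3, 8)$M <= 1 & gen_labeling(tr3, 8)$M >= 0))
  expect_error(labeling_truth(c("a", "b"), diag(2), c(0.1, 0.2), noise_sd = -1),
               "noise_sd")
})

test_that("serum MID generator inverts the turnover relation", {
  mid <- gen_serum_mid(F_true = 90, R = 10, C = 6)
  expect_equal(unname(mid$fractions[["M+6"]]), 0.1)
  expect_equal(sum(mid$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(gen_serum_mid(0, 10, 3)$fractions[["M+3"]]), 1)
  expect_equal(unname(gen_serum_mid(10, 10, 3)$fractions[["M+3"]]), 0.5)
})
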