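mk_paired <- function(te_a, te_b, rna_a = 10, rna_b = 10) {
  n <- length(te_a)
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n)),
    te_a = te_a, te_b = te_b,
    te_ratio = te_a / te_b,
    rna_tpm_a = rep_len(rna_a, n), rna_tpm_b = rep_len(rna_b, n),
    rna_ratio = rep_len(rna_a, n) / rep_len(rna_b, n),
    both_defined = !is.na(te_a) & !is.na(te_b) & te_b > 0)
}

test_that("DTT calling uses a strict fold threshold and the expression gate", {
  paired <- mk_paired(te_a = c(5.0, 5.0, 1.0, 8.0),
                      te_b = c(0.4, 0.5, 1.0, 0.5))
  # ratios: 12.5 (DTT), exactly 10 (not, strict), 1, 16
  paired$rna_tpm_b[4] <- 0.5  # fails the TPM > 1 gate in cell type B
  called <- call_dtts(paired, fold = 10, expression_gate = 1)
  expect_equal(called, "g01")
  flagged <- flag_dtts(paired)
  expect_equal(flagged$is_dtt, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("DTT calling is anti-symmetric under swapping cell types", {
  set.seed(21)
  n <- 200
  paired <- mk_paired(te_a = rlnorm(n, 0, 1.5), te_b = rlnorm(n, 0, 1.5))
  fold <- 10
  fwd <- call_dtts(paired, fold = fold)
  swapped <- paired
  swapped$te_a <- paired$te_b
  swapped$te_b <- paired$te_a
  swapped$te_ratio <- swapped$te_a / swapped$te_b
  swapped$rna_tpm_a <- paired$rna_tpm_b
  swapped$rna_tpm_b <- paired$rna_tpm_a
  rev <- call_dtts(swapped, fold = fold)
  expect_setequal(rev, paired$gene_id[!is.na(paired$te_ratio) &
                                        paired$te_ratio < 1 / fold])
  expect_length(intersect(fwd, rev), 0)
})

test_that("planted large-fold genes are recovered exactly at deep sampling", {
  # 20 genes with true ratio 20x and 180 with 1x, counts deep enough that
  # the >10x rule separates them cleanly
  set.seed(31)
  n <- 200
  base <- rlnorm(n, 0, 0.9)
  idx <- 1:20
  te_a <- base
  te_b <- base
  te_b[idx] <- base[idx] / 20
  noise <- function(x) x * exp(rnorm(n, 0, 0.1))
  paired <- mk_paired(noise(te_a), noise(te_b))
  called <- call_dtts(paired)
  expect_setequal(called, paired$gene_id[idx])
})

test_that("TE spread uses linear-interpolation percentiles", {
  expect_equal(te_spread(rep(2.5, 30)), 1.0)
  # hand computation for 1..10 at type-7 interpolation:
  # p5 -> 1.45, p95 -> 9.55 (small samples warn)
  expect_warning(sp10 <- te_spread(1:10 * 1.0, 5, 95), "fewer than 20")
  expect_equal(sp10, 9.55 / 1.45, tolerance = 1e-12)
  # log-uniform over [1, 100]: q95/q5 = 100^0.9
  set.seed(41)
  te <- 10^stats::runif(2e4, 0, 2)
  expect_equal(te_spread(te), 100^0.9, tolerance = 0.05)
  # invariant under positive scaling
  expect_equal(te_spread(te * 37), te_spread(te), tolerance = 1e-9)
  expect_error(te_spread(numeric(0)), "at least 2")
  expect_warning(te_spread(1:5), "fewer than 20")
  expect_warning(sp0 <- te_spread(c(rep(0, 10), 1:15)), "zero")
  expect_true(is.na(sp0))
})

test_that("TE histogram uses left-closed log2 bins on a fixed lattice", {
  h <- te_histogram(c(1, 2, 2.1, 0.5))
  # log2 values 0, 1, ~1.07, -1
  expect_equal(h$count[h$bin_left == 0], 1L)    # te = 1 in [0, 0.2)
  expect_equal(h$count[h$bin_left == 1], 2L)    # te = 2 and 2.1 in [1, 1.2)
  expect_equal(h$count[h$bin_left == -1], 1L)
  expect_equal(sum(h$count), 4L)
  # conservation on a larger draw
  set.seed(51)
  te <- rlnorm(5000, 0, 1)
  expect_equal(sum(te_histogram(te)$count), 5000L)
  expect_error(te_histogram(c(1, 0)), "positive")
})

test_that("squared Pearson correlation handles exact, noisy and degenerate input", {
  x <- 1:50
  expect_equal(correlation_r2(x, 2 * x), 1.0)
  # hand arithmetic: (1,2),(2,3),(3,5) -> r^2 = 27/28
  expect_equal(correlation_r2(c(1, 2, 3), c(2, 3, 5)), 27 / 28,
               tolerance = 1e-12)
  set.seed(61)
  expect_lt(correlation_r2(rnorm(1e4), rnorm(1e4)), 0.01)
  expect_warning(r0 <- correlation_r2(rep(1, 10), 1:10), "zero variance")
  expect_true(is.na(r0))
  # log transform excludes nonpositive pairs
  expect_equal(correlation_r2(c(10, 100, 1000, 0), c(1, 2, 4, 5),
                              log_transform = TRUE),
               correlation_r2(log10(c(10, 100, 1000)), log10(c(1, 2, 4))))
})

test_that("mRNA-ratio binning assigns genes by direct edge comparison and keeps empty bins", {
  paired <- mk_paired(te_a = c(1, 2, 3, 4), te_b = c(2, 1, 4, 8))
  paired$rna_ratio <- c(0.3, 1.0, 2.5, 40)   # log2: -1.74, 0, 1.32, 5.3 (out)
  bins <- bin_by_mrna_ratio(paired, bin_edges = c(-2, 0, 2, 4))
  expect_named(bins, c("[-2,0)", "[0,2)", "[2,4)"))
  expect_equal(bins[["[-2,0)"]], 2)           # te_b of gene 1
  expect_setequal(bins[["[0,2)"]], c(1, 4))   # log2 ratio 0 is left-closed
  expect_length(bins[["[2,4)"]], 0)           # retained though empty
  # all ratios equal -> one occupied bin
  paired2 <- mk_paired(te_a = 1:4, te_b = 1:4)
  bins2 <- bin_by_mrna_ratio(paired2, bin_edges = c(-1, 1))
  expect_equal(lengths(bins2), c("[-1,1)" = 4L))
})

test_that("simulated mRNA/TE coupling yields monotone per-bin glial TE medians", {
  cfg <- simulation_config(n_genes = 300, n_dtt = 0, mrna_te_coupling = 0.5,
                           depth_fp = 6e5, depth_rna = 1e6, seed = 17)
  sim <- simulate_experiment(cfg)
  mode <- processing_mode("ip")
  ps <- suppressMessages(assign_psites(
    suppressMessages(length_filter(sim$fragments, mode)), mode, sim$catalog))
  fp <- region_tpm(region_rpm(suppressMessages(
    count_by_region(ps, sim$catalog))))
  te <- translational_efficiency(fp, rna_tpm_table(sim$rna_counts,
                                                   sim$catalog))
  paired <- pair_te_tables(te)
  gate <- expression_filter(rna_tpm_table(sim$rna_counts, sim$catalog))
  bins <- bin_by_mrna_ratio(paired[paired$gene_id %in% gate, ],
                            bin_edges = c(-4, -1, 1, 4))
  meds <- vapply(bins, stats::median, numeric(1))
  expect_true(all(lengths(bins) >= 15))
  # genes transcribed less in glia (high neuron/glia ratio) have lower
  # glial TE: medians strictly decrease across the ratio bins
  expect_true(all(diff(meds) < 0))
  # and the wrapper test detects the distributional shift
  kt <- rank_test_groups(bins)
  expect_lt(kt$p.value, 1e-4)
})
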