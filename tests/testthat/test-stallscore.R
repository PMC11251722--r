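uniform_psites <- function(tx, len, per_nt = 1L, sample = "s") {
  tibble::tibble(transcript_id = tx,
                 psite = rep(0:(len - 1L), each = per_nt),
                 length = 28L, sample = sample, region = "CDS")
}

test_that("accumulation score self-normalizes to 1 on uniform coverage", {
  models <- tibble::tibble(transcript_id = "t", gene_id = "g", length = 300L,
                           cds_start = 0L, cds_end = 300L)
  cat <- gene_catalog(models)
  ps <- uniform_psites("t", 300L)
  sc <- codon_accumulation_score(ps, cat, "t", codon_position = 150L)
  expect_equal(sc$score, 1.0)
  expect_equal(sc$reads_at_codon, 3L)
  expect_false(sc$low_confidence)
})

test_that("a focal pile-up over a flat background follows the tiling arithmetic", {
  models <- tibble::tibble(transcript_id = "t", gene_id = "g", length = 303L,
                           cds_start = 0L, cds_end = 303L)
  cat <- gene_catalog(models)
  # one P-site at the first base of every 3-nt tile, plus 9 extra at the
  # focal codon start: focal tile 10, other tiles 1
  base <- tibble::tibble(transcript_id = "t",
                         psite = seq(0L, 300L, by = 3L),
                         length = 28L, sample = "s", region = "CDS")
  extra <- base[rep(51, 9), ]   # psite 150
  ps <- rbind(base, extra)
  sc <- codon_accumulation_score(ps, cat, "t", codon_position = 150L)
  # full +/-50 window: 33 tiles, focal 10, 32 others 1
  expect_equal(sc$score, 10 / (42 / 33), tolerance = 1e-12)
  sc_excl <- codon_accumulation_score(ps, cat, "t", codon_position = 150L,
                                      include_focal = FALSE)
  expect_equal(sc_excl$score, 10.0)
})

test_that("zero-coverage windows are undefined and short windows flagged low-confidence", {
  models <- tibble::tibble(transcript_id = "t", gene_id = "g", length = 120L,
                           cds_start = 0L, cds_end = 120L)
  cat <- gene_catalog(models)
  empty <- uniform_psites("t", 120L)[0, ]
  sc <- codon_accumulation_score(empty, cat, "t", 60L)
  expect_true(is.na(sc$score))
  # a codon at the very start of a short transcript has a clipped window
  models2 <- tibble::tibble(transcript_id = "u", gene_id = "g2",
                            length = 21L, cds_start = 0L, cds_end = 21L)
  cat2 <- gene_catalog(models2)
  sc2 <- codon_accumulation_score(uniform_psites("u", 21L), cat2, "u", 0L)
  expect_true(sc2$low_confidence)
})

test_that("vectorized scores match the brute-force tiling oracle", {
  set.seed(91)
  for (i in 1:20) {
    len <- 3L * sample(30:120, 1)
    models <- tibble::tibble(transcript_id = "t", gene_id = "g",
                             length = len, cds_start = 0L, cds_end = len)
    cat <- gene_catalog(models)
    counts <- rpois(len, 0.5)
    ps <- tibble::tibble(transcript_id = "t",
                         psite = rep(0:(len - 1L), counts),
                         length = 28L, sample = "s", region = "CDS")
    pos <- sample(seq(0L, len - 3L, by = 3L), 10)
    got <- stall_score_table(ps, cat,
                             tibble::tibble(transcript_id = "t",
                                            codon_position = pos))
    want <- vapply(pos, function(p) {
      oracle_codon_score(counts, p, len)
    }, numeric(1))
    expect_equal(got$score, want)
  }
})

test_that("CDS codon sites exclude the annotated start and stop codons", {
  cat <- toy_catalog()
  sites <- cds_codon_sites(cat)
  t1 <- sites[sites$transcript_id == "t1", ]
  # CDS 12..42: codons at 12 (start) and 39 (stop) must be absent
  expect_false(12L %in% t1$codon_position)
  expect_false(39L %in% t1$codon_position)
  expect_equal(t1$codon_position, seq(15L, 36L, by = 3L))
  expect_equal(t1$codon, rep("GCU", 8))
  expect_equal(unique(sites$region), "CDS")
})

test_that("leader codon sites cover upstream starts, optionally with frame mates", {
  cat <- toy_catalog()
  sites <- leader_codon_sites(cat)
  expect_equal(sites$codon_position, 2L)   # the planted uAUG on t1
  expect_equal(sites$codon, "AUG")
  with_mates <- leader_codon_sites(cat, include_frame_mates = TRUE)
  # frame of position 2 on a 12-nt leader: positions 2, 5, 8
  expect_setequal(with_mates$codon_position[with_mates$transcript_id == "t1"],
                  c(2L, 5L, 8L))
})

test_that("simulated glial uAUG stalls raise the AUG score above all other leader codons", {
  cfg <- simulation_config(n_genes = 120, n_dtt = 0, stall_genes = "all",
                           uorf_rate = 3, depth_fp = 6e5, depth_rna = 2e5,
                           seed = 29)
  sim <- simulate_experiment(cfg)
  mode <- processing_mode("ip")
  ps <- suppressMessages(assign_psites(
    suppressMessages(length_filter(sim$fragments, mode)), mode, sim$catalog))
  sites <- leader_codon_sites(sim$catalog, include_frame_mates = TRUE)
  scores <- stall_score_table(ps, sim$catalog, sites, sample = "glia")
  agg <- aggregate_scores_by_codon(scores, "leader")
  agg <- agg[agg$n >= 5, ]
  aug <- agg$median_score[agg$codon == "AUG"]
  others <- agg$median_score[agg$codon != "AUG"]
  expect_gt(aug, max(others, na.rm = TRUE))
})

test_that("per-codon aggregation retains all 64 codons in stable order", {
  cat <- toy_catalog()
  ps <- uniform_psites("t1", 60L)
  scores <- stall_score_table(ps, cat, cds_codon_sites(cat))
  agg <- aggregate_scores_by_codon(scores, "CDS")
  expect_equal(nrow(agg), 64L)
  expect_equal(agg$codon, sort(agg$codon))
  expect_equal(agg$n[agg$codon == "GCU"], 8L)
  expect_equal(agg$median_score[agg$codon == "GCU"], 1.0)
  expect_true(all(agg$n[agg$codon != "GCU"] == 0L))
})

test_that("start-codon accumulation separates cell types by the simulated boost", {
  cfg <- simulation_config(n_genes = 40, n_dtt = 0, depth_fp = 3e5,
                           depth_rna = 2e5,
                           start_stall_boost = c(neuron = 8, glia = 1),
                           seed = 12)
  sim <- simulate_experiment(cfg)
  mode <- processing_mode("ip")
  ps <- suppressMessages(assign_psites(
    suppressMessages(length_filter(sim$fragments, mode)), mode, sim$catalog))
  an <- start_codon_accumulation(ps, sim$catalog, sample = "neuron")
  ag <- start_codon_accumulation(ps, sim$catalog, sample = "glia")
  j <- dplyr::inner_join(an, ag, by = "gene_id", suffix = c("_n", "_g"))
  ratio <- stats::median(j$score_n / j$score_g, na.rm = TRUE)
  expect_gt(ratio, 4)               # boosted cell type piles up on starts
  expect_gt(stats::median(j$score_n, na.rm = TRUE),
            stats::median(j$score_g, na.rm = TRUE))
  # ranked output: defined scores first, descending
  expect_false(is.unsorted(rev(an$score[!is.na(an$score)])))
})

test_that("scores are depth-scale invariant in expectation", {
  # Poisson read fields at two depths over the same intensity landscape
  set.seed(37)
  len <- 300L
  lambda <- rep(1, len); lambda[151:153] <- 6
  models <- tibble::tibble(transcript_id = "t", gene_id = "g", length = len,
                           cds_start = 0L, cds_end = len)
  cat <- gene_catalog(models)
  score_once <- function(scale) {
    counts <- rpois(len, lambda * scale)
    ps <- tibble::tibble(transcript_id = "t",
                         psite = rep(0:(len - 1L), counts), length = 28L,
                         sample = "s", region = "CDS")
    codon_accumulation_score(ps, cat, "t", 150L)$score
  }
  lo <- mean(replicate(60, score_once(1)), na.rm = TRUE)
  hi <- mean(replicate(60, score_once(10)), na.rm = TRUE)
  expect_equal(lo / hi, 1, tolerance = 0.1)
})
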