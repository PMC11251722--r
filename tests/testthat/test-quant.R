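test_that("region counting produces a complete gene x region x sample grid", {
  cat <- toy_catalog()  # t1/g1: leader 12, CDS 30, utr3 18; t2/g2 leaderless
  ps <- tibble::tibble(
    transcript_id = c(rep("t1", 5), "t2"),
    psite = c(13L, 20L, 30L, 2L, 5L, 10L),
    length = 28L,
    sample = c(rep("s1", 5), "s2"),
    region = c("CDS", "CDS", "CDS", "leader", "leader", "CDS"))
  tab <- suppressMessages(count_by_region(ps, cat))
  get <- function(g, r, s) tab$raw_count[tab$gene_id == g & tab$region == r &
                                           tab$sample == s]
  expect_equal(get("g1", "CDS", "s1"), 3)
  expect_equal(get("g1", "leader", "s1"), 2)
  expect_equal(get("g1", "utr3", "s1"), 0)   # zero rows are present
  expect_equal(get("g1", "full", "s1"), 5)
  # samples are kept separate
  expect_equal(get("g1", "CDS", "s2"), 0)
  expect_equal(get("g2", "CDS", "s2"), 1)
  # per-sample conservation across region rows
  for (s in c("s1", "s2")) {
    expect_equal(sum(tab$raw_count[tab$region != "full" & tab$sample == s]),
                 sum(tab$raw_count[tab$region == "full" & tab$sample == s]))
  }
})

test_that("region counts match a record-by-record oracle on simulated labels", {
  sim <- simulate_transcriptome(simulation_config(n_genes = 15, seed = 3))
  models <- sim$catalog$models
  set.seed(8)
  n <- 1e4
  tx <- sample(models$transcript_id, n, TRUE)
  m <- match(tx, models$transcript_id)
  psite <- floor(stats::runif(n) * models$length[m])
  ps <- tibble::tibble(
    transcript_id = tx, psite = as.integer(psite), length = 28L,
    sample = sample(c("a", "b"), n, TRUE),
    region = dplyr::case_when(psite < models$cds_start[m] ~ "leader",
                              psite < models$cds_end[m] ~ "CDS",
                              TRUE ~ "utr3"))
  tab <- suppressMessages(count_by_region(ps, sim$catalog))
  want <- oracle_region_counts(ps, models)
  got <- tab[tab$region != "full" & tab$raw_count > 0, ]
  key <- function(d) paste(d$gene_id, d$region, d$sample)
  expect_setequal(key(got), key(want))
  expect_equal(got$raw_count[match(key(want), key(got))], want$raw_count)
})

test_that("TPM normalization follows the density formula within region classes", {
  # two genes, equal counts, equal lengths -> 500k each
  expect_equal(tpm_from_counts(c(5, 5), c(100, 100)), c(5e5, 5e5))
  # counts (10, 10), lengths (100, 200)
  expect_equal(tpm_from_counts(c(10, 10), c(100, 200)),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  # single gene with any nonzero count
  expect_equal(tpm_from_counts(7, 300), 1e6)
  # all-zero counts are undefined
  expect_true(all(is.na(tpm_from_counts(c(0, 0), c(10, 10)))))

  cat <- toy_catalog()
  ps <- tibble::tibble(transcript_id = c("t1", "t1", "t2"),
                       psite = c(15L, 2L, 4L), length = 28L, sample = "s",
                       region = c("CDS", "leader", "CDS"))
  # (the empty utr3 class warns that its TPM is undefined)
  tab <- suppressWarnings(
    region_tpm(region_rpm(suppressMessages(count_by_region(ps, cat)))))
  for (reg in c("CDS", "full")) {
    expect_equal(sum(tab$tpm[tab$region == reg], na.rm = TRUE), 1e6)
  }
  # zero-length leader rows are excluded from normalization, not poisoned
  expect_true(is.na(tab$tpm[tab$gene_id == "g2" & tab$region == "leader"]))
  expect_equal(sum(tab$tpm[tab$region == "leader"], na.rm = TRUE), 1e6)
  # RPM uses the per-sample mapped total
  expect_equal(tab$rpm[tab$gene_id == "g1" & tab$region == "CDS"],
               1e6 * 1 / 3)
})

test_that("TE is footprint CDS TPM over RNA TPM with explicit undefined flags", {
  fp <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), region = "CDS", sample = "s",
    raw_count = c(4L, 0L, 2L), region_length = 300L,
    tpm = c(10, 0, 5))
  rna <- tibble::tibble(gene_id = c("g1", "g2", "g3"), sample = "s",
                        count = c(100L, 50L, 0L), length = 500L,
                        tpm = c(5, 2.5, 0))
  te <- translational_efficiency(fp, rna)
  expect_equal(te$te[te$gene_id == "g1"], 2.0)
  expect_false(te$te_defined[te$gene_id == "g2"])  # zero footprints
  expect_false(te$te_defined[te$gene_id == "g3"])  # zero RNA reads
  expect_true(all(is.na(te$te[!te$te_defined])))
  expect_false(any(is.infinite(te$te), na.rm = TRUE))
})

test_that("TE ratios between genes are invariant to global footprint scaling", {
  sim <- simulate_transcriptome(simulation_config(n_genes = 20, seed = 13))
  cat <- sim$catalog
  set.seed(14)
  counts <- rpois(20, 200)
  mk_fp <- function(scale) {
    models <- cat$models
    tibble::tibble(gene_id = models$gene_id, region = "CDS", sample = "s",
                   raw_count = counts * scale,
                   region_length = models$cds_end - models$cds_start) |>
      dplyr::mutate(tpm = tpm_from_counts(raw_count, region_length))
  }
  rna <- tibble::tibble(gene_id = cat$models$gene_id, sample = "s",
                        count = 100L, length = cat$models$length,
                        tpm = tpm_from_counts(rep(100, 20),
                                              cat$models$length))
  te1 <- translational_efficiency(mk_fp(1), rna)
  te5 <- translational_efficiency(mk_fp(5), rna)
  r1 <- te1$te / te1$te[1]
  r5 <- te5$te / te5$te[1]
  expect_equal(r1, r5, tolerance = 1e-12)
})

test_that("leader/CDS ratio divides the two region densities and excludes undefined genes", {
  fp <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    region = rep(c("leader", "CDS"), 3),
    sample = "s",
    raw_count = c(1L, 4L, 0L, 3L, 1L, 0L),
    region_length = c(100L, 400L, 0L, 300L, 50L, 200L),
    tpm = c(2, 8, NA, 6, 3, 0))
  rr <- leader_cds_ratio(fp)
  expect_equal(rr$leader_cds_ratio[rr$gene_id == "g1"], 0.25)
  expect_false("g2" %in% rr$gene_id)  # leaderless
  expect_false("g3" %in% rr$gene_id)  # zero CDS density
  expect_equal(attr(rr, "n_excluded"), 2L)
})

test_that("expression filter is strict and requires all samples to pass", {
  rna <- tibble::tibble(
    gene_id = rep(c("g1", "g2", "g3"), each = 2),
    sample = rep(c("a", "b"), 3),
    tpm = c(1.5, 2.0, 1.0, 5.0, 8.0, 0.4))
  expect_equal(expression_filter(rna), "g1")          # g2 fails at exactly 1.0
  expect_equal(expression_filter(rna, samples = "a"), c("g1", "g3"))
  empty <- rna[0, ]
  expect_equal(expression_filter(empty), character(0))
})
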