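# Fixtures are built in code at test time; nothing binary is stored.

# A three-transcript transcript-space GTF plus matching FASTA:
#   tx1: clean model, leader 100, CDS 100-250, length 300
#   tx2: no CDS feature (must be excluded)
#   tx3: CDS of 100 nt, not divisible by 3 (must be excluded with a warning)
write_toy_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gtf <- file.path(dir, "toy.gtf")
  fa <- file.path(dir, "toy.fa")
  attr_of <- function(tx, gene) {
    sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  }
  lines <- c(
    paste("tx1", "toy", "transcript", 1, 300, ".", "+", ".",
          attr_of("tx1", "gA"), sep = "\t"),
    paste("tx1", "toy", "exon", 1, 300, ".", "+", ".",
          attr_of("tx1", "gA"), sep = "\t"),
    paste("tx1", "toy", "CDS", 101, 250, ".", "+", "0",
          attr_of("tx1", "gA"), sep = "\t"),
    paste("tx2", "toy", "transcript", 1, 200, ".", "+", ".",
          attr_of("tx2", "gB"), sep = "\t"),
    paste("tx2", "toy", "exon", 1, 200, ".", "+", ".",
          attr_of("tx2", "gB"), sep = "\t"),
    paste("tx3", "toy", "transcript", 1, 400, ".", "+", ".",
          attr_of("tx3", "gC"), sep = "\t"),
    paste("tx3", "toy", "exon", 1, 400, ".", "+", ".",
          attr_of("tx3", "gC"), sep = "\t"),
    paste("tx3", "toy", "CDS", 51, 150, ".", "+", "0",
          attr_of("tx3", "gC"), sep = "\t"))
  writeLines(lines, gtf)
  set.seed(4242)
  mk <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                          collapse = "")
  tx1 <- paste0(mk(100), "AUG", mk(144), "UAA", mk(50))  # CDS 100..250
  writeLines(c(">tx1", tx1, ">tx2", mk(200), ">tx3", mk(400)), fa)
  list(gtf = gtf, fasta = fa)
}

# Genomic-dialect GTF: two genes on a chromosome, one plus strand
# (two exons, stop codon excluded from CDS with an adjacent stop_codon
# feature) and one minus strand (two exons).
write_genomic_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  gtf <- file.path(dir, "genomic.gtf")
  a1 <- 'gene_id "gP"; transcript_id "txP";'
  a2 <- 'gene_id "gM"; transcript_id "txM";'
  lines <- c(
    # txP: exons chr1:101-200 and 301-400 (+). Transcript length 200.
    # CDS 151-200 + 301-343 (93 nt), stop_codon 344-346 -> CDS includes stop.
    paste("chr1", "toy", "exon", 101, 200, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "toy", "exon", 301, 400, ".", "+", ".", a1, sep = "\t"),
    paste("chr1", "toy", "CDS", 151, 200, ".", "+", "0", a1, sep = "\t"),
    paste("chr1", "toy", "CDS", 301, 343, ".", "+", "1", a1, sep = "\t"),
    paste("chr1", "toy", "stop_codon", 344, 346, ".", "+", "0", a1,
          sep = "\t"),
    # txM: exons chr1:1001-1100 and 1201-1300 (-). Transcript length 200;
    # transcript coordinate 0 is genomic 1300. CDS = genomic 1201-1270
    # (transcript 30-99) plus 1051-1100 (transcript 100-149): 120 nt,
    # stop included, so cds_start = 30 and cds_end = 150.
    paste("chr1", "toy", "exon", 1001, 1100, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "toy", "exon", 1201, 1300, ".", "-", ".", a2, sep = "\t"),
    paste("chr1", "toy", "CDS", 1201, 1270, ".", "-", "0", a2, sep = "\t"),
    paste("chr1", "toy", "CDS", 1051, 1100, ".", "-", "2", a2, sep = "\t"))
  writeLines(lines, gtf)
  gtf
}

# Small in-code catalog for unit tests that need exact coordinates.
toy_catalog <- function() {
  models <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    gene_id = c("g1", "g2"),
    length = c(60L, 45L),
    cds_start = c(12L, 0L),   # t2 is leaderless
    cds_end = c(42L, 30L))
  seqs <- c(
    t1 = paste0("CCAUGUAACCCC", "AUG", strrep("GCU", 8), "UAA",
                strrep("A", 18)),
    t2 = paste0("AUG", strrep("GAU", 8), "UGA", strrep("C", 15)))
  gene_catalog(models, sequences = seqs)
}

# Memoized full-scale simulation shared by the acceptance tests (criteria on
# parameter and structure recovery all refer to the same seeded experiment).
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (!is.null(.acceptance_cache$run)) return(.acceptance_cache$run)
  cfg <- simulation_config(seed = 1L)
  sim <- simulate_experiment(cfg)
  mode <- processing_mode("immunoprecipitated")
  kept <- suppressMessages(length_filter(sim$fragments, mode))
  psites <- suppressMessages(assign_psites(kept, mode, sim$catalog))
  fp <- region_tpm(region_rpm(suppressMessages(
    count_by_region(psites, sim$catalog))))
  rna <- rna_tpm_table(sim$rna_counts, sim$catalog)
  te <- translational_efficiency(fp, rna)
  run <- list(cfg = cfg, sim = sim, mode = mode,
              n_fragments = nrow(sim$fragments),
              n_length_dropped = attr(kept, "n_dropped_length"),
              psite_drops = attr(psites, "dropped"),
              psites = psites, fp = fp, rna = rna, te = te)
  .acceptance_cache$run <- run
  run
}
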