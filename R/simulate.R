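# Synthetic ground-truth generator: transcriptomes with 5' leaders carrying
# planted upstream AUGs / minimal uORFs, per-gene per-cell-type true TE with
# a designated differentially-translated (DTT) gene set, cell-type-specific
# ribosome stalling at uAUGs and start codons, 3-nt CDS periodicity, and
# paired footprint / RNA-seq read sets at configurable depth. Everything is
# deterministic given the seed.

# Run code under a temporary RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.clamped_lognormal <- function(n, spec) {
  x <- round(rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog))
  pmin(pmax(x, spec$min), spec$max)
}

#' Simulation configuration
#'
#' Defines the generative model of the synthetic two-cell-type ribosome
#' profiling experiment. Defaults describe a 500-gene "neuron"/"glia"
#' comparison: log-normal mRNA abundances, log-normal baseline TE whose
#' 5-95 percentile spread is about 20-fold, 25 DTT genes translationally
#' suppressed 20-fold in glia, planted upstream AUGs (about 2 per leader,
#' half of them minimal six-base uORFs), a 10-fold glial stall boost at the
#' uAUG codons of DTT genes, 90/5/5 CDS frame weights, immunoprecipitated-
#' mode fragment lengths (21-36 nt, mode 31), and 2e6 footprints plus 5e6
#' RNA reads per cell type.
#'
#' @param n_genes number of genes (one transcript each).
#' @param leader_length_dist,cds_length_dist,utr3_length_dist clamped
#'   log-normal length specs (`meanlog`, `sdlog`, `min`, `max`); CDS lengths
#'   are in codons, the others in nt.
#' @param uorf_rate expected planted upstream AUGs per leader (Poisson).
#' @param uorf_minimal_frac fraction of planted uAUGs immediately followed by
#'   an in-frame stop (minimal six-base uORFs).
#' @param cell_types two cell-type labels.
#' @param mrna_sdlog log-normal sd of shared mRNA abundance.
#' @param mrna_ratio_sdlog2 sd (log2) of the per-gene neuron/glia mRNA ratio.
#' @param mrna_te_coupling slope coupling glial TE to the mRNA ratio (0 =
#'   independent; positive values suppress glial TE on genes transcribed
#'   less in glia).
#' @param te_sdlog log-normal sd of baseline TE (0.91 gives ~20-fold 5-95
#'   percentile spread).
#' @param n_dtt number of DTT genes (default: 5% of `n_genes`); their TE in
#'   the second cell type is divided by `dtt_fold`.
#' @param dtt_fold true TE fold of DTT genes between the cell types.
#' @param leader_stall_boost named per-cell-type multiplier of P-site
#'   sampling at planted uAUG codons of stall-affected genes.
#' @param start_stall_boost named per-cell-type multiplier at annotated start
#'   codons.
#' @param stall_genes which genes receive the leader stall boost: `"dtt"`
#'   (default; the leader bias is a property of the suppressed genes, not a
#'   genome-wide shift) or `"all"`.
#' @param leader_background,utr3_background per-nt sampling weight of leader
#'   and 3' UTR positions relative to the mean CDS density.
#' @param uorf_stall_weight per-nt sampling weight at planted uAUG codons
#'   before the cell-type boost.
#' @param frame_weights length-3 CDS frame weights (normalized to sum 1).
#' @param fragment_length_dist named numeric of fragment-length proportions;
#'   names are lengths in nt and must lie inside the mode's retained window.
#' @param mode footprint protocol, see [processing_mode()].
#' @param depth_fp,depth_rna footprint / RNA read depth per cell type.
#' @param seed integer seed; fully determines all outputs.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(
    n_genes = 500L,
    leader_length_dist = list(meanlog = log(120), sdlog = 0.45,
                              min = 30L, max = 600L),
    cds_length_dist = list(meanlog = log(300), sdlog = 0.35,
                           min = 60L, max = 1500L),
    utr3_length_dist = list(meanlog = log(100), sdlog = 0.4,
                            min = 30L, max = 400L),
    uorf_rate = 2,
    uorf_minimal_frac = 0.5,
    cell_types = c("neuron", "glia"),
    mrna_sdlog = 1,
    mrna_ratio_sdlog2 = 1,
    mrna_te_coupling = 0,
    te_sdlog = 0.91,
    n_dtt = NULL,
    dtt_fold = 20,
    leader_stall_boost = c(neuron = 1, glia = 10),
    start_stall_boost = c(neuron = 1, glia = 1),
    stall_genes = c("dtt", "all"),
    leader_background = 0.02,
    utr3_background = 0.01,
    uorf_stall_weight = 5,
    frame_weights = c(0.90, 0.05, 0.05),
    fragment_length_dist = NULL,
    mode = "immunoprecipitated",
    depth_fp = 2e6,
    depth_rna = 5e6,
    seed = 1L) {
  stall_genes <- match.arg(stall_genes)
  # default DTT set: 5% of genes (25 at the default 500-gene scale)
  if (is.null(n_dtt)) n_dtt <- n_genes %/% 20L
  pmode <- processing_mode(mode)
  if (is.null(fragment_length_dist)) {
    lens <- pmode$keep_lengths[1]:pmode$keep_lengths[2]
    w <- stats::dnorm(lens, mean = 31, sd = 2.5)
    fragment_length_dist <- setNames(w / sum(w), lens)
  }
  flens <- as.integer(names(fragment_length_dist))
  if (any(flens < pmode$keep_lengths[1] | flens > pmode$keep_lengths[2])) {
    stop("fragment_length_dist includes lengths outside the mode's window")
  }
  stopifnot(length(cell_types) == 2, n_genes >= 1, n_dtt <= n_genes,
            uorf_rate >= 0, uorf_minimal_frac >= 0, uorf_minimal_frac <= 1,
            all(frame_weights >= 0), dtt_fold > 0,
            all(leader_stall_boost >= 0), all(start_stall_boost >= 0),
            leader_background >= 0, utr3_background >= 0,
            uorf_stall_weight >= 0, depth_fp >= 0, depth_rna >= 0)
  if (!all(cell_types %in% names(leader_stall_boost)) ||
      !all(cell_types %in% names(start_stall_boost))) {
    stop("stall boosts must be named by cell type")
  }
  frame_weights <- frame_weights / sum(frame_weights)
  structure(list(
    n_genes = as.integer(n_genes),
    leader_length_dist = leader_length_dist,
    cds_length_dist = cds_length_dist,
    utr3_length_dist = utr3_length_dist,
    uorf_rate = uorf_rate, uorf_minimal_frac = uorf_minimal_frac,
    cell_types = cell_types,
    mrna_sdlog = mrna_sdlog, mrna_ratio_sdlog2 = mrna_ratio_sdlog2,
    mrna_te_coupling = mrna_te_coupling, te_sdlog = te_sdlog,
    n_dtt = as.integer(n_dtt), dtt_fold = dtt_fold,
    leader_stall_boost = leader_stall_boost,
    start_stall_boost = start_stall_boost, stall_genes = stall_genes,
    leader_background = leader_background,
    utr3_background = utr3_background,
    uorf_stall_weight = uorf_stall_weight,
    frame_weights = frame_weights,
    fragment_length_dist = fragment_length_dist,
    mode = pmode, depth_fp = depth_fp, depth_rna = depth_rna,
    seed = as.integer(seed)), class = "sim_config")
}

# Place n non-overlapping 6-nt uORF slots in a leader of given length.
.place_uorfs <- function(leader_len, n) {
  if (n == 0 || leader_len < 6) return(integer(0))
  candidates <- sample(0:(leader_len - 6L))
  chosen <- integer(0)
  for (p in candidates) {
    if (length(chosen) == n) break
    if (all(abs(chosen - p) >= 6L)) chosen <- c(chosen, p)
  }
  sort(chosen)
}

.random_bases <- function(n) {
  sample(RNA_BASES, n, replace = TRUE)
}

#' Simulate a ground-truth transcriptome
#'
#' Generates transcript region models and sequences (CDS beginning with AUG
#' and ending with a stop codon; leaders with planted uAUGs and minimal
#' six-base uORFs at recorded positions), per-gene mRNA abundance and true TE
#' per cell type, and the designated DTT gene set. Deterministic given
#' `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `catalog` (a [gene_catalog()] with sequences
#'   and one representative isoform per gene) and `truth` (list: `genes`
#'   tibble of per-gene ground truth, `uorfs` tibble of planted sites,
#'   `dtt_genes`, `config`).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_genes
    gene_ids <- sprintf("g%04d", seq_len(n))
    tx_ids <- paste0(gene_ids, ".t1")
    leader_len <- .clamped_lognormal(n, config$leader_length_dist)
    cds_codons <- .clamped_lognormal(n, config$cds_length_dist)
    utr3_len <- .clamped_lognormal(n, config$utr3_length_dist)
    cds_start <- leader_len
    cds_end <- cds_start + 3L * cds_codons
    tx_len <- cds_end + utr3_len

    n_uorf <- rpois(n, config$uorf_rate)
    seqs <- character(n)
    uorfs <- vector("list", n)
    for (i in seq_len(n)) {
      leader <- .random_bases(leader_len[i])
      pos <- .place_uorfs(leader_len[i], n_uorf[i])
      minimal <- logical(length(pos))
      for (j in seq_along(pos)) {
        p <- pos[j]
        leader[(p + 1):(p + 3)] <- strsplit(START_CODON, "")[[1]]
        minimal[j] <- stats::runif(1) < config$uorf_minimal_frac
        follower <- if (minimal[j]) sample(STOP_CODONS, 1)
                    else sample(SENSE_CODONS, 1)
        leader[(p + 4):(p + 6)] <- strsplit(follower, "")[[1]]
      }
      body_codons <- sample(SENSE_CODONS, cds_codons[i] - 2L, replace = TRUE)
      cds <- c(START_CODON, body_codons, sample(STOP_CODONS, 1))
      utr3 <- .random_bases(utr3_len[i])
      seqs[i] <- paste0(paste(leader, collapse = ""),
                        paste(cds, collapse = ""),
                        paste(utr3, collapse = ""))
      if (length(pos) > 0) {
        uorfs[[i]] <- tibble(gene_id = gene_ids[i], transcript_id = tx_ids[i],
                             position = as.integer(pos),
                             is_minimal_uorf = minimal)
      }
    }
    uorfs <- bind_rows(uorfs)
    if (nrow(uorfs) == 0) {
      uorfs <- tibble(gene_id = character(), transcript_id = character(),
                      position = integer(), is_minimal_uorf = logical())
    }

    abundance <- rlnorm(n, 0, config$mrna_sdlog)
    delta <- stats::rnorm(n, 0, config$mrna_ratio_sdlog2)  # log2 A/B ratio
    ct <- config$cell_types
    abund <- cbind(abundance * 2^(delta / 2), abundance * 2^(-delta / 2))
    colnames(abund) <- ct

    te_base <- rlnorm(n, 0, config$te_sdlog)
    dtt_genes <- sort(sample(gene_ids, config$n_dtt))
    is_dtt <- gene_ids %in% dtt_genes
    te_a <- te_base
    te_b <- te_base
    te_b[is_dtt] <- te_base[is_dtt] / config$dtt_fold
    te_b <- te_b * 2^(-config$mrna_te_coupling * delta)
    te <- cbind(te_a, te_b)
    colnames(te) <- ct

    genes <- tibble(
      gene_id = gene_ids, transcript_id = tx_ids,
      length = as.integer(tx_len), cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end),
      abundance_a = abund[, 1], abundance_b = abund[, 2],
      te_a = te[, 1], te_b = te[, 2],
      mrna_log2_ratio = delta, is_dtt = is_dtt)

    models <- genes[, c("transcript_id", "gene_id", "length", "cds_start",
                        "cds_end")]
    catalog <- gene_catalog(models, sequences = setNames(seqs, tx_ids),
                            representative = tibble(
                              gene_id = gene_ids, transcript_id = tx_ids,
                              tpm = NA_real_, all_zero = FALSE))
    truth <- list(genes = genes, uorfs = uorfs, dtt_genes = dtt_genes,
                  config = config)
    list(catalog = catalog, truth = truth)
  })
}

#' Simulate RNA-seq gene counts
#'
#' Multinomial sampling of `depth_rna` reads per cell type with per-gene
#' probability proportional to mRNA abundance times transcript length.
#'
#' @param truth ground truth from [simulate_transcriptome()].
#' @param depth_rna reads per cell type (0 gives an all-zero table).
#' @param seed RNG seed.
#' @return tibble `gene_id`, `sample`, `count`.
#' @export
simulate_rna_counts <- function(truth, depth_rna = NULL, seed = NULL) {
  config <- truth$config
  if (is.null(depth_rna)) depth_rna <- config$depth_rna
  if (is.null(seed)) seed <- config$seed + 1L
  g <- truth$genes
  ct <- config$cell_types
  .with_seed(seed, {
    out <- lapply(seq_along(ct), function(k) {
      a <- if (k == 1) g$abundance_a else g$abundance_b
      w <- a * g$length
      counts <- if (depth_rna > 0) {
        as.integer(rmultinom(1, size = depth_rna, prob = w))
      } else rep(0L, nrow(g))
      tibble(gene_id = g$gene_id, sample = ct[k], count = counts)
    })
    bind_rows(out)
  })
}

# Per-cell-type position sampling weights, concatenated over transcripts in
# model order. Returns list(weights, tx_index, tx_offsets).
.footprint_weights <- function(truth, cell_type) {
  config <- truth$config
  g <- truth$genes
  k <- match(cell_type, config$cell_types)
  a <- if (k == 1) g$abundance_a else g$abundance_b
  te <- if (k == 1) g$te_a else g$te_b
  dens <- a * te  # per-nt CDS-scale density unit

  n <- nrow(g)
  offsets <- c(0L, cumsum(g$length))[seq_len(n)]
  total <- sum(g$length)
  w <- numeric(total)

  # leader background
  idx <- sequence(g$cds_start, from = offsets + 1L)
  w[idx] <- rep(dens * config$leader_background, times = g$cds_start)
  # CDS with frame periodicity (weights scaled to mean 1 per nt)
  cds_len <- g$cds_end - g$cds_start
  idx <- sequence(cds_len, from = offsets + g$cds_start + 1L)
  frame <- sequence(cds_len, from = 0L) %% 3L
  w[idx] <- rep(dens, times = cds_len) * 3 *
    config$frame_weights[frame + 1L]
  # start-codon boost
  boost_start <- config$start_stall_boost[[cell_type]]
  if (boost_start != 1) {
    idx <- as.vector(outer(0:2, offsets + g$cds_start + 1L, `+`))
    w[idx] <- w[idx] * boost_start
  }
  # 3' UTR background
  utr3_len <- g$length - g$cds_end
  idx <- sequence(utr3_len, from = offsets + g$cds_end + 1L)
  w[idx] <- rep(dens * config$utr3_background, times = utr3_len)
  # planted uAUG stall sites
  if (nrow(truth$uorfs) > 0) {
    u <- truth$uorfs
    gi <- match(u$gene_id, g$gene_id)
    stalled <- if (config$stall_genes == "dtt") g$is_dtt[gi] else
      rep(TRUE, nrow(u))
    boost <- ifelse(stalled, config$leader_stall_boost[[cell_type]], 1)
    site_w <- dens[gi] * config$uorf_stall_weight * boost
    idx <- as.vector(outer(0:2, offsets[gi] + u$position + 1L, `+`))
    w[idx] <- rep(site_w, each = 3L)
  }
  list(weights = w, offsets = offsets)
}

#' Simulate ribosome footprints
#'
#' Draws `depth_fp` P-site positions per cell type by independent multinomial
#' sampling over all transcript positions: per-gene mass proportional to
#' mRNA abundance times TE times CDS length; within genes, CDS positions
#' follow the frame weights (3-nt periodicity), planted uAUG codons of
#' stall-affected genes are up-weighted by the cell-type leader stall boost,
#' and annotated start codons by the start stall boost. Each P-site is then
#' wrapped in a fragment: length drawn from the fragment-length
#' distribution and 5' end placed so that the length-dependent offset rule
#' recovers the intended P-site exactly. Fragments that would protrude
#' beyond the transcript are dropped (and counted).
#'
#' @param truth ground truth from [simulate_transcriptome()].
#' @param depth_fp footprints per cell type.
#' @param seed RNG seed.
#' @return fragment tibble (`transcript_id`, `five_prime`, `length`,
#'   `sample`) with `attr(, "n_dropped_edge")`.
#' @export
simulate_footprints <- function(truth, depth_fp = NULL, seed = NULL) {
  config <- truth$config
  if (is.null(depth_fp)) depth_fp <- config$depth_fp
  if (is.null(seed)) seed <- config$seed + 2L
  g <- truth$genes
  mode <- config$mode
  flens <- as.integer(names(config$fragment_length_dist))
  fprob <- as.numeric(config$fragment_length_dist)
  tx_len_of <- setNames(g$length, g$transcript_id)

  .with_seed(seed, {
    out <- lapply(config$cell_types, function(ct) {
      fw <- .footprint_weights(truth, ct)
      pos_global <- sample.int(length(fw$weights), size = depth_fp,
                               replace = TRUE, prob = fw$weights)
      gene_idx <- findInterval(pos_global - 1L, fw$offsets)
      psite <- (pos_global - 1L) - fw$offsets[gene_idx]
      len <- sample(flens, depth_fp, replace = TRUE, prob = fprob)
      off <- psite_offset(len, mode)
      five_prime <- psite - off
      tx <- g$transcript_id[gene_idx]
      ok <- five_prime >= 0 & five_prime + len <= g$length[gene_idx]
      res <- tibble(transcript_id = tx[ok],
                    five_prime = as.integer(five_prime[ok]),
                    length = len[ok], sample = ct)
      attr(res, "n_dropped_edge") <- sum(!ok)
      res
    })
    res <- bind_rows(out)
    attr(res, "n_dropped_edge") <- sum(vapply(out, attr, numeric(1),
                                              "n_dropped_edge"))
    res
  })
}

#' Run the full simulation
#'
#' Transcriptome, RNA counts and footprints for both cell types under one
#' config; seeds for the three stages are derived from `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list: `catalog`, `truth`, `rna_counts`, `fragments`.
#' @export
simulate_experiment <- function(config) {
  sim <- simulate_transcriptome(config)
  rna <- simulate_rna_counts(sim$truth)
  fp <- simulate_footprints(sim$truth)
  list(catalog = sim$catalog, truth = sim$truth, rna_counts = rna,
       fragments = fp)
}

#' Write simulated data in the pipeline's exchange dialects
#'
#' Emits transcript FASTA, transcript-space GTF (seqnames are
#' transcript_ids; CDS features include the stop codon), BED-like fragment
#' TSV, RNA count TSV, and a ground-truth JSON.
#'
#' @param sim output of [simulate_experiment()].
#' @param dir output directory (created if needed).
#' @return named character vector of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "transcripts.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    fragments = file.path(dir, "fragments.bed"),
    rna = file.path(dir, "rna_counts.tsv"),
    truth = file.path(dir, "ground_truth.json"))

  seqs <- Biostrings::RNAStringSet(sim$catalog$sequences)
  Biostrings::writeXStringSet(seqs, paths[["fasta"]])

  m <- sim$catalog$models
  gr <- GenomicRanges::GRanges(
    seqnames = rep(m$transcript_id, each = 3L),
    ranges = IRanges::IRanges(
      start = as.vector(rbind(1L, 1L, m$cds_start + 1L)),
      end = as.vector(rbind(m$length, m$length, m$cds_end))),
    strand = "+",
    type = rep(c("transcript", "exon", "CDS"), nrow(m)),
    phase = rep(c(NA_integer_, NA_integer_, 0L), nrow(m)),
    source = "ribotype_sim",
    gene_id = rep(m$gene_id, each = 3L),
    transcript_id = rep(m$transcript_id, each = 3L))
  rtracklayer::export(gr, paths[["gtf"]], format = "gtf")

  write_fragments_bed(sim$fragments, paths[["fragments"]])
  readr::write_tsv(sim$rna_counts, paths[["rna"]])

  g <- sim$truth$genes
  jsonlite::write_json(
    list(genes = g, uorfs = sim$truth$uorfs,
         dtt_genes = sim$truth$dtt_genes,
         cell_types = sim$truth$config$cell_types,
         leader_stall_boost = as.list(sim$truth$config$leader_stall_boost),
         start_stall_boost = as.list(sim$truth$config$start_stall_boost),
         seed = sim$truth$config$seed),
    paths[["truth"]], digits = NA)
  paths
}
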