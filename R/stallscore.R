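# Per-codon footprint accumulation ("stall") scores: the number of P-sites
# on a codon divided by the mean P-sites per 3-nt tile over the surrounding
# -50/+50 nt, tiled in the codon's frame. Dimensionless (arbitrary units);
# 1 means no accumulation over the local background.

#' Footprint accumulation score at one codon
#'
#' `score = reads_at_codon / window_mean`, where `reads_at_codon` counts
#' P-sites in `[codon_position, codon_position + 3)` and `window_mean` is the
#' mean count per 3-nt tile over the ±`window` nt surrounding region, tiled
#' in the codon's frame and clipped to the transcript bounds. The focal codon
#' is included in the mean by default (the window runs from -50 to +50
#' through the codon); set `include_focal = FALSE` to use the flanks only.
#'
#' @param psites P-site tibble (see [assign_psites()]), optionally
#'   pre-filtered to one sample.
#' @param catalog a [gene_catalog()].
#' @param transcript_id transcript carrying the codon.
#' @param codon_position 0-based transcript coordinate of the codon's first
#'   base.
#' @param window half-window in nt (default 50).
#' @param include_focal include the focal codon tile in the window mean.
#' @param sample optional sample label to restrict to.
#' @return one-row tibble: `transcript_id`, `codon_position`, `score`,
#'   `reads_at_codon`, `window_mean`, `low_confidence` (fewer than 30 nt of
#'   usable flanking window). `score` is `NA` when the window mean is zero.
#' @export
codon_accumulation_score <- function(psites, catalog, transcript_id,
                                     codon_position, window = 50L,
                                     include_focal = TRUE, sample = NULL) {
  sites <- tibble(transcript_id = transcript_id,
                  codon_position = as.integer(codon_position),
                  codon = NA_character_, region = NA_character_)
  stall_score_table(psites, catalog, sites, window = window,
                    include_focal = include_focal, sample = sample) %>%
    select(-codon, -region)
}

#' Footprint accumulation scores for a table of codon sites
#'
#' Vectorized scoring of many codon positions (the per-transcript P-site
#' counts are tabulated once and window tiles are read off cumulative sums).
#'
#' @param psites P-site tibble.
#' @param catalog a [gene_catalog()].
#' @param sites tibble with columns `transcript_id`, `codon_position`, and
#'   optionally `codon` and `region` (carried through).
#' @param window half-window in nt (default 50).
#' @param include_focal include the focal codon tile in the window mean.
#' @param sample optional sample label to restrict to.
#' @return `sites` with `score`, `reads_at_codon`, `window_mean`,
#'   `low_confidence` columns appended.
#' @export
stall_score_table <- function(psites, catalog, sites, window = 50L,
                              include_focal = TRUE, sample = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  sites <- as_tibble(sites)
  if (!"codon" %in% names(sites)) sites$codon <- NA_character_
  if (!"region" %in% names(sites)) sites$region <- NA_character_
  ps <- psites
  if (!is.null(sample)) ps <- ps[ps$sample == sample, , drop = FALSE]
  models <- catalog$models
  ks <- seq(-(window %/% 3L), window %/% 3L)
  n_tiles <- length(ks)

  out <- vector("list", length(unique(sites$transcript_id)))
  i <- 0L
  for (tx in unique(sites$transcript_id)) {
    m <- models[models$transcript_id == tx, ]
    if (nrow(m) != 1) stop("unknown transcript in sites: ", tx)
    len <- m$length
    cnt <- tabulate(ps$psite[ps$transcript_id == tx] + 1L, nbins = len)
    cs <- c(0, cumsum(cnt))
    sub <- sites[sites$transcript_id == tx, , drop = FALSE]
    starts <- outer(sub$codon_position, 3L * ks, `+`)
    valid <- starts >= 0L & starts + 3L <= len
    tile_counts <- matrix(0, nrow(starts), ncol(starts))
    tile_counts[valid] <- cs[starts[valid] + 4L] - cs[starts[valid] + 1L]
    focal_col <- which(ks == 0L)
    reads_at <- tile_counts[, focal_col]
    mean_mask <- valid
    if (!include_focal) mean_mask[, focal_col] <- FALSE
    n_used <- rowSums(mean_mask)
    wmean <- ifelse(n_used > 0,
                    rowSums(tile_counts * mean_mask) / n_used, NA_real_)
    flank_tiles <- rowSums(valid) - as.integer(valid[, focal_col])
    sub$score <- ifelse(!is.na(wmean) & wmean > 0, reads_at / wmean, NA_real_)
    sub$reads_at_codon <- as.integer(reads_at)
    sub$window_mean <- wmean
    sub$low_confidence <- 3L * flank_tiles < 30L
    i <- i + 1L
    out[[i]] <- sub
  }
  bind_rows(out)
}

#' Codon sites of annotated CDSs (start and stop excluded)
#'
#' All annotated in-frame codons of each representative transcript except the
#' first (start) and last (stop) codons, with codon identities read from the
#' transcript sequence.
#'
#' @param catalog a [gene_catalog()] with sequences.
#' @return site tibble for [stall_score_table()] (`region = "CDS"`).
#' @export
cds_codon_sites <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.null(catalog$sequences)) stop("catalog carries no sequences")
  m <- representative_models(catalog)
  out <- lapply(seq_len(nrow(m)), function(i) {
    n_codons <- (m$cds_end[i] - m$cds_start[i]) %/% 3L
    if (n_codons <= 2) return(NULL)
    pos <- m$cds_start[i] + 3L * seq(1L, n_codons - 2L)
    tibble(transcript_id = m$transcript_id[i], codon_position = pos,
           codon = substring(catalog$sequences[[m$transcript_id[i]]],
                             pos + 1L, pos + 3L),
           region = "CDS")
  })
  bind_rows(out)
}

#' Codon sites on 5' leaders
#'
#' By default the upstream start-like sites reported by
#' [find_upstream_starts()] (the codon set whose accumulation is of primary
#' interest); with `include_frame_mates = TRUE`, every leader codon in the
#' reading frames anchored at those sites is added as background.
#'
#' @param catalog a [gene_catalog()] with sequences.
#' @param include_frame_mates add all leader 3-mers in the frames of the
#'   upstream start sites.
#' @return site tibble for [stall_score_table()] (`region = "leader"`).
#' @export
leader_codon_sites <- function(catalog, include_frame_mates = FALSE) {
  sites <- find_upstream_starts(catalog)
  base <- tibble(transcript_id = sites$transcript_id,
                 codon_position = sites$position,
                 codon = sites$codon, region = "leader")
  if (!include_frame_mates || nrow(sites) == 0) return(base)
  models <- catalog$models
  extra <- lapply(unique(sites$transcript_id), function(tx) {
    cds_start <- models$cds_start[models$transcript_id == tx]
    frames <- unique(sites$position[sites$transcript_id == tx] %% 3L)
    pos <- unlist(lapply(frames, function(f) seq(f, cds_start - 3L, by = 3L)))
    pos <- sort(unique(pos))
    tibble(transcript_id = tx, codon_position = as.integer(pos),
           codon = substring(catalog$sequences[[tx]], pos + 1L, pos + 3L),
           region = "leader")
  })
  bind_rows(extra) %>%
    dplyr::anti_join(base, by = c("transcript_id", "codon_position")) %>%
    bind_rows(base, .) %>%
    arrange(transcript_id, codon_position)
}

#' Aggregate accumulation scores by codon identity
#'
#' Groups a score table by codon (within one region class) and summarises
#' each of the 64 codons; codons without instances are retained with an empty
#' distribution. Ordering is lexicographic by codon.
#'
#' @param scores output of [stall_score_table()].
#' @param region region class to aggregate (`"leader"` or `"CDS"`).
#' @return tibble `codon`, `region`, `n`, `median_score`, plus a list-column
#'   `scores` holding each codon's score vector.
#' @export
aggregate_scores_by_codon <- function(scores, region = c("leader", "CDS")) {
  region <- match.arg(region)
  sub <- scores[!is.na(scores$region) & scores$region == region &
                  !is.na(scores$score), , drop = FALSE]
  per <- split(sub$score, factor(normalize_rna(sub$codon),
                                 levels = ALL_CODONS))
  tibble(codon = ALL_CODONS, region = region,
         n = as.integer(lengths(per)),
         median_score = unname(vapply(per, function(v) {
           if (length(v) == 0) NA_real_ else median(v)
         }, numeric(1))),
         scores = unname(per))
}

#' Start-codon accumulation score per gene
#'
#' Evaluates the accumulation score at the annotated start codon of every
#' representative transcript and returns the genes ranked by score — the
#' screen for transcripts whose ribosomes pile up on the initiation codon.
#'
#' @param psites P-site tibble.
#' @param catalog a [gene_catalog()].
#' @param window half-window in nt (default 50).
#' @param sample optional sample label to restrict to.
#' @return tibble `gene_id`, `transcript_id`, `codon_position`, `score`,
#'   `reads_at_codon`, `window_mean`, `low_confidence`, ranked by descending
#'   score (undefined scores last).
#' @export
start_codon_accumulation <- function(psites, catalog, window = 50L,
                                     sample = NULL) {
  m <- representative_models(catalog)
  sites <- tibble(transcript_id = m$transcript_id,
                  codon_position = m$cds_start,
                  codon = NA_character_, region = "CDS")
  res <- stall_score_table(psites, catalog, sites, window = window,
                           sample = sample)
  res$gene_id <- m$gene_id[match(res$transcript_id, m$transcript_id)]
  res %>%
    select(gene_id, transcript_id, codon_position, score, reads_at_codon,
           window_mean, low_confidence) %>%
    arrange(dplyr::desc(!is.na(score)), dplyr::desc(score))
}

#' Write a stall-score table and per-codon summary (TSV)
#'
#' @param scores output of [stall_score_table()].
#' @param path output TSV path.
#' @export
write_stall_scores <- function(scores, path) {
  readr::write_tsv(as_tibble(scores), path)
  invisible(path)
}

#' @rdname write_stall_scores
#' @param summary output of [aggregate_scores_by_codon()].
#' @export
write_codon_summary <- function(summary, path) {
  readr::write_tsv(summary %>% select(codon, region, n, median_score), path)
  invisible(path)
}
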