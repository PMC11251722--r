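# Metagene profiles: P-site density aggregated across transcripts relative
# to a common anchor (annotated start/stop codons, upstream AUGs, or custom
# positions). Offset 0 is the anchor's first nucleotide (the A of AUG);
# windows are inclusive of both ends.

#' Anchor tables for metagene profiles
#'
#' Convenience constructors of `(transcript_id, position)` anchor tables:
#' annotated start codons, annotated stop codons (first base of the stop
#' codon), and upstream start codons from [find_upstream_starts()].
#'
#' @param catalog a [gene_catalog()]; representative isoforms are used when
#'   a representative mapping is present.
#' @return tibble with columns `transcript_id`, `position`.
#' @export
start_codon_anchors <- function(catalog) {
  m <- representative_models(catalog)
  tibble(transcript_id = m$transcript_id, position = m$cds_start)
}

#' @rdname start_codon_anchors
#' @export
stop_codon_anchors <- function(catalog) {
  m <- representative_models(catalog)
  tibble(transcript_id = m$transcript_id, position = m$cds_end - 3L)
}

#' @rdname start_codon_anchors
#' @param sites upstream-start table (see [find_upstream_starts()]).
#' @param codon_class subset of codon classes to anchor on (default: AUG
#'   only).
#' @export
uaug_anchors <- function(sites, codon_class = "AUG") {
  s <- sites[sites$codon_class %in% codon_class, , drop = FALSE]
  tibble(transcript_id = s$transcript_id, position = s$position)
}

#' Metagene profile around anchor positions
#'
#' Sums P-site counts at each offset relative to a set of anchors, optionally
#' restricted to a fragment-length subset (different fragment lengths are
#' analysed separately in different figures of a typical study), then
#' normalizes. Window positions falling outside a transcript contribute
#' nothing for that anchor.
#'
#' @param psites P-site tibble (see [assign_psites()]).
#' @param anchors tibble with columns `transcript_id`, `position`.
#' @param window length-2 vector `c(upstream, downstream)` in nt (default
#'   ±50); both ends inclusive.
#' @param length_subset optional integer set of fragment lengths to keep.
#' @param normalization `"per_window_total"` (profile sums to 1), `"rpm"`
#'   (counts per million P-sites in `psites` after length subsetting), or
#'   `"none"` (raw counts).
#' @param anchor_kind label recorded in the profile.
#' @return object of class `metagene_profile`: list with `offsets`,
#'   `values`, `n_anchors`, `n_reads` (reads in window), `anchor_kind`,
#'   `window`, `normalization`, `zero_reads` flag.
#' @export
metagene_profile <- function(psites, anchors, window = c(50L, 50L),
                             length_subset = NULL,
                             normalization = c("per_window_total", "rpm",
                                               "none"),
                             anchor_kind = "custom") {
  normalization <- match.arg(normalization)
  anchors <- as_tibble(anchors)
  if (nrow(anchors) == 0) stop("empty anchor list")
  stopifnot(length(window) == 2, all(window >= 0))
  up <- as.integer(window[1]); down <- as.integer(window[2])
  ps <- psites
  if (!is.null(length_subset)) {
    ps <- ps[ps$length %in% length_subset, , drop = FALSE]
  }
  total_reads <- nrow(ps)
  hits <- dplyr::inner_join(
    ps[, c("transcript_id", "psite")], anchors,
    by = "transcript_id", relationship = "many-to-many")
  off <- hits$psite - hits$position
  off <- off[off >= -up & off <= down]
  counts <- tabulate(off + up + 1L, nbins = up + down + 1L)
  zero <- sum(counts) == 0
  values <- switch(normalization,
    per_window_total = if (zero) counts * 0 else counts / sum(counts),
    rpm = if (total_reads == 0) counts * 0 else 1e6 * counts / total_reads,
    none = counts)
  if (zero) warning("no P-sites in any anchor window", call. = FALSE)
  structure(list(offsets = seq(-up, down), values = as.numeric(values),
                 n_anchors = nrow(anchors), n_reads = sum(counts),
                 anchor_kind = anchor_kind, window = c(up, down),
                 normalization = normalization, zero_reads = zero),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("<metagene_profile> %s: %d anchors, %d reads in [-%d, +%d], %s-normalized\n",
              x$anchor_kind, x$n_anchors, x$n_reads, x$window[1], x$window[2],
              x$normalization))
  invisible(x)
}

#' Per-nucleotide footprint track for one transcript
#'
#' Footprint RPM at every transcript position, normalized by the gene's mRNA
#' level (TPM), with region labels — the single-transcript profile used to
#' display leader-biased ribosome distributions.
#'
#' @param psites P-site tibble (all samples; filtered to `sample` if given).
#' @param catalog a [gene_catalog()].
#' @param transcript_id transcript to profile.
#' @param rna_tpm the gene's mRNA TPM (scalar, > 0).
#' @param sample optional sample label to restrict to.
#' @return tibble `position`, `region`, `count`, `rpm`, `value`
#'   (= rpm / rna_tpm).
#' @export
gene_profile <- function(psites, catalog, transcript_id, rna_tpm,
                         sample = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.na(rna_tpm) || rna_tpm <= 0) {
    stop("rna_tpm must be positive; profile undefined otherwise")
  }
  m <- catalog$models[catalog$models$transcript_id == transcript_id, ]
  if (nrow(m) != 1) stop("unknown transcript: ", transcript_id)
  ps <- psites
  if (!is.null(sample)) ps <- ps[ps$sample == sample, , drop = FALSE]
  total <- nrow(ps)
  ps <- ps[ps$transcript_id == transcript_id, , drop = FALSE]
  counts <- tabulate(ps$psite + 1L, nbins = m$length)
  pos <- seq_len(m$length) - 1L
  region <- dplyr::case_when(pos < m$cds_start ~ "leader",
                             pos < m$cds_end ~ "CDS",
                             TRUE ~ "utr3")
  rpm <- if (total > 0) 1e6 * counts / total else rep(NA_real_, m$length)
  tibble(position = pos, region = region, count = counts, rpm = rpm,
         value = rpm / rna_tpm)
}

#' Write a metagene profile (TSV + JSON sidecar)
#'
#' The TSV holds `offset` and `value` columns; the sidecar
#' (`<path>.json`) records anchor kind, window, anchor count and
#' normalization.
#'
#' @param profile a [metagene_profile()].
#' @param path output TSV path.
#' @export
write_metagene <- function(profile, path) {
  readr::write_tsv(tibble(offset = profile$offsets, value = profile$values),
                   path)
  jsonlite::write_json(
    list(anchor_kind = profile$anchor_kind,
         window = profile$window,
         n_anchors = profile$n_anchors,
         n_reads = profile$n_reads,
         normalization = profile$normalization),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
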