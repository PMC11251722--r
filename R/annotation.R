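# Transcript region models: every transcript is represented in transcript
# coordinates (0-based, half-open) partitioned into 5' leader [0, cds_start),
# CDS [cds_start, cds_end) (stop codon included), and 3' UTR [cds_end, length).

#' Construct a gene catalog
#'
#' A gene catalog bundles per-transcript region models, optional transcript
#' sequences, and (once selected) the gene-to-representative-isoform mapping.
#'
#' @param models tibble with columns `transcript_id`, `gene_id`, `length`,
#'   `cds_start`, `cds_end`. Coordinates are 0-based; `cds_end` is half-open
#'   and includes the stop codon.
#' @param sequences optional named character vector of transcript sequences
#'   (names = transcript_id); normalized to uppercase RNA.
#' @param representative optional tibble with columns `gene_id`,
#'   `transcript_id` mapping each gene to its representative isoform.
#' @return an object of class `gene_catalog`.
#' @export
gene_catalog <- function(models, sequences = NULL, representative = NULL) {
  models <- as_tibble(models)
  required <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  missing_cols <- setdiff(required, names(models))
  if (length(missing_cols) > 0) {
    stop("models is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(models$transcript_id)) {
    stop("duplicated transcript_id in models")
  }
  bad <- with(models, !(cds_start >= 0 & cds_start < cds_end & cds_end <= length))
  if (any(bad)) {
    stop("invalid CDS interval for: ",
         paste(models$transcript_id[bad], collapse = ", "))
  }
  frame_bad <- (models$cds_end - models$cds_start) %% 3L != 0L
  if (any(frame_bad)) {
    stop("CDS length not a multiple of 3 for: ",
         paste(models$transcript_id[frame_bad], collapse = ", "))
  }
  if (!is.null(sequences)) {
    sequences <- setNames(normalize_rna(as.character(sequences)),
                          names(sequences))
    miss <- setdiff(models$transcript_id, names(sequences))
    if (length(miss) > 0) {
      stop("missing sequence for transcripts: ", paste(miss, collapse = ", "))
    }
    len_bad <- nchar(sequences[models$transcript_id]) != models$length
    if (any(len_bad)) {
      stop("sequence length disagrees with model length for: ",
           paste(models$transcript_id[len_bad], collapse = ", "))
    }
  }
  structure(
    list(models = models, sequences = sequences,
         representative = representative),
    class = "gene_catalog"
  )
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d transcripts, %d genes%s%s\n",
              nrow(x$models), length(unique(x$models$gene_id)),
              if (!is.null(x$sequences)) ", with sequences" else "",
              if (!is.null(x$representative)) ", representatives selected"
              else ""))
  invisible(x)
}

# Map one genomic interval [start0, end) onto transcript coordinates given the
# transcript's exon table (genomic start0/end, one strand). GTF/GFF CDS
# features are per-exon, so each feature falls inside a single exon.
.genomic_to_tx <- function(start0, end, exons, strand) {
  exons <- exons[order(exons$start0), , drop = FALSE]
  widths <- exons$end - exons$start0
  if (strand == "-") {
    # transcript runs over exons in descending genomic order
    ord <- rev(seq_len(nrow(exons)))
    cum_before <- cumsum(c(0L, widths[ord]))[seq_len(nrow(exons))]
    cum_before <- cum_before[match(seq_len(nrow(exons)), ord)]
    hit <- which(start0 >= exons$start0 & end <= exons$end)
    if (length(hit) != 1) return(NULL)
    tx_start <- cum_before[hit] + (exons$end[hit] - end)
    list(start = tx_start, end = tx_start + (end - start0))
  } else {
    cum_before <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
    hit <- which(start0 >= exons$start0 & end <= exons$end)
    if (length(hit) != 1) return(NULL)
    tx_start <- cum_before[hit] + (start0 - exons$start0[hit])
    list(start = tx_start, end = tx_start + (end - start0))
  }
}

# Reduce the features of one transcript to (length, cds_start, cds_end) in
# transcript coordinates, or a character reason for exclusion.
.model_from_features <- function(tx_id, rows, seq_len_hint) {
  cds <- rows[rows$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return("no_cds")
  tx_space <- all(rows$seqname == tx_id)

  if (tx_space) {
    tx_rows <- rows[rows$type %in% c("transcript", "mRNA"), , drop = FALSE]
    len <- if (nrow(tx_rows) > 0) max(tx_rows$end)
           else if (!is.na(seq_len_hint)) seq_len_hint
           else max(rows$end)
    ivs <- data.frame(start = cds$start0, end = cds$end)
    stop_rows <- rows[rows$type == "stop_codon", , drop = FALSE]
    stop_start <- if (nrow(stop_rows) > 0) min(stop_rows$start0) else NA_integer_
  } else {
    exons <- rows[rows$type == "exon", , drop = FALSE]
    if (nrow(exons) == 0) return("no_exons_for_projection")
    strand <- rows$strand[1]
    len <- sum(exons$end - exons$start0)
    proj <- lapply(seq_len(nrow(cds)), function(i) {
      .genomic_to_tx(cds$start0[i], cds$end[i], exons, strand)
    })
    if (any(vapply(proj, is.null, logical(1)))) return("cds_outside_exons")
    ivs <- data.frame(start = vapply(proj, `[[`, numeric(1), "start"),
                      end = vapply(proj, `[[`, numeric(1), "end"))
    stop_rows <- rows[rows$type == "stop_codon", , drop = FALSE]
    stop_start <- NA_integer_
    if (nrow(stop_rows) > 0) {
      sp <- lapply(seq_len(nrow(stop_rows)), function(i) {
        .genomic_to_tx(stop_rows$start0[i], stop_rows$end[i], exons, strand)
      })
      sp <- sp[!vapply(sp, is.null, logical(1))]
      if (length(sp) > 0) {
        stop_start <- min(vapply(sp, `[[`, numeric(1), "start"))
      }
    }
  }

  cds_start <- min(ivs$start)
  cds_end <- max(ivs$end)
  if (sum(ivs$end - ivs$start) != cds_end - cds_start) {
    return("cds_not_contiguous_in_transcript")
  }
  # GTF dialects that exclude the stop codon from CDS features carry an
  # adjacent stop_codon feature; fold it in so the CDS is one half-open
  # interval ending after the stop codon.
  if (!is.na(stop_start) && stop_start == cds_end) cds_end <- cds_end + 3L
  if ((cds_end - cds_start) %% 3L != 0L) return("cds_length_not_multiple_of_3")
  if (!(cds_start >= 0 && cds_end <= len)) return("cds_outside_transcript")
  list(length = as.integer(len), cds_start = as.integer(cds_start),
       cds_end = as.integer(cds_end))
}

#' Load transcript region models from annotation and sequence files
#'
#' Reads a GTF or GFF3 annotation (via `rtracklayer`) and, optionally,
#' transcript-level FASTA sequences (via `Biostrings`), and builds one region
#' model per annotated coding transcript. Two annotation dialects are
#' supported: transcript-space (feature seqnames equal transcript_ids, as
#' emitted by [simulate_transcriptome()]) and genomic (features on
#' chromosomes; CDS coordinates are projected through the transcript's exons,
#' strand-aware). Transcripts without CDS features, with non-contiguous or
#' non-triplet CDS, are excluded with a warning/message; transcripts missing
#' from the FASTA are a hard error.
#'
#' Input alignments downstream are assumed already UMI-deduplicated and
#' transcriptome-mapped; no deduplication happens in this package.
#'
#' @param annotation_path path to a GTF/GFF3 file with `transcript_id` and
#'   `gene_id` attributes on transcript/exon/CDS features.
#' @param fasta_path optional path to transcript FASTA; headers must match
#'   transcript_ids.
#' @return a [gene_catalog()] without representative mapping. Exclusions are
#'   recorded in `attr(, "excluded")` (tibble of transcript_id, reason).
#' @export
load_transcript_models <- function(annotation_path, fasta_path = NULL) {
  gr <- rtracklayer::import(annotation_path)
  mc <- S4Vectors::mcols(gr)
  if (!all(c("transcript_id", "gene_id") %in% names(mc))) {
    stop("annotation must carry transcript_id and gene_id attributes")
  }
  feats <- tibble(
    seqname = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    transcript_id = as.character(mc$transcript_id),
    gene_id = as.character(mc$gene_id)
  )
  feats <- feats[!is.na(feats$transcript_id), , drop = FALSE]

  sequences <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readBStringSet(fasta_path)
    nm <- sub("\\s.*$", "", names(ss))
    sequences <- setNames(normalize_rna(as.character(ss)), nm)
  }

  tx_ids <- unique(feats$transcript_id)
  if (!is.null(sequences)) {
    miss <- setdiff(tx_ids, names(sequences))
    if (length(miss) > 0) {
      stop("missing sequence for annotated transcripts: ",
           paste(miss, collapse = ", "))
    }
  }

  rows_by_tx <- split(feats, feats$transcript_id)
  models <- vector("list", length(tx_ids))
  excluded <- list()
  for (i in seq_along(tx_ids)) {
    tx <- tx_ids[i]
    rows <- rows_by_tx[[tx]]
    hint <- if (!is.null(sequences)) nchar(sequences[[tx]]) else NA_integer_
    res <- .model_from_features(tx, rows, hint)
    if (is.character(res)) {
      excluded[[length(excluded) + 1L]] <- tibble(transcript_id = tx,
                                                 reason = res)
      next
    }
    gene <- rows$gene_id[!is.na(rows$gene_id)][1]
    models[[i]] <- tibble(transcript_id = tx, gene_id = gene,
                          length = res$length, cds_start = res$cds_start,
                          cds_end = res$cds_end)
  }
  models <- bind_rows(models)
  excluded <- if (length(excluded) > 0) bind_rows(excluded) else
    tibble(transcript_id = character(), reason = character())
  if (nrow(models) == 0) stop("no usable coding transcripts in annotation")

  n_frame <- sum(excluded$reason == "cds_length_not_multiple_of_3")
  if (n_frame > 0) {
    warning(sprintf("excluded %d transcript(s) with CDS length not divisible by 3",
                    n_frame), call. = FALSE)
  }
  if (nrow(excluded) > 0) {
    message(sprintf("excluded %d of %d annotated transcripts (%s)",
                    nrow(excluded), length(tx_ids),
                    paste(sprintf("%s: %d", names(table(excluded$reason)),
                                  table(excluded$reason)), collapse = ", ")))
  }
  if (!is.null(sequences)) {
    sequences <- sequences[models$transcript_id]
    start_codons <- substr(sequences, models$cds_start + 1L,
                           models$cds_start + 3L)
    odd <- !(start_codons %in% c(START_CODON, NEAR_COGNATE_CODONS))
    if (any(odd)) {
      warning(sprintf("%d transcript(s) do not begin their CDS with AUG or a near-cognate codon",
                      sum(odd)), call. = FALSE)
    }
  }
  out <- gene_catalog(models, sequences = sequences)
  attr(out, "excluded") <- excluded
  out
}

#' Select representative isoforms by RNA-seq TPM
#'
#' For each gene, the isoform with the highest TPM in a reference RNA-seq
#' sample becomes the gene's representative; all gene-level quantification
#' downstream uses representative isoforms only. Ties (including genes whose
#' isoforms all have zero TPM) are broken deterministically by the
#' lexicographically smallest transcript_id; all-zero genes are flagged.
#'
#' @param catalog a [gene_catalog()].
#' @param rna_tpm either a data frame with columns `transcript_id` and `tpm`,
#'   or a named numeric vector. Transcripts absent from the table are treated
#'   as TPM 0.
#' @return the catalog with its `representative` mapping filled in (columns
#'   `gene_id`, `transcript_id`, `tpm`, `all_zero`).
#' @export
select_representative_isoforms <- function(catalog, rna_tpm) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.data.frame(rna_tpm)) {
    tpm <- setNames(rna_tpm$tpm, rna_tpm$transcript_id)
  } else {
    tpm <- rna_tpm
  }
  models <- catalog$models
  models$tpm <- unname(tpm[models$transcript_id])
  models$tpm[is.na(models$tpm)] <- 0
  rep_map <- models %>%
    group_by(gene_id) %>%
    mutate(all_zero = all(tpm == 0)) %>%
    arrange(dplyr::desc(tpm), transcript_id, .by_group = TRUE) %>%
    slice(1L) %>%
    ungroup() %>%
    select(gene_id, transcript_id, tpm, all_zero) %>%
    arrange(gene_id)
  catalog$representative <- rep_map
  catalog
}

#' Representative region models of a catalog
#'
#' @param catalog a [gene_catalog()].
#' @return the `models` tibble restricted to representative isoforms (or all
#'   models if no representative mapping has been selected).
#' @export
representative_models <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.null(catalog$representative)) return(catalog$models)
  catalog$models %>%
    semi_join(catalog$representative, by = c("gene_id", "transcript_id"))
}

#' Classify codons as AUG, near-cognate or other
#'
#' Near-cognate start codons are the single-mismatch neighbours of AUG within
#' NUG or AUN: CUG, GUG, UUG, AUA, AUC, AUU.
#'
#' @param codons character vector of 3-mers (RNA or DNA alphabet).
#' @return character vector: `"AUG"`, `"near-cognate"`, or `NA`.
#' @export
classify_start_codon <- function(codons) {
  codons <- normalize_rna(codons)
  out <- rep(NA_character_, length(codons))
  out[codons %in% NEAR_COGNATE_CODONS] <- "near-cognate"
  out[codons == START_CODON] <- "AUG"
  out
}

#' Find upstream start codons and minimal uORFs in 5' leaders
#'
#' Scans every position of the 5' leader, in all three reading phases, for
#' AUG or near-cognate 3-mers that lie entirely upstream of the annotated
#' start codon (`position + 3 <= cds_start`). A site is a minimal (six-base)
#' uORF when the codon is immediately followed, in frame, by a stop codon
#' (UAA/UAG/UGA).
#'
#' @param catalog a [gene_catalog()] with sequences.
#' @param transcript_ids optional subset of transcripts to scan (default: all
#'   transcripts with sequence).
#' @return tibble with columns `transcript_id`, `position` (0-based
#'   transcript coordinate of the codon's first base), `codon`, `codon_class`
#'   (`"AUG"` or `"near-cognate"`), `is_minimal_uorf`.
#' @export
find_upstream_starts <- function(catalog, transcript_ids = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (is.null(catalog$sequences)) {
    stop("catalog carries no sequences; load with a FASTA to scan leaders")
  }
  models <- catalog$models
  if (!is.null(transcript_ids)) {
    models <- models[models$transcript_id %in% transcript_ids, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(models)), function(i) {
    tx <- models$transcript_id[i]
    scan_upstream_starts(catalog$sequences[[tx]], models$cds_start[i],
                         transcript_id = tx)
  })
  bind_rows(out)
}

#' Scan one sequence for upstream start codons
#'
#' Workhorse behind [find_upstream_starts()]; exported for direct use on raw
#' sequences. Leaders shorter than 3 nt yield an empty table.
#'
#' @param sequence transcript sequence (character scalar).
#' @param cds_start 0-based transcript coordinate of the annotated start.
#' @param transcript_id optional label carried into the output.
#' @return tibble as in [find_upstream_starts()].
#' @export
scan_upstream_starts <- function(sequence, cds_start,
                                 transcript_id = NA_character_) {
  sequence <- normalize_rna(sequence)
  empty <- tibble(transcript_id = character(), position = integer(),
                  codon = character(), codon_class = character(),
                  is_minimal_uorf = logical())
  if (cds_start < 3) return(empty)
  pos <- 0:(cds_start - 3L)
  codons <- substring(sequence, pos + 1L, pos + 3L)
  cls <- classify_start_codon(codons)
  keep <- !is.na(cls)
  if (!any(keep)) return(empty)
  pos <- pos[keep]
  codons <- codons[keep]
  cls <- cls[keep]
  nxt <- substring(sequence, pos + 4L, pos + 6L)
  tibble(transcript_id = transcript_id, position = as.integer(pos),
         codon = codons, codon_class = cls,
         is_minimal_uorf = nxt %in% STOP_CODONS)
}

#' Region lengths of the three transcript regions
#'
#' @param models region-model tibble (see [gene_catalog()]).
#' @return tibble with one row per transcript and region (`leader`, `CDS`,
#'   `utr3`, `full`) and its length in nt.
#' @export
region_lengths <- function(models) {
  bind_rows(
    tibble(transcript_id = models$transcript_id, gene_id = models$gene_id,
           region = "leader", region_length = models$cds_start),
    tibble(transcript_id = models$transcript_id, gene_id = models$gene_id,
           region = "CDS", region_length = models$cds_end - models$cds_start),
    tibble(transcript_id = models$transcript_id, gene_id = models$gene_id,
           region = "utr3", region_length = models$length - models$cds_end),
    tibble(transcript_id = models$transcript_id, gene_id = models$gene_id,
           region = "full", region_length = models$length)
  )
}

#' Write / read a region-model table
#'
#' Plain tab-separated exchange format: transcript_id, gene_id, length,
#' cds_start, cds_end.
#'
#' @param catalog a [gene_catalog()].
#' @param path output path.
#' @return `write_region_models()` returns `path` invisibly;
#'   `read_region_models()` returns a [gene_catalog()] without sequences.
#' @export
write_region_models <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  readr::write_tsv(catalog$models, path)
  invisible(path)
}

#' @rdname write_region_models
#' @export
read_region_models <- function(path) {
  models <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              transcript_id = readr::col_character(),
                              gene_id = readr::col_character(),
                              length = readr::col_integer(),
                              cds_start = readr::col_integer(),
                              cds_end = readr::col_integer()))
  gene_catalog(models)
}

#' Write an upstream-start (uORF) table
#'
#' @param sites output of [find_upstream_starts()].
#' @param path output path (TSV).
#' @export
write_uorf_table <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}
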