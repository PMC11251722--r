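# P-site assignment: footprint 5' ends plus a fragment-length-dependent
# offset. The offset rules and retained length windows follow the two library
# protocols (whole-head lysate vs immunoprecipitated, tagged-ribosome
# libraries) and are overridable for other protocols.

#' Footprint processing modes and their P-site offset rules
#'
#' A processing mode bundles the fragment-length window retained for analysis
#' with the length-dependent P-site offset rule:
#' \describe{
#'   \item{whole_head}{keep 20-34 nt; offset 12 nt for 20-31 nt fragments,
#'     13 nt for 32-34 nt fragments.}
#'   \item{immunoprecipitated (alias "ip")}{keep 21-36 nt; offset 12 nt for
#'     21 nt fragments, 13 nt for 22-36 nt fragments.}
#' }
#'
#' @param name `"whole_head"`, `"immunoprecipitated"` or `"ip"`.
#' @param keep_lengths optional length-2 integer vector overriding the
#'   inclusive retained-length window.
#' @param offset_rule optional data frame overriding the offset table, with
#'   columns `min_len`, `max_len`, `offset`; must cover every retained length.
#' @return an object of class `processing_mode`.
#' @export
processing_mode <- function(name = c("whole_head", "immunoprecipitated", "ip"),
                            keep_lengths = NULL, offset_rule = NULL) {
  name <- match.arg(name)
  if (name == "ip") name <- "immunoprecipitated"
  if (is.null(keep_lengths)) {
    keep_lengths <- switch(name,
      whole_head = c(20L, 34L),
      immunoprecipitated = c(21L, 36L))
  }
  if (is.null(offset_rule)) {
    offset_rule <- switch(name,
      whole_head = tibble(min_len = c(20L, 32L), max_len = c(31L, 34L),
                          offset = c(12L, 13L)),
      immunoprecipitated = tibble(min_len = c(21L, 22L), max_len = c(21L, 36L),
                                  offset = c(12L, 13L)))
  }
  offset_rule <- as_tibble(offset_rule)
  covered <- vapply(keep_lengths[1]:keep_lengths[2], function(l) {
    sum(l >= offset_rule$min_len & l <= offset_rule$max_len) == 1L
  }, logical(1))
  if (!all(covered)) {
    stop("offset_rule must define exactly one offset for every retained length")
  }
  structure(list(name = name, keep_lengths = as.integer(keep_lengths),
                 offset_rule = offset_rule),
            class = "processing_mode")
}

#' @export
print.processing_mode <- function(x, ...) {
  cat(sprintf("<processing_mode> %s: keep %d-%d nt; offsets %s\n",
              x$name, x$keep_lengths[1], x$keep_lengths[2],
              paste(sprintf("%d-%d nt -> +%d", x$offset_rule$min_len,
                            x$offset_rule$max_len, x$offset_rule$offset),
                    collapse = ", ")))
  invisible(x)
}

#' Filter footprint fragments by retained length window
#'
#' @param fragments tibble of aligned fragments with columns `transcript_id`,
#'   `five_prime` (0-based transcript coordinate of the fragment 5' end),
#'   `length`, `sample`.
#' @param mode a [processing_mode()].
#' @return the retained fragments; the number dropped is reported via
#'   `message()` and attached as `attr(, "n_dropped_length")`.
#' @export
length_filter <- function(fragments, mode) {
  stopifnot(inherits(mode, "processing_mode"))
  keep <- fragments$length >= mode$keep_lengths[1] &
    fragments$length <= mode$keep_lengths[2]
  out <- fragments[keep, , drop = FALSE]
  message(sprintf("length_filter (%s): retained %d / %d fragments",
                  mode$name, nrow(out), nrow(fragments)))
  attr(out, "n_dropped_length") <- sum(!keep)
  out
}

#' P-site offset for a fragment length
#'
#' @param length integer vector of fragment lengths (nt); every length must
#'   lie inside the mode's retained window (apply [length_filter()] first).
#' @param mode a [processing_mode()].
#' @return integer vector of offsets (nt downstream of the 5' end).
#' @export
psite_offset <- function(length, mode) {
  stopifnot(inherits(mode, "processing_mode"))
  bad <- length < mode$keep_lengths[1] | length > mode$keep_lengths[2]
  if (any(bad)) {
    stop(sprintf("fragment length(s) outside the retained window %d-%d: %s",
                 mode$keep_lengths[1], mode$keep_lengths[2],
                 paste(unique(length[bad]), collapse = ", ")))
  }
  rule <- mode$offset_rule
  off <- rep(NA_integer_, length(length))
  for (i in seq_len(nrow(rule))) {
    sel <- length >= rule$min_len[i] & length <= rule$max_len[i]
    off[sel] <- rule$offset[i]
  }
  off
}

#' Assign P-sites to length-filtered fragments and classify by region
#'
#' The P-site is `five_prime + offset(length)`. A P-site is on the CDS when
#' it lies between the annotated start and stop codons, i.e. in
#' `[cds_start, cds_end)`; upstream P-sites are on the 5' leader and
#' downstream ones on the 3' UTR. Records whose P-site falls at or beyond the
#' transcript end, and records on transcripts absent from the catalog, are
#' dropped and counted.
#'
#' @param fragments length-filtered fragment tibble (see [length_filter()]).
#' @param mode a [processing_mode()].
#' @param catalog a [gene_catalog()].
#' @param max_unknown_frac error if more than this fraction of fragments maps
#'   to transcripts missing from the catalog (default 0.1).
#' @return tibble of P-site records (`transcript_id`, `psite`, `length`,
#'   `sample`, `region`). Dropped-record tallies are attached as
#'   `attr(, "dropped")` (named integer: `unknown_transcript`,
#'   `psite_out_of_bounds`).
#' @export
assign_psites <- function(fragments, mode, catalog, max_unknown_frac = 0.1) {
  stopifnot(inherits(mode, "processing_mode"), inherits(catalog, "gene_catalog"))
  models <- catalog$models
  n_in <- nrow(fragments)
  known <- fragments$transcript_id %in% models$transcript_id
  n_unknown <- sum(!known)
  if (n_in > 0 && n_unknown / n_in > max_unknown_frac) {
    stop(sprintf("%d / %d fragments (%.1f%%) map to transcripts missing from the catalog",
                 n_unknown, n_in, 100 * n_unknown / n_in))
  }
  fr <- fragments[known, , drop = FALSE]
  fr$psite <- fr$five_prime + psite_offset(fr$length, mode)
  m <- match(fr$transcript_id, models$transcript_id)
  tx_len <- models$length[m]
  in_bounds <- fr$psite < tx_len & fr$psite >= 0
  n_oob <- sum(!in_bounds)
  fr <- fr[in_bounds, , drop = FALSE]
  m <- m[in_bounds]
  fr$region <- dplyr::case_when(
    fr$psite < models$cds_start[m] ~ "leader",
    fr$psite < models$cds_end[m] ~ "CDS",
    TRUE ~ "utr3"
  )
  out <- fr[, c("transcript_id", "psite", "length", "sample", "region")]
  dropped <- c(unknown_transcript = n_unknown, psite_out_of_bounds = n_oob)
  if (sum(dropped) > 0) {
    message(sprintf("assign_psites: %d in, %d out (dropped: %d unknown transcript, %d out of bounds)",
                    n_in, nrow(out), n_unknown, n_oob))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Reading-frame fractions of CDS P-sites
#'
#' The fraction of CDS-region P-sites in each of the three frames relative to
#' the annotated start codon; a strong frame-0 excess is the 3-nt
#' periodicity signature of elongating ribosomes.
#'
#' @param psites P-site tibble (see [assign_psites()]); only rows with
#'   `region == "CDS"` are used.
#' @param catalog a [gene_catalog()].
#' @return named numeric of length 3 (`frame0`, `frame1`, `frame2`) summing
#'   to 1, with `attr(, "n")` the number of CDS P-sites; all-`NA` with a
#'   warning when there are none.
#' @export
frame_fractions <- function(psites, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  cds <- psites[psites$region == "CDS", , drop = FALSE]
  out <- setNames(rep(NA_real_, 3), paste0("frame", 0:2))
  if (nrow(cds) == 0) {
    warning("no CDS P-sites; frame fractions undefined", call. = FALSE)
    attr(out, "n") <- 0L
    return(out)
  }
  m <- match(cds$transcript_id, catalog$models$transcript_id)
  frame <- (cds$psite - catalog$models$cds_start[m]) %% 3L
  tab <- tabulate(frame + 1L, nbins = 3L)
  out[] <- tab / sum(tab)
  attr(out, "n") <- sum(tab)
  out
}

#' Read / write footprint fragments (BED-like TSV)
#'
#' The exchange format is a headerless 6-column BED-like TSV in transcript
#' coordinates: transcript_id, start (0-based fragment 5' end), end
#' (half-open), name, length, sample.
#'
#' @param path file path.
#' @return tibble with columns `transcript_id`, `five_prime`, `length`,
#'   `sample`.
#' @export
read_fragments_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("transcript_id", "start", "end",
                                             "name", "length", "sample"),
                         show_col_types = FALSE,
                         col_types = "ciicic")
  tibble(transcript_id = bed$transcript_id, five_prime = bed$start,
         length = bed$length, sample = bed$sample)
}

#' @rdname read_fragments_bed
#' @param fragments fragment tibble.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- tibble(transcript_id = fragments$transcript_id,
                start = fragments$five_prime,
                end = fragments$five_prime + fragments$length,
                name = sprintf("frag%d", seq_len(nrow(fragments))),
                length = fragments$length,
                sample = fragments$sample)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Read footprint fragments from a transcript-space BAM file
#'
#' Extracts the 5' end and read length of each aligned record from a BAM file
#' whose reference sequences are transcripts (as produced by a
#' transcriptome-space aligner). Reads are expected to be uniquely mapped and
#' already deduplicated.
#'
#' @param path BAM file path.
#' @param sample sample label attached to every record.
#' @return fragment tibble as in [read_fragments_bed()].
#' @export
read_fragments_bam <- function(path, sample) {
  b <- Rsamtools::scanBam(path,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  tibble(transcript_id = as.character(b$rname),
         five_prime = b$pos - 1L,
         length = b$qwidth,
         sample = sample)
}

#' Read / write P-site tables (TSV)
#'
#' @param path file path.
#' @param psites P-site tibble (see [assign_psites()]).
#' @export
write_psites <- function(psites, path) {
  readr::write_tsv(as_tibble(psites), path)
  invisible(path)
}

#' @rdname write_psites
#' @export
read_psites <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    transcript_id = readr::col_character(),
                    psite = readr::col_integer(),
                    length = readr::col_integer(),
                    sample = readr::col_character(),
                    region = readr::col_character()))
}
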