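# Region-resolved density quantification: raw P-site counts per gene and
# region, RPM, within-region-class TPM, translational efficiency (TE), and
# the 5' leader / CDS density ratio.

REGIONS <- c("leader", "CDS", "utr3")

#' Generic TPM from counts and feature lengths
#'
#' `tpm_i = 1e6 * (count_i / length_i) / sum_j(count_j / length_j)`.
#'
#' @param counts non-negative numeric vector.
#' @param lengths positive numeric vector of feature lengths (nt).
#' @return numeric TPM vector summing to 1e6 (all-`NA` if every count is 0).
#' @export
tpm_from_counts <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  rate <- counts / lengths
  denom <- sum(rate)
  if (denom == 0) return(rep(NA_real_, length(counts)))
  1e6 * rate / denom
}

#' Count P-sites per gene, region and sample
#'
#' Counts are taken over representative isoforms only; P-sites on
#' non-representative isoforms are dropped and counted. Every gene appears in
#' every region row (`leader`, `CDS`, `utr3`, plus a `full` whole-transcript
#' row) for every sample, with zero counts where no P-sites landed.
#'
#' @param psites classified P-site tibble (see [assign_psites()]).
#' @param catalog a [gene_catalog()] (representative mapping applied if
#'   present).
#' @return region density tibble with columns `gene_id`, `region`, `sample`,
#'   `raw_count`, `region_length`. The number of P-sites dropped as
#'   non-representative is attached as `attr(, "n_dropped_nonrep")`.
#' @export
count_by_region <- function(psites, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  models <- representative_models(catalog)
  n_in <- nrow(psites)
  keep <- psites$transcript_id %in% models$transcript_id
  ps <- psites[keep, , drop = FALSE]
  n_dropped <- n_in - nrow(ps)
  if (n_dropped > 0) {
    message(sprintf("count_by_region: dropped %d P-sites on non-representative isoforms",
                    n_dropped))
  }
  samples <- sort(unique(ps$sample))
  if (length(samples) == 0) stop("no P-sites to count")
  gene_of <- setNames(models$gene_id, models$transcript_id)
  ps$gene_id <- unname(gene_of[ps$transcript_id])

  counted <- ps %>%
    count(gene_id, region, sample, name = "raw_count")
  full <- ps %>%
    count(gene_id, sample, name = "raw_count") %>%
    mutate(region = "full")
  counted <- bind_rows(counted, full)

  grid <- tidyr::expand_grid(gene_id = sort(unique(models$gene_id)),
                             region = c(REGIONS, "full"),
                             sample = samples)
  lens <- region_lengths(models) %>% select(gene_id, region, region_length)
  out <- grid %>%
    left_join(counted, by = c("gene_id", "region", "sample")) %>%
    mutate(raw_count = ifelse(is.na(raw_count), 0L, raw_count)) %>%
    left_join(lens, by = c("gene_id", "region")) %>%
    arrange(gene_id, region, sample)
  attr(out, "n_dropped_nonrep") <- n_dropped
  out
}

#' Add RPM (reads per million mapped) to a region density table
#'
#' The per-sample denominator is the total number of counted P-sites in that
#' sample (the sum of the `full` rows).
#'
#' @param table output of [count_by_region()].
#' @return the table with an `rpm` column.
#' @export
region_rpm <- function(table) {
  totals <- table %>%
    filter(region == "full") %>%
    group_by(sample) %>%
    summarise(total = sum(raw_count), .groups = "drop")
  table %>%
    left_join(totals, by = "sample") %>%
    mutate(rpm = ifelse(total > 0, 1e6 * raw_count / total, NA_real_)) %>%
    select(-total)
}

#' Add within-region-class TPM to a region density table
#'
#' TPM is computed per sample and per region class: leader rows are
#' normalized against all genes' leaders, CDS rows against all CDSs, and so
#' on, each class summing to 1e6. Rows with zero region length (e.g.
#' leaderless transcripts) are excluded from the normalization and get `NA`.
#' The per-region-class denominator is one per-sample constant, so any
#' between-gene or between-cell-type comparison of these densities is
#' invariant to it.
#'
#' @param table output of [count_by_region()].
#' @param region_scope region classes to fill (default: all present).
#' @return the table with a `tpm` column.
#' @export
region_tpm <- function(table, region_scope = NULL) {
  if (is.null(region_scope)) region_scope <- unique(table$region)
  out <- table
  out$tpm <- NA_real_
  for (s in unique(out$sample)) {
    for (reg in region_scope) {
      sel <- out$sample == s & out$region == reg & out$region_length > 0
      if (!any(sel)) next
      vals <- tpm_from_counts(out$raw_count[sel], out$region_length[sel])
      if (all(is.na(vals))) {
        warning(sprintf("all-zero counts for region %s in sample %s; TPM undefined",
                        reg, s), call. = FALSE)
      }
      out$tpm[sel] <- vals
    }
  }
  out
}

#' RNA-seq TPM table from gene counts
#'
#' RNA TPM uses the full length of each gene's representative transcript.
#'
#' @param rna_counts tibble with columns `gene_id`, `sample`, `count`.
#' @param catalog a [gene_catalog()].
#' @return tibble `gene_id`, `sample`, `count`, `length`, `tpm`.
#' @export
rna_tpm_table <- function(rna_counts, catalog) {
  models <- representative_models(catalog)
  lens <- setNames(models$length, models$gene_id)
  out <- as_tibble(rna_counts)
  out$length <- unname(lens[out$gene_id])
  if (any(is.na(out$length))) {
    stop("RNA counts reference genes absent from the catalog: ",
         paste(head(unique(out$gene_id[is.na(out$length)])), collapse = ", "))
  }
  out %>%
    group_by(sample) %>%
    mutate(tpm = tpm_from_counts(count, length)) %>%
    ungroup()
}

#' Translational efficiency (TE)
#'
#' TE is the ribosome-footprint density on the CDS (TPM) divided by the mRNA
#' level (TPM). TE is defined only for genes with at least one footprint read
#' on the CDS and at least one RNA read; undefined values are flagged, never
#' emitted as infinities or sentinels.
#'
#' @param fp region density table with TPM filled (see [region_tpm()]);
#'   its `CDS` rows are used.
#' @param rna RNA TPM table (see [rna_tpm_table()]), matching sample labels.
#' @return TE tibble: `gene_id`, `sample`, `fp_cds_count`, `fp_cds_tpm`,
#'   `rna_count`, `rna_tpm`, `te`, `te_defined`.
#' @export
translational_efficiency <- function(fp, rna) {
  cds <- fp %>%
    filter(region == "CDS") %>%
    select(gene_id, sample, fp_cds_count = raw_count, fp_cds_tpm = tpm)
  rna_sel <- rna %>% select(gene_id, sample, rna_count = count, rna_tpm = tpm)
  out <- cds %>%
    left_join(rna_sel, by = c("gene_id", "sample")) %>%
    mutate(rna_count = ifelse(is.na(rna_count), 0L, rna_count),
           te_defined = fp_cds_count >= 1 & rna_count >= 1 &
             !is.na(rna_tpm) & rna_tpm > 0,
           te = ifelse(te_defined, fp_cds_tpm / rna_tpm, NA_real_))
  out
}

#' 5' leader to CDS density ratio
#'
#' Per gene and sample, the ratio of footprint density on the 5' leader (TPM)
#' to density on the CDS (TPM). Defined only for genes with a nonzero-length
#' leader and nonzero CDS footprint TPM; other genes are excluded and
#' counted.
#'
#' @param fp region density table with TPM filled (see [region_tpm()]).
#' @return tibble `gene_id`, `sample`, `leader_tpm`, `cds_tpm`,
#'   `leader_cds_ratio`, with `attr(, "n_excluded")`.
#' @export
leader_cds_ratio <- function(fp) {
  wide <- fp %>%
    filter(region %in% c("leader", "CDS")) %>%
    select(gene_id, sample, region, tpm, region_length) %>%
    tidyr::pivot_wider(names_from = region,
                       values_from = c(tpm, region_length))
  ok <- !is.na(wide$tpm_leader) & wide$region_length_leader > 0 &
    !is.na(wide$tpm_CDS) & wide$tpm_CDS > 0
  out <- wide[ok, , drop = FALSE] %>%
    mutate(leader_cds_ratio = tpm_leader / tpm_CDS) %>%
    select(gene_id, sample, leader_tpm = tpm_leader, cds_tpm = tpm_CDS,
           leader_cds_ratio)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Expression filter on RNA TPM
#'
#' Genes with RNA TPM strictly greater than `threshold` in all required
#' samples.
#'
#' @param rna RNA TPM table (see [rna_tpm_table()]).
#' @param threshold TPM cutoff (strict; default 1).
#' @param samples samples that must each pass (default: all samples in the
#'   table).
#' @return character vector of gene ids.
#' @export
expression_filter <- function(rna, threshold = 1, samples = NULL) {
  if (is.null(samples)) samples <- unique(rna$sample)
  rna %>%
    filter(sample %in% samples) %>%
    group_by(gene_id) %>%
    summarise(pass = sum(!is.na(tpm) & tpm > threshold) == length(samples),
              .groups = "drop") %>%
    filter(pass) %>%
    pull(gene_id)
}

#' Write / read a region density or TE table (TSV)
#'
#' @param table tibble to write.
#' @param path file path.
#' @export
write_density_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

#' @rdname write_density_table
#' @export
read_density_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
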