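# Joint two-cell-type TE analysis: paired TE tables, differential-translation
# calling (DTT), TE spread and histogram summaries, correlation, and binning
# by mRNA expression ratio.

#' Pair TE tables of two cell types
#'
#' Builds the paired per-gene table underlying all two-cell-type comparisons:
#' TE in each cell type, their ratio (A over B), and the RNA abundance ratio.
#' Ratios are defined only where both members are defined and positive.
#'
#' @param te TE tibble (see [translational_efficiency()]) containing both
#'   cell types in its `sample` column.
#' @param cell_type_a,cell_type_b sample labels of the two cell types
#'   (defaults `"neuron"` and `"glia"`).
#' @return tibble with columns `gene_id`, `te_a`, `te_b`, `te_ratio`,
#'   `rna_tpm_a`, `rna_tpm_b`, `rna_ratio`, `both_defined`.
#' @export
pair_te_tables <- function(te, cell_type_a = "neuron", cell_type_b = "glia") {
  pick <- function(ct, suffix) {
    d <- te[te$sample == ct, c("gene_id", "te", "rna_tpm")]
    names(d)[2:3] <- paste0(c("te_", "rna_tpm_"), suffix)
    d
  }
  a <- pick(cell_type_a, "a")
  b <- pick(cell_type_b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("one of the requested cell types is absent from the TE table")
  }
  a %>%
    dplyr::inner_join(b, by = "gene_id") %>%
    mutate(both_defined = !is.na(te_a) & !is.na(te_b) & te_b > 0,
           te_ratio = ifelse(both_defined, te_a / te_b, NA_real_),
           rna_ratio = ifelse(!is.na(rna_tpm_a) & !is.na(rna_tpm_b) &
                                rna_tpm_b > 0,
                              rna_tpm_a / rna_tpm_b, NA_real_)) %>%
    select(gene_id, te_a, te_b, te_ratio, rna_tpm_a, rna_tpm_b, rna_ratio,
           both_defined)
}

#' Call differentially translated transcripts (DTTs)
#'
#' A gene is a DTT when its TE in cell type A exceeds that in cell type B by
#' strictly more than `fold` (default 10), among genes expressed above the
#' RNA TPM gate (strictly greater than `expression_gate`, default 1) in both
#' cell types and with TE defined in both.
#'
#' @param paired paired TE tibble (see [pair_te_tables()]).
#' @param fold ratio threshold (strict inequality).
#' @param expression_gate RNA TPM gate applied in both cell types (strict).
#' @return character vector of DTT gene ids.
#' @export
call_dtts <- function(paired, fold = 10, expression_gate = 1) {
  candidates <- paired %>%
    filter(both_defined,
           !is.na(rna_tpm_a) & rna_tpm_a > expression_gate,
           !is.na(rna_tpm_b) & rna_tpm_b > expression_gate)
  candidates$gene_id[candidates$te_ratio > fold]
}

#' @rdname call_dtts
#' @return `flag_dtts()` returns the paired table with an `is_dtt` column.
#' @export
flag_dtts <- function(paired, fold = 10, expression_gate = 1) {
  paired$is_dtt <- paired$gene_id %in%
    call_dtts(paired, fold = fold, expression_gate = expression_gate)
  paired
}

#' TE spread between two percentiles
#'
#' The fold difference between the upper and lower percentile of the TE
#' distribution (default 95th over 5th), using linear-interpolation
#' percentiles.
#'
#' @param te_values numeric TE values; `NA`s are dropped. Fewer than 20
#'   defined values triggers a small-sample warning (tail percentiles are
#'   then poorly determined); fewer than 2 is an error.
#' @param lo_pct,hi_pct percentiles in \[0, 100\].
#' @return the fold difference (scalar); `NA` with a warning when the lower
#'   percentile is zero.
#' @export
te_spread <- function(te_values, lo_pct = 5, hi_pct = 95) {
  te_values <- te_values[!is.na(te_values)]
  if (length(te_values) < 2) {
    stop("need at least 2 defined TE values to estimate the spread")
  }
  if (length(te_values) < 20) {
    warning("fewer than 20 defined TE values; percentile spread is unstable",
            call. = FALSE)
  }
  q <- quantile(te_values, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  if (q[1] == 0) {
    warning("lower percentile is zero; spread undefined", call. = FALSE)
    return(NA_real_)
  }
  q[2] / q[1]
}

#' Histogram of TE in log2 bins
#'
#' Counts genes in left-closed bins `[k*w, (k+1)*w)` of log2(TE) with bin
#' edges at integer multiples of the bin width (default 0.2 in log2 units).
#'
#' @param te_values positive TE values (`NA`s dropped; nonpositive values are
#'   an error).
#' @param bin_width bin width in log2 units.
#' @return tibble `bin_left`, `bin_right` (log2 units), `count`; counts sum
#'   to the number of included genes.
#' @export
te_histogram <- function(te_values, bin_width = 0.2) {
  te_values <- te_values[!is.na(te_values)]
  if (any(te_values <= 0)) stop("TE values must be positive for log2 binning")
  l2 <- log2(te_values)
  idx <- floor(l2 / bin_width)
  tab <- table(idx)
  lefts <- as.numeric(names(tab)) * bin_width
  tibble(bin_left = lefts, bin_right = lefts + bin_width,
         count = as.integer(tab)) %>%
    arrange(bin_left)
}

#' Squared Pearson correlation
#'
#' @param x,y paired numeric vectors.
#' @param log_transform log10-transform both vectors first; pairs with a
#'   nonpositive member are excluded.
#' @return R squared (scalar); `NA` with a warning if fewer than 3 finite
#'   pairs remain or either variance is zero.
#' @export
correlation_r2 <- function(x, y, log_transform = FALSE) {
  stopifnot(length(x) == length(y))
  if (log_transform) {
    ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
    x <- log10(x[ok]); y <- log10(y[ok])
  } else {
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
  }
  if (length(x) < 3) {
    warning("fewer than 3 usable pairs; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; R^2 undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(x, y)^2
}

#' Bin genes by mRNA expression ratio and collect TE distributions
#'
#' Groups genes into left-closed bins of log2(mRNA ratio A/B) and returns the
#' per-bin TE values (by default TE in cell type B, i.e. how translation in B
#' tracks relative transcription). Empty bins are retained.
#'
#' @param paired paired TE tibble (see [pair_te_tables()]), typically already
#'   expression-gated.
#' @param bin_edges increasing numeric vector of bin edges in log2 units of
#'   the RNA ratio; values outside the range are dropped.
#' @param value which TE to collect: `"te_b"` (default) or `"te_a"`.
#' @return named list (one element per bin, label `[lo,hi)`) of numeric TE
#'   vectors.
#' @export
bin_by_mrna_ratio <- function(paired, bin_edges = seq(-4, 4, by = 2),
                              value = c("te_b", "te_a")) {
  value <- match.arg(value)
  stopifnot(length(bin_edges) >= 2, !is.unsorted(bin_edges, strictly = TRUE))
  dat <- paired %>% filter(!is.na(rna_ratio), rna_ratio > 0, !is.na(.data[[value]]))
  l2 <- log2(dat$rna_ratio)
  labels <- sprintf("[%g,%g)", bin_edges[-length(bin_edges)], bin_edges[-1])
  out <- setNames(vector("list", length(labels)), labels)
  bin <- findInterval(l2, bin_edges, rightmost.closed = FALSE, left.open = FALSE)
  for (k in seq_along(labels)) {
    out[[k]] <- dat[[value]][bin == k]
  }
  out
}

#' Rank-based tests between groups (thin wrappers)
#'
#' Convenience wrappers around the established routines used for
#' distributional comparisons: the Mann-Whitney (Wilcoxon rank-sum) test for
#' two groups and the Kruskal-Wallis test across several groups.
#'
#' @param x,y numeric vectors (two-group test).
#' @param groups named list of numeric vectors (multi-group test), e.g. the
#'   output of [bin_by_mrna_ratio()].
#' @return the `htest` object from [stats::wilcox.test()] or
#'   [stats::kruskal.test()].
#' @export
rank_test_two_groups <- function(x, y) {
  stats::wilcox.test(x, y)
}

#' @rdname rank_test_two_groups
#' @export
rank_test_groups <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  stats::kruskal.test(groups)
}

#' Write a paired TE table and a DTT gene list
#'
#' @param paired paired TE tibble with `is_dtt` flag (see [flag_dtts()]).
#' @param path output TSV path.
#' @export
write_paired_te <- function(paired, path) {
  readr::write_tsv(as_tibble(paired), path)
  invisible(path)
}

#' @rdname write_paired_te
#' @param genes character vector of DTT gene ids.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
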