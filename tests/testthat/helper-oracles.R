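# Independent brute-force oracles. These deliberately use naive loops and
# explicit codon tables so they share no code path with the package
# implementations they check.

oracle_scan_starts <- function(sequence, cds_start) {
  sequence <- chartr("Tt", "Uu", toupper(sequence))
  aug <- "AUG"
  near <- c("CUG", "GUG", "UUG", "AUA", "AUC", "AUU")
  stops <- c("UAA", "UAG", "UGA")
  hits <- list()
  p <- 0
  while (p + 3 <= cds_start) {
    codon <- substr(sequence, p + 1, p + 3)
    if (codon == aug || codon %in% near) {
      nxt <- substr(sequence, p + 4, p + 6)
      hits[[length(hits) + 1]] <- data.frame(
        position = p, codon = codon,
        codon_class = if (codon == aug) "AUG" else "near-cognate",
        is_minimal_uorf = nxt %in% stops)
    }
    p <- p + 1
  }
  if (length(hits) == 0) {
    return(data.frame(position = integer(), codon = character(),
                      codon_class = character(), is_minimal_uorf = logical()))
  }
  do.call(rbind, hits)
}

# Tally P-sites per gene/region/sample by iterating record by record.
oracle_region_counts <- function(psites, models) {
  key <- list()
  for (i in seq_len(nrow(psites))) {
    tx <- psites$transcript_id[i]
    m <- models[models$transcript_id == tx, ]
    p <- psites$psite[i]
    region <- if (p < m$cds_start) "leader"
              else if (p < m$cds_end) "CDS" else "utr3"
    k <- paste(m$gene_id, region, psites$sample[i], sep = "\r")
    key[[k]] <- (if (is.null(key[[k]])) 0L else key[[k]]) + 1L
  }
  if (length(key) == 0) {
    return(data.frame(gene_id = character(), region = character(),
                      sample = character(), raw_count = integer()))
  }
  parts <- strsplit(names(key), "\r", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1),
             region = vapply(parts, `[`, "", 2),
             sample = vapply(parts, `[`, "", 3),
             raw_count = unlist(key, use.names = FALSE))
}

# Accumulation score by explicit tiling of the window in the codon's frame.
oracle_codon_score <- function(position_counts, codon_position, tx_len,
                               window = 50, include_focal = TRUE) {
  tile_count <- function(s) {
    if (s < 0 || s + 3 > tx_len) return(NA_real_)
    sum(position_counts[(s + 1):(s + 3)])
  }
  ks <- seq(-(window %/% 3), window %/% 3)
  tiles <- vapply(codon_position + 3 * ks, tile_count, numeric(1))
  focal <- tiles[ks == 0]
  pool <- if (include_focal) tiles else tiles[ks != 0]
  pool <- pool[!is.na(pool)]
  if (length(pool) == 0 || mean(pool) == 0) return(NA_real_)
  focal / mean(pool)
}
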