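#!/usr/bin/env Rscript

# Stage 5: upstream ORFs and ribosome stalling.
#
# Scans 5' leaders for upstream AUG / near-cognate start codons and minimal
# six-base uORFs, aggregates the metagene profile around upstream AUGs,
# compares the leader/CDS density bias between cell types on the DTT set,
# computes per-codon footprint accumulation scores on leaders and CDSs, and
# ranks genes by start-codon accumulation.

suppressMessages(library(ribotype))
suppressMessages(library(dplyr))

data_dir <- file.path("results", "data")
catalog <- load_transcript_models(file.path(data_dir, "annotation.gtf"),
                                  file.path(data_dir, "transcripts.fa"))
catalog <- select_representative_isoforms(
  catalog, setNames(rep(1, nrow(catalog$models)),
                    catalog$models$transcript_id))
psites <- read_psites(file.path("results", "psites.tsv"))

uorfs <- find_upstream_starts(catalog)
write_uorf_table(uorfs, file.path("results", "uorf_sites.tsv"))
cat(sprintf("upstream start sites: %d (%d AUG, %d near-cognate; %d minimal six-base uORFs)\n",
            nrow(uorfs), sum(uorfs$codon_class == "AUG"),
            sum(uorfs$codon_class == "near-cognate"),
            sum(uorfs$is_minimal_uorf)))

# leader/CDS bias of the called DTTs, per cell type
ratios <- read_density_table(file.path("results", "leader_cds_ratio.tsv"))
dtts <- readLines(file.path("results", "dtt_genes.txt"))
med <- ratios %>%
  filter(gene_id %in% dtts) %>%
  group_by(sample) %>%
  summarise(median_ratio = median(leader_cds_ratio), .groups = "drop")
print.data.frame(as.data.frame(med), row.names = FALSE)
fold <- med$median_ratio[med$sample == "glia"] /
  med$median_ratio[med$sample == "neuron"]
cat(sprintf("DTT leader/CDS ratio, glia over neuron: %.1f-fold\n", fold))

# metagene around upstream AUGs, per cell type
anchors <- uaug_anchors(uorfs)
for (ct in unique(psites$sample)) {
  prof <- metagene_profile(psites[psites$sample == ct, ], anchors,
                           anchor_kind = "upstream_AUG")
  write_metagene(prof, file.path("results",
                                 sprintf("metagene_uaug_%s.tsv", ct)))
}

# per-codon accumulation scores, glia
leader_sites <- leader_codon_sites(catalog, include_frame_mates = TRUE)
cds_sites <- cds_codon_sites(catalog)
scores <- bind_rows(
  stall_score_table(psites, catalog, leader_sites, sample = "glia"),
  stall_score_table(psites, catalog, cds_sites, sample = "glia"))
write_stall_scores(scores, file.path("results", "stall_scores_glia.tsv"))
for (reg in c("leader", "CDS")) {
  agg <- aggregate_scores_by_codon(scores, reg)
  write_codon_summary(agg, file.path("results",
                                     sprintf("codon_summary_%s_glia.tsv",
                                             reg)))
  top <- agg %>% filter(n >= 5) %>% arrange(desc(median_score)) %>% head(3)
  cat(sprintf("top %s codons by median accumulation (glia): %s\n", reg,
              paste(sprintf("%s=%.2f", top$codon, top$median_score),
                    collapse = ", ")))
}

# start-codon accumulation ranking per cell type
for (ct in unique(psites$sample)) {
  acc <- start_codon_accumulation(psites, catalog, sample = ct)
  write_density_table(acc, file.path(
    "results", sprintf("start_codon_accumulation_%s.tsv", ct)))
}
cat("wrote uORF table, uAUG metagenes, stall scores and start-codon rankings\n")
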