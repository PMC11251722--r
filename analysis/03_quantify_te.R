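#!/usr/bin/env Rscript

# Stage 3: region-resolved densities and translational efficiency.
#
# Counts P-sites per gene and region, computes RPM and within-region-class
# TPM, RNA TPM from the paired RNA-seq counts, TE = CDS footprint TPM / RNA
# TPM per cell type, and the 5' leader / CDS density ratio.

suppressMessages(library(ribotype))

catalog <- read_region_models(file.path("results", "region_models.tsv"))
catalog <- select_representative_isoforms(
  catalog, setNames(rep(1, nrow(catalog$models)),
                    catalog$models$transcript_id))
psites <- read_psites(file.path("results", "psites.tsv"))

fp <- region_tpm(region_rpm(count_by_region(psites, catalog)))
write_density_table(fp, file.path("results", "region_density.tsv"))

rna_counts <- readr::read_tsv(file.path("results", "data", "rna_counts.tsv"),
                              show_col_types = FALSE)
rna <- rna_tpm_table(rna_counts, catalog)
te <- translational_efficiency(fp, rna)
write_density_table(te, file.path("results", "te.tsv"))

ratios <- leader_cds_ratio(fp)
write_density_table(ratios, file.path("results", "leader_cds_ratio.tsv"))

for (ct in unique(te$sample)) {
  v <- te$te[te$sample == ct & te$te_defined]
  cat(sprintf("%s: %d genes with defined TE; median %.2f; 5-95%% spread %.1f-fold\n",
              ct, length(v), median(v), te_spread(v)))
}
cat("wrote region_density.tsv, te.tsv, leader_cds_ratio.tsv\n")
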