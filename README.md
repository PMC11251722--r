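# ribotype

Cell-type-resolved ribosome profiling analysis in R: from aligned footprint
fragments to translational efficiency, differential translation between two
cell types, upstream-ORF annotation and ribosome stalling scores.

## What it is for

Ribosome profiling (Ribo-seq) sequences the short mRNA fragments protected
by ribosomes, so footprint density measures translation at codon
resolution. Combined with RNA-seq, it separates transcription from
translation. `ribotype` is for studies that compare translation between two
genetically defined cell populations — e.g. neurons versus glia in an
insect brain — and ask which transcripts are translationally suppressed in
one cell type, and whether ribosomes stall on upstream AUGs and minimal
uORFs in the 5′ leader of the suppressed transcripts.

The core quantities, in the field's standard notation:

- **P-site position** of a footprint of length *L*: its 5′ end plus a
  length-dependent offset (12 nt for 20–31 nt fragments and 13 nt for
  32–34 nt in whole-tissue libraries; 12 nt for 21 nt and 13 nt for
  22–36 nt in immunoprecipitated, tagged-ribosome libraries). A footprint
  is on the CDS if its P-site lies between the annotated start and stop
  codons.
- **Translational efficiency** of gene *g*:
  TE_g = (footprint TPM on CDS_g) / (mRNA TPM_g), defined for genes with
  ≥1 read in both assays.
- **DTT** (differentially translated transcript): TE ratio between the two
  cell types strictly greater than a fold threshold (default 10×), among
  genes with RNA TPM > 1 in both.
- **Leader/CDS ratio**: footprint TPM on the 5′ leader over footprint TPM
  on the CDS — the signature of leader-biased ribosome distribution.
- **Accumulation (stall) score** of a codon: P-sites on the codon divided
  by the mean P-sites per 3-nt tile over the surrounding ±50 nt, tiled in
  the codon's frame; dimensionless, 1 = no accumulation.

A seeded synthetic-data generator (`simulation_config()`,
`simulate_experiment()`) produces transcriptomes with planted uAUGs/minimal
uORFs, known per-gene per-cell-type TE, a designated DTT set, cell-type
specific uAUG stalling and 3-nt CDS periodicity, so the whole pipeline is
testable with known ground truth and no downloads.

## Worked example

The `analysis/` directory holds the numbered drivers of the full study on
the simulated dataset. Running them in order:

```sh
Rscript analysis/01_simulate.R       # generate the ground-truth experiment
Rscript analysis/02_psites.R         # region models + P-site assignment
Rscript analysis/03_quantify_te.R    # densities, TE, leader/CDS ratios
Rscript analysis/04_compare_dtt.R    # neuron vs glia, DTT calling
Rscript analysis/05_uorf_stalling.R  # uORFs, metagenes, stall scores
```

prints, among other things:

```
simulated 500 genes (25 planted DTTs at 20x, 1017 uAUG sites)
3980207 P-sites assigned; 96.8% on CDS
CDS frame fractions: 0.900 / 0.050 / 0.050 (3-nt periodicity)
neuron: 500 genes with defined TE; median 0.67; 5-95% spread 21.2-fold
DTTs called: 25; planted: 25; recall 1.00, precision 1.00
neuron vs glia TE R^2 (log10): 0.658
DTT leader/CDS ratio, glia over neuron: 9.1-fold
```

Reading this: ~97% of P-sites fall on coding sequence and 90% of CDS
P-sites sit in frame 0 — the periodicity signature of elongating
ribosomes, matching the generator's 0.90/0.05/0.05 frame weights. TE
spans a ~21-fold range between the 5th and 95th percentile. All 25 genes
planted with 20-fold glial TE suppression are recovered by the strict
>10× rule with no false calls, and on exactly those genes the glial
footprint distribution is ~9-fold more leader-biased than the neuronal
one — the uORF-stalling signature the comparison is designed to expose.
All tables land under `results/`.

Equivalent programmatic use:

```r
library(ribotype)
sim  <- simulate_experiment(simulation_config(seed = 1))
mode <- processing_mode("immunoprecipitated")
ps   <- assign_psites(length_filter(sim$fragments, mode), mode, sim$catalog)
fp   <- region_tpm(region_rpm(count_by_region(ps, sim$catalog)))
te   <- translational_efficiency(fp, rna_tpm_table(sim$rna_counts, sim$catalog))
call_dtts(pair_te_tables(te, "neuron", "glia"))
```

`run_pipeline()` executes the same stages from a single YAML config on any
GTF/FASTA + fragment TSV + RNA count inputs and writes a manifest with
per-stage record counts.

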