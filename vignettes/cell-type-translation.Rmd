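---
title: "Quantifying cell-type-specific translation from ribosome profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-type-specific translation from ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribotype)
```

# The analysis

Ribosome profiling (Ribo-seq) sequences the ~20–36 nt mRNA fragments that
ribosomes protect from RNase digestion. Where ribosomes sit, footprints
accumulate, so footprint density reports translation with single-codon
resolution. Paired with RNA-seq from the same material, it separates two
layers of regulation: how much mRNA a gene makes, and how efficiently that
mRNA is translated. `ribotype` implements the comparative analysis used to
contrast translation between two genetically labelled cell populations —
the motivating case is neurons versus glia, where selective translational
suppression of neuronal transcripts in glia, mediated by upstream open
reading frames (uORFs) in long 5′ leaders, sharpens the proteomic
distinction between the two cell types beyond what transcription alone
provides.

Every stage operates in transcript coordinates (0-based, half-open).
A transcript is partitioned into three regions:

* 5′ leader: `[0, cds_start)`
* CDS: `[cds_start, cds_end)` — the stop codon is included, so "the P-site
  lies between the annotated start and stop codons" is a single half-open
  interval test. Annotation dialects that keep the stop codon out of their
  CDS features but provide an adjacent `stop_codon` feature are unified at
  load time by extending the CDS by 3 nt.
* 3′ UTR: `[cds_end, length)`

For genes with several isoforms, the isoform with the highest TPM in a
reference RNA-seq sample is the gene's *representative*, and all gene-level
quantities use representative isoforms only. Ties, including genes whose
isoforms are all unexpressed, fall back deterministically to the
lexicographically smallest transcript id (the choice is arbitrary but must
be reproducible; the annotation itself offers no better criterion).

## P-site assignment

The ribosome's P-site is estimated from each footprint's 5′ end plus a
fragment-length-dependent offset. Two protocols are built in and both are
overridable via `processing_mode()`:

| mode | retained lengths | offset |
|---|---|---|
| `whole_head` | 20–34 nt | 12 nt (20–31 nt), 13 nt (32–34 nt) |
| `immunoprecipitated` | 21–36 nt | 12 nt (21 nt), 13 nt (22–36 nt) |

The offsets are a fixed rule, not learned from data: the analysis this
package reproduces treats them as protocol constants, and offset learning
is deliberately out of scope. Fragments outside the retained window are
removed first (`length_filter()`); requesting an offset for an unretained
length is an error rather than a guess. P-sites that fall beyond the
transcript end are dropped and counted; the count conservation
`fragments in = P-sites out + dropped` is asserted in the tests and
recorded in the pipeline manifest.

Within the CDS, elongating ribosomes step codon-wise, so P-sites
concentrate in one reading frame. `frame_fractions()` summarizes this 3-nt
periodicity as the fraction of CDS P-sites in each frame relative to the
annotated start.

## Densities, TE and the leader/CDS ratio

`count_by_region()` tallies P-sites per gene, region and sample (zero rows
retained), and `region_tpm()` converts counts to TPM *within a region
class*: leader densities are normalized against all genes' leaders, CDS
against all CDSs, and so on, each class summing to 10⁶ per sample. The
alternative — one shared denominator across all regions — differs only by
a per-sample constant; any between-gene or between-cell-type comparison is
invariant to the choice, but absolute leader/CDS ratios would shift by
that constant, which is why the choice is documented here.

Translational efficiency is

$$\mathrm{TE}_g = \frac{\text{footprint TPM on CDS}_g}{\text{mRNA TPM}_g}$$

with RNA TPM computed over the full representative transcript length
(mRNA abundance is a property of the whole transcript, not its CDS). TE is
defined only for genes with at least one footprint read and one RNA read;
undefined values are carried as explicit flags, never as zeros, infinities
or pseudocounted ratios. No pseudocounts are used anywhere in the package.

The 5′ leader bias of a gene is its leader TPM over CDS TPM
(`leader_cds_ratio()`), defined for genes with a nonzero-length leader and
nonzero CDS density.

## Two-cell-type comparison

`pair_te_tables()` joins per-gene TE across the two cell types.
Differentially translated transcripts (DTTs) are genes whose TE ratio
strictly exceeds a fold threshold (default 10×) among genes passing an RNA
expression gate (TPM strictly greater than 1 in both cell types). Both
inequalities are strict — a gene at exactly the threshold is not called —
and both thresholds are parameters, not constants. Summary statistics
follow the conventions of the field: TE spread as the ratio of the 95th to
5th percentile with linear-interpolation (type 7) percentiles; TE
histograms in left-closed log2 bins of width 0.2 anchored at integer
multiples of the bin width; squared Pearson correlation on log-transformed
values with nonpositive pairs excluded. Distributional comparisons
delegate to `stats::wilcox.test()` (Mann–Whitney) and
`stats::kruskal.test()`; these wrappers exist so the analysis scripts name
the test they use, not to reimplement anything.

## Metagene profiles and accumulation scores

`metagene_profile()` sums P-site counts at each offset relative to a set of
anchors (annotated starts, stops, upstream AUGs, or arbitrary positions).
Offset 0 is the anchor's first nucleotide — the A of AUG — and the window
(default ±50 nt) is inclusive at both ends. Fragment-length subsetting is
a first-class parameter because different fragment lengths are
conventionally profiled separately (e.g. 21-nt fragments for periodicity,
32-nt for uORF occupancy). Per-window-total normalization ("height
normalized by the total reads on the region") is computed over the plotted
window per anchor group; normalizing each transcript before summing is a
different statistic, noted but intentionally not the default.

The footprint accumulation (stall) score of a codon is

$$\mathrm{score} = \frac{\text{P-sites on the codon}}{\text{mean P-sites per 3-nt tile over the surrounding} \pm 50 \text{ nt}}$$

with the window tiled in the codon's frame. The focal codon is included in
the window mean — the literal reading of "the average over the –50 to +50
region" — and `include_focal = FALSE` is available for the flanks-only
variant; with the default, a delta-like pile-up on an otherwise flat
window of 33 tiles tops out at 33, not infinity. Windows are clipped at
transcript edges, the mean is taken over available tiles only, and codons
with fewer than 30 nt of usable flanking window are flagged
low-confidence. A zero window mean leaves the score undefined rather than
zero or infinite.

On 5′ leaders the default codon universe is the upstream start-like sites
themselves (AUG and the near-cognate single-mismatch neighbours CUG, GUG,
UUG, AUA, AUC, AUU); `include_frame_mates = TRUE` adds every leader codon
in the reading frames anchored at those sites as a background set. This
ambiguity (start-like codons only versus all leader codons) is real in the
source analysis; both are computable and the default is the focused set.
Inside CDSs, annotated in-frame codons are scored excluding the start and
stop codons. Upstream-start scanning itself considers all three reading
phases of the leader; restricting to specific frames is a downstream
filter on the site table, not a scanner option.

# The synthetic-data generator

Real data for this analysis requires sequencing libraries that cannot be
bundled with a package, so `ribotype` ships a generator whose defaults
define the study conditions all tests run under
(`simulation_config()`):

* 500 genes, one transcript each; leader lengths log-normal around ~120 nt
  (clamped 30–600), CDS lengths around ~300 codons, 3′ UTRs around
  ~100 nt.
* log-normal mRNA abundance (sdlog 1) shared between cell types, with a
  per-gene log2 neuron/glia ratio (sd 1); log-normal baseline TE with
  sdlog 0.91, which puts the 5–95 percentile TE spread near 20-fold.
* 25 DTT genes (5%) whose glial TE is divided by 20; all other genes have
  identical true TE in both cell types, so planted-DTT recall and
  precision are well-defined.
* ~2 planted upstream AUGs per leader (Poisson), half followed
  immediately by an in-frame stop (minimal six-base uORFs), at recorded
  positions.
* a 10× glial sampling boost at the planted uAUG codons of the DTT genes.
  The boost targets the suppressed gene set rather than the whole genome:
  per-region-class TPM normalization absorbs any genome-wide shift, so a
  uniform boost would (correctly) leave every leader/CDS ratio unchanged —
  the leader bias is a property of the regulated genes. Start-codon
  boosts are available per cell type (default off).
* CDS frame weights 0.90/0.05/0.05; leader background density 0.02 and 3′
  UTR background 0.01 relative to the mean CDS density; uAUG sampling
  weight 5 before the cell-type boost.
* immunoprecipitated-mode fragment lengths 21–36 nt (discretized normal,
  mode 31 nt); 2×10⁶ footprints and 5×10⁶ RNA reads per cell type.

Footprints are drawn by independent multinomial sampling over transcript
positions with per-gene mass proportional to abundance × TE × CDS length;
each P-site is wrapped in a fragment whose 5′ end is placed so the offset
rule recovers the intended P-site exactly. Fragments that would protrude
beyond the transcript are dropped and counted. RNA reads are multinomial
over genes proportional to abundance × length, emitted as counts
(alignment is out of scope). A per-gene coupling between the mRNA ratio
and glial TE (`mrna_te_coupling`) emulates the situation where genes
transcribed less in one cell type are also translated less there; it
defaults to 0 and is switched on explicitly where that structure is under
test. Everything is deterministic given the seed, including the emitted
FASTA/GTF/TSV files.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real libraries — includes ribosome-exclusion
physics and dwell-time structure (draws are independent), sequence-level
error, rRNA contamination, UMI duplication, multi-isoform genes (the
generator emits one isoform per gene; isoform selection is exercised on
hand-built fixtures), and biological correlation between leader length,
uORF content and TE. It is a test harness for the *counting and scoring
machinery*, not a model of translation.

# Numerical and scale choices

Problem sizes were chosen so the full suite exercises every stage at the
generator's default depth while staying quick: the shared acceptance
simulation is one 500-gene experiment at 2×10⁶ footprints + 5×10⁶ RNA
reads per cell type (seed 1), reused across the recovery checks; oracle
equivalence runs 100 random small transcripts against naive brute-force
reimplementations with exact equality; smaller scenario simulations
(30–300 genes, 4×10⁴–6×10⁵ footprints) cover start-codon stalling,
mRNA/TE coupling and leader stalling. At the default depth, the recovered
quantities are stable across seeds: Spearman correlation between true and
estimated TE ≈ 0.999 per cell type, planted-DTT recall and precision 1.0,
frame weights recovered within 2×10⁻⁴, and the DTT-gene leader/CDS ratio
about 9-fold higher in glia (the per-region TPM constants compress the
nominal 10× boost slightly; at these depths the compression is dominated
by the normalization shift of ~4% of boosted footprint mass, not noise).

Degenerate inputs are handled by explicit flags and empty results rather
than sentinels: leaderless transcripts are excluded from leader
normalization and ratios, all-zero samples yield undefined TPM with a
warning, zero-read metagene windows yield a flagged all-zero profile, and
fragment streams mapping >10% to unknown transcripts abort (the threshold
is configurable).

# Limitations

* The offset rule is fixed per protocol; footprints from other protocols
  need a custom `processing_mode()`.
* Single-CDS models only: transcripts with stop-codon readthrough or
  internal ORFs are represented by their first annotated CDS.
* Isoform-resolved quantification (EM over shared reads) is out of scope;
  gene-level results rest on the representative-isoform convention.
* The per-region-class TPM convention makes absolute leader/CDS ratios
  depend on a per-sample constant; only comparisons are
  normalization-free.
* `run_pipeline()` orchestrates the full analysis for two cell types from
  one config; normalization across more than two conditions is not
  implemented.
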