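# End-to-end orchestration: annotation -> P-sites -> quantification ->
# two-cell-type comparison -> metagene -> stall scores, from a single
# validated config, with a run log and a manifest of per-stage record counts.

.pipeline_defaults <- list(
  mode = "immunoprecipitated",
  cell_type_a = "neuron",
  cell_type_b = "glia",
  dtt_fold = 10,
  expression_tpm = 1,
  window = 50,
  metagene_length_subset = NULL,
  seed = 1L
)

#' Build and validate a pipeline run configuration
#'
#' @param config a named list or the path of a YAML file. Required fields:
#'   `annotation` (GTF/GFF path), `fragments` (BED-like TSV path),
#'   `rna_counts` (TSV path: gene_id, sample, count), `out_dir`. Optional:
#'   `fasta` (transcript FASTA; enables uORF and codon-identity analyses),
#'   `rna_tpm_transcripts` (TSV: transcript_id, tpm; required for
#'   representative-isoform selection when genes have several isoforms),
#'   `mode` (default "immunoprecipitated"), `cell_type_a`/`cell_type_b`
#'   (default neuron/glia), `dtt_fold` (default 10), `expression_tpm`
#'   (default 1), `window` (default 50), `metagene_length_subset`, `seed`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.pipeline_defaults, config)
  required <- c("annotation", "fragments", "rna_counts", "out_dir")
  miss <- setdiff(required, names(cfg))
  if (length(miss) > 0) stop("config missing fields: ",
                             paste(miss, collapse = ", "))
  for (f in c("annotation", "fragments", "rna_counts", "fasta",
              "rna_tpm_transcripts")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  stopifnot(cfg$dtt_fold > 0, cfg$expression_tpm >= 0, cfg$window > 0)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes TSV/JSON
#' artifacts plus a manifest (`manifest.json`) and run log (`run.log`) to
#' `out_dir`. Outputs are deterministic for fixed inputs. The manifest
#' records package version, a config hash, and per-stage record counts; the
#' count conservation `fragments_in = length_dropped + unknown_dropped +
#' out_of_bounds_dropped + psites_out` is recorded explicitly.
#'
#' @param config a [run_config()] (or list / YAML path accepted by it).
#' @return invisibly, a list with the main in-memory results (`catalog`,
#'   `psites`, `fp_density`, `te`, `paired`, `dtt_genes`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  cts <- c(config$cell_type_a, config$cell_type_b)

  say("annotation: loading %s", config$annotation)
  catalog <- stage("annotation",
                   load_transcript_models(config$annotation, config$fasta))

  say("annotation: selecting representative isoforms")
  multi <- any(table(catalog$models$gene_id) > 1)
  if (!is.null(config$rna_tpm_transcripts)) {
    tx_tpm <- readr::read_tsv(config$rna_tpm_transcripts,
                              show_col_types = FALSE)
    catalog <- stage("annotation",
                     select_representative_isoforms(catalog, tx_tpm))
  } else if (multi) {
    stop("genes with several isoforms require config$rna_tpm_transcripts ",
         "for representative selection")
  } else {
    catalog <- select_representative_isoforms(
      catalog, setNames(rep(1, nrow(catalog$models)),
                        catalog$models$transcript_id))
  }
  write_region_models(catalog, file.path(config$out_dir, "region_models.tsv"))

  mode <- processing_mode(config$mode)
  say("psite: reading fragments from %s (%s mode)", config$fragments,
      mode$name)
  fragments <- stage("psite", read_fragments_bed(config$fragments))
  n_frag <- nrow(fragments)
  kept <- stage("psite", length_filter(fragments, mode))
  n_len_drop <- attr(kept, "n_dropped_length")
  psites <- stage("psite", assign_psites(kept, mode, catalog))
  drops <- attr(psites, "dropped")
  write_psites(psites, file.path(config$out_dir, "psites.tsv"))
  ff <- suppressWarnings(frame_fractions(psites, catalog))
  say("psite: %d P-sites; CDS frame fractions %.3f/%.3f/%.3f",
      nrow(psites), ff[1], ff[2], ff[3])

  say("quant: region counts, RPM, TPM, TE")
  fp_density <- stage("quant", count_by_region(psites, catalog))
  fp_density <- region_tpm(region_rpm(fp_density))
  write_density_table(fp_density,
                      file.path(config$out_dir, "region_density.tsv"))
  rna_counts <- stage("quant", readr::read_tsv(config$rna_counts,
                                               show_col_types = FALSE))
  rna <- stage("quant", rna_tpm_table(rna_counts, catalog))
  te <- stage("quant", translational_efficiency(fp_density, rna))
  write_density_table(te, file.path(config$out_dir, "te.tsv"))
  ratios <- stage("quant", leader_cds_ratio(fp_density))
  write_density_table(ratios,
                      file.path(config$out_dir, "leader_cds_ratio.tsv"))

  say("compare: pairing %s vs %s, DTT fold > %g, RNA TPM > %g",
      cts[1], cts[2], config$dtt_fold, config$expression_tpm)
  paired <- stage("compare", pair_te_tables(te, cts[1], cts[2]))
  paired <- flag_dtts(paired, fold = config$dtt_fold,
                      expression_gate = config$expression_tpm)
  dtt_genes <- paired$gene_id[paired$is_dtt]
  write_paired_te(paired, file.path(config$out_dir, "paired_te.tsv"))
  write_gene_list(dtt_genes, file.path(config$out_dir, "dtt_genes.txt"))
  say("compare: %d DTT genes", length(dtt_genes))

  say("metagene: start-codon profiles per cell type")
  w <- as.integer(config$window)
  for (ct in cts) {
    prof <- stage("metagene", metagene_profile(
      psites[psites$sample == ct, ], start_codon_anchors(catalog),
      window = c(w, w), length_subset = config$metagene_length_subset,
      anchor_kind = "start_codon"))
    write_metagene(prof, file.path(config$out_dir,
                                   sprintf("metagene_start_%s.tsv", ct)))
  }

  uorfs <- NULL
  if (!is.null(catalog$sequences)) {
    say("annotation: scanning 5' leaders for upstream starts")
    uorfs <- stage("annotation", find_upstream_starts(catalog))
    write_uorf_table(uorfs, file.path(config$out_dir, "uorf_sites.tsv"))
    anchors <- uaug_anchors(uorfs)
    if (nrow(anchors) > 0) {
      for (ct in cts) {
        prof <- stage("metagene", metagene_profile(
          psites[psites$sample == ct, ], anchors, window = c(w, w),
          length_subset = config$metagene_length_subset,
          anchor_kind = "upstream_AUG"))
        write_metagene(prof, file.path(config$out_dir,
                                       sprintf("metagene_uaug_%s.tsv", ct)))
      }
    }
    say("stallscore: leader and CDS codon accumulation per cell type")
    leader_sites <- leader_codon_sites(catalog)
    cds_sites <- cds_codon_sites(catalog)
    for (ct in cts) {
      scores <- stage("stallscore", bind_rows(
        stall_score_table(psites, catalog, leader_sites, window = w,
                          sample = ct),
        stall_score_table(psites, catalog, cds_sites, window = w,
                          sample = ct)))
      write_stall_scores(scores, file.path(
        config$out_dir, sprintf("stall_scores_%s.tsv", ct)))
      for (reg in c("leader", "CDS")) {
        write_codon_summary(
          aggregate_scores_by_codon(scores, reg),
          file.path(config$out_dir,
                    sprintf("codon_summary_%s_%s.tsv", reg, ct)))
      }
    }
  }

  say("stallscore: start-codon accumulation per cell type")
  for (ct in cts) {
    acc <- stage("stallscore",
                 start_codon_accumulation(psites, catalog, window = w,
                                          sample = ct))
    write_density_table(acc, file.path(
      config$out_dir, sprintf("start_codon_accumulation_%s.tsv", ct)))
  }

  manifest <- list(
    package = "ribotype",
    version = as.character(utils::packageVersion("ribotype")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    counts = list(
      transcripts = nrow(catalog$models),
      genes = length(unique(catalog$models$gene_id)),
      fragments_in = n_frag,
      fragments_length_dropped = n_len_drop,
      fragments_unknown_dropped = unname(drops[["unknown_transcript"]]),
      psites_out_of_bounds_dropped = unname(drops[["psite_out_of_bounds"]]),
      psites_out = nrow(psites),
      conservation_ok = n_frag == n_len_drop +
        sum(drops) + nrow(psites),
      te_rows = nrow(te),
      dtt_genes = length(dtt_genes),
      uorf_sites = if (is.null(uorfs)) NA else nrow(uorfs)
    )
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  say("done: outputs in %s", config$out_dir)

  invisible(list(catalog = catalog, psites = psites, fp_density = fp_density,
                 rna = rna, te = te, ratios = ratios, paired = paired,
                 dtt_genes = dtt_genes, uorfs = uorfs, manifest = manifest))
}
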