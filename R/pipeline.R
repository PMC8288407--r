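#' Assemble a pipeline configuration
#'
#' Builds the single configuration document driving [run_pipeline()].
#' Defaults reproduce the package's standard synthetic-atlas analysis;
#' any element can be overridden from a YAML file and/or a named override
#' list (overrides win over the file, the file over the defaults).  Every
#' stage threshold is surfaced here — nothing is hard-coded in the
#' pipeline.
#'
#' @param path Optional YAML file with (partial) configuration.
#' @param overrides Optional named list of (partial) overrides.
#' @return Nested configuration list with elements `seed`, `outdir`,
#'   `simulate` (generator parameters, see [atlas_sim_config()]), `qc`,
#'   `de`, `adjacency`, `ras`, `projection`, `run` (stage toggles).
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    outdir = tempfile("abc_run_"),
    simulate = atlas_sim_config(),
    qc = list(min_coding = 1000L, min_lnc = 500L),
    de = list(min_lfc = 1, max_q = 0.05, min_pct_in = 0.25),
    adjacency = list(max_dist = 5000L),
    ras = list(top_fraction = 0.05, min_on_fraction = 0.5, max_other = 2L),
    projection = list(threshold = 0.7, n_folds = 5L, n_features = 1000L),
    run = list(deg_matrix = TRUE, projection = TRUE)
  )
  merge2 <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
                        !is.data.frame(base[[nm]]) && !is.data.frame(new[[nm]]))
        merge2(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge2(cfg, yaml::read_yaml(path))
  cfg <- merge2(cfg, overrides)
  if (is.list(cfg$simulate) && !is.data.frame(cfg$simulate$cell_types))
    cfg$simulate$cell_types <- abc_cell_types()
  cfg
}

#' Run the full atlas analysis pipeline
#'
#' Orchestrates every stage end-to-end from one configuration: synthetic
#' atlas generation (or, in future, loading), UMI-count QC, log2(TPM/10+1)
#' normalization per biotype, detection statistics, signature calling for
#' coding genes and lncRNAs, pairwise DEG matrices and their concordance,
#' adjacency scanning and signature-adjacency proportions, conservation
#' and specificity comparisons, regulon activity scoring / binarization /
#' cluster states / novelty flagging, and self-projection accuracy.
#' Outputs and a machine-readable `summary.json` are written under
#' `config$outdir`; identical config + seed gives byte-identical
#' summaries.
#'
#' @param config Configuration list from [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[bloodatlas] ", ...)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config$simulate$seed <- config$seed

  say("simulate: generating synthetic atlas")
  sim <- simulate_atlas(config$simulate)
  write_atlas(sim, file.path(outdir, "input"))
  say("simulate: ", nrow(sim$cells), " cells x ", ncol(sim$counts), " genes")

  say("qc: mapping-rate and detection filters")
  qc <- qc_filter(sim$counts, sim$cells, sim$biotype,
                  min_coding = config$qc$min_coding,
                  min_lnc = config$qc$min_lnc,
                  type_table = config$simulate$cell_types)
  utils::write.table(qc$report, file.path(outdir, "qc_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say("qc: retained ", qc$summary$retained_coding, " cells (coding), ",
      qc$summary$retained_lncrna, " (lncRNA)")

  cells_cod <- sim$cells[match(rownames(qc$coding), sim$cells$cell_id), ]
  cells_lnc <- sim$cells[match(rownames(qc$lncrna), sim$cells$cell_id), ]
  norm_cod <- normalize_log2tpm10(qc$coding)
  norm_lnc <- normalize_log2tpm10(qc$lncrna)

  det_cod <- detection_stats(qc$coding, cells_cod)
  det_lnc <- detection_stats(qc$lncrna, cells_lnc)
  utils::write.table(det_cod, file.path(outdir, "detection_coding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(det_lnc, file.path(outdir, "detection_lncrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("signatures: one-vs-rest Wilcoxon per biotype")
  sig_cod <- find_signatures(norm_cod, cells_cod, min_lfc = config$de$min_lfc,
                             max_q = config$de$max_q,
                             min_pct_in = config$de$min_pct_in)
  sig_lnc <- find_signatures(norm_lnc, cells_lnc, min_lfc = config$de$min_lfc,
                             max_q = config$de$max_q,
                             min_pct_in = config$de$min_pct_in)
  utils::write.table(sig_cod, file.path(outdir, "signatures_coding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sig_lnc, file.path(outdir, "signatures_lncrna.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  rho <- NA_real_
  if (isTRUE(config$run$deg_matrix)) {
    say("deg: pairwise DEG matrices and concordance")
    deg_cod <- pairwise_deg_counts(norm_cod, cells_cod,
                                   min_lfc = config$de$min_lfc,
                                   max_q = config$de$max_q)
    deg_lnc <- pairwise_deg_counts(norm_lnc, cells_lnc,
                                   min_lfc = config$de$min_lfc,
                                   max_q = config$de$max_q)
    conc <- deg_concordance(deg_cod, deg_lnc)
    rho <- conc$rho
    utils::write.table(deg_cod$raw, file.path(outdir, "deg_counts_coding.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(deg_lnc$raw, file.path(outdir, "deg_counts_lncrna.tsv"),
                       sep = "\t", quote = FALSE)
  }

  say("lncrna: adjacency, conservation, specificity")
  adj <- adjacency_scan(sim$annotation, max_dist = config$adjacency$max_dist)
  prop <- signature_adjacency_proportion(sig_lnc, sig_cod, adj)
  utils::write.table(prop, file.path(outdir, "signature_adjacency.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_lnc_ids <- unique(sig_lnc$gene_id)
  bg_lnc_ids <- setdiff(colnames(norm_lnc)[colSums(norm_lnc) > 0],
                        sig_lnc_ids)
  cons <- conservation_compare(sim$conservation, sig_lnc_ids, bg_lnc_ids)
  spec <- specificity_scores(norm_lnc, cells_lnc)
  spec_p <- rank_sum_test(spec$max_score[sig_lnc_ids],
                          spec$max_score[bg_lnc_ids],
                          alternative = "greater")$p

  say("regulons: activity, binarization, cluster states")
  ras <- ras_scores(norm_cod, sim$regulons$regulons,
                    top_fraction = config$ras$top_fraction)
  bin <- binarize_ras(ras)
  states <- cluster_regulon_states(bin, cells_cod$family,
                                   min_on_fraction = config$ras$min_on_fraction,
                                   max_other = config$ras$max_other)
  novel <- flag_novel_regulons(states, sim$regulons$canonical_tfs)
  utils::write.table(states$state, file.path(outdir, "regulon_states.tsv"),
                     sep = "\t", quote = FALSE)

  acc <- NULL
  if (isTRUE(config$run$projection)) {
    say("projection: stratified self-projection accuracy")
    acc <- self_projection_accuracy(norm_cod, cells_cod,
                                    n_folds = config$projection$n_folds,
                                    seed = config$seed,
                                    n_features = config$projection$n_features,
                                    threshold = config$projection$threshold)
    utils::write.table(acc$per_type,
                       file.path(outdir, "projection_accuracy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    seed = config$seed,
    n_cells = nrow(sim$cells),
    n_genes = ncol(sim$counts),
    retained_coding = qc$summary$retained_coding,
    retained_lncrna = qc$summary$retained_lncrna,
    mean_detected_coding = mean(rowSums(qc$coding > 0)),
    mean_detected_lncrna = mean(rowSums(qc$lncrna > 0)),
    n_signature_coding = nrow(sig_cod),
    n_signature_lncrna = nrow(sig_lnc),
    deg_concordance_rho = rho,
    adjacency_proportion_overall =
      sum(prop$n_adjacent) / max(1L, sum(prop$n_signature_lnc)),
    conservation_delta_median = cons$delta_median,
    conservation_p = cons$p,
    specificity_p = spec_p,
    n_regulons_activated = sum(colSums(states$state) >= 1L),
    n_novel_regulons = length(novel),
    projection_accuracy = if (is.null(acc)) NA_real_ else acc$overall
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("done: ", file.path(outdir, "summary.json"))
  invisible(summary)
}
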