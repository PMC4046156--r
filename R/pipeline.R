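#' Pipeline configuration
#'
#' Thresholds default to the analysis' standard values: detectability
#' CT < 30, high-expression CT < 25, 2-fold change, N:C ratio > 0.1,
#' MFE < -30 kcal/mol, alpha = 0.05.
#'
#' @param ct_table,sample_sheet,assay_classes Whole-cell CT inputs.
#' @param fraction_ct_table,fraction_sample_sheet Fractionation CT inputs.
#' @param expression_table mRNA log2 expression TSV (genes x samples) with
#'   a side-car sample sheet `expression_samples`.
#' @param expression_samples Sample sheet for the expression table.
#' @param utr_fasta,mirna_fasta,pri_fasta Sequence inputs.
#' @param comparison `c(test, ref)` cell types for the target-inference arm.
#' @param ct_threshold,ct_high,min_fold,ratio_threshold,mfe_cut,alpha,p_cut
#'   Stage thresholds.
#' @param controls Optional control-miRNA list for enrichment calling.
#' @param n_shuffles Shuffles for duplex p-value calibration.
#' @param scan_window,scan_step Duplex scan geometry (nt).
#' @param seed Integer seed (all randomness in a run flows from it).
#' @param out_dir Output directory.
#' @param strict Abort (rather than warn) on marker QC failure.
#' @param make_figures Render the cluster heatmap and N:C scatter (PNG).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ct_table = NULL, sample_sheet = NULL,
                            assay_classes = NULL,
                            fraction_ct_table = NULL,
                            fraction_sample_sheet = NULL,
                            expression_table = NULL,
                            expression_samples = NULL,
                            utr_fasta = NULL, mirna_fasta = NULL,
                            pri_fasta = NULL,
                            comparison = c("granulocyte", "promyelocyte"),
                            ct_threshold = 30, ct_high = 25, min_fold = 2,
                            ratio_threshold = 0.1, mfe_cut = -30,
                            alpha = 0.05, p_cut = 0.05,
                            controls = NULL, n_shuffles = 200,
                            scan_window = 60, scan_step = 10,
                            seed = 1L, out_dir = "nucmir_run",
                            strict = FALSE, make_figures = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingest, detectability filtering, whole-cell miRNA
#' differential expression, clustering of highly expressed miRNAs, mRNA
#' moderated-t differential expression, anti-correlated target pairing,
#' fractionation marker QC, contamination regression, nuclear-enrichment
#' calling, and the pri-miRNA duplex scan with candidate filtering. Every
#' stage writes a TSV report under `out_dir`; filter-boundary counts are
#' logged and collected into a machine-readable `summary.json` that is
#' byte-identical across runs with the same config and seed.
#'
#' @param cfg A [pipeline_config()].
#' @return The summary list, invisibly; reports under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(stage, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
  }
  summary <- list(seed = cfg$seed,
                  parameters = list(ct_threshold = cfg$ct_threshold,
                                    ct_high = cfg$ct_high,
                                    min_fold = cfg$min_fold,
                                    ratio_threshold = cfg$ratio_threshold,
                                    mfe_cut = cfg$mfe_cut, alpha = cfg$alpha,
                                    p_cut = cfg$p_cut),
                  counts = list())
  count <- function(name, value) summary$counts[[name]] <<- value

  ## miRNA arm -------------------------------------------------------------
  mirna_de <- NULL; whole_coll <- NULL
  if (!is.null(cfg$ct_table)) {
    whole <- read_ct_table(cfg$ct_table, cfg$sample_sheet, cfg$assay_classes)
    logmsg("ingest", nrow(whole$values), " assays x ", ncol(whole$values),
           " samples (whole cell)")
    whole_coll <- collapse_replicates(whole)
    detectable <- detectability_filter(whole_coll, cfg$ct_threshold)
    count("assays_total", sum(whole$assay_class == "miRNA"))
    count("assays_detectable", length(intersect(
      detectable, names(whole$assay_class)[whole$assay_class == "miRNA"])))
    mirna_de <- mirna_differential(whole_coll, min_fold = cfg$min_fold,
                                   ct_threshold = cfg$ct_threshold)
    .write_tsv(mirna_de, file.path(cfg$out_dir, "mirna_de.tsv"))
    count("mirnas_differential", length(attr(mirna_de, "de_entities")))
    logmsg("mirna_de", length(attr(mirna_de, "de_entities")),
           " miRNAs pass |fold| >= ", cfg$min_fold)

    clus <- cluster_high_expressers(whole_coll, mirna_de, ct_high = cfg$ct_high)
    count("mirnas_clustered", length(clus$entities))
    if (length(clus$entities) > 0) {
      .write_tsv(data.frame(order = seq_along(clus$entities),
                            assay = clus$entities),
                 file.path(cfg$out_dir, "cluster_leaves.tsv"))
      .write_tsv(data.frame(merge1 = clus$hclust$merge[, 1],
                            merge2 = clus$hclust$merge[, 2],
                            height = clus$hclust$height),
                 file.path(cfg$out_dir, "cluster_linkage.tsv"))
      if (cfg$make_figures) .plot_heatmap(clus, cfg$out_dir)
    }
  }

  ## mRNA arm + target inference ------------------------------------------
  pairs <- NULL
  if (!is.null(cfg$expression_table)) {
    expr <- as.matrix(read.delim(cfg$expression_table, row.names = 1,
                                 check.names = FALSE))
    esamp <- read.delim(cfg$expression_samples, stringsAsFactors = FALSE)
    grp <- factor(esamp$cell_type[match(colnames(expr), esamp$sample_id)],
                  levels = rev(cfg$comparison)) # fold = test vs ref
    gene_de <- moderated_t_de(expr, grp, min_fold = cfg$min_fold,
                              alpha = cfg$alpha)
    .write_tsv(gene_de, file.path(cfg$out_dir, "gene_de.tsv"))
    count("genes_significant", sum(gene_de$significant))
    logmsg("gene_de", sum(gene_de$significant), " genes significant")

    if (!is.null(cfg$utr_fasta) && !is.null(cfg$mirna_fasta) &&
        !is.null(mirna_de)) {
      utrs <- read_fasta_rna(cfg$utr_fasta)
      mirnas <- read_fasta_rna(cfg$mirna_fasta)
      pairs <- anticorrelated_pairs(mirna_de, gene_de, utrs, mirnas,
                                    comparison = cfg$comparison,
                                    min_gene_fold = cfg$min_fold,
                                    alpha = cfg$alpha)
      .write_tsv(pairs, file.path(cfg$out_dir, "target_pairs.tsv"))
      count("target_pairs", nrow(pairs))
      logmsg("targets", nrow(pairs), " anti-correlated pairs with seed support")
    }
  }

  ## fractionation arm ------------------------------------------------------
  enrich <- NULL; fp <- NULL
  if (!is.null(cfg$fraction_ct_table)) {
    frac <- read_ct_table(cfg$fraction_ct_table, cfg$fraction_sample_sheet,
                          cfg$assay_classes)
    fp <- fraction_pairs(frac)
    qc <- marker_qc(fp)
    .write_tsv(qc, file.path(cfg$out_dir, "fraction_qc.tsv"))
    count("marker_qc_pass", as.integer(attr(qc, "pass")))
    if (!attr(qc, "pass")) {
      if (cfg$strict) stop("marker QC failed (strict mode)")
      warning("marker QC failed; fractionation results are advisory")
    }
    reg <- lapply(fp$cell_types, function(ct)
      as.data.frame(contamination_regression(fp, ct, cfg$ct_threshold)))
    reg <- do.call(rbind, reg)
    .write_tsv(reg, file.path(cfg$out_dir, "contamination.tsv"))
    enrich <- call_nuclear_enriched(fp, controls = cfg$controls,
                                    ratio_threshold = cfg$ratio_threshold,
                                    ct_threshold = cfg$ct_threshold,
                                    alpha = cfg$alpha)
    .write_tsv(enrich, file.path(cfg$out_dir, "enrichment.tsv"))
    called <- unique(enrich$assay[enrich$call == "nuclear_enriched"])
    count("nuclear_enriched", length(called))
    logmsg("fractions", length(called), " nuclear-enriched miRNAs")
    if (cfg$make_figures) .plot_nc_scatter(fp, cfg$out_dir)
  }

  ## pri-miRNA scan ---------------------------------------------------------
  if (!is.null(cfg$pri_fasta) && !is.null(enrich) &&
      !is.null(cfg$mirna_fasta)) {
    pri <- read_fasta_rna(cfg$pri_fasta)
    mirnas <- read_fasta_rna(cfg$mirna_fasta)
    nuclear <- unique(enrich$assay[enrich$call == "nuclear_enriched"])
    nuclear <- intersect(nuclear, names(mirnas))
    em <- energy_model()
    hits <- list()
    for (m in nuclear) for (tr in names(pri)) {
      h <- scan_transcript(mirnas[[m]], pri[[tr]], em,
                           window = cfg$scan_window, step = cfg$scan_step,
                           mirna_name = m, transcript_name = tr)
      cal <- calibrate_p(mirnas[[m]], pri[[tr]], em,
                         n_shuffles = cfg$n_shuffles,
                         window = cfg$scan_window, step = cfg$scan_step)
      h$p_value <- cal$p_empirical
      h$p_gumbel <- cal$p_gumbel
      hits[[paste(m, tr)]] <- h
    }
    if (length(hits) > 0) {
      hits <- do.call(rbind, hits)
      rownames(hits) <- NULL
      .write_tsv(hits, file.path(cfg$out_dir, "pri_hits.tsv"))
      count("pri_hits_screened", nrow(hits))
      if (!is.null(fp)) {
        nuc_prof <- -fp$ct_nuc # expression scale
        mat_prof <- -fp$ct_cyto
        cand <- nuclear_target_candidates(
          hits, nuc_prof, mat_prof, mfe_cut = cfg$mfe_cut, p_cut = cfg$p_cut,
          stages = rev(cfg$comparison))
        .write_tsv(cand, file.path(cfg$out_dir, "pri_candidates.tsv"))
        count("pri_candidates", nrow(cand))
        count("pri_candidates_anticorrelated", sum(cand$anti_correlated))
        logmsg("priscan", nrow(cand), " candidates below MFE/p cutoffs")
      }
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logmsg("done", "summary written")
  invisible(summary)
}

.plot_heatmap <- function(clus, out_dir) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    grDevices::png(file.path(out_dir, "cluster_heatmap.png"), 900, 1200,
                   res = 120)
    pheatmap::pheatmap(clus$profiles, cluster_cols = FALSE,
                       clustering_method = clus$linkage_method)
    grDevices::dev.off()
  }
}

.plot_nc_scatter <- function(fp, out_dir) {
  grDevices::png(file.path(out_dir, "nc_scatter.png"), 900, 900, res = 120)
  graphics::par(mfrow = c(2, 2))
  for (ct in fp$cell_types) {
    keep <- fp$assay_class == "miRNA"
    graphics::plot(fp$ct_cyto[keep, ct], fp$ct_nuc[keep, ct],
                   xlab = "cytoplasmic CT", ylab = "nuclear CT", main = ct,
                   pch = 20, col = "grey30")
    graphics::abline(0, 1, lty = 2)
  }
  graphics::dev.off()
}

#' Write simulated pipeline inputs to a directory
#'
#' Runs the three synthetic-data generators under one seed and serializes
#' every input the pipeline consumes (CT tables + sample sheets, expression
#' matrix, FASTA files) plus the ground truth as JSON, with the
#' configuration echoed.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a list of the written paths plus the in-memory
#'   simulated objects.
#' @export
simulate_run_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_ct_experiment(cfg)
  mirnas <- simulate_mirna_sequences(cfg$n_mirnas)
  de_lfc <- setNames(sim$truth$de$log2_fold_full, sim$truth$de$assay)
  tx <- simulate_transcriptome(cfg, mirnas, mirna_log2fold = de_lfc)
  enr <- setNames(sim$truth$nuclear_enriched$assay,
                  sim$truth$nuclear_enriched$assay)
  pri <- simulate_pri_targets(cfg, mirnas[sim$truth$nuclear_enriched$assay])

  paths <- list(
    ct_table = file.path(dir, "ct_whole.tsv"),
    sample_sheet = file.path(dir, "ct_whole.tsv.samples.tsv"),
    assay_classes = file.path(dir, "assay_classes.tsv"),
    fraction_ct_table = file.path(dir, "ct_fractions.tsv"),
    fraction_sample_sheet = file.path(dir, "ct_fractions.tsv.samples.tsv"),
    expression_table = file.path(dir, "expression.tsv"),
    expression_samples = file.path(dir, "expression.samples.tsv"),
    utr_fasta = file.path(dir, "utrs.fa"),
    mirna_fasta = file.path(dir, "mirnas.fa"),
    pri_fasta = file.path(dir, "pri_mirnas.fa"))

  write_ct_table(sim$whole, paths$ct_table,
                 assay_class_path = paths$assay_classes)
  write_ct_table(sim$fractions, paths$fraction_ct_table,
                 assay_class_path = NULL)
  expr_df <- data.frame(gene = rownames(tx$expr$values), tx$expr$values,
                        check.names = FALSE)
  .write_tsv(expr_df, paths$expression_table)
  .write_tsv(tx$expr$samples, paths$expression_samples)
  write_fasta(tx$utrs, paths$utr_fasta)
  write_fasta(mirnas, paths$mirna_fasta)
  write_fasta(pri$pri, paths$pri_fasta)

  truth <- list(ct = sim$truth[setdiff(names(sim$truth), "effect")],
                transcriptome = tx$truth[c("pairs")],
                pri = pri$truth,
                config = unclass(cfg))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(c(paths, list(sim = sim, transcriptome = tx, pri = pri,
                          mirnas = mirnas)))
}
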