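#' Simulation configuration
#'
#' Collects the knobs of the synthetic-data generators. The defaults
#' emulate the magnitudes of the emulated TLDA/fractionation/microarray
#' design: CT values in the 20-30 cycle range, Gaussian CT noise of 0.25
#' cycles, 10% cytoplasmic carry-over into the nuclear fraction, planted
#' expression changes of 4-fold for miRNAs and ~2.8-fold (1.5 log2 units)
#' for target genes, nuclear-enriched miRNAs at a true N:C ratio of 2,
#' nuclear markers at 8-56x and cytoplasmic markers at 4-9x enrichment,
#' and a 35-cycle detection limit beyond which reactions come up
#' undetermined.
#'
#' @param n_mirnas,n_genes Panel sizes.
#' @param stages Ordered differentiation stages.
#' @param n_replicates Replicates per stage (and per fraction).
#' @param sigma_ct CT noise standard deviation (cycles).
#' @param contamination_fraction Cytoplasmic carry-over into the nuclear
#'   fraction, in (0, 1).
#' @param n_de_mirnas,de_fold Number of differentially expressed miRNAs and
#'   their full linear fold change across the stage series.
#' @param n_nuclear_enriched,true_nc_ratio Planted nuclear-enriched assays
#'   and their true N:C ratio.
#' @param n_true_target_pairs Planted miRNA-mRNA target pairs.
#' @param utr_length_range Min/max UTR length (nt).
#' @param gene_effect_log2 Absolute log2 change planted in target genes.
#' @param sigma_expr Microarray replicate noise (log2 units).
#' @param detection_limit_ct CT beyond which a reaction is undetermined.
#' @param n_pri,pri_length_range Number and length range of pri-miRNA
#'   transcripts.
#' @param mirna_length Mature miRNA length (nt).
#' @param seed Optional integer seed used by the generators.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_mirnas = 200, n_genes = 500,
                       stages = c("LSK", "promyelocyte", "myelocyte",
                                  "granulocyte"),
                       n_replicates = 3, sigma_ct = 0.25,
                       contamination_fraction = 0.1,
                       n_de_mirnas = 30, de_fold = 4,
                       n_nuclear_enriched = 6, true_nc_ratio = 2,
                       n_true_target_pairs = 30,
                       utr_length_range = c(200, 800),
                       gene_effect_log2 = 1.5, sigma_expr = 0.25,
                       detection_limit_ct = 35,
                       n_pri = 20, pri_length_range = c(500, 2000),
                       mirna_length = 22, seed = NULL) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes, stages = stages,
              n_replicates = n_replicates, sigma_ct = sigma_ct,
              contamination_fraction = contamination_fraction,
              n_de_mirnas = n_de_mirnas, de_fold = de_fold,
              n_nuclear_enriched = n_nuclear_enriched,
              true_nc_ratio = true_nc_ratio,
              n_true_target_pairs = n_true_target_pairs,
              utr_length_range = utr_length_range,
              gene_effect_log2 = gene_effect_log2, sigma_expr = sigma_expr,
              detection_limit_ct = detection_limit_ct,
              n_pri = n_pri, pri_length_range = pri_length_range,
              mirna_length = mirna_length, seed = seed)
  if (cfg$n_de_mirnas > cfg$n_mirnas)
    stop("n_de_mirnas exceeds n_mirnas")
  if (cfg$n_nuclear_enriched > cfg$n_mirnas)
    stop("n_nuclear_enriched exceeds n_mirnas")
  if (cfg$n_true_target_pairs > cfg$n_genes)
    stop("n_true_target_pairs exceeds n_genes")
  if (cfg$sigma_ct < 0) stop("sigma_ct must be >= 0")
  if (cfg$contamination_fraction <= 0 || cfg$contamination_fraction >= 1)
    stop("contamination_fraction must be in (0, 1)")
  structure(cfg, class = "sim_config")
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Random mature miRNA sequences
#' @param n Number of sequences.
#' @param length Sequence length (nt).
#' @param names Optional names (default `miR-001`...).
#' @return Named character vector of RNA sequences.
#' @export
simulate_mirna_sequences <- function(n, length = 22,
                                     names = sprintf("miR-%03d", seq_len(n))) {
  setNames(vapply(seq_len(n), function(i) .random_seq(length), character(1)),
           names)
}

# DE trajectory shape across the 4 stages: monotone with a unique extremum
# at the last stage, applied as (shape * direction * log2 full fold).
.stage_shape <- function(n_stages) {
  if (n_stages == 4) c(0, 0.2, 0.6, 1) else seq(0, 1, length.out = n_stages)
}

#' Simulate a TLDA-style CT experiment with fractionation
#'
#' Generates whole-cell and nuclear/cytoplasmic CT matrices with planted
#' ground truth. Baseline whole-cell CTs are uniform on [20, 29]; planted
#' DE miRNAs follow a monotone stage trajectory reaching the full
#' `de_fold` change (half up, half down). The cytoplasmic fraction mirrors
#' the whole cell; nuclear linear abundance is `true_nc_ratio` times
#' cytoplasmic for planted nuclear-enriched assays and
#' `contamination_fraction` times cytoplasmic otherwise (pure carry-over
#' model). Gaussian CT noise (sd `sigma_ct`) is added per replicate and
#' values beyond `detection_limit_ct` are censored to undetermined.
#' Nuclear markers are planted at 8-56x nuclear enrichment and
#' cytoplasmic markers at 4-9x cytoplasmic enrichment.
#'
#' @param cfg A [sim_config()].
#' @return List: `whole` (whole-cell [ct_matrix()]), `fractions`
#'   (nuclear + cytoplasmic [ct_matrix()]), `truth` (planted DE table,
#'   enriched assays with true ratios, marker identities and folds,
#'   contamination fraction).
#' @export
simulate_ct_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  stages <- cfg$stages
  n_st <- length(stages)
  mir_names <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))
  nuc_markers <- c("SnoRNA-like-1", "SnoRNA-like-2")
  cyt_markers <- c("Y1-like-1", "Y1-like-2")
  assays <- c(mir_names, nuc_markers, cyt_markers)
  assay_class <- setNames(c(rep("miRNA", cfg$n_mirnas),
                            rep("nuclear_marker", 2),
                            rep("cytoplasmic_marker", 2)), assays)

  baseline <- setNames(stats::runif(cfg$n_mirnas, 20, 29), mir_names)
  de_idx <- sample(mir_names, cfg$n_de_mirnas)
  direction <- setNames(rep(c(1, -1), length.out = cfg$n_de_mirnas), de_idx)
  shape <- .stage_shape(n_st)
  # true log2 expression change per stage, relative to the first stage
  effect <- matrix(0, cfg$n_mirnas, n_st, dimnames = list(mir_names, stages))
  for (a in de_idx)
    effect[a, ] <- direction[[a]] * log2(cfg$de_fold) * shape

  pool <- setdiff(mir_names, de_idx)
  if (length(pool) < cfg$n_nuclear_enriched) pool <- mir_names
  enriched <- sample(pool, cfg$n_nuclear_enriched)
  ratio_true <- setNames(rep(cfg$contamination_fraction, cfg$n_mirnas),
                         mir_names)
  ratio_true[enriched] <- cfg$true_nc_ratio

  noise <- function(n) stats::rnorm(n, 0, cfg$sigma_ct)
  censor <- function(x) ifelse(x > cfg$detection_limit_ct, NA_real_, x)

  # marker baselines and enrichment folds are per stage, shared between the
  # paired fractions, so marker folds land inside the planted ranges
  nm_base <- matrix(stats::runif(2 * n_st, 18, 22), n_st, 2)
  nm_fold <- matrix(stats::runif(2 * n_st, 8, 56), n_st, 2)
  cm_base <- matrix(stats::runif(2 * n_st, 18, 22), n_st, 2)
  cm_fold <- matrix(stats::runif(2 * n_st, 4, 9), n_st, 2)

  make_cols <- function(fraction) {
    cols <- list(); meta <- list()
    for (st in seq_len(n_st)) for (r in seq_len(cfg$n_replicates)) {
      true_ct <- baseline - effect[, st]
      if (fraction == "nuclear") true_ct <- true_ct - log2(ratio_true)
      mir_ct <- censor(true_ct + noise(cfg$n_mirnas))
      nm_ct <- nm_base[st, ] +
        if (fraction == "cytoplasmic") log2(nm_fold[st, ]) else 0
      cm_ct <- cm_base[st, ] +
        if (fraction == "nuclear") log2(cm_fold[st, ]) else 0
      id <- paste(stages[st], fraction, r, sep = ".")
      cols[[id]] <- c(mir_ct, censor(nm_ct + noise(2)), censor(cm_ct + noise(2)))
      meta[[id]] <- data.frame(sample_id = id, cell_type = stages[st],
                               fraction = fraction, replicate = r,
                               stringsAsFactors = FALSE)
    }
    vals <- do.call(cbind, cols)
    rownames(vals) <- assays
    list(values = vals, samples = do.call(rbind, meta))
  }

  w <- make_cols("whole")
  whole <- ct_matrix(w$values, w$samples, assay_class = assay_class)
  nu <- make_cols("nuclear")
  cy <- make_cols("cytoplasmic")
  fractions <- ct_matrix(cbind(nu$values, cy$values),
                         rbind(nu$samples, cy$samples),
                         assay_class = assay_class)

  truth <- list(
    de = data.frame(assay = de_idx, direction = unname(direction[de_idx]),
                    log2_fold_full = unname(direction[de_idx]) * log2(cfg$de_fold),
                    stringsAsFactors = FALSE),
    effect = effect,
    nuclear_enriched = data.frame(assay = enriched,
                                  true_nc_ratio = rep(cfg$true_nc_ratio,
                                                      length(enriched)),
                                  stringsAsFactors = FALSE),
    markers = data.frame(assay = c(nuc_markers, cyt_markers),
                         class = assay_class[c(nuc_markers, cyt_markers)],
                         stringsAsFactors = FALSE),
    marker_folds = list(nuclear = nm_fold, cytoplasmic = cm_fold),
    contamination_fraction = cfg$contamination_fraction,
    baseline_ct = baseline)
  list(whole = whole, fractions = fractions, truth = truth)
}

.site_for <- function(mirna, type) {
  rc7 <- reverse_complement_rna(substr(mirna, 2, 8))
  rc6 <- reverse_complement_rna(substr(mirna, 2, 7))
  switch(type,
         "8mer" = paste0(rc7, "A"),
         "7mer-m8" = rc7,
         "7mer-A1" = paste0(rc6, "A"))
}

# Mutate one base inside [start, end] (1-based) avoiding protected ranges;
# returns NULL when every base of the site is protected.
.scrub_site <- function(seq, start, end, protected) {
  pos <- setdiff(start:end, protected)
  if (length(pos) == 0) return(NULL)
  p <- pos[ceiling(length(pos) / 2)]
  old <- substr(seq, p, p)
  new <- sample(setdiff(c("A", "C", "G", "U"), old), 1)
  substr(seq, p, p) <- new
  seq
}

#' Simulate a transcriptome with planted miRNA target pairs
#'
#' Generates random-sequence 3'UTRs and a two-group (promyelocyte vs
#' granulocyte) log2 expression matrix with replicates. For each planted
#' target pair, one seed-match site (type drawn among 8mer / 7mer-m8 /
#' 7mer-A1) is inserted at a recorded position and the gene's expression
#' change is set opposite in sign to its miRNA's change
#' (`gene_effect_log2` log2 units). Non-target genes get independent noise
#' and no planted site: accidental seed sites for the differentially
#' expressed miRNAs are audited post-generation and scrubbed by single-base
#' mutation (scrubs recorded in the ground truth; sites that cannot be
#' scrubbed without touching a planted site are recorded as residual).
#'
#' @param cfg A [sim_config()].
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param mirna_log2fold Named numeric: the log2 change (test vs ref) of
#'   the miRNAs eligible for target planting. Defaults to alternating
#'   `+/- log2(de_fold)` over the first `n_de_mirnas` entries of `mirnas`.
#' @return List: `expr` (list with `values` genes x samples and `samples`
#'   data frame), `utrs` (named character), `truth` (planted pairs with
#'   site types/coordinates, gene folds, scrub log, residual accidental
#'   sites).
#' @export
simulate_transcriptome <- function(cfg, mirnas, mirna_log2fold = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(mirna_log2fold)) {
    k <- min(cfg$n_de_mirnas, length(mirnas))
    mirna_log2fold <- setNames(
      rep(c(1, -1), length.out = k) * log2(cfg$de_fold),
      names(mirnas)[seq_len(k)])
  }
  genes <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  lens <- sample(seq(cfg$utr_length_range[1], cfg$utr_length_range[2]),
                 cfg$n_genes, replace = TRUE)
  utrs <- setNames(vapply(lens, .random_seq, character(1)), genes)

  target_genes <- sample(genes, cfg$n_true_target_pairs)
  target_mirnas <- rep(names(mirna_log2fold),
                       length.out = cfg$n_true_target_pairs)
  site_types <- sample(c("8mer", "7mer-m8", "7mer-A1"),
                       cfg$n_true_target_pairs, replace = TRUE)

  n_pairs <- cfg$n_true_target_pairs
  pairs <- data.frame(mirna = target_mirnas, gene = target_genes,
                      site_type = site_types,
                      utr_start = rep(NA_integer_, n_pairs),
                      utr_end = rep(NA_integer_, n_pairs),
                      stringsAsFactors = FALSE)
  protected <- setNames(vector("list", cfg$n_genes), genes)
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]
    site <- .site_for(mirnas[[pairs$mirna[i]]], pairs$site_type[i])
    L <- nchar(utrs[[g]])
    if (L < nchar(site) + 2) stop("UTR too short to host a seed site")
    pos <- sample(2:(L - nchar(site)), 1)
    substr(utrs[[g]], pos, pos + nchar(site) - 1) <- site
    # guard the flanking bases so the planted site keeps its recorded type:
    # a 7mer-m8 followed by A would scan as an 8mer, and a 7mer-A1 preceded
    # by the complement of miRNA position 8 would be absorbed into an 8mer
    comp_m8 <- chartr("ACGU", "UGCA", substr(mirnas[[pairs$mirna[i]]], 8, 8))
    after <- pos + nchar(site)
    if (pairs$site_type[i] == "7mer-m8" && after <= L &&
        substr(utrs[[g]], after, after) == "A")
      substr(utrs[[g]], after, after) <- "C"
    if (pairs$site_type[i] == "7mer-A1" &&
        substr(utrs[[g]], pos - 1, pos - 1) == comp_m8)
      substr(utrs[[g]], pos - 1, pos - 1) <- sample(
        setdiff(c("A", "C", "G", "U"), comp_m8), 1)
    pairs$utr_start[i] <- pos - 1L # 0-based half-open
    pairs$utr_end[i] <- pos - 1L + nchar(site)
    protected[[g]] <- c(protected[[g]], (pos - 1):(pos + nchar(site)))
  }

  # audit: scrub accidental sites of the DE miRNAs from non-planted loci
  scrubbed <- list(); residual <- list()
  for (m in names(mirna_log2fold)) {
    for (g in genes) {
      planted_here <- pairs$utr_start[pairs$mirna == m & pairs$gene == g]
      for (pass in 1:10) {
        hits <- scan_utr(utrs[[g]], mirnas[[m]])
        hits <- hits[!hits$utr_start %in% planted_here, , drop = FALSE]
        if (nrow(hits) == 0) break
        h <- hits[1, ]
        new_seq <- .scrub_site(utrs[[g]], h$utr_start + 1L, h$utr_end,
                               protected[[g]])
        if (is.null(new_seq)) {
          residual[[length(residual) + 1]] <-
            data.frame(mirna = m, gene = g, utr_start = h$utr_start,
                       match_type = h$match_type, stringsAsFactors = FALSE)
          break
        }
        utrs[[g]] <- new_seq
        scrubbed[[length(scrubbed) + 1]] <-
          data.frame(mirna = m, gene = g, utr_start = h$utr_start,
                     match_type = h$match_type, stringsAsFactors = FALSE)
      }
    }
  }

  groups <- c("promyelocyte", "granulocyte")
  n_rep <- cfg$n_replicates
  samples <- data.frame(
    sample_id = paste(rep(groups, each = n_rep), rep(seq_len(n_rep), 2),
                      sep = "."),
    cell_type = rep(groups, each = n_rep),
    fraction = "whole", replicate = rep(seq_len(n_rep), 2),
    stringsAsFactors = FALSE)
  base_expr <- stats::runif(cfg$n_genes, 6, 10)
  gene_lfc <- setNames(rep(0, cfg$n_genes), genes)
  gene_lfc[pairs$gene] <- -sign(mirna_log2fold[pairs$mirna]) *
    cfg$gene_effect_log2
  vals <- matrix(NA_real_, cfg$n_genes, nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    shift <- if (samples$cell_type[j] == groups[2]) gene_lfc else 0
    vals[, j] <- base_expr + shift + stats::rnorm(cfg$n_genes, 0, cfg$sigma_expr)
  }

  pairs$gene_log2_fold <- unname(gene_lfc[pairs$gene])
  pairs$mirna_log2_fold <- unname(mirna_log2fold[pairs$mirna])
  truth <- list(
    pairs = pairs,
    gene_log2_fold = gene_lfc,
    mirna_log2_fold = mirna_log2fold,
    scrubbed = if (length(scrubbed)) do.call(rbind, scrubbed) else NULL,
    residual_accidental = if (length(residual)) do.call(rbind, residual)
      else NULL)
  list(expr = list(values = vals, samples = samples), utrs = utrs,
       truth = truth)
}

#' Simulate pri-miRNA transcripts with planted binding sites
#'
#' Random pri-miRNA transcripts; for each nuclear miRNA, `n_targets_per`
#' transcripts carry an embedded (exact or 1-2 mismatch) reverse
#' complement of the miRNA at a recorded position; the rest are decoys.
#'
#' @param cfg A [sim_config()].
#' @param nuclear_mirnas Named character vector of nuclear miRNA sequences.
#' @param n_targets_per Planted target transcripts per nuclear miRNA.
#' @param n_mismatches Mismatches introduced into each planted site
#'   (recycled; 0 = exact complement).
#' @return List: `pri` (named character transcripts), `truth` (data frame
#'   `mirna`, `transcript`, `t_start`, `t_end` 0-based half-open,
#'   `n_mismatches`).
#' @export
simulate_pri_targets <- function(cfg, nuclear_mirnas, n_targets_per = 2,
                                 n_mismatches = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(nuclear_mirnas) == 0) stop("need >= 1 nuclear miRNA")
  n <- cfg$n_pri
  lens <- sample(seq(cfg$pri_length_range[1], cfg$pri_length_range[2]),
                 n, replace = TRUE)
  pri <- setNames(vapply(lens, .random_seq, character(1)),
                  sprintf("pri-mir-%03d", seq_len(n)))
  slots <- sample(names(pri))
  need <- length(nuclear_mirnas) * n_targets_per
  if (need > n) stop("not enough transcripts for the requested plants")
  mm <- rep_len(n_mismatches, need)
  truth <- list(); k <- 0
  for (m in names(nuclear_mirnas)) {
    for (j in seq_len(n_targets_per)) {
      k <- k + 1
      tr <- slots[k]
      site <- reverse_complement_rna(nuclear_mirnas[[m]])
      if (mm[k] > 0) {
        pos_mm <- sample(nchar(site), mm[k])
        for (p in pos_mm) {
          old <- substr(site, p, p)
          substr(site, p, p) <- sample(setdiff(c("A", "C", "G", "U"), old), 1)
        }
      }
      L <- nchar(pri[[tr]])
      at <- sample(seq_len(L - nchar(site) + 1), 1)
      substr(pri[[tr]], at, at + nchar(site) - 1) <- site
      truth[[k]] <- data.frame(mirna = m, transcript = tr,
                               t_start = at - 1L,
                               t_end = at - 1L + nchar(site),
                               n_mismatches = mm[k], stringsAsFactors = FALSE)
    }
  }
  list(pri = pri, truth = do.call(rbind, truth))
}
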