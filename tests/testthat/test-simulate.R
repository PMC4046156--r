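test_that("CT simulation is deterministic and censoring only removes values", {
  cfg <- sim_config(n_mirnas = 50, n_de_mirnas = 10, n_nuclear_enriched = 3,
                    n_true_target_pairs = 0, seed = 5)
  a <- simulate_ct_experiment(cfg)
  b <- simulate_ct_experiment(cfg)
  expect_identical(a$whole$values, b$whole$values)
  expect_identical(a$fractions$values, b$fractions$values)
  expect_identical(a$truth, b$truth)

  # with the detection limit pushed out, the same draws reappear uncensored
  cfg_far <- cfg; cfg_far$detection_limit_ct <- 1e6
  c1 <- simulate_ct_experiment(cfg_far)
  keep <- !is.na(a$fractions$values)
  expect_equal(a$fractions$values[keep], c1$fractions$values[keep])
  expect_true(all(c1$fractions$values[!keep] > cfg$detection_limit_ct))
})

test_that("noise-free simulation reproduces planted ratios exactly", {
  cfg <- sim_config(n_mirnas = 30, n_de_mirnas = 4, n_nuclear_enriched = 2,
                    n_true_target_pairs = 0, sigma_ct = 0, seed = 8)
  sim <- simulate_ct_experiment(cfg)
  fp <- fraction_pairs(sim$fractions)
  mir <- fp$assay_class == "miRNA"
  ratios <- nc_ratio(fp$ct_nuc[mir, "LSK"], fp$ct_cyto[mir, "LSK"])
  planted <- rownames(fp$ct_nuc[mir, , drop = FALSE]) %in%
    sim$truth$nuclear_enriched$assay
  expect_equal(unname(ratios[planted]), rep(2, 2), tolerance = 1e-9)
  expect_equal(unname(ratios[!planted & !is.na(ratios)]),
               rep(0.1, sum(!planted & !is.na(ratios))), tolerance = 1e-9)
})

test_that("planted DE miRNAs are recovered by the CT differential filter", {
  cfg <- sim_config(n_mirnas = 80, n_de_mirnas = 12, n_true_target_pairs = 0,
                    seed = 9)
  sim <- simulate_ct_experiment(cfg)
  de <- mirna_differential(collapse_replicates(sim$whole))
  called <- attr(de, "de_entities")
  expect_true(all(sim$truth$de$assay %in% called))
  # null assays rarely reach 2-fold at sigma_ct = 0.25
  expect_lt(length(setdiff(called, sim$truth$de$assay)), 5)
})

test_that("transcriptome simulation plants recoverable sites and effects", {
  cfg <- sim_config(n_mirnas = 20, n_genes = 60, n_de_mirnas = 10,
                    n_true_target_pairs = 12, seed = 10)
  set.seed(10)
  mirnas <- simulate_mirna_sequences(cfg$n_mirnas)
  tx <- simulate_transcriptome(cfg, mirnas)
  tr <- tx$truth$pairs
  for (i in seq_len(nrow(tr))) {
    sites <- scan_utr(tx$utrs[[tr$gene[i]]], mirnas[[tr$mirna[i]]])
    hit <- sites[sites$utr_start == tr$utr_start[i], ]
    expect_equal(hit$match_type, tr$site_type[i])
  }
  # scrubbing removed accidental sites of the DE miRNAs from other UTRs
  de_mirnas <- names(tx$truth$mirna_log2_fold)
  resid <- tx$truth$residual_accidental
  for (m in names(tx$truth$mirna_log2fold)) {
    for (g in setdiff(names(tx$utrs), tr$gene[tr$mirna == m])) {
      n_acc <- nrow(scan_utr(tx$utrs[[g]], mirnas[[m]]))
      n_known <- if (is.null(resid)) 0 else
        sum(resid$mirna == m & resid$gene == g)
      expect_equal(n_acc, n_known)
    }
  }
  # planted expression effects point opposite to the miRNA change
  expect_equal(sign(tr$gene_log2_fold), -sign(tr$mirna_log2_fold))

  gde <- moderated_t_de(tx$expr$values,
                        factor(tx$expr$samples$cell_type,
                               levels = c("promyelocyte", "granulocyte")))
  flagged <- gde$gene[gde$significant]
  expect_gte(mean(tr$gene %in% flagged), 0.9)

  # with no planted pairs the pairing stage returns (almost) nothing
  cfg0 <- sim_config(n_mirnas = 20, n_genes = 60, n_de_mirnas = 10,
                     n_true_target_pairs = 0, seed = 11)
  set.seed(11)
  tx0 <- simulate_transcriptome(cfg0, mirnas)
  mirna_de <- data.frame(entity = names(tx0$truth$mirna_log2_fold),
                         test = "granulocyte", ref = "promyelocyte",
                         log2_fold = unname(tx0$truth$mirna_log2_fold),
                         passes = TRUE)
  gde0 <- moderated_t_de(tx0$expr$values,
                         factor(tx0$expr$samples$cell_type,
                                levels = c("promyelocyte", "granulocyte")))
  p0 <- anticorrelated_pairs(mirna_de, gde0, tx0$utrs, mirnas)
  expect_equal(nrow(p0), 0)
})

test_that("pri-miRNA simulation plants localizable binding sites", {
  cfg <- sim_config(n_pri = 10, pri_length_range = c(400, 800), seed = 12)
  set.seed(12)
  nuc <- simulate_mirna_sequences(2, names = c("miR-709", "miR-706"))
  em <- energy_model()

  sim0 <- simulate_pri_targets(cfg, nuc, n_targets_per = 2, n_mismatches = 0)
  for (i in seq_len(nrow(sim0$truth))) {
    row <- sim0$truth[i, ]
    hit <- scan_transcript(nuc[[row$mirna]], sim0$pri[[row$transcript]], em)
    expect_lt(hit$mfe, -30)
    overlap <- min(hit$t_end, row$t_end) - max(hit$t_start, row$t_start)
    expect_gte(overlap / 22, 0.8)
  }
  # 2-mismatch plants still localize to the planted window
  sim2 <- simulate_pri_targets(cfg, nuc, n_targets_per = 1, n_mismatches = 2)
  for (i in seq_len(nrow(sim2$truth))) {
    row <- sim2$truth[i, ]
    hit <- scan_transcript(nuc[[row$mirna]], sim2$pri[[row$transcript]], em)
    overlap <- min(hit$t_end, row$t_end) - max(hit$t_start, row$t_start)
    expect_gte(overlap / 22, 0.8)
  }
  # decoys score strictly worse than planted transcripts
  planted_mfe <- min(vapply(seq_len(nrow(sim0$truth)), function(i)
    scan_transcript(nuc[[sim0$truth$mirna[i]]],
                    sim0$pri[[sim0$truth$transcript[i]]], em)$mfe,
    numeric(1)))
  decoys <- setdiff(names(sim0$pri), sim0$truth$transcript)
  decoy_mfe <- min(vapply(decoys, function(tr)
    scan_transcript(nuc[[1]], sim0$pri[[tr]], em)$mfe, numeric(1)))
  expect_lt(planted_mfe, decoy_mfe)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_mirnas = 5, n_de_mirnas = 10), "n_de_mirnas")
  expect_error(sim_config(contamination_fraction = 1.2), "contamination")
  expect_error(sim_config(sigma_ct = -1), "sigma_ct")
})
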