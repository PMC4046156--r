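# Build a fractionation ct_matrix from per-replicate nuclear/cytoplasmic CTs.
frac_matrix <- function(ct_nuc, ct_cyto, assay_class = NULL,
                        cell_type = "promyelocyte") {
  n_rep <- ncol(ct_nuc)
  sm <- data.frame(
    sample_id = c(paste(cell_type, "nuclear", 1:n_rep, sep = "."),
                  paste(cell_type, "cytoplasmic", 1:n_rep, sep = ".")),
    cell_type = cell_type,
    fraction = rep(c("nuclear", "cytoplasmic"), each = n_rep),
    replicate = rep(1:n_rep, 2), stringsAsFactors = FALSE)
  ct_matrix(cbind(ct_nuc, ct_cyto), sm, assay_class = assay_class)
}

test_that("marker QC computes enrichment folds with class-specific thresholds", {
  nuc <- rbind("SnoRNA-like" = 22, "Y1-like" = 27, "flat" = 24, "m1" = 25)
  cyt <- rbind("SnoRNA-like" = 25, "Y1-like" = 25, "flat" = 24, "m1" = 25)
  cls <- c("SnoRNA-like" = "nuclear_marker", "Y1-like" = "cytoplasmic_marker",
           "flat" = "nuclear_marker")
  fp <- fraction_pairs(frac_matrix(nuc, cyt, cls))
  qc <- marker_qc(fp)
  expect_equal(qc$fold[qc$assay == "SnoRNA-like"], 8.0) # within 8-56x range
  expect_true(qc$pass[qc$assay == "SnoRNA-like"])
  expect_equal(qc$fold[qc$assay == "Y1-like"], 4.0)     # within 4-9x range
  expect_true(qc$pass[qc$assay == "Y1-like"])
  expect_equal(qc$fold[qc$assay == "flat"], 1.0)
  expect_false(qc$pass[qc$assay == "flat"])
  expect_false(attr(qc, "pass"))

  fp2 <- fraction_pairs(frac_matrix(nuc, cyt, cls[1:2]))
  expect_true(attr(marker_qc(fp2), "pass"))
  fp3 <- fraction_pairs(frac_matrix(nuc, cyt, cls[1]))
  expect_error(marker_qc(fp3), "marker")
})

test_that("N:C ratios follow the cell-equivalent delta-CT rule", {
  expect_equal(nc_ratio(24, 24), 1.0)
  expect_equal(nc_ratio(27, 24), 0.125)
  expect_gt(nc_ratio(27, 24), 0.1) # a candidate under the > 0.1 rule
  set.seed(2)
  a <- runif(40, 18, 34); b <- runif(40, 18, 34)
  expect_equal(nc_ratio(a, b) * nc_ratio(b, a), rep(1, 40))
  expect_true(is.na(nc_ratio(NA, 24)))
})

test_that("contamination regression recovers planted carry-over", {
  set.seed(21)
  cyt <- matrix(runif(60, 20, 29), 60, 1,
                dimnames = list(sprintf("m%03d", 1:60), NULL))
  # exact 10% carry-over: nuclear CT = cytoplasmic + log2(10)
  nuc <- cyt + log2(10)
  fp <- fraction_pairs(frac_matrix(nuc, cyt))
  fit <- contamination_regression(fp, "promyelocyte")
  expect_equal(fit$slope, 1.0, tolerance = 1e-9)
  expect_equal(fit$intercept, 3.3219, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(fit$implied_contamination_fraction, 0.10, tolerance = 1e-4)

  # identical fractions imply full "contamination" (no nuclear depletion)
  fp0 <- fraction_pairs(frac_matrix(cyt, cyt))
  fit0 <- contamination_regression(fp0, "promyelocyte")
  expect_equal(fit0$slope, 1.0, tolerance = 1e-9)
  expect_equal(fit0$implied_contamination_fraction, 1.0, tolerance = 1e-9)

  # Gaussian CT noise: R^2 drops below 1, slope stays near 1 at n = 200
  set.seed(22)
  cyt2 <- matrix(runif(200, 20, 29), 200, 1,
                 dimnames = list(sprintf("m%03d", 1:200), NULL))
  nuc2 <- cyt2 + log2(10) + rnorm(200, 0, 0.5)
  fit2 <- contamination_regression(fraction_pairs(frac_matrix(nuc2, cyt2)),
                                   "promyelocyte")
  expect_lt(fit2$r_squared, 1)
  expect_lt(abs(fit2$slope - 1), 0.1)

  expect_error(
    contamination_regression(fraction_pairs(frac_matrix(nuc[1:5, , drop = FALSE],
                                                        cyt[1:5, , drop = FALSE])),
                             "promyelocyte"),
    "insufficient")
})

test_that("nuclear-enrichment calls combine the ratio rule and control t-test", {
  set.seed(31)
  n <- 30; reps <- 3
  assays <- sprintf("m%03d", 1:n)
  base <- runif(n, 21, 26)
  base[2] <- 22 # keep the pure-cytoplasmic example detectable in the nucleus
  cyt <- matrix(rep(base, reps), n, reps) + rnorm(n * reps, 0, 0.1)
  # controls/null at N:C = 0.05; one planted enriched assay at 1.3
  ratio <- rep(0.05, n); ratio[1] <- 1.3; ratio[2] <- 0.05
  nuc <- cyt - log2(ratio) + rnorm(n * reps, 0, 0.1)
  nuc[3, ] <- NA # undetermined everywhere
  rownames(nuc) <- rownames(cyt) <- assays
  fp <- fraction_pairs(frac_matrix(nuc, cyt))
  calls <- call_nuclear_enriched(fp)

  r1 <- calls[calls$assay == "m001", ]
  expect_equal(r1$call, "nuclear_enriched")
  expect_true(r1$ratio_gt_1)
  expect_lt(r1$p_value, 0.05)
  expect_lt(r1$control_baseline, 0.1)
  expect_equal(calls$call[calls$assay == "m002"], "cytoplasmic")
  expect_equal(calls$call[calls$assay == "m003"], "not_detectable")

  # raising the ratio threshold never adds a candidate
  above <- function(th) {
    cc <- call_nuclear_enriched(fp, ratio_threshold = th)
    cc$assay[cc$call %in% c("candidate", "nuclear_enriched")]
  }
  prev <- above(0.01)
  for (th in c(0.05, 0.1, 0.5, 1.5)) {
    cur <- above(th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  expect_error(call_nuclear_enriched(fp, controls = character(0)), "control")
})

test_that("pure carry-over simulations match the planted contamination", {
  cfg <- sim_config(n_mirnas = 200, n_nuclear_enriched = 0, n_de_mirnas = 0,
                    n_true_target_pairs = 0, seed = 77)
  sim <- simulate_ct_experiment(cfg)
  fp <- fraction_pairs(sim$fractions)
  for (ct in c("LSK", "granulocyte")) {
    keep <- fp$assay_class == "miRNA"
    med <- median(nc_ratio(fp$ct_nuc[keep, ct], fp$ct_cyto[keep, ct]),
                  na.rm = TRUE)
    expect_gt(med, 0.08)
    expect_lt(med, 0.12)
    fit <- contamination_regression(fp, ct)
    expect_lt(abs(fit$intercept - log2(1 / 0.1)), 0.2)
  }
})
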