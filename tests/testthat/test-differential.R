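coll_matrix <- function(vals, cell_types = c("LSK", "promyelocyte",
                                             "myelocyte", "granulocyte")) {
  sm <- data.frame(sample_id = paste0(cell_types, ".whole"),
                   cell_type = cell_types, fraction = "whole", replicate = 1L)
  colnames(vals) <- sm$sample_id
  ct_matrix(vals, sm)
}

test_that("miRNA differential expression applies the inclusive 2-fold rule", {
  vals <- rbind(
    "down2x" = c(25, 24, 25, 26),   # gran vs prom: fold 0.25, down
    "lowexp" = c(31, 33, 31, 33),   # never below CT 30: not detectable
    "exact2" = c(25, 25, 25, 24))   # gran vs prom: fold exactly 2
  de <- mirna_differential(coll_matrix(vals))
  row <- de[de$entity == "down2x" & de$test == "granulocyte" &
              de$ref == "promyelocyte", ]
  expect_equal(row$fold, 0.25)
  expect_equal(row$direction, "down")
  expect_true(row$passes)
  expect_false(any(de$passes[de$entity == "lowexp"]))
  expect_true(de$passes[de$entity == "exact2" & de$test == "granulocyte" &
                          de$ref == "promyelocyte"])

  # fold(A vs B) * fold(B vs A) = 1 across all assays and pairs
  f1 <- de[order(de$entity, de$test, de$ref), ]
  f2 <- de[order(de$entity, de$ref, de$test), ]
  expect_equal(f1$fold * f2$fold, rep(1, nrow(de)))

  expect_error(
    mirna_differential(coll_matrix(vals[, 1, drop = FALSE], "LSK")),
    "2 cell types")
})

test_that("signed-rank p-values are exact and match full sign enumeration", {
  expect_equal(wilcoxon_delta_ct(1:5, rep(0, 5))$p_value, 0.0625)
  expect_equal(wilcoxon_delta_ct(1:6, rep(0, 6))$p_value, 0.03125)
  expect_warning(res <- wilcoxon_delta_ct(rep(2, 4), rep(2, 4)), "zero")
  expect_equal(res$p_value, 1.0)

  set.seed(101)
  for (n in 5:10) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.3, 1), 3)
      d <- d[d != 0]
      if (length(d) < 3 || anyDuplicated(abs(d))) next
      got <- wilcoxon_delta_ct(d)
      expect_equal(got$p_value, oracle_signrank_p(d), tolerance = 1e-12)
      # and agrees with the reference exact implementation
      expect_equal(got$p_value,
                   suppressWarnings(wilcox.test(d, exact = TRUE)$p.value),
                   tolerance = 1e-12)
    }
  }
})

test_that("clustering selects CT<25 differentially regulated assays", {
  # two planted groups with opposite trajectories, plus boundary/flat decoys
  set.seed(5)
  up <- t(sapply(1:4, function(i) c(24, 23, 22, 21) + rnorm(4, 0, 0.1)))
  dn <- t(sapply(1:4, function(i) c(21, 22, 23, 24) + rnorm(4, 0, 0.1)))
  boundary <- matrix(c(25.0, 26, 27, 28), 1) # min CT exactly 25: excluded
  vals <- rbind(up, dn, boundary)
  rownames(vals) <- c(paste0("up", 1:4), paste0("dn", 1:4), "boundary")
  m <- coll_matrix(vals)
  de <- mirna_differential(m)
  cl <- cluster_high_expressers(m, de)
  expect_false("boundary" %in% cl$entities)
  expect_setequal(cl$entities, c(paste0("up", 1:4), paste0("dn", 1:4)))
  # leaf order separates the two planted groups contiguously
  grp <- substr(cl$entities, 1, 2)
  expect_equal(length(rle(grp)$lengths), 2)

  # identical profiles merge at height zero
  two <- coll_matrix(rbind(a = c(20, 21, 22, 23), b = c(20, 21, 22, 23)))
  de2 <- mirna_differential(two)
  cl2 <- cluster_high_expressers(two, de2)
  expect_equal(min(cl2$hclust$height), 0, tolerance = 1e-12)

  expect_warning(
    cluster_high_expressers(coll_matrix(rbind(a = c(20, 21, 22, 23))),
                            de2[de2$entity == "a", ]),
    "fewer than 2")
})

test_that("cross-species concordance reports Spearman rho and agreement", {
  fa <- setNames(seq(-3, 3, length.out = 20), paste0("mmu-miR-", 1:20))
  fb <- setNames(2 * seq(-3, 3, length.out = 20), paste0("hsa-miR-", 1:20))
  r <- cross_species_concordance(fa, fb)
  expect_equal(r$rho, 1.0)
  expect_equal(r$n_common, 20)
  r2 <- cross_species_concordance(fa, -fb)
  expect_equal(r2$rho, -1.0)

  # rho is invariant under strictly monotone transforms
  set.seed(8)
  fa2 <- setNames(rnorm(30), paste0("m", 1:30))
  fb2 <- setNames(rnorm(30), paste0("m", 1:30))
  base <- cross_species_concordance(fa2, fb2, name_mapper = identity)
  warped <- cross_species_concordance(sign(fa2) * abs(fa2)^3,
                                      exp(fb2), name_mapper = identity)
  expect_equal(warped$rho, base$rho)

  # bivariate-normal draw at known rank correlation (n = 64)
  set.seed(64)
  r_pearson <- 0.9
  z1 <- rnorm(64); z2 <- r_pearson * z1 + sqrt(1 - r_pearson^2) * rnorm(64)
  rho_expect <- 6 / pi * asin(r_pearson / 2)
  got <- cross_species_concordance(setNames(z1, paste0("m", 1:64)),
                                   setNames(z2, paste0("m", 1:64)),
                                   name_mapper = identity)
  expect_lt(abs(got$rho - rho_expect), 0.1)

  # direction agreement among strong changes in dataset A
  agree <- cross_species_concordance(fa, fb)$concordance
  expect_equal(agree$n, agree$agree) # perfectly concordant case

  expect_error(cross_species_concordance(fa[1:2], fb[1:2]), "fewer than 3")
})

test_that("moderated t shrinks variances and matches limma numerically", {
  skip_if_not_installed("limma")
  set.seed(12)
  n_genes <- 200
  sd_g <- exp(rnorm(n_genes, 0, 0.5)) # heteroscedastic genes
  x <- matrix(rnorm(n_genes * 6, 8, rep(sd_g, 6)), n_genes, 6,
              dimnames = list(sprintf("g%03d", 1:n_genes), NULL))
  x[1:10, 4:6] <- x[1:10, 4:6] + 2
  groups <- rep(c("promyelocyte", "granulocyte"), each = 3)
  res <- moderated_t_de(x, factor(groups, levels = unique(groups)))

  design <- cbind(1, groups == "granulocyte")
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "d_prior"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s2_prior"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_moderated, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p_moderated, unname(fit$p.value[, 2]), tolerance = 1e-8)

  # posterior variance lies between the prior and the gene variance
  d0 <- attr(res, "d_prior"); s02 <- attr(res, "s2_prior")
  s2_post <- (d0 * s02 + 4 * res$s2_gene) / (d0 + 4)
  expect_true(all(s2_post >= pmin(s02, res$s2_gene) - 1e-12))
  expect_true(all(s2_post <= pmax(s02, res$s2_gene) + 1e-12))
})

test_that("moderated t has the correct degenerate limits", {
  set.seed(13)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(paste0("g", 1:50), NULL))
  groups <- rep(c("a", "b"), each = 3)

  # d0 = 0: ordinary equal-variance two-sample t per gene
  res0 <- moderated_t_de(x, groups, prior_df_override = 0)
  t_ref <- apply(x, 1, function(v)
    t.test(v[4:6], v[1:3], var.equal = TRUE)$statistic)
  expect_equal(res0$t_moderated, unname(t_ref), tolerance = 1e-10)
  expect_equal(unique(res0$df_total), 4)

  # d0 = Inf: every posterior variance collapses to the prior
  resInf <- moderated_t_de(x, groups, prior_df_override = Inf)
  expect_equal(length(unique(round(resInf$t_moderated / resInf$log2_fold, 9))),
               1) # common scale for all genes

  # identical gene variances: moderated t = ordinary t with that variance
  pattern <- c(-1, 0, 1) / sqrt(2) # zero-mean, unit variance residual
  xx <- outer(rep(1, 20), c(pattern + 5, pattern + 5))
  xx[1:5, 4:6] <- xx[1:5, 4:6] + 1.5
  rownames(xx) <- paste0("g", 1:20)
  rese <- moderated_t_de(xx, groups)
  s2 <- rese$s2_gene[1]
  expect_equal(rese$t_moderated,
               rese$log2_fold / sqrt(s2 * (2 / 3)), tolerance = 1e-9)

  # all-zero variance is a degenerate prior
  flat <- matrix(5, 10, 6, dimnames = list(paste0("g", 1:10), NULL))
  expect_error(moderated_t_de(flat, groups), "degenerate")
})
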