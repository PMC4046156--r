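LET7_LIKE <- "UAGCUUAUCAGACUGAUGUUGA"

test_that("seed region extracts miRNA positions 2-8", {
  expect_equal(seed_region(LET7_LIKE), "AGCUUAU")
  expect_equal(seed_region("UAAAAAAG"), "AAAAAAG")
  expect_error(seed_region("UAAAAAG"), ">= 8")
  expect_equal(seed_region("tagcttatcagactgatgttga"), "AGCUUAU") # DNA input
})

test_that("scan_utr classifies canonical site types with precedence", {
  # 8mer: seed match (positions 2-8) followed by A
  s8 <- scan_utr("GGAUAAGCUAGG", LET7_LIKE)
  expect_equal(nrow(s8), 1)
  expect_equal(s8$match_type, "8mer")
  expect_equal(c(s8$utr_start, s8$utr_end), c(2, 10))
  expect_equal(s8$site_sequence, "AUAAGCUA")
  # 7mer-m8: seed match, no A after
  s7 <- scan_utr("GGAUAAGCUUGG", LET7_LIKE)
  expect_equal(s7$match_type, "7mer-m8")
  expect_equal(c(s7$utr_start, s7$utr_end), c(2, 9))
  # 7mer-A1: positions 2-7 match followed by A
  sa <- scan_utr("GGUAAGCUAGG", LET7_LIKE)
  expect_equal(sa$match_type, "7mer-A1")
  expect_equal(c(sa$utr_start, sa$utr_end), c(2, 9))
  expect_equal(sa$site_sequence, "UAAGCUA")

  # an 8mer locus implies both 7mer patterns; only the 8mer is reported
  both <- scan_utr("CCAUAAGCUACC", LET7_LIKE)
  expect_equal(both$match_type, "8mer")
  expect_equal(nrow(both), 1)

  # DNA and RNA alphabets give identical results
  expect_identical(scan_utr("GGATAAGCTAGG", LET7_LIKE),
                   scan_utr("GGAUAAGCUAGG", LET7_LIKE))
  expect_equal(nrow(scan_utr("", LET7_LIKE)), 0)
  expect_error(scan_utr("GGANNAGG", LET7_LIKE), "invalid")
  expect_equal(nrow(scan_utr("GGANNAGG", LET7_LIKE, invalid = "keep")), 0)
})

test_that("scan_utr agrees with the complementation oracle on random pairs", {
  set.seed(97)
  for (i in 1:200) {
    mirna <- random_rna(sample(18:24, 1))
    utr <- random_rna(sample(50:400, 1))
    got <- scan_utr(utr, mirna)
    expect_identical(got, oracle_scan_utr(utr, mirna))
    # reported site sequences re-extract from the UTR at their coordinates
    if (nrow(got) > 0)
      expect_equal(got$site_sequence,
                   substring(normalize_rna(utr), got$utr_start + 1,
                             got$utr_end))
  }
})

test_that("anti-correlated pairing requires opposite direction and a site", {
  mirnas <- c("miR-up" = LET7_LIKE, "miR-alsoup" = "UGAGGUAGUAGGUUGUAUAGUU")
  utrs <- c(gene_site = paste0(random_rna(30), "AUAAGCUA", random_rna(30)),
            gene_nosite = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
            gene_up = paste0(random_rna(10), "AUAAGCUA", random_rna(10)))
  mirna_de <- data.frame(entity = names(mirnas), test = "granulocyte",
                         ref = "promyelocyte", log2_fold = c(2, 2),
                         passes = TRUE)
  gene_de <- data.frame(gene = names(utrs),
                        log2_fold = c(-1.3, -1.3, 1.3),
                        p_moderated = 0.01)
  pairs <- anticorrelated_pairs(mirna_de, gene_de, utrs, mirnas)
  # retained: miRNA up 4x, gene down ~2.5x, 8mer present
  expect_true(any(pairs$mirna == "miR-up" & pairs$gene == "gene_site"))
  # same direction excluded even though gene_up carries a site
  expect_false("gene_up" %in% pairs$gene)
  # no seed site excluded despite anti-correlation
  expect_false("gene_nosite" %in% pairs$gene)
  expect_true(all(pairs$n_sites >= 1))
  expect_equal(unique(pairs$rationale), "anti_correlated")
  m <- attr(pairs, "matches")[["miR-up|gene_site"]]
  expect_equal(m$match_type[1], "8mer")
})

test_that("stage-specific filtering matches peaks to troughs with strict ties", {
  stages <- c("LSK", "promyelocyte", "myelocyte", "granulocyte")
  mp <- rbind("miR-a" = c(1, 5, 2, 1),   # peaks in promyelocytes
              "miR-b" = c(1, 2, 3, 9),   # peaks in granulocytes
              "miR-t" = c(5, 5, 1, 1))   # tied peak
  gp <- rbind("gene_1" = c(4, 0, 3, 4),  # lowest in promyelocytes
              "gene_2" = c(0, 4, 4, 4),  # lowest in LSK
              "gene_3" = c(4, 0, 3, 4))
  colnames(mp) <- colnames(gp) <- stages
  pairs <- data.frame(
    mirna = c("miR-a", "miR-b", "miR-t"),
    gene = c("gene_1", "gene_2", "gene_3"),
    mirna_log2_fold = 1, gene_log2_fold = -1, n_sites = 1,
    match_types = "8mer", rationale = "anti_correlated",
    known_validated = FALSE, stringsAsFactors = FALSE)

  prom <- stage_specific_pairs(mp, gp, pairs, "promyelocyte")
  expect_equal(prom$mirna, "miR-a")
  expect_equal(prom$rationale, "stage_specific:promyelocyte")
  # peak and trough in different stages: excluded for every stage
  for (st in stages)
    expect_false("miR-b" %in% stage_specific_pairs(mp, gp, pairs, st)$mirna)
  # exact tie for the peak: excluded
  expect_false("miR-t" %in%
                 stage_specific_pairs(mp, gp, pairs, "LSK")$mirna)

  mp_na <- mp; mp_na["miR-a", "LSK"] <- NA
  expect_warning(stage_specific_pairs(mp_na, gp, pairs, "promyelocyte"),
                 "missing stage")
  expect_error(stage_specific_pairs(mp, gp, pairs, "blast"), "missing from")
})
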