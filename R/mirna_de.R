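#' Whole-cell miRNA differential expression from CT values
#'
#' For every detectable assay and every ordered pair of cell types, the
#' linear fold change is `2^(CT_ref - CT_test)`. An assay passes a
#' comparison when it is detectable (CT < `ct_threshold` in at least one
#' cell type) and its fold change is at least `min_fold` in either
#' direction (the "2-fold or more" rule is inclusive).
#'
#' @param m A collapsed whole-cell [ct_matrix()] (one column per cell type).
#' @param min_fold Minimum linear fold change (inclusive) to call a change.
#' @param ct_threshold Detectability cutoff in cycles (strict `<`).
#' @return Data frame with one row per assay and ordered cell-type pair:
#'   `entity`, `test`, `ref`, `log2_fold`, `fold`, `direction`,
#'   `detectable`, `passes`. The attribute `"de_entities"` lists assays
#'   passing in at least one comparison.
#' @export
mirna_differential <- function(m, min_fold = 2.0, ct_threshold = 30) {
  stopifnot(inherits(m, "ct_matrix"))
  cts <- unique(m$samples$cell_type)
  if (length(cts) < 2)
    stop("differential expression needs at least 2 cell types")
  if (any(table(m$samples$cell_type) > 1))
    stop("matrix must be collapsed to one column per cell type")
  vals <- m$values[m$assay_class == "miRNA", , drop = FALSE]
  colnames(vals) <- m$samples$cell_type[match(colnames(vals), m$samples$sample_id)]
  detect <- apply(vals, 1, function(v) any(!is.na(v) & v < ct_threshold))

  combos <- expand.grid(test = cts, ref = cts, stringsAsFactors = FALSE)
  combos <- combos[combos$test != combos$ref, ]
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    test <- combos$test[i]; ref <- combos$ref[i]
    lf <- vals[, ref] - vals[, test]
    data.frame(entity = rownames(vals), test = test, ref = ref,
               comparison = paste(test, "vs", ref),
               ct_test = vals[, test], ct_ref = vals[, ref],
               log2_fold = lf, fold = 2^lf,
               direction = ifelse(lf >= 0, "up", "down"),
               detectable = detect,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  res$passes <- res$detectable & !is.na(res$fold) &
    (res$fold >= min_fold | res$fold <= 1 / min_fold)
  attr(res, "de_entities") <- unique(res$entity[res$passes])
  attr(res, "min_fold") <- min_fold
  res
}

#' Wilcoxon signed-rank test on paired delta-CT values
#'
#' Two-sided signed-rank test on paired differences. Zero differences are
#' dropped (Wilcoxon's original treatment); tied absolute differences get
#' mid-ranks. Without ties and for n <= `exact_max`, the exact null
#' distribution of the rank sum is computed by the shift convolution over
#' all 2^n sign assignments; otherwise a normal approximation with tie and
#' continuity corrections is used.
#'
#' @param delta_ct_a,delta_ct_b Paired numeric vectors (e.g. per-replicate
#'   delta-CT values in two conditions). If `delta_ct_b` is `NULL`,
#'   `delta_ct_a` is taken as the differences directly.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (rank sum of positive differences, W+),
#'   `p_value` (two-sided), `n` (pairs used after dropping zeros), `method`.
#' @export
wilcoxon_delta_ct <- function(delta_ct_a, delta_ct_b = NULL, exact_max = 25) {
  d <- if (is.null(delta_ct_b)) delta_ct_a else {
    if (length(delta_ct_a) != length(delta_ct_b))
      stop("paired test needs equal-length vectors")
    delta_ct_a - delta_ct_b
  }
  d <- d[!is.na(d)]
  nonzero <- d != 0
  if (!any(nonzero)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1.0, n = 0L, method = "degenerate"))
  }
  d <- d[nonzero]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0

  if (!ties && n <= exact_max) {
    # exact null: counts over all 2^n sign assignments, built by convolution
    maxw <- n * (n + 1) / 2
    counts <- c(1, rep(0, maxw)) # index k+1 holds #assignments with W+ = k
    for (rr in seq_len(n)) {
      shifted <- c(rep(0, rr), counts[seq_len(maxw + 1 - rr)])
      counts <- counts + shifted
    }
    total <- 2^n
    p_le <- sum(counts[seq_len(w + 1)]) / total
    p_ge <- sum(counts[(w + 1):(maxw + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

#' Hierarchical clustering of highly expressed, differentially regulated miRNAs
#'
#' Selects assays with CT strictly below `ct_high` in at least one cell
#' type that also pass differential expression in at least
#' `min_passing_comparisons` (unordered) stage comparisons, then clusters
#' their centered expression profiles (negative delta-CT, so higher values
#' mean higher expression). The default distance is Pearson correlation
#' distance (1 - r) with average linkage; Euclidean/complete are available.
#'
#' @param m Collapsed whole-cell [ct_matrix()].
#' @param de_calls Output of [mirna_differential()].
#' @param ct_high High-expression cutoff in cycles (strict `<`).
#' @param min_passing_comparisons Minimum number of unordered stage
#'   comparisons an assay must pass (an assay differentially regulated
#'   "between two or more stages" passes at least one).
#' @param distance `"pearson"` or `"euclidean"`.
#' @param linkage Any method accepted by [stats::hclust()].
#' @return A `cluster_result`: list with `entities` (leaf order), `hclust`,
#'   `profiles` (centered expression matrix), `distance_metric`,
#'   `linkage_method`; or an empty result (with a warning) when fewer than
#'   two assays qualify.
#' @export
cluster_high_expressers <- function(m, de_calls, ct_high = 25,
                                    min_passing_comparisons = 1,
                                    distance = c("pearson", "euclidean"),
                                    linkage = "average") {
  stopifnot(inherits(m, "ct_matrix"))
  distance <- match.arg(distance)
  vals <- m$values[m$assay_class == "miRNA", , drop = FALSE]
  high <- apply(vals, 1, function(v) any(!is.na(v) & v < ct_high))

  pass <- de_calls[de_calls$passes, , drop = FALSE]
  pair_key <- apply(cbind(pmin(pass$test, pass$ref), pmax(pass$test, pass$ref)),
                    1, paste, collapse = "|")
  n_comp <- tapply(pair_key, pass$entity, function(k) length(unique(k)))
  de_ok <- rownames(vals) %in% names(n_comp)[n_comp >= min_passing_comparisons]

  sel <- rownames(vals)[high & de_ok]
  x <- vals[sel, , drop = FALSE]
  complete <- rowSums(is.na(x)) == 0
  if (any(!complete)) {
    warning(sum(!complete), " selected assay(s) dropped: undetermined CT in >=1 cell type")
    x <- x[complete, , drop = FALSE]
  }
  empty <- structure(list(entities = character(0), hclust = NULL,
                          profiles = NULL, distance_metric = distance,
                          linkage_method = linkage),
                     class = "cluster_result")
  if (nrow(x) < 2) {
    warning("fewer than 2 assays qualify for clustering")
    return(empty)
  }
  profiles <- -sweep(x, 1, rowMeans(x)) # expression scale, row-centered
  if (distance == "pearson") {
    r <- suppressWarnings(cor(t(profiles)))
    r[is.na(r)] <- 0 # zero-variance profile: maximally uninformative
    d <- as.dist(1 - r)
  } else {
    d <- dist(profiles)
  }
  hc <- hclust(d, method = linkage)
  structure(list(entities = rownames(profiles)[hc$order], hclust = hc,
                 profiles = profiles, distance_metric = distance,
                 linkage_method = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d assays (%s distance, %s linkage)\n",
              length(x$entities), x$distance_metric, x$linkage_method))
  if (length(x$entities) > 0)
    cat("  leaf order:", paste(head(x$entities, 8), collapse = ", "),
        if (length(x$entities) > 8) "..." else "", "\n")
  invisible(x)
}

#' Default miRNA-name normalization for cross-species matching
#'
#' Strips the three-letter species prefix (mmu-, hsa-, ...) and lower-cases.
#' @param x Character vector of miRNA names.
#' @return Normalized names.
#' @export
strip_species_prefix <- function(x) {
  sub("^[a-z]{3}-", "", tolower(x))
}

#' Cross-species concordance of miRNA fold changes
#'
#' Matches miRNAs between two datasets (after name normalization), computes
#' the Spearman rank correlation of their log2 fold changes, the R-squared
#' of the linear fold-fold fit, and direction-agreement counts among
#' entities passing the fold filter in dataset A.
#'
#' @param fold_a,fold_b Named numeric vectors of log2 fold changes.
#' @param name_mapper Function normalizing names before matching.
#' @param min_fold Linear fold cutoff (on dataset A) for the agreement table.
#' @return List: `rho`, `p_value` (two-sided Spearman), `r_squared`,
#'   `n_common`, `concordance` (data frame of up/down agreement counts),
#'   `common` (the matched fold table).
#' @export
cross_species_concordance <- function(fold_a, fold_b,
                                      name_mapper = strip_species_prefix,
                                      min_fold = 2.0) {
  names(fold_a) <- name_mapper(names(fold_a))
  names(fold_b) <- name_mapper(names(fold_b))
  common <- intersect(names(fold_a), names(fold_b))
  if (length(common) < 3)
    stop("fewer than 3 miRNAs in common after name mapping")
  a <- fold_a[common]; b <- fold_b[common]
  ct <- suppressWarnings(cor.test(a, b, method = "spearman"))
  fit <- suppressWarnings(lm(b ~ a))
  sel <- abs(a) >= log2(min_fold)
  conc <- data.frame(
    direction_a = c("up", "down"),
    n = c(sum(sel & a > 0), sum(sel & a < 0)),
    agree = c(sum(sel & a > 0 & b > 0), sum(sel & a < 0 & b < 0)))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n_common = length(common),
       concordance = conc,
       common = data.frame(name = common, fold_a = unname(a), fold_b = unname(b)))
}
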