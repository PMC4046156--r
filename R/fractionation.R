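#' Pair nuclear and cytoplasmic CT measurements per cell type
#'
#' Builds a fraction-pair view of a CT matrix containing nuclear and
#' cytoplasmic samples on a cell-equivalent basis (equal input volumes from
#' the same lysate split, so CT values compare directly with no
#' housekeeping normalization). Replicates are collapsed by mean CT for
#' ranking; per-replicate log2 N:C ratios (nuclear replicate r paired with
#' cytoplasmic replicate r) are retained for statistical testing.
#'
#' @param m A [ct_matrix()] whose samples include `nuclear` and
#'   `cytoplasmic` fractions for each included cell type.
#' @return A `fraction_pairs` object: list with `assays`, `cell_types`,
#'   `ct_nuc`/`ct_cyto` (collapsed CT matrices, assays x cell types),
#'   `log2_ratio_reps` (per cell type, matrix of per-replicate log2 N:C
#'   ratios), `assay_class`.
#' @export
fraction_pairs <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  frac <- m$samples$fraction
  cts <- unique(m$samples$cell_type[frac %in% c("nuclear", "cytoplasmic")])
  have_both <- vapply(cts, function(ct) {
    all(c("nuclear", "cytoplasmic") %in%
          frac[m$samples$cell_type == ct])
  }, logical(1))
  if (!any(have_both))
    stop("no cell type has both nuclear and cytoplasmic samples")
  cts <- cts[have_both]

  coll <- collapse_replicates(m)
  pick <- function(fraction) {
    idx <- match(paste(cts, fraction, sep = "."), coll$samples$sample_id)
    out <- coll$values[, idx, drop = FALSE]
    colnames(out) <- cts
    out
  }
  ct_nuc <- pick("nuclear")
  ct_cyto <- pick("cytoplasmic")

  ratio_reps <- lapply(cts, function(ct) {
    nuc <- m$samples$cell_type == ct & frac == "nuclear"
    cyt <- m$samples$cell_type == ct & frac == "cytoplasmic"
    reps <- intersect(m$samples$replicate[nuc], m$samples$replicate[cyt])
    out <- sapply(reps, function(r) {
      cn <- m$values[, which(nuc & m$samples$replicate == r)[1]]
      cc <- m$values[, which(cyt & m$samples$replicate == r)[1]]
      cc - cn # log2 N:C ratio
    })
    out <- matrix(out, nrow = nrow(m$values),
                  dimnames = list(rownames(m$values), paste0("rep", reps)))
    out
  })
  names(ratio_reps) <- cts

  structure(list(assays = rownames(m$values), cell_types = cts,
                 ct_nuc = ct_nuc, ct_cyto = ct_cyto,
                 log2_ratio_reps = ratio_reps,
                 assay_class = m$assay_class),
            class = "fraction_pairs")
}

#' @export
print.fraction_pairs <- function(x, ...) {
  cat(sprintf("fraction_pairs: %d assays, cell types: %s\n",
              length(x$assays), paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Nuclear:cytoplasmic expression ratio from CT values
#'
#' On a cell-equivalent basis the N:C ratio is `2^(ct_cyto - ct_nuc)`:
#' below 1 the assay is mostly cytoplasmic, above 1 mostly nuclear.
#'
#' @param ct_nuc,ct_cyto CT values in cycles (vectorized); `NA`
#'   (undetermined) propagates.
#' @return Positive numeric ratio (or `NA`).
#' @export
nc_ratio <- function(ct_nuc, ct_cyto) {
  2^(ct_cyto - ct_nuc)
}

#' Marker-based fractionation quality control
#'
#' Nuclear markers (SnoRNA-like) must be enriched in the nuclear fraction
#' (fold `2^(ct_cyto - ct_nuc)` at least `min_nuclear_fold`); cytoplasmic
#' markers (Y1-like) in the cytoplasmic fraction. A cell type passes when
#' all its marker folds meet their thresholds.
#'
#' @param fp A [fraction_pairs()] object.
#' @param min_nuclear_fold,min_cyto_fold Minimum marker enrichment folds.
#' @return Data frame `cell_type`, `assay`, `class`, `fold`, `pass`, with a
#'   logical attribute `"pass"` (all markers in all cell types pass).
#' @export
marker_qc <- function(fp, min_nuclear_fold = 4.0, min_cyto_fold = 2.0) {
  stopifnot(inherits(fp, "fraction_pairs"))
  nuc_m <- fp$assays[fp$assay_class == "nuclear_marker"]
  cyt_m <- fp$assays[fp$assay_class == "cytoplasmic_marker"]
  if (length(nuc_m) == 0 || length(cyt_m) == 0)
    stop("marker QC needs at least one nuclear and one cytoplasmic marker")
  rows <- list()
  for (ct in fp$cell_types) {
    for (a in nuc_m) {
      fold <- 2^(fp$ct_cyto[a, ct] - fp$ct_nuc[a, ct])
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, assay = a, class = "nuclear_marker", fold = fold,
        pass = !is.na(fold) && fold >= min_nuclear_fold)
    }
    for (a in cyt_m) {
      fold <- 2^(fp$ct_nuc[a, ct] - fp$ct_cyto[a, ct])
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, assay = a, class = "cytoplasmic_marker", fold = fold,
        pass = !is.na(fold) && fold >= min_cyto_fold)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Contamination regression of nuclear on cytoplasmic CT
#'
#' Ordinary least squares of nuclear CT on cytoplasmic CT over non-marker
#' assays detectable in the cytoplasm. When the nuclear signal is pure
#' cytoplasmic carry-over at fraction alpha, the relation is
#' `ct_nuc = ct_cyto + log2(1/alpha)` (slope 1), so the implied
#' contamination fraction is `2^(-intercept)`.
#'
#' @param fp A [fraction_pairs()] object.
#' @param cell_type Cell type to fit.
#' @param detect_threshold Cytoplasmic detectability cutoff in cycles.
#' @return List `cell_type`, `slope`, `intercept`, `r_squared`,
#'   `implied_contamination_fraction`, `n`.
#' @export
contamination_regression <- function(fp, cell_type, detect_threshold = 30) {
  stopifnot(inherits(fp, "fraction_pairs"))
  if (!cell_type %in% fp$cell_types) stop("unknown cell type: ", cell_type)
  keep <- fp$assay_class == "miRNA" &
    !is.na(fp$ct_cyto[, cell_type]) & fp$ct_cyto[, cell_type] < detect_threshold &
    !is.na(fp$ct_nuc[, cell_type])
  x <- fp$ct_cyto[keep, cell_type]
  y <- fp$ct_nuc[keep, cell_type]
  if (length(x) < 10)
    stop("insufficient data: ", length(x), " detectable assays (need >= 10)")
  fit <- lm(y ~ x)
  list(cell_type = cell_type,
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       implied_contamination_fraction = 2^(-unname(coef(fit)[1])),
       n = length(x))
}

#' Call nuclear-enriched miRNAs against cytoplasmic controls
#'
#' An assay is assessed in the nucleus: assays whose nuclear CT is at or
#' above `ct_threshold` in every cell type are `not_detectable`. Detectable
#' assays with N:C ratio at or below `ratio_threshold` in a cell type are
#' `cytoplasmic` there; above the threshold they are `candidate`, and
#' `nuclear_enriched` when additionally a one-sided Welch t-test of their
#' per-replicate log2 N:C ratios against the pooled control replicates (same
#' cell type) gives p below `alpha`. Controls default to the
#' `n_controls` detectable non-marker assays with the consistently lowest
#' N:C ratio (ranked by their maximum collapsed ratio across cell types).
#'
#' @param fp A [fraction_pairs()] object.
#' @param controls Character vector of control assay names, or `NULL` to
#'   select automatically.
#' @param n_controls Number of automatically selected controls.
#' @param ratio_threshold N:C ratio above which an assay is a candidate.
#' @param ct_threshold Nuclear detectability cutoff in cycles (strict `<`).
#' @param alpha Significance level for the control comparison.
#' @return Data frame with one row per detectable assay and cell type:
#'   `assay`, `cell_type`, `ct_nuc`, `ct_cyto`, `nc_ratio`,
#'   `control_baseline`, `p_value`, `call`, `ratio_gt_1`, `is_control`.
#'   Attribute `"controls"` records the control set.
#' @export
call_nuclear_enriched <- function(fp, controls = NULL, n_controls = 10,
                                  ratio_threshold = 0.1, ct_threshold = 30,
                                  alpha = 0.05) {
  stopifnot(inherits(fp, "fraction_pairs"))
  mir <- fp$assays[fp$assay_class == "miRNA"]
  ratios <- nc_ratio(fp$ct_nuc[mir, , drop = FALSE],
                     fp$ct_cyto[mir, , drop = FALSE])
  detectable <- apply(fp$ct_nuc[mir, , drop = FALSE], 1,
                      function(v) any(!is.na(v) & v < ct_threshold))

  if (is.null(controls)) {
    cand <- mir[detectable]
    if (length(cand) == 0) stop("no detectable assays to choose controls from")
    worst <- apply(ratios[cand, , drop = FALSE], 1,
                   function(r) if (all(is.na(r))) Inf else max(r, na.rm = TRUE))
    controls <- cand[order(worst)][seq_len(min(n_controls, length(cand)))]
  }
  controls <- intersect(controls, mir)
  if (length(controls) == 0) stop("empty control set")

  control_reps <- lapply(fp$cell_types, function(ct) {
    v <- as.vector(fp$log2_ratio_reps[[ct]][controls, , drop = FALSE])
    v[!is.na(v)]
  })
  names(control_reps) <- fp$cell_types
  control_baseline <- vapply(fp$cell_types, function(ct)
    mean(ratios[controls, ct], na.rm = TRUE), numeric(1))

  rows <- list()
  for (a in mir) {
    for (ct in fp$cell_types) {
      r <- ratios[a, ct]
      p <- NA_real_
      if (!detectable[a]) {
        call <- "not_detectable"
      } else if (is.na(r) || is.na(fp$ct_nuc[a, ct]) ||
                 fp$ct_nuc[a, ct] >= ct_threshold) {
        call <- "not_detectable"
      } else if (r <= ratio_threshold) {
        call <- "cytoplasmic"
      } else {
        call <- "candidate"
        x <- fp$log2_ratio_reps[[ct]][a, ]
        x <- x[!is.na(x)]
        y <- control_reps[[ct]]
        if (length(x) >= 2 && length(y) >= 2 && !a %in% controls) {
          p <- t.test(x, y, alternative = "greater")$p.value
          if (p < alpha) call <- "nuclear_enriched"
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        assay = a, cell_type = ct,
        ct_nuc = fp$ct_nuc[a, ct], ct_cyto = fp$ct_cyto[a, ct],
        nc_ratio = r, control_baseline = unname(control_baseline[ct]),
        p_value = p, call = call,
        ratio_gt_1 = !is.na(r) & r > 1,
        is_control = a %in% controls,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "controls") <- controls
  out
}
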