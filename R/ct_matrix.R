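#' @useDynLib nucmir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cor.test dist hclust lm median pnorm pt qt sd setNames
#'   t.test var as.dist complete.cases coef
#' @importFrom utils read.delim write.table head
"_PACKAGE"

CELL_TYPES <- c("LSK", "promyelocyte", "myelocyte", "granulocyte")
FRACTIONS <- c("whole", "nuclear", "cytoplasmic")
ASSAY_CLASSES <- c("miRNA", "nuclear_marker", "cytoplasmic_marker")

#' Construct a CT matrix
#'
#' A `ct_matrix` holds RT-qPCR cycle-threshold (CT) values for a panel of
#' assays (miRNAs plus nuclear/cytoplasmic marker RNAs) across samples
#' annotated with cell type, subcellular fraction and replicate.
#' Undetermined reactions (no amplification within the run) are represented
#' as `NA`, kept distinct from any numeric CT: they are never imputed and
#' are excluded from replicate means.
#'
#' @param values Numeric matrix, assays in rows (rownames required), samples
#'   in columns. Non-missing entries must lie in `ct_range`.
#' @param samples Data frame with columns `sample_id`, `cell_type`,
#'   `fraction` (one of `"whole"`, `"nuclear"`, `"cytoplasmic"`) and
#'   `replicate` (positive integer); one row per column of `values`.
#' @param assay_class Optional character vector (named by assay, or in row
#'   order) with values `"miRNA"`, `"nuclear_marker"` or
#'   `"cytoplasmic_marker"`. Defaults to `"miRNA"` for all assays.
#' @param ct_range Numeric length-2: the admissible CT range (default the
#'   standard 40-cycle run, `c(0, 40)`).
#' @return An object of class `ct_matrix`: a list with elements `values`,
#'   `samples`, `assay_class`.
#' @export
ct_matrix <- function(values, samples, assay_class = NULL, ct_range = c(0, 40)) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("'values' must have assay rownames")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample_id", "cell_type", "fraction", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(values))
    stop("sample sheet has ", nrow(samples), " rows but the CT table has ",
         ncol(values), " sample columns")
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet")
  if (any(is.na(samples$cell_type)) || any(!nzchar(samples$cell_type)))
    stop("every sample must have a cell_type")
  bad_frac <- !samples$fraction %in% FRACTIONS
  if (any(is.na(samples$fraction)) || any(bad_frac))
    stop("sample(s) ", paste(samples$sample_id[bad_frac], collapse = ", "),
         " lack a valid fraction (whole/nuclear/cytoplasmic)")
  samples$replicate <- as.integer(samples$replicate)
  if (any(is.na(samples$replicate)) || any(samples$replicate < 1))
    stop("replicate must be a positive integer for every sample")
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), as.character(samples$sample_id)))
    stop("CT table column names do not match the sample sheet sample_id order")
  colnames(values) <- samples$sample_id

  out_of_range <- which(!is.na(values) &
                          (values < ct_range[1] | values > ct_range[2]),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    i <- out_of_range[1, ]
    stop(sprintf("CT value %.3f at assay '%s', sample '%s' outside [%g, %g]",
                 values[i[1], i[2]], rownames(values)[i[1]],
                 colnames(values)[i[2]], ct_range[1], ct_range[2]))
  }

  if (is.null(assay_class)) {
    assay_class <- setNames(rep("miRNA", nrow(values)), rownames(values))
  } else {
    if (is.null(names(assay_class))) {
      if (length(assay_class) != nrow(values))
        stop("unnamed assay_class must have one entry per assay")
      names(assay_class) <- rownames(values)
    }
    full <- setNames(rep("miRNA", nrow(values)), rownames(values))
    unknown <- setdiff(names(assay_class), rownames(values))
    if (length(unknown) > 0)
      stop("assay_class names not in the CT table: ",
           paste(unknown, collapse = ", "))
    full[names(assay_class)] <- assay_class
    assay_class <- full
  }
  bad_class <- !assay_class %in% ASSAY_CLASSES
  if (any(bad_class))
    stop("invalid assay_class: ", paste(unique(assay_class[bad_class]), collapse = ", "))

  structure(list(values = values, samples = samples, assay_class = assay_class),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("ct_matrix: %d assays x %d samples\n", nrow(x$values), ncol(x$values)))
  cat("  cell types: ", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  cat("  fractions:  ", paste(unique(x$samples$fraction), collapse = ", "), "\n")
  cat(sprintf("  undetermined cells: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' Read a CT table with its sample sheet
#'
#' The CT table is delimited text with a header row: first column `assay`,
#' remaining columns one per sample. Cells equal to the sentinel token
#' (default `"Undetermined"`, as emitted by SDS-style qPCR software) become
#' `NA`. Sample metadata comes from a side-car sample sheet (TSV with
#' columns `sample_id`, `cell_type`, `fraction`, `replicate`); assay classes
#' optionally from a two-column TSV (`assay`, `class`).
#'
#' @param path Path to the CT table.
#' @param sample_sheet Path to the sample-sheet TSV, or a data frame.
#' @param assay_class Path to an assay-class TSV, a named character vector,
#'   or `NULL` (all assays treated as miRNA assays).
#' @param sentinel Token marking undetermined reactions.
#' @param sep Field separator (default tab).
#' @inheritParams ct_matrix
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, sample_sheet, assay_class = NULL,
                          sentinel = "Undetermined", sep = "\t",
                          ct_range = c(0, 40)) {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("CT table must have an assay column plus >=1 sample")
  assays <- raw[[1]]
  if (anyDuplicated(assays)) stop("duplicated assay names in CT table")
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals == sentinel] <- NA_character_
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric CT '%s' at assay '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], assays[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(assays, colnames(vals))

  if (is.character(sample_sheet) && length(sample_sheet) == 1)
    sample_sheet <- read.delim(sample_sheet, sep = "\t", stringsAsFactors = FALSE)
  sample_sheet <- sample_sheet[match(colnames(num), sample_sheet$sample_id), ,
                               drop = FALSE]
  if (any(is.na(sample_sheet$sample_id)))
    stop("sample sheet is missing metadata for sample(s): ",
         paste(setdiff(colnames(num), sample_sheet$sample_id), collapse = ", "))

  if (is.character(assay_class) && length(assay_class) == 1 && file.exists(assay_class)) {
    cls <- read.delim(assay_class, sep = "\t", stringsAsFactors = FALSE)
    assay_class <- setNames(cls[[2]], cls[[1]])
  }
  ct_matrix(num, sample_sheet, assay_class = assay_class, ct_range = ct_range)
}

#' Write a CT table, sample sheet and assay classes
#'
#' Values are serialized with `%.17g` so a write/read round trip reproduces
#' the doubles bit-exactly; `NA` cells are written as the sentinel token.
#'
#' @param m A [ct_matrix()].
#' @param path Output path for the CT table (TSV).
#' @param sample_sheet_path Output path for the sample sheet TSV (default
#'   `<path>.samples.tsv`).
#' @param assay_class_path Output path for the assay-class TSV, or `NULL`
#'   to skip when all assays are miRNA assays.
#' @inheritParams read_ct_table
#' @return Invisibly, the CT table path.
#' @export
write_ct_table <- function(m, path,
                           sample_sheet_path = paste0(path, ".samples.tsv"),
                           assay_class_path = NULL,
                           sentinel = "Undetermined") {
  stopifnot(inherits(m, "ct_matrix"))
  chr <- matrix(sprintf("%.17g", m$values), nrow = nrow(m$values))
  chr[is.na(m$values)] <- sentinel
  df <- data.frame(assay = rownames(m$values), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("assay", colnames(m$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$samples, sample_sheet_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (is.null(assay_class_path) && any(m$assay_class != "miRNA"))
    assay_class_path <- paste0(path, ".classes.tsv")
  if (!is.null(assay_class_path))
    write.table(data.frame(assay = names(m$assay_class), class = m$assay_class),
                assay_class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse replicates to one column per (cell type, fraction)
#'
#' CT values are averaged arithmetically across replicates (the geometric
#' mean on the linear expression scale, the conventional qPCR treatment);
#' undetermined replicates are excluded, and a group whose replicates are
#' all undetermined stays `NA`. The number of non-missing replicates behind
#' each collapsed cell is recorded in the `"n_obs"` attribute.
#'
#' @param m A [ct_matrix()].
#' @return A [ct_matrix()] with one column per (cell_type, fraction) group,
#'   `replicate = 1`, and an `"n_obs"` attribute (matrix of replicate counts).
#' @export
collapse_replicates <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  key <- paste(m$samples$cell_type, m$samples$fraction, sep = ".")
  groups <- unique(key)
  vals <- matrix(NA_real_, nrow(m$values), length(groups),
                 dimnames = list(rownames(m$values), groups))
  nobs <- vals
  for (g in groups) {
    cols <- m$values[, key == g, drop = FALSE]
    n <- rowSums(!is.na(cols))
    vals[, g] <- ifelse(n > 0, rowMeans(cols, na.rm = TRUE), NA_real_)
    nobs[, g] <- n
  }
  first <- match(groups, key)
  samples <- data.frame(sample_id = groups,
                        cell_type = m$samples$cell_type[first],
                        fraction = m$samples$fraction[first],
                        replicate = 1L, stringsAsFactors = FALSE)
  out <- ct_matrix(vals, samples, assay_class = m$assay_class)
  attr(out, "n_obs") <- nobs
  out
}

#' Relative expression from a pair of CT values
#'
#' Converts a CT difference to a linear expression ratio,
#' `efficiency^(ct_ref - ct_test)`: a lower CT means more template, so the
#' ratio exceeds 1 when the test sample expresses more than the reference.
#' Amplification efficiency defaults to 2 (100% doubling per cycle); no
#' efficiency correction is applied.
#'
#' @param ct_test,ct_ref CT values in cycles (vectorized).
#' @param efficiency Per-cycle amplification factor.
#' @return Positive numeric: fold expression of test relative to reference.
#' @examples
#' relative_expression(20.432, 21.599) # 2.246: ~2.2-fold higher in test
#' @export
relative_expression <- function(ct_test, ct_ref, efficiency = 2.0) {
  if (any(is.na(ct_test)) || any(is.na(ct_ref)))
    stop("relative expression is undefined for undetermined CT values")
  stopifnot(efficiency > 1)
  efficiency^(ct_ref - ct_test)
}

#' Detectability filter on a collapsed CT matrix
#'
#' Retains assays whose CT is strictly below `threshold` in at least one
#' column (cell type). Undetermined values never satisfy the test. The
#' conventional cutoff of 30 cycles marks the limit below which TLDA
#' quantification is reliable.
#'
#' @param m A [ct_matrix()], typically collapsed to one column per cell type.
#' @param threshold Cycles; assays need CT < threshold somewhere to pass.
#' @return Character vector of retained assay names (input row order).
#' @export
detectability_filter <- function(m, threshold = 30) {
  stopifnot(inherits(m, "ct_matrix"))
  keep <- apply(m$values, 1, function(v) any(!is.na(v) & v < threshold))
  rownames(m$values)[keep]
}
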