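#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U. Characters outside ACGU either raise an
#' error (default) or are left in place for the caller to skip.
#'
#' @param x Character scalar (DNA or RNA).
#' @param invalid `"error"` or `"keep"`.
#' @return RNA string.
#' @export
normalize_rna <- function(x, invalid = c("error", "keep")) {
  invalid <- match.arg(invalid)
  out <- chartr("tT", "uU", x)
  out <- toupper(out)
  if (invalid == "error" && grepl("[^ACGU]", out))
    stop("invalid nucleotide character(s) in sequence")
  out
}

#' Reverse complement of an RNA string
#' @param x RNA string (ACGU).
#' @return Reverse complement, 5' to 3'.
#' @export
reverse_complement_rna <- function(x) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Seed region of a mature miRNA
#'
#' Nucleotides 2-8 (1-based) of the mature sequence, the primary
#' determinant of canonical target recognition.
#'
#' @param mirna Mature miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @return RNA string of length 7.
#' @export
seed_region <- function(mirna) {
  s <- normalize_rna(mirna)
  if (nchar(s) < 8)
    stop("mature miRNA must be >= 8 nt (seed positions 2-8 must exist)")
  substr(s, 2, 8)
}

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Finds TargetScan-convention sites for one miRNA, Watson-Crick and
#' antiparallel: a 7mer-m8 is the reverse complement of miRNA positions
#' 2-8; a 7mer-A1 is the reverse complement of positions 2-7 followed
#' (3' on the UTR) by a genomic A regardless of the miRNA's first
#' nucleotide; an 8mer is the reverse complement of positions 2-8 followed
#' by that A. Overlapping calls at one locus collapse to the strongest
#' type (8mer > 7mer-m8 > 7mer-A1). Coordinates are 0-based half-open.
#'
#' @param utr UTR sequence (DNA or RNA; normalized internally, so output is
#'   alphabet-invariant).
#' @param mirna Mature miRNA sequence, 5' to 3'.
#' @param invalid Passed to [normalize_rna()]: `"error"` rejects ambiguity
#'   codes, `"keep"` leaves them unmatched.
#' @return Data frame `match_type`, `utr_start`, `utr_end`,
#'   `site_sequence`, ordered by position.
#' @export
scan_utr <- function(utr, mirna, invalid = c("error", "keep")) {
  invalid <- match.arg(invalid)
  empty <- data.frame(match_type = character(0), utr_start = integer(0),
                      utr_end = integer(0), site_sequence = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(utr) || nchar(utr) == 0) return(empty)
  u <- normalize_rna(utr, invalid = invalid)
  m <- normalize_rna(mirna)
  if (nchar(m) < 8) stop("mature miRNA must be >= 8 nt")
  rc7 <- reverse_complement_rna(substr(m, 2, 8))
  rc6 <- reverse_complement_rna(substr(m, 2, 7))
  site8 <- paste0(rc7, "A")
  site7a1 <- paste0(rc6, "A")

  find <- function(pattern) {
    if (nchar(u) < nchar(pattern)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(pattern, u))
  }
  s8 <- find(site8)
  s7m8 <- setdiff(find(rc7), s8)
  s7a1 <- setdiff(find(site7a1), c(s8 + 1L, s7m8))

  res <- rbind(
    if (length(s8)) data.frame(match_type = "8mer", utr_start = s8 - 1L,
                               utr_end = s8 + 7L),
    if (length(s7m8)) data.frame(match_type = "7mer-m8", utr_start = s7m8 - 1L,
                                 utr_end = s7m8 + 6L),
    if (length(s7a1)) data.frame(match_type = "7mer-A1", utr_start = s7a1 - 1L,
                                 utr_end = s7a1 + 6L))
  if (is.null(res) || nrow(res) == 0) return(empty)
  res <- res[order(res$utr_start, res$match_type), , drop = FALSE]
  res$site_sequence <- substring(u, res$utr_start + 1L, res$utr_end)
  rownames(res) <- NULL
  res
}

#' Read sequences from FASTA as normalized RNA strings
#'
#' @param path FASTA file (uncompressed or gzipped).
#' @param invalid Passed to [normalize_rna()].
#' @return Named character vector of RNA sequences; names are the first
#'   whitespace-delimited token of each description line.
#' @export
read_fasta_rna <- function(path, invalid = "error") {
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(as.character(set), normalize_rna, character(1),
                 invalid = invalid)
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write named sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", seqs[[i]]), con)
  }
  invisible(path)
}

#' Anti-correlated miRNA-mRNA target pairs with seed support
#'
#' Pairs every miRNA passing its fold filter with every gene passing the
#' fold and moderated-p filters, keeps pairs whose expression changes go in
#' opposite directions, and requires at least one canonical seed-match
#' site in the gene's 3'UTR.
#'
#' @param mirna_de Output of [mirna_differential()], or a data frame with
#'   columns `entity`, `log2_fold`, `passes` for one comparison.
#' @param gene_de Output of [moderated_t_de()].
#' @param utrs Named character vector of 3'UTR sequences (DNA or RNA).
#' @param mirnas Named character vector of mature miRNA sequences.
#' @param comparison Optional `c(test, ref)` cell types selecting rows of
#'   `mirna_de`; must be supplied when `mirna_de` holds several comparisons.
#' @param min_gene_fold,alpha Gene significance filters (fold inclusive,
#'   p-value at most `alpha`).
#' @param validated Optional character vector of `"miRNA|gene"` keys marking
#'   externally validated interactions (e.g. a Tarbase lookup).
#' @return Data frame of target pairs: `mirna`, `gene`, `mirna_log2_fold`,
#'   `gene_log2_fold`, `n_sites`, `match_types`, `rationale`,
#'   `known_validated`. Attribute `"matches"`: per-pair site tables from
#'   [scan_utr()].
#' @export
anticorrelated_pairs <- function(mirna_de, gene_de, utrs, mirnas,
                                 comparison = NULL, min_gene_fold = 2.0,
                                 alpha = 0.05, validated = NULL) {
  if (!is.null(comparison)) {
    mirna_de <- mirna_de[mirna_de$test == comparison[1] &
                           mirna_de$ref == comparison[2], , drop = FALSE]
    if (nrow(mirna_de) == 0)
      stop("no miRNA DE rows for comparison ",
           paste(comparison, collapse = " vs "))
  } else if (!is.null(mirna_de$comparison) &&
             length(unique(mirna_de$comparison)) > 1) {
    stop("mirna_de holds several comparisons; supply 'comparison'")
  }
  mir_sel <- mirna_de[mirna_de$passes, c("entity", "log2_fold"), drop = FALSE]
  gene_sig <- gene_de$p_moderated <= alpha &
    abs(gene_de$log2_fold) >= log2(min_gene_fold)
  gene_sel <- gene_de[gene_sig, c("gene", "log2_fold"), drop = FALSE]

  rows <- list(); matches <- list()
  for (i in seq_len(nrow(mir_sel))) {
    mname <- mir_sel$entity[i]
    if (!mname %in% names(mirnas)) next
    mfold <- mir_sel$log2_fold[i]
    opp <- gene_sel[sign(gene_sel$log2_fold) == -sign(mfold) &
                      gene_sel$log2_fold != 0, , drop = FALSE]
    for (j in seq_len(nrow(opp))) {
      g <- opp$gene[j]
      if (!g %in% names(utrs)) next
      sites <- scan_utr(utrs[[g]], mirnas[[mname]])
      if (nrow(sites) == 0) next
      key <- paste(mname, g, sep = "|")
      rows[[key]] <- data.frame(
        mirna = mname, gene = g,
        mirna_log2_fold = mfold, gene_log2_fold = opp$log2_fold[j],
        n_sites = nrow(sites),
        match_types = paste(sites$match_type, collapse = ","),
        rationale = "anti_correlated",
        known_validated = key %in% validated,
        stringsAsFactors = FALSE)
      matches[[key]] <- sites
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), gene = character(0),
               mirna_log2_fold = numeric(0), gene_log2_fold = numeric(0),
               n_sites = integer(0), match_types = character(0),
               rationale = character(0), known_validated = logical(0))
  rownames(out) <- NULL
  attr(out, "matches") <- matches
  out
}

#' Stage-specific filtering of target pairs
#'
#' Keeps pairs whose miRNA is expressed highest, and whose gene is
#' expressed lowest, in the given stage. Exact ties for the extremum are
#' excluded (conservative); pairs with a missing stage value are skipped
#' with a warning.
#'
#' @param mirna_profiles,gene_profiles Numeric matrices (entities x stages)
#'   on an expression scale where larger means more expressed (for CT data
#'   use the negated CT).
#' @param pairs Output of [anticorrelated_pairs()].
#' @param stage Stage label (a column of both profile matrices).
#' @return The filtered pairs with `rationale` set to
#'   `"stage_specific:<stage>"`.
#' @export
stage_specific_pairs <- function(mirna_profiles, gene_profiles, pairs, stage) {
  if (!stage %in% colnames(mirna_profiles) ||
      !stage %in% colnames(gene_profiles))
    stop("stage '", stage, "' missing from the profile matrices")
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mp <- mirna_profiles[pairs$mirna[i], ]
    gp <- gene_profiles[pairs$gene[i], ]
    if (any(is.na(mp)) || any(is.na(gp))) {
      warning("pair ", pairs$mirna[i], "|", pairs$gene[i],
              " skipped: missing stage value")
      next
    }
    peak_unique <- sum(mp == max(mp)) == 1
    trough_unique <- sum(gp == min(gp)) == 1
    keep[i] <- peak_unique && trough_unique &&
      names(which.max(mp)) == stage && names(which.min(gp)) == stage
  }
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) > 0) out$rationale <- paste0("stage_specific:", stage)
  attr(out, "matches") <- attr(pairs, "matches")[
    paste(out$mirna, out$gene, sep = "|")]
  rownames(out) <- NULL
  out
}
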