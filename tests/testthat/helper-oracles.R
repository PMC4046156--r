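# Independent oracles used to cross-check the package implementations.
# They deliberately use different mechanisms than the code under test:
# explicit base-by-base complementation for seed scanning, exhaustive
# chain enumeration for the duplex DP, and explicit 2^n sign enumeration
# for the signed-rank test.

RNA_BASES <- c("A", "C", "G", "U")
RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

random_rna <- function(n) {
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

# Seed-match oracle: tests every UTR offset by explicit Watson-Crick
# complementation of the miRNA seed (antiparallel: ascending UTR positions
# pair with descending miRNA positions), then applies the 8mer > 7mer-m8 >
# 7mer-A1 collapse at overlapping loci.
oracle_scan_utr <- function(utr, mirna) {
  u <- strsplit(normalize_rna(utr), "")[[1]]
  m <- strsplit(normalize_rna(mirna), "")[[1]]
  L <- length(u)
  # offsets where miRNA positions `from` down to 2 pair with consecutive
  # UTR bases (antiparallel; checked base by base via the complement map)
  paired_starts <- function(from) {
    span <- from - 1 # number of paired bases
    if (L < span) return(integer(0))
    ok <- rep(TRUE, L - span + 1)
    for (k in 0:(span - 1))
      ok <- ok & (u[seq_len(L - span + 1) + k] == RNA_COMP[m[from - k]])
    which(ok)
  }
  rows <- list()
  core7 <- paired_starts(8) # miRNA 8..2 paired
  core6 <- paired_starts(7) # miRNA 7..2 paired
  s8 <- core7[core7 + 7 <= L & u[pmin(core7 + 7, L)] == "A"]
  s7m8 <- setdiff(core7, s8)
  s7a1 <- core6[core6 + 6 <= L & u[pmin(core6 + 6, L)] == "A"]
  s7a1 <- setdiff(s7a1, c(s8 + 1L, s7m8))
  add <- function(starts, type, len) {
    for (s in starts)
      rows[[length(rows) + 1]] <<- data.frame(
        match_type = type, utr_start = s - 1L, utr_end = s - 1L + len,
        site_sequence = paste(u[s:(s + len - 1)], collapse = ""),
        stringsAsFactors = FALSE)
  }
  add(s8, "8mer", 8L); add(s7m8, "7mer-m8", 7L); add(s7a1, "7mer-A1", 7L)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(match_type = character(0), utr_start = integer(0),
               utr_end = integer(0), site_sequence = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$utr_start, out$match_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_pair_idx <- function(a, b, allow_gu = TRUE) {
  i <- match(paste0(a, b), c("AU", "UA", "CG", "GC", "GU", "UG"))
  if (!is.na(i) && i >= 5 && !allow_gu) return(NA_integer_)
  i
}

# Duplex oracle: enumerate every legal pairing chain (increasing query
# position, decreasing target position, loop caps enforced) and score it
# under the same energy model; feasible for query <= 8 nt, window <= 12 nt.
oracle_duplex_mfe <- function(query, target, em = energy_model()) {
  q <- strsplit(normalize_rna(query), "")[[1]]
  t <- strsplit(normalize_rna(target), "")[[1]]
  n <- length(q); m <- length(t)
  pid <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m))
    pid[i, j] <- oracle_pair_idx(q[i], t[j], em$allow_gu)
  best <- 0
  rec <- function(i, j, e) {
    if (e < best) best <<- e
    if (i >= n || j <= 1) return()
    for (i2 in (i + 1):n) for (j2 in seq_len(j - 1)) {
      if (is.na(pid[i2, j2])) next
      g1 <- i2 - i - 1; g2 <- j - j2 - 1
      if (g1 == 0 && g2 == 0) {
        cost <- em$stacks[pid[i, j], pid[i2, j2]]
      } else if (g1 == 0 || g2 == 0) {
        g <- g1 + g2
        if (g > em$max_bulge) next
        cost <- em$bulge_open + em$bulge_ext * g
      } else {
        if (g1 + g2 > em$max_internal) next
        cost <- em$internal_open + em$internal_ext * (g1 + g2)
      }
      rec(i2, j2, e + cost)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    if (!is.na(pid[i, j])) rec(i, j, 0)
  best
}

# Signed-rank oracle: two-sided exact p by explicit enumeration of all
# 2^n sign assignments (no ties, zeros already dropped).
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

dinucleotide_counts <- function(x) {
  s <- strsplit(x, "")[[1]]
  table(paste0(s[-length(s)], s[-1]))
}
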