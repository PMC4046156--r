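PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Nearest-neighbor stack free energies (kcal/mol at 37C) for the doublet
# 5'-x1 x2-3' paired antiparallel with 3'-y1 y2-5'; rows index the 5'-side
# pair (x1:y1), columns the 3'-side pair (x2:y2). Watson-Crick entries are
# standard published values; G:U-containing entries are representative
# values completed under strand-flip symmetry stack(p1,p2) =
# stack(rev(p2), rev(p1)). This is an intentionally minimal model: no
# helix initiation, no terminal-mismatch or dangling-end terms.
.default_stacks <- local({
  s <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_TYPES, PAIR_TYPES))
  s["AU", ] <- c(-0.93, -1.10, -2.24, -2.08, -0.55, -1.36)
  s["UA", ] <- c(-1.33, -0.93, -2.35, -2.11, -1.00, -1.27)
  s["CG", ] <- c(-2.11, -2.08, -3.26, -2.36, -1.41, -1.53)
  s["GC", ] <- c(-2.35, -2.24, -3.42, -3.26, -2.51, -2.11)
  s["GU", ] <- c(-1.27, -1.36, -2.11, -1.53, -0.50, -0.30)
  s["UG", ] <- c(-1.00, -0.55, -2.51, -1.41, -0.30, -0.50)
  s
})

#' Energy model for intermolecular RNA-RNA duplexes
#'
#' A simplified nearest-neighbor model: adjacent base pairs contribute a
#' stacking free energy from an embedded doublet table; bulges and internal
#' loops contribute affine non-negative penalties and break stacking; only
#' intermolecular, antiparallel pairing is considered. Allowed pairs are
#' the Watson-Crick pairs plus (optionally) G:U wobbles. Absolute energies
#' are therefore not comparable to full physics-based tools, and energy
#' cutoffs downstream should be treated as calibratable parameters.
#'
#' @param stacks 6x6 stacking matrix (kcal/mol), rows/columns named
#'   `c("AU","UA","CG","GC","GU","UG")`; rows index the 5'-side pair of a
#'   doublet. Watson-Crick entries must be negative.
#' @param bulge_open,bulge_ext Affine bulge penalty: `open + ext * length`.
#' @param internal_open,internal_ext Affine internal-loop penalty on the
#'   total number of unpaired nucleotides.
#' @param max_bulge Maximum bulge length (nt).
#' @param max_internal Maximum total unpaired nucleotides in an internal
#'   loop.
#' @param allow_gu Allow G:U wobble pairs.
#' @return An `energy_model` list.
#' @export
energy_model <- function(stacks = .default_stacks,
                         bulge_open = 3.3, bulge_ext = 0.5,
                         internal_open = 1.5, internal_ext = 0.5,
                         max_bulge = 4L, max_internal = 6L,
                         allow_gu = TRUE) {
  stopifnot(is.matrix(stacks), all(dim(stacks) == c(6, 6)))
  wc <- PAIR_TYPES[1:4]
  if (any(stacks[wc, wc] >= 0))
    stop("all Watson-Crick stack energies must be negative")
  if (bulge_open < 0 || bulge_ext < 0 || internal_open < 0 || internal_ext < 0)
    stop("loop penalties must be non-negative")
  structure(list(stacks = stacks, bulge_open = bulge_open,
                 bulge_ext = bulge_ext, internal_open = internal_open,
                 internal_ext = internal_ext,
                 max_bulge = as.integer(max_bulge),
                 max_internal = as.integer(max_internal),
                 allow_gu = isTRUE(allow_gu)),
            class = "energy_model")
}

.encode_rna <- function(x) {
  match(strsplit(normalize_rna(x, invalid = "keep"), "")[[1]],
        c("A", "C", "G", "U")) - 1L
}

.pairing_string <- function(query, window, qpos, tpos) {
  if (length(qpos) == 0) return("")
  qc <- strsplit(query, "")[[1]]
  tc <- strsplit(window, "")[[1]]
  top <- mid <- bot <- character(0)
  for (k in seq_along(qpos)) {
    if (k > 1) {
      gq <- qpos[k] - qpos[k - 1] - 1    # unpaired query nt in between
      gt <- tpos[k - 1] - tpos[k] - 1    # unpaired target nt in between
      w <- max(gq, gt)
      if (w > 0) {
        qgap <- if (gq > 0) qc[(qpos[k - 1] + 1):(qpos[k] - 1)] else character(0)
        tgap <- if (gt > 0) tc[(tpos[k] + 1):(tpos[k - 1] - 1)] else character(0)
        top <- c(top, c(qgap, rep("-", w - gq)))
        mid <- c(mid, rep(" ", w))
        bot <- c(bot, c(rev(tgap), rep("-", w - gt)))
      }
    }
    top <- c(top, qc[qpos[k]])
    mid <- c(mid, "|")
    bot <- c(bot, tc[tpos[k]])
  }
  paste0("5'-", paste(top, collapse = ""), "-3'\n   ",
         paste(mid, collapse = ""), "\n3'-",
         paste(bot, collapse = ""), "-5'")
}

#' Minimum free energy of an intermolecular RNA duplex
#'
#' Dynamic program over (query position, target position) minimizing the
#' summed stacking energies plus bulge/internal-loop penalties of an
#' antiparallel intermolecular duplex under the package's [energy_model()].
#' Returns 0 and an empty trace when no stabilizing duplex exists.
#'
#' @param query Query RNA (the miRNA), 5' to 3'.
#' @param target Target RNA window, 5' to 3'.
#' @param em An [energy_model()].
#' @return List: `mfe` (kcal/mol, <= 0), `pairs` (data frame of 1-based
#'   paired positions `q_pos`, `t_pos`), `pairing_string` (text diagram,
#'   query on top 5'->3').
#' @export
duplex_mfe <- function(query, target, em = energy_model()) {
  q <- .encode_rna(query)
  t <- .encode_rna(target)
  if (anyNA(q) || anyNA(t)) stop("sequences must be RNA (ACGU) after T->U")
  if (length(q) == 0 || length(t) == 0)
    return(list(mfe = 0, pairs = data.frame(q_pos = integer(0),
                                            t_pos = integer(0)),
                pairing_string = ""))
  r <- .duplex_mfe_cpp(q, t, em$stacks, em$bulge_open, em$bulge_ext,
                       em$internal_open, em$internal_ext, em$max_bulge,
                       em$max_internal, em$allow_gu)
  list(mfe = r$mfe,
       pairs = data.frame(q_pos = r$qpos, t_pos = r$tpos),
       pairing_string = .pairing_string(normalize_rna(query),
                                        normalize_rna(target),
                                        r$qpos, r$tpos))
}

#' Scan a transcript for the best duplex with a miRNA
#'
#' Slides windows of `window` nt every `step` nt (plus a final window
#' flushed to the transcript end), computes the duplex MFE in each, and
#' returns the minimum-energy hit with transcript-level coordinates
#' (0-based half-open, covering the paired span). Ties go to the first
#' window.
#'
#' @param mirna Mature miRNA sequence (query), 5' to 3'.
#' @param transcript Transcript sequence, 5' to 3'.
#' @param em An [energy_model()].
#' @param window,step Window size and stride in nt.
#' @param mirna_name,transcript_name Labels carried into the result.
#' @return A one-row data frame (`duplex_hit`): `mirna`, `transcript`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, `mfe`, plus the pairing
#'   diagram in the `"pairing_string"` attribute.
#' @export
scan_transcript <- function(mirna, transcript, em = energy_model(),
                            window = 60, step = 10,
                            mirna_name = "query", transcript_name = "target") {
  q <- .encode_rna(mirna)
  t <- .encode_rna(transcript)
  if (anyNA(q) || anyNA(t)) stop("sequences must be RNA (ACGU) after T->U")
  r <- .scan_duplex_cpp(q, t, as.integer(window), as.integer(step),
                        em$stacks, em$bulge_open, em$bulge_ext,
                        em$internal_open, em$internal_ext, em$max_bulge,
                        em$max_internal, em$allow_gu)
  has <- length(r$qpos) > 0
  out <- data.frame(
    mirna = mirna_name, transcript = transcript_name,
    q_start = if (has) min(r$qpos) - 1L else NA_integer_,
    q_end = if (has) max(r$qpos) else NA_integer_,
    t_start = if (has) min(r$tpos) - 1L else NA_integer_,
    t_end = if (has) max(r$tpos) else NA_integer_,
    mfe = r$mfe, stringsAsFactors = FALSE)
  win_len <- min(nchar(transcript), window)
  attr(out, "pairing_string") <- .pairing_string(
    normalize_rna(mirna),
    substr(normalize_rna(transcript), r$window_start + 1,
           r$window_start + win_len),
    r$qpos, r$tpos - r$window_start)
  out
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson style shuffle: the sequence is viewed as an Eulerian
#' walk on the directed multigraph of dinucleotide transitions; a random
#' last-edge arborescence into the terminal base is drawn, remaining edges
#' are permuted, and the walk is rebuilt. The shuffle preserves the exact
#' dinucleotide (and hence mononucleotide) counts and keeps the first and
#' last base fixed. Uses R's RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param x Sequence (character scalar), length >= 10.
#' @return A shuffled sequence with identical dinucleotide counts.
#' @export
dinucleotide_shuffle <- function(x) {
  s <- strsplit(x, "")[[1]]
  n <- length(s)
  if (n < 10) stop("sequence too short to shuffle (< 10 nt)")
  letters_u <- unique(s)
  if (length(letters_u) == 1) return(x)
  last <- s[n]
  from <- s[-n]; to <- s[-1]
  edges <- split(to, factor(from, levels = letters_u))

  verts <- names(edges)[lengths(edges) > 0]
  for (attempt in 1:1000) {
    # pick a candidate last edge out of every non-terminal vertex
    last_edge <- vapply(verts, function(v) {
      if (v == last) NA_character_ else {
        e <- edges[[v]]
        e[sample.int(length(e), 1)]
      }
    }, character(1))
    # the last-edge graph must lead every vertex into `last`
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      seen <- character(0); cur <- v
      while (!is.na(cur) && cur != last && !cur %in% seen) {
        seen <- c(seen, cur)
        cur <- if (cur %in% names(last_edge)) last_edge[[cur]] else NA_character_
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("failed to draw a valid shuffle arborescence")

  shuffled <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v == last) return(e[sample.int(length(e))])
    le <- last_edge[[v]]
    e <- e[-match(le, e)]
    c(if (length(e)) e[sample.int(length(e))], le)
  })
  names(shuffled) <- verts

  out <- character(n)
  out[1] <- s[1]
  ptr <- setNames(rep(1L, length(verts)), verts)
  cur <- s[1]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' Empirical p-value calibration for a transcript's best duplex hit
#'
#' Recomputes the best duplex MFE on `n_shuffles` dinucleotide-preserving
#' shuffles of the transcript, fits a Gumbel (extreme-value) distribution
#' to the shuffled minima by moment matching, and reports
#' `p = P(null MFE <= observed)` together with the rank-based empirical
#' p-value `(1 + #{null <= observed}) / (n_shuffles + 1)`.
#'
#' @inheritParams scan_transcript
#' @param n_shuffles Number of shuffles (>= 50).
#' @param seed Optional integer seed set before shuffling.
#' @return List: `p_gumbel`, `p_empirical`, `observed_mfe`, `null_mfes`,
#'   `gumbel_location`, `gumbel_scale`.
#' @export
calibrate_p <- function(mirna, transcript, em = energy_model(),
                        n_shuffles = 200, seed = NULL,
                        window = 60, step = 10) {
  if (n_shuffles < 50) stop("n_shuffles must be >= 50")
  if (nchar(transcript) < 10) stop("transcript too short to shuffle (< 10 nt)")
  if (!is.null(seed)) set.seed(seed)
  obs <- scan_transcript(mirna, transcript, em, window, step)$mfe
  nulls <- vapply(seq_len(n_shuffles), function(i) {
    scan_transcript(mirna, dinucleotide_shuffle(transcript), em,
                    window, step)$mfe
  }, numeric(1))
  # minima: fit a Gumbel to Y = -MFE (maxima domain) by moments
  y <- -nulls
  if (sd(y) > 0) {
    beta <- sd(y) * sqrt(6) / pi
    mu <- mean(y) - 0.5772156649015329 * beta
    p_gumbel <- 1 - exp(-exp(-((-obs) - mu) / beta))
  } else {
    mu <- mean(y); beta <- 0
    p_gumbel <- as.numeric(obs <= nulls[1])
  }
  list(p_gumbel = p_gumbel,
       p_empirical = (1 + sum(nulls <= obs)) / (n_shuffles + 1),
       observed_mfe = obs, null_mfes = nulls,
       gumbel_location = mu, gumbel_scale = beta)
}

#' Filter duplex hits into nuclear-miRNA target candidates
#'
#' Keeps hits below the MFE cutoff with calibrated p below `p_cut`, and
#' flags anti-correlation: the nuclear miRNA's trajectory and the mature
#' miRNA processed from the targeted pri-miRNA must change in opposite
#' directions between two stages.
#'
#' @param hits Data frame of duplex hits with columns `mirna`,
#'   `transcript`, `mfe` and `p_value`.
#' @param nuclear_mirna_profiles,mature_mirna_profiles Numeric matrices
#'   (entity x stage) on an expression scale (larger = more expressed).
#' @param mfe_cut MFE cutoff in kcal/mol (strict `<`).
#' @param p_cut p-value cutoff (strict `<`).
#' @param stages Length-2 character: the compared stages (from, to).
#' @param mature_of Function mapping a transcript name to its mature miRNA
#'   name (default strips a leading `"pri-"`).
#' @return The retained hits with `nuclear_delta`, `mature_delta` and
#'   `anti_correlated` columns appended.
#' @export
nuclear_target_candidates <- function(hits, nuclear_mirna_profiles,
                                      mature_mirna_profiles,
                                      mfe_cut = -30, p_cut = 0.05,
                                      stages = c("promyelocyte", "granulocyte"),
                                      mature_of = function(x) sub("^pri-", "", x)) {
  keep <- !is.na(hits$mfe) & hits$mfe < mfe_cut &
    !is.na(hits$p_value) & hits$p_value < p_cut
  out <- hits[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$nuclear_delta <- numeric(0)
    out$mature_delta <- numeric(0)
    out$anti_correlated <- logical(0)
    return(out)
  }
  delta <- function(profiles, entity) {
    if (!entity %in% rownames(profiles)) return(NA_real_)
    profiles[entity, stages[2]] - profiles[entity, stages[1]]
  }
  out$nuclear_delta <- vapply(out$mirna, function(m)
    delta(nuclear_mirna_profiles, m), numeric(1))
  out$mature_delta <- vapply(mature_of(out$transcript), function(m)
    delta(mature_mirna_profiles, m), numeric(1))
  out$anti_correlated <- !is.na(out$nuclear_delta) & !is.na(out$mature_delta) &
    sign(out$nuclear_delta) * sign(out$mature_delta) < 0
  rownames(out) <- NULL
  out
}
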