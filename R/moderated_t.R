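#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y` for `x > 0`, used when
#' matching moments of log gene-wise variances to a scaled-F prior.
#'
#' @param y Positive numeric vector.
#' @return `x` with `trigamma(x) = y` elementwise.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Fit the variance prior by moment matching on log variances
#'
#' Gene-wise sample variances are modeled as `s0^2 * F(d_g, d0)`. On the
#' log scale, `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)` has mean
#' `log(s0^2) - digamma(d0/2) + log(d0/2)` and variance
#' `trigamma(d_g/2) + trigamma(d0/2)`, so the prior degrees of freedom
#' `d0` come from a trigamma inversion of the excess spread of `e_g` and
#' `s0^2` from its mean. Zero variances are excluded from the fit.
#'
#' @param s2 Gene-wise sample variances.
#' @param df Residual degrees of freedom per gene (scalar or vector).
#' @return List `d0` (prior df, possibly `Inf`) and `s02` (prior variance).
#' @keywords internal
fit_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    stop("degenerate prior: fewer than 2 genes with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  ebar <- mean(e)
  excess <- mean((e - ebar)^2 * length(e) / (length(e) - 1)) -
    mean(trigamma(df[ok] / 2))
  if (excess > 0) {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-square sampling noise: variances are
    # exchangeable and the prior is their plain mean
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated t-test for two-group expression data
#'
#' Per gene, the log2 fold change between group means is tested with a
#' t-statistic whose variance estimate is shrunk toward a prior fitted
#' across all genes: the posterior variance is
#' `(d0 s0^2 + d_g s2_g) / (d0 + d_g)` and the statistic is referred to a
#' t distribution on `d0 + d_g` degrees of freedom. Genes are significant
#' when the (optionally BH-adjusted) moderated p-value is at most `alpha`
#' and the linear fold change is at least `min_fold`.
#'
#' @param x Numeric matrix of log2 expression, genes in rows; or a list
#'   with elements `values` and `samples` as produced by the simulator.
#' @param groups Two-level factor (or coercible) over columns of `x`. The
#'   reported fold is level 2 minus level 1.
#' @param min_fold Minimum linear fold change for significance.
#' @param alpha Significance level on the moderated p-value.
#' @param adjust `"none"` (the raw-threshold convention) or `"BH"`.
#' @param prior_df_override Force the prior degrees of freedom (e.g. `0`
#'   recovers the ordinary two-sample t per gene; `Inf` pools fully).
#' @return Data frame with `gene`, `log2_fold`, `fold`, `s2_gene`,
#'   `t_moderated`, `df_total`, `p_moderated`, `p_adjusted`, `significant`;
#'   attributes `s2_prior`, `d_prior` and `comparison`.
#' @export
moderated_t_de <- function(x, groups, min_fold = 2.0, alpha = 0.05,
                           adjust = c("none", "BH"),
                           prior_df_override = NULL) {
  adjust <- match.arg(adjust)
  if (is.list(x) && !is.matrix(x)) x <- x$values
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(x)) stop("'groups' must match the columns of x")
  g1 <- levels(groups)[1]; g2 <- levels(groups)[2]
  x1 <- x[, groups == g1, drop = FALSE]
  x2 <- x[, groups == g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per group")
  d_g <- n1 + n2 - 2

  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  lfc <- m2 - m1
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d_g

  if (is.null(prior_df_override)) {
    prior <- fit_variance_prior(s2, d_g)
  } else {
    prior <- list(d0 = prior_df_override,
                  s02 = if (is.finite(prior_df_override) && prior_df_override == 0)
                    NA_real_ else fit_variance_prior(s2, d_g)$s02)
  }
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else if (d0 == 0) s2 else
    (d0 * s02 + d_g * s2) / (d0 + d_g)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- lfc / se
  df_total <- d0 + d_g
  p <- 2 * pt(-abs(tstat), df = df_total)
  p_adj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p

  res <- data.frame(gene = rownames(x), log2_fold = lfc, fold = 2^lfc,
                    s2_gene = s2, t_moderated = tstat,
                    df_total = df_total, p_moderated = p, p_adjusted = p_adj,
                    significant = p_adj <= alpha & abs(lfc) >= log2(min_fold),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "s2_prior") <- s02
  attr(res, "d_prior") <- d0
  attr(res, "comparison") <- paste(g2, "vs", g1)
  res
}
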