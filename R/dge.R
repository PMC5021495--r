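# Two-group differential expression with empirical-Bayes variance moderation.
#
# The model: per gene g, the pooled within-group variance s_g^2 on
# d_g = nA + nB - 2 df is shrunk toward a prior variance s0^2 carrying d0
# prior df, giving the posterior variance
#     s~^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)
# and the moderated statistic t = logFC / (s~ sqrt(1/nA + 1/nB)), referred to
# a t distribution on d0 + d_g df. (d0, s0^2) are estimated by the method of
# moments from the distribution of log s_g^2 across genes.

#' Construct a variance-moderation prior
#'
#' @param d0 Prior degrees of freedom; `Inf` means all genes share one
#'   variance (`s0_sq`); `0` is the explicit "no moderation" request, under
#'   which [moderated_t()] falls back to the ordinary pooled-variance t-test.
#' @param s0_sq Prior variance (> 0; ignored when `d0 = 0`).
#' @return Object of class `moderation_prior`.
#' @export
moderation_prior <- function(d0, s0_sq) {
  if (!is.numeric(d0) || length(d0) != 1L || is.na(d0) || d0 < 0)
    stop("d0 must be a single number >= 0 (Inf allowed)")
  if (!is.numeric(s0_sq) || length(s0_sq) != 1L || is.na(s0_sq) || s0_sq <= 0)
    stop("s0_sq must be a single positive number")
  structure(list(d0 = d0, s0_sq = s0_sq), class = "moderation_prior")
}

#' @export
print.moderation_prior <- function(x, ...) {
  cat("moderation_prior: d0 =", x$d0, ", s0^2 =", signif(x$s0_sq, 6), "\n")
  invisible(x)
}

# Newton solve of trigamma(y) = x, vectorized; x > 0
trigamma_inverse <- function(x) {
  if (any(x <= 0)) stop("trigamma_inverse requires positive input")
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Estimate the moderation prior from per-gene variances
#'
#' Method-of-moments fit on the log scale: under the model
#' `s2 ~ s0_sq * chisq(df) / df` scaled by a gene-level inverse-chi-square
#' with d0 df, the excess of `var(log s2)` over `trigamma(df/2)` identifies
#' d0 via the trigamma function, and the mean of log s2 (bias-corrected)
#' identifies s0^2. When the observed spread does not exceed the chi-square
#' sampling spread, `d0 = Inf` is returned. Genes with zero variance are
#' excluded from the fit.
#'
#' @param s2 Per-gene pooled variances (length >= 2, all >= 0, not all 0).
#' @param df_resid Residual degrees of freedom of each s2 (single value >= 1).
#' @return A [moderation_prior()].
#' @export
fit_moderation_prior <- function(s2, df_resid) {
  if (length(s2) < 2L) stop("need at least 2 gene variances")
  if (any(!is.finite(s2)) || any(s2 < 0)) stop("variances must be finite and >= 0")
  if (all(s2 == 0)) stop("all gene variances are zero: degenerate input")
  if (!is.numeric(df_resid) || length(df_resid) != 1L || df_resid < 1)
    stop("df_resid must be a single value >= 1")
  z <- log(s2[s2 > 0])
  # all variances (numerically) identical: the empirical distribution is a
  # point mass, so moment-match it directly rather than bias-correcting
  if (stats::var(z) < 1e-24)
    return(moderation_prior(Inf, exp(mean(z))))
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df_resid / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  moderation_prior(d0, s0_sq)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min_{j >= rank(i)} m * p_(j) / j`, capped at 1, returned in the
#' input order. Implemented directly (not via [stats::p.adjust()]) so the
#' procedure itself is under test.
#'
#' @param p_raw Vector of p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values, same length and order.
#' @export
bh_adjust <- function(p_raw) {
  if (!length(p_raw)) return(numeric(0))
  if (any(!is.finite(p_raw)) || any(p_raw < 0) || any(p_raw > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p_raw)
  o <- order(p_raw)
  q_sorted <- p_raw[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

#' Two-group moderated t-test
#'
#' For each gene, computes the log2 fold change `mean(groupA) - mean(groupB)`,
#' the pooled within-group variance, the moderated t-statistic under the
#' supplied (or estimated) prior, the two-sided p-value on `d0 + d_g` df and
#' the BH-adjusted q-value.
#'
#' @param expr Validated expression matrix (genes x samples, log2 scale).
#' @param meta Metadata data frame with columns `sample_id`, `group`.
#' @param contrast Length-2 character vector `c(groupA, groupB)`; positive
#'   `log_fc` means higher in `groupA`.
#' @param prior Optional [moderation_prior()]. `NULL` (default) estimates it
#'   from the data with [fit_moderation_prior()]. `moderation_prior(0, ...)`
#'   requests the ordinary (unmoderated) pooled t-test.
#' @return A `dge_table` data frame with columns `gene_id`, `log_fc`, `s2`,
#'   `t_mod`, `df_total`, `p_raw`, `q_bh`; the prior used is attached as
#'   attribute `"prior"`, the contrast as `"contrast"`.
#' @export
moderated_t <- function(expr, meta, contrast, prior = NULL) {
  validate_expression(expr)
  if (length(contrast) != 2L) stop("contrast must name exactly two groups")
  known <- unique(meta$group)
  bad <- setdiff(contrast, known)
  if (length(bad))
    stop("unknown group label in contrast: ", paste(bad, collapse = ", "))
  sel <- function(g) intersect(meta$sample_id[meta$group == g], colnames(expr))
  a <- sel(contrast[1]); b <- sel(contrast[2])
  nA <- length(a); nB <- length(b)
  if (nA < 2L || nB < 2L)
    stop("each contrast group needs >= 2 samples in the matrix (got ",
         nA, " '", contrast[1], "', ", nB, " '", contrast[2], "')")

  xa <- expr[, a, drop = FALSE]; xb <- expr[, b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  dg <- nA + nB - 2
  s2 <- (ssa + ssb) / dg
  log_fc <- ma - mb

  if (is.null(prior)) prior <- fit_moderation_prior(s2, dg)
  stopifnot(inherits(prior, "moderation_prior"))
  d0 <- prior$d0
  if (d0 == 0) {
    s_post <- s2
    df_total <- dg
  } else if (is.infinite(d0)) {
    s_post <- rep(prior$s0_sq, length(s2))
    df_total <- Inf
  } else {
    s_post <- (d0 * prior$s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }

  se <- sqrt(s_post * (1 / nA + 1 / nB))
  t_mod <- ifelse(log_fc == 0, 0, log_fc / se)   # 0/0 -> 0 by convention
  p_raw <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p_raw <- pmax(p_raw, .Machine$double.xmin)     # keep p in (0, 1]

  tab <- data.frame(gene_id = rownames(expr), log_fc = log_fc, s2 = s2,
                    t_mod = t_mod, df_total = rep(df_total, length(s2)),
                    p_raw = p_raw, q_bh = bh_adjust(p_raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "contrast") <- contrast
  attr(tab, "prior") <- prior
  attr(tab, "n_samples") <- c(nA, nB)
  class(tab) <- c("dge_table", "data.frame")
  tab
}

#' Partition significant genes by direction
#'
#' @param tab A `dge_table`.
#' @param alpha BH significance threshold in (0, 1\]; `alpha = 1` selects
#'   every gene with nonzero fold change.
#' @return List with character vectors `up` (`q_bh <= alpha, log_fc > 0`) and
#'   `down` (`q_bh <= alpha, log_fc < 0`); always disjoint.
#' @export
significant_genes <- function(tab, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  sig <- tab$q_bh <= alpha
  list(up = tab$gene_id[sig & tab$log_fc > 0],
       down = tab$gene_id[sig & tab$log_fc < 0])
}
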