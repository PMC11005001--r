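# Moderated differential testing per contrast, Benjamini-Hochberg adjustment,
# protein-level exclusion of phosphopeptide changes, persistence/overlap set
# arithmetic and per-protein median summaries.

#' Inverse of the trigamma function
#'
#' Solves trigamma(y) = x by Newton iteration (monotone and convex in 1/y,
#' so the iteration converges from the asymptotic start y = 0.5 + 1/x).
#'
#' @param x Positive numeric vector.
#' @return y with trigamma(y) = x.
#' @keywords internal
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (iter in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Moment matching of the variance prior (d0, s0^2) on log sample variances:
# log s_g^2 is distributed as a constant plus the difference of two log
# chi-square variables, so its mean and variance identify the prior.
fit_variance_prior <- function(s2, df1) {
  ok <- is.finite(s2) & df1 > 0
  s2 <- pmax(s2[ok], 1e-300)
  df1 <- df1[ok]
  z <- log(s2)
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df1 / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated t-test for one contrast
#'
#' Fits per-feature ordinary least-squares group means on the samples of the
#' contrast's plex, shrinks the residual variances toward a prior estimated
#' by moment matching on the log sample variances (posterior variance
#' \eqn{(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)}) and tests the treatment-minus-
#' control log2 fold change with a t statistic on \eqn{d_0 + d_g} degrees of
#' freedom. P-values are Benjamini-Hochberg adjusted within the contrast and
#' features are called significant at adjusted p < 0.05.
#'
#' @param mat Complete numeric matrix (features x samples) for one plex.
#' @param design Design rows matching the columns of `mat`.
#' @param contrast A contrast from [pipeline_contrasts()] (list with `label`,
#'   `plex`, `treatment`, `control`).
#' @param covariates Optional numeric matrix of nuisance covariates (e.g.
#'   surrogate vectors), one row per sample of the contrast's plex, included
#'   in the per-feature linear model.
#' @param d0,s0_sq Optional forced prior degrees of freedom / prior variance
#'   (d0 = 0 gives the ordinary t-test; d0 = Inf pools all variances).
#' @param sig_level Adjusted-p significance threshold (default 0.05).
#' @return Data.frame with feature_id, log2FC, t, df_total, p, adj_p and
#'   significant; the estimated prior is attached as attribute
#'   `"moderation"`.
#' @export
fit_moderated_test <- function(mat, design, contrast, covariates = NULL,
                               d0 = NULL, s0_sq = NULL, sig_level = 0.05) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == nrow(design))
  use <- design$plex == contrast$plex
  mat <- mat[, use, drop = FALSE]
  design <- design[use, , drop = FALSE]
  if (anyNA(mat)) stop_format("fit_moderated_test requires a complete matrix")
  group <- factor(design$group)
  counts <- table(group)
  for (g in c(contrast$treatment, contrast$control)) {
    if (!g %in% names(counts) || counts[[g]] < 2L) {
      stop_format("design error: contrast group '%s' needs >= 2 samples", g)
    }
  }
  G <- stats::model.matrix(~ 0 + group)
  colnames(G) <- levels(group)
  X <- G
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(mat)) {
      stop_format("design error: covariates must have one row per plex sample")
    }
    X <- cbind(G, covariates)
  }
  if (qr(X)$rank < ncol(X)) {
    stop_format("design error: rank-deficient design matrix")
  }
  df_resid <- ncol(mat) - ncol(X)
  if (df_resid <= 0L) {
    stop_format("design error: zero residual degrees of freedom")
  }
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, t(mat))       # coefficients x features
  resid <- t(mat) - X %*% beta
  s2 <- colSums(resid^2) / df_resid

  prior <- if (is.null(d0) || is.null(s0_sq)) {
    est <- fit_variance_prior(s2, rep(df_resid, length(s2)))
    list(d0 = d0 %||% est$d0, s0_sq = s0_sq %||% est$s0_sq)
  } else {
    list(d0 = d0, s0_sq = s0_sq)
  }

  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s0_sq, length(s2))
  } else {
    (prior$d0 * prior$s0_sq + df_resid * s2) / (prior$d0 + df_resid)
  }
  cvec <- numeric(ncol(X))
  cvec[match(contrast$treatment, colnames(X))] <- 1
  cvec[match(contrast$control, colnames(X))] <- -1
  lfc <- as.vector(crossprod(cvec, beta))
  lev <- as.numeric(t(cvec) %*% XtXi %*% cvec)
  t_mod <- lfc / sqrt(s2_post * lev)
  df_total <- prior$d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  adj_p <- adjust_bh(p)
  res <- data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    contrast = contrast$label,
    log2FC = unname(lfc),
    t = unname(t_mod),
    df_total = df_total,
    p = unname(p),
    adj_p = unname(adj_p),
    significant = unname(adj_p < sig_level),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "moderation") <- prior
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in sorted order, capped at 1).
#' @export
adjust_bh <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Exclude phosphopeptide changes driven by protein-level changes
#'
#' A significant phosphopeptide is flagged for exclusion from downstream
#' significant sets iff its gene's protein is significant (adjusted p below
#' the threshold) in the matching comparison at either timepoint, so that
#' retained phospho-signals reflect stoichiometry rather than expression.
#' Phosphopeptides whose gene has no protein record are always kept.
#'
#' @param phospho_results Data.frame of phosphopeptide results (must carry
#'   `gene` and `contrast` columns, e.g. from [fit_moderated_test()] joined
#'   with feature annotations).
#' @param protein_results Data.frame of protein-level results with `gene`,
#'   `contrast` and `adj_p`.
#' @param sig_level Protein significance threshold (default 0.05).
#' @return `phospho_results` with added logical `protein_excluded` column;
#'   the `significant` column is left untouched so raw and filtered counts
#'   can both be reported.
#' @export
exclude_protein_driven <- function(phospho_results, protein_results,
                                   sig_level = 0.05) {
  stopifnot(all(c("gene", "contrast") %in% names(phospho_results)),
            all(c("gene", "contrast", "adj_p") %in% names(protein_results)))
  ptype <- contrast_type(protein_results$contrast)
  sig_prot <- protein_results[!is.na(protein_results$adj_p) &
                                protein_results$adj_p < sig_level, , drop = FALSE]
  excluded <- logical(nrow(phospho_results))
  for (ct in unique(phospho_results$contrast)) {
    rows <- phospho_results$contrast == ct
    hit_genes <- unique(sig_prot$gene[contrast_type(sig_prot$contrast) ==
                                        contrast_type(ct)])
    excluded[rows] <- phospho_results$gene[rows] %in% hit_genes
  }
  phospho_results$protein_excluded <- excluded
  phospho_results
}

#' Overlap summary of two feature sets
#'
#' @param ids_a,ids_b Character vectors of feature identifiers (e.g. the
#'   significant sets at 4 h and 24 h, or all detected features per plex).
#' @return List with `n_a`, `n_b`, `n_intersect`, `n_union` (inclusion-
#'   exclusion identity enforced) and persistence percentages
#'   `pct_of_a`/`pct_of_b` (100 * intersection / set size).
#' @export
persistence_and_overlap <- function(ids_a, ids_b) {
  ids_a <- unique(ids_a)
  ids_b <- unique(ids_b)
  n_ab <- length(intersect(ids_a, ids_b))
  overlap_summary_from_counts(length(ids_a), length(ids_b), n_ab)
}

#' Overlap summary from printed counts
#'
#' Inclusion-exclusion arithmetic on reported per-timepoint counts: the
#' union is |A| + |B| - |A n B|.
#'
#' @param n_a,n_b Set sizes.
#' @param n_intersect Size of the intersection.
#' @return Same structure as [persistence_and_overlap()].
#' @export
overlap_summary_from_counts <- function(n_a, n_b, n_intersect) {
  stopifnot(n_intersect <= n_a, n_intersect <= n_b)
  list(
    n_a = n_a,
    n_b = n_b,
    n_intersect = n_intersect,
    n_union = n_a + n_b - n_intersect,
    pct_of_a = if (n_a > 0) 100 * n_intersect / n_a else 0,
    pct_of_b = if (n_b > 0) 100 * n_intersect / n_b else 0
  )
}

#' Median significant log2 fold change per gene
#'
#' Summarizes a protein's phospho-regulation as the median of the
#' significant log2 fold changes across its phosphopeptides (the values
#' underlying per-protein heatmaps of phospho-regulation direction).
#'
#' @param results Data.frame with `gene`, `log2FC` and `significant` columns
#'   (typically already protein-exclusion filtered).
#' @param genes Optional gene subset.
#' @return Data.frame with `gene`, `median_log2FC` and `n_significant`;
#'   genes without significant features are absent.
#' @export
median_protein_summary <- function(results, genes = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  if (!is.null(results$protein_excluded)) {
    sig <- sig[!sig$protein_excluded, , drop = FALSE]
  }
  if (!is.null(genes)) sig <- sig[sig$gene %in% genes, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(gene = character(0), median_log2FC = numeric(0),
                      n_significant = integer(0), stringsAsFactors = FALSE))
  }
  spl <- split(sig$log2FC, sig$gene)
  data.frame(
    gene = names(spl),
    median_log2FC = vapply(spl, stats::median, numeric(1)),
    n_significant = vapply(spl, length, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
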