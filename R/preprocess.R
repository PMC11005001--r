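# Preprocessing of a per-plex log2 intensity matrix: quantile normalization,
# group-wise missingness filtering, kNN imputation, surrogate-variable batch
# correction and Mahalanobis outlier screening on the first two PCs.

#' Quantile-normalize a log2 intensity matrix
#'
#' Forces every sample (column) onto the common distribution of per-rank
#' means. For complete data every column's sorted values become identical;
#' missing entries stay missing and the observed entries of incomplete
#' columns are mapped through interpolated ranks (limma's scheme, which
#' reduces to the classical definition when no values are missing).
#'
#' @param mat Numeric matrix, features x samples, log2 scale, NAs allowed.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) {
    warning("single-sample matrix: quantile normalization skipped")
    return(mat)
  }
  dn <- dimnames(mat)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dn
  out
}

#' Filter features by within-group missingness
#'
#' A feature is kept iff in every required sample group its fraction of
#' missing values does not exceed `max_group_frac` (default: each group is
#' permitted 25% missing data).
#'
#' @param mat Numeric matrix, features x samples.
#' @param design Design rows for the columns of `mat` (same order).
#' @param max_group_frac Maximum tolerated missing fraction per group.
#' @param groups Optional subset of group names that the requested contrasts
#'   require; defaults to all groups in `design`.
#' @return The filtered matrix.
#' @export
filter_missingness <- function(mat, design, max_group_frac = 0.25,
                               groups = NULL) {
  stopifnot(ncol(mat) == nrow(design))
  groups <- groups %||% unique(design$group)
  keep <- rep(TRUE, nrow(mat))
  for (g in groups) {
    cols <- which(design$group == g)
    if (length(cols) == 0L) next
    frac <- rowMeans(is.na(mat[, cols, drop = FALSE]))
    keep <- keep & frac <= max_group_frac
  }
  mat[keep, , drop = FALSE]
}

#' k-nearest-neighbour imputation of missing log2 intensities
#'
#' Each missing entry is replaced by the mean, in that sample, of the k
#' features nearest to the incomplete feature by Euclidean distance computed
#' on co-observed samples (distances are averaged over the co-observed
#' columns so features with different missingness patterns are comparable).
#' Neighbours must themselves be observed in the target sample; if fewer
#' than k candidates exist all available ones are used, and if none exist
#' the feature's own row mean is imputed. Observed entries are never
#' altered.
#'
#' @param mat Numeric matrix, features x samples.
#' @param k Number of neighbours (default 10, the classical default for
#'   this imputation scheme).
#' @return A complete matrix.
#' @export
knn_impute <- function(mat, k = 10L) {
  mat <- as.matrix(mat)
  miss_rows <- which(rowSums(is.na(mat)) > 0L)
  if (length(miss_rows) == 0L) return(mat)
  out <- mat
  for (i in miss_rows) {
    v <- mat[i, ]
    d2 <- rowMeans(sweep(mat, 2L, v)^2, na.rm = TRUE)
    d2[i] <- Inf
    d2[!is.finite(d2)] <- Inf          # no co-observed samples
    miss_cols <- which(is.na(v))
    for (j in miss_cols) {
      cand <- which(!is.na(mat[, j]) & is.finite(d2))
      if (length(cand) == 0L) {
        out[i, j] <- mean(v, na.rm = TRUE)
      } else {
        nb <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
        out[i, j] <- mean(mat[nb, j])
      }
    }
  }
  out
}

#' Estimate and remove unwanted technical variation
#'
#' Surrogate vectors capturing structured variation orthogonal to the primary
#' group design are estimated by the iterative residual-SVD surrogate
#' variable procedure; the number of surrogates is chosen by the
#' Buja-Eyuboglu permutation criterion. The returned matrix has the
#' surrogate components regressed out while protecting the group effects
#' (the group design is included in the removal regression).
#'
#' @param mat Complete numeric matrix, features x samples.
#' @param design Design rows for the columns of `mat`.
#' @param n_sv Number of surrogates; `NULL` (default) chooses automatically.
#' @param seed Integer seed for the permutation criterion.
#' @return List with `corrected` (matrix), `sv` (samples x n_sv matrix or
#'   NULL) and `n_sv`.
#' @export
remove_unwanted_variation <- function(mat, design, n_sv = NULL, seed = NULL) {
  mat <- as.matrix(mat)
  stopifnot(!anyNA(mat), ncol(mat) == nrow(design))
  group <- factor(design$group)
  mod <- stats::model.matrix(~group)
  mod0 <- stats::model.matrix(~1, data = design)
  if (qr(mod)$rank < ncol(mod)) {
    stop_format("design error: rank-deficient primary design matrix")
  }
  # degenerate case: (numerically) no residual structure at all
  fit <- stats::lm.fit(mod, t(mat))
  res <- t(fit$residuals)
  if (max(abs(res)) < 1e-10) {
    return(list(corrected = mat, sv = NULL, n_sv = 0L))
  }
  if (is.null(n_sv)) {
    n_sv <- sva::num.sv(mat, mod, method = "be", B = 20,
                        seed = if (is.null(seed)) NULL else as.integer(seed))
  }
  n_sv <- min(n_sv, ncol(mat) - qr(mod)$rank - 1L)
  if (n_sv <= 0L) {
    return(list(corrected = mat, sv = NULL, n_sv = 0L))
  }
  utils::capture.output(
    svobj <- sva::sva(mat, mod, mod0, n.sv = n_sv)
  )
  sv <- as.matrix(svobj$sv)
  colnames(sv) <- paste0("SV", seq_len(ncol(sv)))
  # regress surrogates out, protecting the primary design
  X <- cbind(mod, sv)
  beta <- stats::lm.fit(X, t(mat))$coefficients
  sv_cols <- ncol(mod) + seq_len(ncol(sv))
  corrected <- mat - t(X[, sv_cols, drop = FALSE] %*% beta[sv_cols, , drop = FALSE])
  list(corrected = corrected, sv = sv, n_sv = ncol(sv))
}

#' Flag outlier samples in principal-component space
#'
#' Samples are projected onto the first `n_pcs` principal components of the
#' normalized (and corrected) intensity matrix; a sample is flagged when its
#' squared Mahalanobis distance in that space exceeds the chi-square
#' quantile at 1 - alpha with `n_pcs` degrees of freedom. The reference
#' mean and covariance for each sample are estimated from the remaining
#' samples (leave-one-out): with the sample itself included, the squared
#' distance is bounded by (n-1)^2/n, which for a typical plex lies below
#' the chi-square quantile at small alpha, so a gross outlier would mask
#' itself.
#'
#' @param mat Complete numeric matrix, features x samples.
#' @param n_pcs Number of principal components (default 2).
#' @param alpha Tail probability for flagging (default 1e-4).
#' @return Character vector of flagged sample names (possibly empty), with
#'   the squared distances attached as attribute `"d2"`.
#' @export
detect_outlier_samples <- function(mat, n_pcs = 2L, alpha = 1e-4) {
  mat <- as.matrix(mat)
  stopifnot(!anyNA(mat))
  n <- ncol(mat)
  if (n < n_pcs + 2L) {
    stop_format("design error: need at least n_pcs + 2 samples")
  }
  pca <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pca$x))
  scores <- pca$x[, seq_len(n_pcs), drop = FALSE]
  d2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    others <- scores[-i, , drop = FALSE]
    S <- stats::cov(others)
    if (!all(is.finite(S)) || rcond(S) < 1e-12) {
      warning("singular covariance in PC space: no outliers flagged")
      out <- character(0)
      attr(out, "d2") <- rep(NA_real_, n)
      return(out)
    }
    d2[i] <- stats::mahalanobis(scores[i, , drop = FALSE], colMeans(others), S)
  }
  flagged <- colnames(mat)[d2 > stats::qchisq(1 - alpha, df = n_pcs)]
  attr(flagged, "d2") <- stats::setNames(d2, colnames(mat))
  flagged
}
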