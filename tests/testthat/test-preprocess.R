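# Normalization, missingness filtering, imputation, surrogate-variable
# correction and outlier screening.

test_that("quantile normalization matches the sort/row-mean definition", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(1.5, 3.5, 5.5))
  expect_equal(unname(out[, 2]), c(1.5, 3.5, 5.5))

  # already-identical columns are a fixed point
  m2 <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(quantile_normalize(m2), m2)

  # missing entries stay missing; observed entries match the masking oracle
  set.seed(42)
  m3 <- matrix(rnorm(60, 20), 12, 5)
  m3[cbind(c(2, 5, 9), c(1, 3, 4))] <- NA
  out3 <- quantile_normalize(m3)
  expect_true(all(is.na(out3[cbind(c(2, 5, 9), c(1, 3, 4))])))
  expect_equal(out3, oracle_quantile_normalize(m3), tolerance = 1e-12)

  expect_warning(quantile_normalize(matrix(1:3, 3, 1)), "single-sample")
})

test_that("quantile normalization preserves ranks and equalizes column means", {
  set.seed(7)
  m <- matrix(rnorm(400, 20, 2), 80, 5)
  out <- quantile_normalize(m)
  for (j in 1:5) expect_equal(order(out[, j]), order(m[, j]))
  expect_equal(diff(range(colMeans(out))), 0, tolerance = 1e-10)
})

test_that("group missingness filter enforces the 25% allowance", {
  design <- two_group_design(4L, 4L)
  m <- matrix(1, 3, 8)
  m[2, 1] <- NA            # 1 of 4 mock missing (25%): kept
  m[3, 1:2] <- NA          # 2 of 4 mock missing (50%): dropped
  rownames(m) <- c("full", "quarter", "half")
  out <- filter_missingness(m, design)
  expect_equal(rownames(out), c("full", "quarter"))
})

test_that("kNN imputation averages nearest neighbours and is conservative", {
  # complete data: identity
  m <- matrix(rnorm(50), 10, 5)
  expect_identical(knn_impute(m), m)

  # a feature identical to 10 complete features except one missing entry
  # whose neighbours all hold 5.0 there
  base <- rep(1, 5)
  m2 <- rbind(matrix(rep(base, 10), 10, byrow = TRUE), base)
  m2[, 3] <- 5
  m2[11, 3] <- NA
  out <- knn_impute(m2, k = 10)
  expect_equal(unname(out[11, 3]), 5.0)
  expect_identical(out[-11, ], m2[-11, ])

  # mask-and-recover on smooth synthetic data: median absolute error < 0.5
  set.seed(5)
  sig <- matrix(rnorm(30 * 8, 20, 2), 30, 8)
  smooth <- sig[rep(1:30, each = 12), ] + matrix(rnorm(360 * 8, 0, 0.2), 360, 8)
  holes <- cbind(sample(360, 80), sample(8, 80, replace = TRUE))
  masked <- smooth
  masked[holes] <- NA
  rec <- knn_impute(masked, k = 10)
  expect_lt(median(abs(rec[holes] - smooth[holes])), 0.5)
  expect_false(anyNA(rec))
})

test_that("surrogate variables capture planted orthogonal batch structure", {
  design <- two_group_design(6L, 6L)
  set.seed(11)
  n <- 1500
  group_eff <- c(rep(0, 6), rep(1, 6))
  batch <- rep(c(-1, 1), 6)             # orthogonal to group
  loading <- ifelse(runif(n) < 0.4, rnorm(n, 0, 0.8), 0)
  m <- matrix(rnorm(n * 12, 20, 0.5), n, 12) +
    outer(ifelse(runif(n) < 0.3, 1, 0), group_eff) +
    outer(loading, batch)
  sv <- remove_unwanted_variation(m, design, seed = 1)
  expect_gte(sv$n_sv, 1L)
  expect_gt(abs(cor(sv$sv[, 1], batch)), 0.9)
  # the surrogate must not absorb the protected group factor
  expect_lt(abs(cor(sv$sv[, 1], group_eff)), 0.3)

  # zero residual structure: no surrogates, matrix unchanged
  flat <- outer(rep(1, 50), group_eff) + 20
  out <- remove_unwanted_variation(flat, design)
  expect_equal(out$n_sv, 0L)
  expect_equal(out$corrected, flat)
})

test_that("surrogate adjustment lowers the FPR of batch-loaded null features", {
  dsg <- subset(default_design(), plex == "4h")
  ct <- pm_contrast()
  one <- function(s, n = 2000) {
    set.seed(s)
    # batch partially aligned with treatment: 3 of 4 pilocarpine samples
    batch <- ifelse(dsg$sample %in% c("P_4h_1", "P_4h_2", "P_4h_3",
                                      "M_4h_1", "U_4h_1"), 1, -1)
    hit <- runif(n) < 0.4
    loading <- ifelse(hit, rnorm(n, 0, 1.2), 0)
    m <- matrix(rnorm(n * 11, 20, 0.5), n, 11) + outer(loading, batch)
    rownames(m) <- paste0("F", 1:n)
    raw <- fit_moderated_test(m, dsg, ct)
    sv <- remove_unwanted_variation(m, dsg, seed = s)
    adj <- fit_moderated_test(m, dsg, ct, covariates = sv$sv)
    c(raw = mean(raw$p[hit] < 0.05), adj = mean(adj$p[hit] < 0.05))
  }
  runs <- vapply(1:5, one, numeric(2))
  expect_gt(mean(runs["raw", ]), mean(runs["adj", ]))
})

test_that("surrogate removal leaves planted effects unbiased", {
  design <- two_group_design(4L, 4L)
  ct <- pm_contrast()
  set.seed(21)
  n <- 2000
  planted <- 1:300
  lfc <- numeric(n); lfc[planted] <- 1
  batch <- rep(c(-1, 1), 4)                      # orthogonal to group
  loading <- ifelse(runif(n) < 0.4, rnorm(n, 0, 0.7), 0)
  m <- matrix(rnorm(n * 8, 20, 0.5), n, 8) +
    outer(lfc, c(rep(0, 4), rep(1, 4))) + outer(loading, batch)
  rownames(m) <- paste0("F", 1:n)
  corr <- remove_unwanted_variation(m, design, seed = 2)
  cor_res <- fit_moderated_test(corr$corrected, design, ct)
  plain_res <- fit_moderated_test(m, design, ct)
  # planted log2FC recovered within 10% (median over planted features),
  # with and without the planted orthogonal batch removed
  expect_lt(abs(median(cor_res$log2FC[planted]) - 1), 0.1)
  expect_lt(abs(median(plain_res$log2FC[planted]) - 1), 0.1)
})

test_that("Mahalanobis screening flags displaced samples and only those", {
  set.seed(31)
  m <- matrix(rnorm(500 * 11, 20, 0.5), 500, 11)
  colnames(m) <- sprintf("s%02d", 1:11)
  # displace one sample far along the first principal axis
  m2 <- m
  m2[, 4] <- m2[, 4] + 10 * 0.5
  expect_equal(as.character(detect_outlier_samples(m2)), "s04")

  # null data: essentially no flags across seeded replicates
  flags <- vapply(1:10, function(s) {
    set.seed(100 + s)
    length(detect_outlier_samples(matrix(rnorm(500 * 11, 20, 0.5), 500, 11,
                                         dimnames = list(NULL, sprintf("s%02d", 1:11)))))
  }, integer(1))
  expect_true(mean(flags <= 1L) >= 0.95)

  # identical samples: singular covariance, warning, no flags
  flat <- matrix(5, 100, 6, dimnames = list(NULL, paste0("s", 1:6)))
  expect_warning(f <- detect_outlier_samples(flat), "singular")
  expect_length(f, 0L)

  # invariance to feature and sample order
  perm_f <- sample(nrow(m2)); perm_s <- sample(ncol(m2))
  expect_setequal(detect_outlier_samples(m2[perm_f, perm_s]), "s04")
})
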