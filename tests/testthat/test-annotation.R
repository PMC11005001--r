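# Regulatory-site matching, function trends, ranked gene lists, ordered
# enrichment and heatmap clustering.

test_that("regulatory matching uses the +/-4 core and keeps largest magnitude", {
  wins <- fixed_windows(3, seed = 20)
  feats <- data.frame(feature_id = c("f1", "f2", "f3"),
                      gene = c("GA", "GA", "GB"),
                      window = c(wins[1L], wins[1L], wins[2L]),
                      stringsAsFactors = FALSE)
  # db window differs from wins[1] at position +/-6 but not in the core
  db_win <- wins[1L]
  substr(db_win, 14, 14) <- "A"
  core_mismatch <- wins[2L]
  substr(core_mismatch, 6, 6) <- if (substr(wins[2L], 6, 6) == "A") "C" else "A"
  reg <- data.frame(gene = c("GA", "GB"), pos = 8L,
                    window = c(db_win, core_mismatch),
                    fun = "translation", direction = "induced",
                    stringsAsFactors = FALSE)
  d <- make_diff_results(c("f1", "f2", "f3"), log2FC = c(0.3, -1.2, 0.7),
                         p = 0.001)
  m <- match_regulatory_sites(feats, d, reg)
  # GA matched despite the +/-6 mismatch; two features collapse to the
  # largest-magnitude value; GB core mismatch not matched
  expect_equal(nrow(m), 1L)
  expect_equal(m$gene, "GA")
  expect_equal(m$log2FC, -1.2)
  expect_false("GB" %in% m$gene)
})

test_that("function trends report medians and perturbed fractions", {
  ann <- data.frame(
    gene = paste0("G", 1:8), core = "x", fun = "translation",
    direction = "induced", feature_id = paste0("f", 1:8),
    log2FC = c(0.2, 0.8, 1.0, 0.1, -0.1, 0.3, 0.5, 0.4),
    significant = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  tr <- function_trends(ann)
  expect_equal(tr$median_log2FC, 0.8)
  expect_equal(tr$n_detected, 8L)

  # 2 perturbed of 5 detected -> 40%; no significant -> 0% and no median
  ann2 <- data.frame(gene = paste0("H", 1:8), core = "x",
                     fun = rep(c("apoptosis", "cell growth"), c(5, 3)),
                     direction = "inhibited", feature_id = paste0("h", 1:8),
                     log2FC = 0.5,
                     significant = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                     FALSE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  tr2 <- function_trends(ann2)
  expect_equal(tr2$perturbed_pct[tr2$fun == "apoptosis"], 40)
  expect_equal(tr2$perturbed_pct[tr2$fun == "cell growth"], 0)
  expect_true(is.na(tr2$median_log2FC[tr2$fun == "cell growth"]))
})

test_that("planted induced shifts give positive medians in every seeded run", {
  for (s in 1:5) {
    set.seed(s)
    wins <- phosphoswing:::random_window(40)
    feats <- data.frame(feature_id = paste0("f", 1:40),
                        gene = paste0("G", 1:40), window = wins,
                        stringsAsFactors = FALSE)
    reg <- data.frame(gene = feats$gene, pos = 8L, window = wins,
                      fun = rep(c("translation", "apoptosis"), 20),
                      direction = "induced", stringsAsFactors = FALSE)
    lfc <- rnorm(40, 0, 0.3)
    lfc[reg$fun == "translation"] <- lfc[reg$fun == "translation"] + 1
    d <- make_diff_results(feats$feature_id, log2FC = lfc, p = 0.001)
    tr <- function_trends(match_regulatory_sites(feats, d, reg))
    expect_gt(tr$median_log2FC[tr$fun == "translation"], 0)
  }
})

test_that("combined ranking orders, ties and deduplication are deterministic", {
  d <- data.frame(
    feature_id = c("fA", "fB", "fC"), gene = c("A", "B", "C"),
    log2FC = c(0.5, 2.0, 1.0), adj_p = c(0.001, 0.01, 0.005),
    significant = TRUE, stringsAsFactors = FALSE)
  rl <- build_ranked_gene_list(d, "up", background = c("A", "B", "C", "D"))
  # rank_sig (1,3,2) + rank_mag (3,1,2) all tie at 4; rank_sig then breaks it
  expect_equal(rl$genes, c("A", "C", "B"))
  # input order must not matter
  rl2 <- build_ranked_gene_list(d[c(3, 1, 2), ], "up",
                                background = c("A", "B", "C", "D"))
  expect_equal(rl2$genes, rl$genes)

  expect_equal(build_ranked_gene_list(d[1L, ], "up", "A")$genes, "A")
  # same gene twice: best combined rank kept, one entry
  d2 <- rbind(d, data.frame(feature_id = "fA2", gene = "A", log2FC = 0.1,
                            adj_p = 0.04, significant = TRUE))
  rl3 <- build_ranked_gene_list(d2, "up", background = c("A", "B", "C"))
  expect_equal(sum(rl3$genes == "A"), 1L)
  expect_equal(length(rl3$genes), length(unique(d2$gene)))
  # direction gate and empty input
  expect_length(build_ranked_gene_list(transform(d, log2FC = -log2FC),
                                       "up", "A")$genes, 0L)
})

test_that("ordered enrichment equals the brute-force prefix scan", {
  set.seed(23)
  background <- sprintf("g%04d", 1:1000)
  genes <- sample(background, 100)
  term_sets <- list(
    top10 = genes[1:10],                       # exactly the top ten
    spread = sample(background, 50),
    none = sprintf("x%03d", 1:20))             # disjoint from background
  rl <- structure(list(genes = genes, direction = "up", contrast = NULL,
                       background = background), class = "ranked_gene_list")
  out <- ordered_enrichment(rl, term_sets)
  expect_false("none" %in% out$term)           # disjoint term skipped
  for (tm in out$term) {
    expect_equal(out$p[out$term == tm],
                 oracle_ordered_enrichment(genes, term_sets[[tm]], background),
                 tolerance = 1e-8)
  }
  top <- out[out$term == "top10", ]
  expect_equal(top$best_prefix, 10L)
  expect_equal(top$overlap, 10L)
  # the prefix minimum cannot exceed the whole-list tail probability
  whole <- oracle_hyper_tail(length(intersect(genes, term_sets$spread)),
                             50, 1000, 100)
  expect_lte(out$p[out$term == "spread"], whole + 1e-12)
  # term-size cap
  out_cap <- ordered_enrichment(rl, term_sets, max_term_size = 20)
  expect_false("spread" %in% out_cap$term)
})

test_that("enrichment p-values are near-uniform for shuffled term sets", {
  set.seed(24)
  background <- sprintf("g%04d", 1:400)
  genes <- sample(background, 60)
  rl <- structure(list(genes = genes, direction = "up", contrast = NULL,
                       background = background), class = "ranked_gene_list")
  shuffled <- lapply(1:200, function(i) sample(background, 25))
  names(shuffled) <- paste0("t", 1:200)
  out <- ordered_enrichment(rl, shuffled)
  # min-over-prefixes is anti-conservative by construction; compare to its
  # own null by a second, independent shuffle set
  out2 <- ordered_enrichment(rl, stats::setNames(
    lapply(1:200, function(i) sample(background, 25)), paste0("u", 1:200)))
  ks <- suppressWarnings(stats::ks.test(out$p, out2$p))$statistic
  expect_lt(unname(ks), 0.15)
})

test_that("complete-linkage clustering merges and heights are correct", {
  # identical rows merge first at height zero
  m <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  cl <- cluster_heatmap(m, cluster_cols = FALSE)
  expect_equal(cl$row_hclust$height[1L], 0)
  expect_equal(sort(cl$row_hclust$merge[1L, ]), c(-2L, -1L))
  # collinear points with d(a,b) = d(b,c) = 1, d(a,c) = 2: final height 2
  m2 <- cbind(c(0, 1, 2), c(0, 0, 0))
  cl2 <- cluster_heatmap(m2, cluster_cols = FALSE)
  expect_equal(max(cl2$row_hclust$height), 2)
  expect_equal(cl2$row_hclust$height[1L], 1)
  # permuting rows permutes leaves but preserves merge heights
  set.seed(25)
  m3 <- matrix(rnorm(40), 10, 4)
  h1 <- sort(cluster_heatmap(m3)$row_hclust$height)
  h2 <- sort(cluster_heatmap(m3[sample(10), ])$row_hclust$height)
  expect_equal(h1, h2)
  # degenerate single row: identity order
  expect_equal(cluster_heatmap(m3[1, , drop = FALSE])$row_order, 1L)
})
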