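# Regulatory-site function trends, ranked gene list construction with a
# detected-gene background, a minimal ordered hypergeometric enrichment and
# complete-linkage heatmap clustering.

#' Read a regulatory-site flat file
#'
#' Tab-separated columns `GENE`, `POS`, `SITE_7_AA`, `FUNCTION`, `DIRECTION`
#' (direction `induced` or `inhibited`), describing phosphosites with a
#' curated functional effect.
#'
#' @param path File path.
#' @return Data.frame with columns `gene`, `pos`, `window`, `fun`,
#'   `direction`, deduplicated on (gene, window core, function, direction).
#' @export
read_regulatory_db <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("GENE", "POS", "SITE_7_AA", "FUNCTION", "DIRECTION")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_format("format error: missing mandatory column(s): %s",
                paste(miss, collapse = ", "))
  }
  db <- data.frame(gene = tab$GENE, pos = as.integer(tab$POS),
                   window = tab$SITE_7_AA, fun = tab$FUNCTION,
                   direction = tab$DIRECTION, stringsAsFactors = FALSE)
  key <- paste(db$gene, window_core(db$window), db$fun, db$direction)
  db <- db[!duplicated(key), , drop = FALSE]
  rownames(db) <- NULL
  db
}

#' Match regulatory sites to detected phosphopeptide features
#'
#' Regulatory database entries are matched to features by identical gene
#' name and identical sequence within four residues either side of the
#' phosphorylation site (multi-phosphorylated features via their first
#' site's window). When several features match one (gene, window) database
#' entry for a function/direction, the quantitative value with the largest
#' magnitude is kept.
#'
#' @param features Data.frame with `feature_id`, `gene`, `window`.
#' @param diff_results Data.frame with `feature_id`, `log2FC`, `adj_p`,
#'   `significant`.
#' @param reg_db Regulatory-site data.frame (see [read_regulatory_db()]).
#' @return Data.frame of matched sites: gene, window core, function,
#'   direction, feature_id, log2FC, significant.
#' @export
match_regulatory_sites <- function(features, diff_results, reg_db) {
  reg_db$core <- window_core(reg_db$window)
  reg_db <- reg_db[!duplicated(reg_db[, c("gene", "core", "fun", "direction")]), ,
                   drop = FALSE]
  feat <- data.frame(feature_id = features$feature_id, gene = features$gene,
                     core = window_core(features$window),
                     stringsAsFactors = FALSE)
  d <- diff_results[match(feat$feature_id, diff_results$feature_id), ,
                    drop = FALSE]
  feat$log2FC <- d$log2FC
  sig <- d$significant
  if (!is.null(d$protein_excluded)) sig <- sig & !d$protein_excluded
  feat$significant <- sig
  m <- merge(reg_db[, c("gene", "core", "fun", "direction")], feat,
             by = c("gene", "core"))
  if (nrow(m) == 0L) return(m)
  # redundant matches: keep the largest-magnitude quantitative value
  key <- paste(m$gene, m$core, m$fun, m$direction)
  ord <- order(key, -abs(m$log2FC), m$feature_id)
  m <- m[ord, , drop = FALSE]
  m <- m[!duplicated(key[ord]), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Per-function phospho-regulation trends
#'
#' For each (function, direction) pair: the median significant log2 fold
#' change over matched regulatory sites, and the perturbed fraction --
#' significant matched sites as a percentage of all detected matched sites.
#'
#' @param annotated Matched site table from [match_regulatory_sites()].
#' @return Data.frame with `fun`, `direction`, `median_log2FC` (NA when no
#'   site is significant), `n_detected`, `n_perturbed`, `perturbed_pct`.
#'   Functions with zero detected sites are omitted by construction.
#' @export
function_trends <- function(annotated) {
  if (nrow(annotated) == 0L) {
    return(data.frame(fun = character(0), direction = character(0),
                      median_log2FC = numeric(0), n_detected = integer(0),
                      n_perturbed = integer(0), perturbed_pct = numeric(0),
                      stringsAsFactors = FALSE))
  }
  spl <- split(annotated, paste(annotated$fun, annotated$direction, sep = "\r"))
  rows <- lapply(spl, function(a) {
    sig <- a$significant %in% TRUE
    data.frame(fun = a$fun[1L], direction = a$direction[1L],
               median_log2FC = if (any(sig)) stats::median(a$log2FC[sig]) else NA_real_,
               n_detected = nrow(a),
               n_perturbed = sum(sig),
               perturbed_pct = 100 * sum(sig) / nrow(a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$fun, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a ranked gene list for ordered enrichment
#'
#' Significant features of one direction are ranked from most to least
#' significant (ascending adjusted p) and from largest to smallest magnitude
#' (descending |log2FC|); the two rank values are summed into a combined
#' rank. Ties on the combined rank are broken by the significance rank and
#' then by gene symbol, making the order deterministic and independent of
#' input order. Redundant gene names are discarded keeping the highest
#' ranked entry per gene.
#'
#' @param diff_results Data.frame with `gene`, `log2FC`, `adj_p`,
#'   `significant` (and optionally `protein_excluded`).
#' @param direction `"up"` (log2FC > 0) or `"down"` (log2FC < 0).
#' @param background Character vector of background genes (the genes
#'   detected in both the proteome and the phosphoproteome); extended to
#'   cover the list if needed.
#' @param contrast Optional contrast label carried through.
#' @return A `ranked_gene_list` object: list with `genes` (ordered),
#'   `direction`, `contrast`, `background`.
#' @export
build_ranked_gene_list <- function(diff_results, direction = c("up", "down"),
                                   background, contrast = NULL) {
  direction <- match.arg(direction)
  res <- diff_results[diff_results$significant %in% TRUE, , drop = FALSE]
  if (!is.null(res$protein_excluded)) {
    res <- res[!res$protein_excluded, , drop = FALSE]
  }
  res <- if (direction == "up") res[res$log2FC > 0, , drop = FALSE]
         else res[res$log2FC < 0, , drop = FALSE]
  if (nrow(res) == 0L) {
    return(structure(list(genes = character(0), direction = direction,
                          contrast = contrast, background = unique(background)),
                     class = "ranked_gene_list"))
  }
  rank_sig <- rank(res$adj_p, ties.method = "min")
  rank_mag <- rank(-abs(res$log2FC), ties.method = "min")
  combined <- rank_sig + rank_mag
  ord <- order(combined, rank_sig, res$gene)
  genes <- res$gene[ord]
  genes <- genes[!duplicated(genes)]
  background <- unique(c(background, genes))
  structure(list(genes = genes, direction = direction, contrast = contrast,
                 background = background),
            class = "ranked_gene_list")
}

#' @export
print.ranked_gene_list <- function(x, ...) {
  cat(sprintf("ranked_gene_list (%s%s): %d genes over background of %d\n",
              x$direction,
              if (is.null(x$contrast)) "" else paste0(", ", x$contrast),
              length(x$genes), length(x$background)))
  invisible(x)
}

#' Ordered hypergeometric enrichment over list prefixes
#'
#' A minimal ordered-query enrichment: for each term, the hypergeometric
#' upper-tail probability of the term/prefix overlap is evaluated at every
#' prefix of the ranked list and the minimum is reported, weighting
#' enrichment toward highly ranked genes. P-values are Benjamini-Hochberg
#' adjusted across terms. This evaluates all prefixes rather than the
#' iterative truncation of external ordered-query services, and is an
#' approximation of those.
#'
#' @param ranked_list A `ranked_gene_list` object.
#' @param term_gene_sets Named list of character vectors (term -> genes).
#' @param background Optional background override (defaults to the list's).
#' @param max_term_size Optional cap: terms with more (background-
#'   intersected) genes are skipped.
#' @return Data.frame with `term`, `term_size`, `best_prefix`,
#'   `overlap`, `p`, `adj_p`, ordered by p.
#' @export
ordered_enrichment <- function(ranked_list, term_gene_sets, background = NULL,
                               max_term_size = NULL) {
  stopifnot(inherits(ranked_list, "ranked_gene_list"))
  background <- unique(background %||% ranked_list$background)
  genes <- ranked_list$genes
  N <- length(background)
  L <- length(genes)
  rows <- lapply(names(term_gene_sets), function(tm) {
    term <- intersect(unique(term_gene_sets[[tm]]), background)
    m <- length(term)
    if (m == 0L) return(NULL)
    if (!is.null(max_term_size) && m > max_term_size) return(NULL)
    if (L == 0L) {
      return(data.frame(term = tm, term_size = m, best_prefix = 0L,
                        overlap = 0L, p = 1, stringsAsFactors = FALSE))
    }
    k_cum <- cumsum(genes %in% term)
    n_pref <- seq_len(L)
    p_pref <- stats::phyper(k_cum - 1L, m, N - m, n_pref, lower.tail = FALSE)
    best <- which.min(p_pref)
    data.frame(term = tm, term_size = m, best_prefix = best,
               overlap = k_cum[best], p = p_pref[best],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term = character(0), term_size = integer(0),
                      best_prefix = integer(0), overlap = integer(0),
                      p = numeric(0), adj_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- adjust_bh(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (term, description, genes... per tab-separated line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, character(1), 1L))
}

#' Hierarchical clustering orders for a heatmap
#'
#' Agglomerative complete-linkage clustering on Euclidean distance for both
#' rows and columns; deterministic given input order.
#'
#' @param mat Complete numeric matrix.
#' @param cluster_cols Also cluster columns (default TRUE).
#' @return List with `row_order`, `col_order` (integer permutations),
#'   `row_hclust`, `col_hclust` (NULL when fewer than 2 items).
#' @export
cluster_heatmap <- function(mat, cluster_cols = TRUE) {
  mat <- as.matrix(mat)
  stopifnot(!anyNA(mat))
  cluster_one <- function(m) {
    if (nrow(m) < 2L) {
      return(list(order = seq_len(nrow(m)), hclust = NULL))
    }
    hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "complete")
    list(order = hc$order, hclust = hc)
  }
  rows <- cluster_one(mat)
  cols <- if (cluster_cols) cluster_one(t(mat)) else
    list(order = seq_len(ncol(mat)), hclust = NULL)
  list(row_order = rows$order, col_order = cols$order,
       row_hclust = rows$hclust, col_hclust = cols$hclust)
}
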