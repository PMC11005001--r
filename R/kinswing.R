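# Kinase activity inference from the differential phosphoproteome: position
# weight matrix substrate models, empirical background match p-values, a
# kinase-substrate network, the signed weighted swing statistic with
# z-transform and label-permutation significance, and validation against
# known-substrate fold changes.

#' Build a kinase position weight matrix from substrate windows
#'
#' Per-position amino-acid frequencies over the 15-residue substrate windows
#' of one kinase, with a pseudocount:
#' freq = (count + pseudocount) / (n + 20 * pseudocount), where n is the
#' number of non-padding residues observed at that position (equal to the
#' number of windows away from protein termini, so every column sums to 1).
#' Padding characters (`_`) contribute to no amino-acid count.
#'
#' @param windows Character vector of 15-mer substrate windows centered on
#'   the phospho-acceptor.
#' @param pseudocount Additive pseudocount (default 0.01).
#' @param kinase Kinase gene symbol.
#' @param residue_class `"ST"` or `"Y"`; inferred from the window centers
#'   when NULL.
#' @param background Named amino-acid background probabilities (default
#'   uniform 1/20).
#' @return A `kinase_pwm` object (list with `kinase`, `residue_class`,
#'   `freq` 20 x 15 matrix, `background`, `n_seqs`).
#' @export
build_pwm <- function(windows, pseudocount = 0.01, kinase = NA_character_,
                      residue_class = NULL, background = NULL) {
  if (length(windows) == 0L) {
    warning(sprintf("kinase %s has no substrate windows: skipped", kinase))
    return(NULL)
  }
  if (any(nchar(windows) != WINDOW_WIDTH)) {
    stop_format("format error: substrate window length != %d", WINDOW_WIDTH)
  }
  centers <- unique(center_residue(windows))
  if (is.null(residue_class)) {
    residue_class <- if (all(centers %in% c("S", "T"))) "ST"
      else if (all(centers == "Y")) "Y"
      else stop_format("mixed S/T and Y centers: partition windows by residue class")
  }
  chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                  byrow = TRUE)
  counts <- apply(chars, 2L, function(col)
    table(factor(col, levels = AA20)))
  counts <- matrix(as.numeric(counts), nrow = 20L,
                   dimnames = list(AA20, NULL))
  n_obs <- colSums(counts)  # non-padding residues per position
  freq <- sweep(counts + pseudocount, 2L, n_obs + 20 * pseudocount, "/")
  background <- background %||% stats::setNames(rep(1 / 20, 20), AA20)
  structure(list(kinase = kinase, residue_class = residue_class, freq = freq,
                 background = background[AA20],
                 n_seqs = length(windows), pseudocount = pseudocount),
            class = "kinase_pwm")
}

#' @export
print.kinase_pwm <- function(x, ...) {
  cat(sprintf("kinase_pwm: %s (%s), n_seqs = %d\n",
              x$kinase, x$residue_class, x$n_seqs))
  invisible(x)
}

#' Score sequence windows against a kinase PWM
#'
#' Log2 likelihood ratio of the window under the PWM versus the amino-acid
#' background, summed over the 15 positions; `_` padding positions
#' contribute zero. Windows whose center residue is incompatible with the
#' PWM's residue class (S/T versus Y) receive NA.
#'
#' @param pwm A `kinase_pwm` object.
#' @param windows Character vector of 15-mers.
#' @return Numeric vector of scores (NA where incompatible).
#' @export
score_windows <- function(pwm, windows) {
  stopifnot(inherits(pwm, "kinase_pwm"))
  if (length(windows) == 0L) return(numeric(0))
  if (any(nchar(windows) != WINDOW_WIDTH)) {
    stop_format("format error: window length != %d", WINDOW_WIDTH)
  }
  L <- log2(sweep(pwm$freq, 1L, pwm$background, "/"))
  chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                  byrow = TRUE)
  idx <- matrix(match(chars, AA20), nrow = nrow(chars))
  contrib <- matrix(0, nrow = nrow(chars), ncol = WINDOW_WIDTH)
  obs <- !is.na(idx)
  pos <- col(idx)
  contrib[obs] <- L[cbind(idx[obs], pos[obs])]
  scores <- rowSums(contrib)
  class_chars <- if (pwm$residue_class == "ST") c("S", "T") else "Y"
  scores[!(center_residue(windows) %in% class_chars)] <- NA_real_
  scores
}

#' @rdname score_windows
#' @param window A single 15-mer.
#' @export
score_window <- function(pwm, window) score_windows(pwm, window)

#' Empirical match p-value of a window against a PWM
#'
#' The observed PWM score is calibrated against scores of windows sampled
#' from the detected phosphopeptide windows of the matching residue class;
#' p = (1 + #\{background >= observed\}) / (n_draws + 1).
#'
#' @param pwm A `kinase_pwm` object.
#' @param window A 15-mer to score.
#' @param background_windows Pool of detected windows to sample from.
#' @param n_draws Background sample size (default 1000); pools smaller than
#'   `n_draws` are sampled with replacement.
#' @param seed Optional integer seed.
#' @return Empirical p-value in (0, 1].
#' @export
match_pvalue <- function(pwm, window, background_windows, n_draws = 1000L,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- score_windows(pwm, window)
  if (is.na(obs)) return(NA_real_)
  bg <- sample_background_scores(pwm, background_windows, n_draws)
  (1 + sum(bg >= obs)) / (n_draws + 1)
}

sample_background_scores <- function(pwm, background_windows, n_draws) {
  class_chars <- if (pwm$residue_class == "ST") c("S", "T") else "Y"
  pool <- background_windows[center_residue(background_windows) %in% class_chars]
  if (length(pool) == 0L) {
    stop_format("no background windows of residue class %s", pwm$residue_class)
  }
  drawn <- sample(pool, n_draws, replace = length(pool) < n_draws)
  score_windows(pwm, drawn)
}

#' Build the kinase-substrate edge network
#'
#' Every detected phosphopeptide (represented by the sequence window of its
#' first phosphorylation site) is scored against every residue-class
#' compatible PWM; an edge is created where the empirical match p-value is
#' at or below the threshold.
#'
#' @param pwms List of `kinase_pwm` objects.
#' @param features Data.frame with `feature_id` and `window` (first-site
#'   15-mer) columns.
#' @param edge_p_threshold Match p-value threshold for an edge (default
#'   0.05).
#' @param n_draws Background draws per kinase (default 1000).
#' @param seed Optional integer seed (one RNG stream across kinases, so the
#'   whole network is reproducible).
#' @param background_windows Pool for match calibration; defaults to the
#'   feature windows themselves.
#' @return Data.frame of edges: `kinase`, `feature_id`, `match_score`,
#'   `match_p`.
#' @export
build_network <- function(pwms, features, edge_p_threshold = 0.05,
                          n_draws = 1000L, seed = NULL,
                          background_windows = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pwms <- Filter(Negate(is.null), pwms)
  background_windows <- background_windows %||% features$window
  edges <- vector("list", length(pwms))
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    scores <- score_windows(pwm, features$window)
    ok <- which(!is.na(scores))
    if (length(ok) == 0L) next
    bg <- sort(sample_background_scores(pwm, background_windows, n_draws))
    # #{bg >= s} via position of s in the sorted background
    n_ge <- n_draws - findInterval(scores[ok], bg, left.open = TRUE)
    p <- (1 + n_ge) / (n_draws + 1)
    hit <- p <= edge_p_threshold
    if (!any(hit)) next
    edges[[k]] <- data.frame(kinase = pwm$kinase,
                             feature_id = features$feature_id[ok][hit],
                             match_score = scores[ok][hit],
                             match_p = p[hit],
                             stringsAsFactors = FALSE)
  }
  edges <- edges[!vapply(edges, is.null, logical(1))]
  if (length(edges) == 0L) {
    return(data.frame(kinase = character(0), feature_id = character(0),
                      match_score = numeric(0), match_p = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Kinase swing statistic with permutation significance
#'
#' For each kinase, the proportions of network substrates with significant
#' positive and negative fold changes (raw p at or below `fc_p_threshold`)
#' are differenced and weighted by the logarithms of the edge count and of
#' the number of substrate sequences behind the PWM:
#' swing = (p+ - p-) * ln(n_edges + 1) * ln(n_seqs + 1).
#' Swing scores are z-transformed across kinases. Significance comes from a
#' degree-preserving permutation null: substrate nodes are reassigned to
#' kinase nodes at random (each kinase keeps its edge count, substrates
#' drawn without replacement from the network's substrate pool) and each
#' tail probability is (1 + #\{permuted >= observed\}) / (n_perm + 1).
#'
#' @param edges Edge data.frame from [build_network()].
#' @param diff_results Data.frame with `feature_id`, `log2FC`, `p` (raw p).
#' @param pwms List of `kinase_pwm` objects (provides `n_seqs`).
#' @param fc_p_threshold Raw-p threshold for a substrate to count (default
#'   0.05).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @return Data.frame with kinase, n_edges, n_pos, n_neg, p_pos_frac,
#'   p_neg_frac, swing_raw, z, perm_p_pos, perm_p_neg, n_perm, n_seqs.
#' @export
compute_swing <- function(edges, diff_results, pwms, fc_p_threshold = 0.05,
                          n_perm = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pwms <- Filter(Negate(is.null), pwms)
  n_seqs_map <- stats::setNames(
    vapply(pwms, function(p) p$n_seqs, numeric(1)),
    vapply(pwms, function(p) paste0(p$kinase, "|", p$residue_class), character(1)))
  # kinases may be modeled once per residue class; edges carry the kinase name
  kin_nseq <- stats::setNames(
    vapply(pwms, function(p) p$n_seqs, numeric(1)),
    vapply(pwms, function(p) p$kinase, character(1)))

  stats_map <- diff_results[match(unique(edges$feature_id),
                                  diff_results$feature_id), , drop = FALSE]
  if (anyNA(stats_map$feature_id)) {
    stop_format("diff_results does not cover all substrate features")
  }
  pool_ids <- stats_map$feature_id
  pos_flag <- stats_map$log2FC > 0 & stats_map$p <= fc_p_threshold
  neg_flag <- stats_map$log2FC < 0 & stats_map$p <= fc_p_threshold
  n_pool <- length(pool_ids)

  kin <- unique(edges$kinase)
  sub_idx <- lapply(kin, function(k)
    match(edges$feature_id[edges$kinase == k], pool_ids))
  n_edges <- lengths(sub_idx)
  keep <- n_edges > 0L
  kin <- kin[keep]; sub_idx <- sub_idx[keep]; n_edges <- n_edges[keep]
  if (length(kin) < 2L) {
    stop_format("swing z-scores need at least two kinases with edges")
  }
  n_pos <- vapply(sub_idx, function(i) sum(pos_flag[i]), integer(1))
  n_neg <- vapply(sub_idx, function(i) sum(neg_flag[i]), integer(1))
  w <- log(n_edges + 1) * log(kin_nseq[kin] + 1)
  swing_raw <- (n_pos / n_edges - n_neg / n_edges) * w
  sd_sw <- stats::sd(swing_raw)
  if (!is.finite(sd_sw) || sd_sw == 0) {
    stop_format("swing standard deviation over kinases is zero: z undefined")
  }
  z <- (swing_raw - mean(swing_raw)) / sd_sw

  ge <- integer(length(kin))
  le <- integer(length(kin))
  for (b in seq_len(n_perm)) {
    for (k in seq_along(kin)) {
      s <- sample.int(n_pool, n_edges[k])
      perm <- (sum(pos_flag[s]) - sum(neg_flag[s])) / n_edges[k] * w[k]
      if (perm >= swing_raw[k]) ge[k] <- ge[k] + 1L
      if (perm <= swing_raw[k]) le[k] <- le[k] + 1L
    }
  }
  data.frame(
    kinase = kin,
    n_edges = n_edges,
    n_pos = n_pos,
    n_neg = n_neg,
    p_pos_frac = n_pos / n_edges,
    p_neg_frac = n_neg / n_edges,
    swing_raw = unname(swing_raw),
    z = unname(z),
    perm_p_pos = (1 + ge) / (n_perm + 1),
    perm_p_neg = (1 + le) / (n_perm + 1),
    n_perm = n_perm,
    n_seqs = unname(kin_nseq[kin]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Read a kinase-substrate flat file
#'
#' Tab-separated columns `KINASE`, `SUB_GENE`, `SUB_POS`, `SITE_7_AA`
#' (kinase gene, substrate gene, 1-based site position, +/-7 sequence
#' window) in the style of curated kinase-substrate resources.
#'
#' @param path File path.
#' @return Data.frame with lower-case column names `kinase`, `sub_gene`,
#'   `sub_pos`, `window`.
#' @export
read_kinase_substrate_db <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("KINASE", "SUB_GENE", "SUB_POS", "SITE_7_AA")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_format("format error: missing mandatory column(s): %s",
                paste(miss, collapse = ", "))
  }
  data.frame(kinase = tab$KINASE, sub_gene = tab$SUB_GENE,
             sub_pos = as.integer(tab$SUB_POS), window = tab$SITE_7_AA,
             stringsAsFactors = FALSE)
}

#' Average significant fold change of a kinase's known substrates
#'
#' Known kinase-substrate pairs are matched to detected features by
#' identical gene name and identical sequence within four residues either
#' side of the phosphorylation site (the +/-4 window core); duplicate
#' (gene, window-core) combinations in the database are counted once.
#' Multi-phosphorylated features are matched via their first site's window.
#' A kinase is reported only when at least `min_substrates` matched
#' substrates are significant; its value is the mean of their significant
#' log2 fold changes.
#'
#' @param diff_results Data.frame with `feature_id`, `log2FC`, `adj_p`.
#' @param features Data.frame with `feature_id`, `gene`, `window`
#'   (first-site window).
#' @param ks_db Kinase-substrate data.frame (see
#'   [read_kinase_substrate_db()]).
#' @param min_substrates Minimum significant matched substrates (default 4).
#' @param sig_level Adjusted-p threshold for significance (default 0.05).
#' @return Data.frame with `kinase`, `mean_log2FC`, `n_substrates`.
#' @export
known_substrate_average <- function(diff_results, features, ks_db,
                                    min_substrates = 4L, sig_level = 0.05) {
  ks_db$core <- window_core(ks_db$window)
  ks_db <- ks_db[!duplicated(ks_db[, c("kinase", "sub_gene", "core")]), ,
                 drop = FALSE]
  feat_key <- paste(features$gene, window_core(features$window))
  db_key <- paste(ks_db$sub_gene, ks_db$core)
  hit <- match(db_key, feat_key)
  matched <- data.frame(kinase = ks_db$kinase[!is.na(hit)],
                        feature_id = features$feature_id[hit[!is.na(hit)]],
                        stringsAsFactors = FALSE)
  matched <- matched[!duplicated(matched), , drop = FALSE]
  d <- diff_results[match(matched$feature_id, diff_results$feature_id), ,
                    drop = FALSE]
  sig <- !is.na(d$adj_p) & d$adj_p < sig_level
  out <- lapply(split(d$log2FC[sig], matched$kinase[sig]), function(v) v)
  out <- out[lengths(out) >= min_substrates]
  data.frame(
    kinase = names(out),
    mean_log2FC = vapply(out, mean, numeric(1)),
    n_substrates = lengths(out),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
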