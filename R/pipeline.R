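# End-to-end orchestration: ingest -> preprocess -> differential testing ->
# kinase activity inference -> regulatory-site trends and ranked lists, with
# a run manifest recording seeds, thresholds and removed samples.

#' Default pipeline parameters
#'
#' @return Named list of tunable thresholds: `missing.max_group_frac`
#'   (per-group missing allowance, 0.25), `impute.k` (kNN neighbours, 10),
#'   `sva.mode` (`"regress"` removes surrogates before testing,
#'   `"covariate"` includes them in the per-feature model),
#'   `outlier.alpha`/`outlier.n_pcs` (Mahalanobis screening, 1e-4 on 2 PCs),
#'   `sig_level` (adjusted-p significance, 0.05), `edge_p` (PWM match
#'   threshold, 0.05), `fc_p` (raw-p threshold for swing substrates, 0.05),
#'   `n_draws`/`n_perm` (background draws and permutations, 1000),
#'   `min_substrates` (known-substrate validation, 4) and `pseudocount`
#'   (PWM, 0.01).
#' @export
pipeline_params <- function() {
  list(missing.max_group_frac = 0.25, impute.k = 10L,
       sva.mode = "regress", outlier.alpha = 1e-4, outlier.n_pcs = 2L,
       sig_level = 0.05, edge_p = 0.05, fc_p = 0.05,
       n_draws = 1000L, n_perm = 1000L, min_substrates = 4L,
       pseudocount = 0.01)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_format("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

# normalize -> impute -> surrogate correction -> outlier screen for one plex;
# outlier removal triggers exactly one re-run without the flagged samples
preprocess_plex <- function(log2_mat, design_p, params, seed,
                            screen_outliers = TRUE) {
  removed <- character(0)
  run_once <- function(mat, dsg) {
    m <- filter_missingness(mat, dsg,
                            max_group_frac = params$missing.max_group_frac)
    m <- quantile_normalize(m)
    m <- knn_impute(m, k = params$impute.k)
    sv <- remove_unwanted_variation(m, dsg, seed = seed)
    list(normalized = m, corrected = sv$corrected, sv = sv$sv, n_sv = sv$n_sv,
         design = dsg)
  }
  res <- run_once(log2_mat, design_p)
  if (screen_outliers && ncol(res$corrected) >= params$outlier.n_pcs + 2L) {
    flagged <- detect_outlier_samples(res$corrected,
                                      n_pcs = params$outlier.n_pcs,
                                      alpha = params$outlier.alpha)
    if (length(flagged)) {
      removed <- flagged
      keep <- !(design_p$sample %in% flagged)
      res <- run_once(log2_mat[, keep, drop = FALSE],
                      design_p[keep, , drop = FALSE])
    }
  }
  res$removed_samples <- removed
  res
}

first_window <- function(features_info) {
  vapply(split_semi(features_info$windows), `[`, character(1), 1L)
}

#' Run the full analysis pipeline
#'
#' Executes ingest (parse, window re-annotation, localization filtering,
#' duplicate collapsing), per-plex preprocessing (group-missingness filter,
#' quantile normalization, kNN imputation, surrogate-variable correction,
#' one round of Mahalanobis outlier removal), moderated differential testing
#' for every contrast with BH adjustment and protein-level exclusion, PWM
#' based kinase activity inference with permutation significance and
#' known-substrate validation, regulatory-site trend scoring, and ranked
#' gene list construction, then writes result tables, a set-summary JSON and
#' a run manifest.
#'
#' @param x Either the list returned by [generate_experiment()] or a named
#'   list of file paths (`phospho`, `protein`, `fasta`, `design`, and
#'   optionally `ks_db`, `reg_db`).
#' @param out_dir Optional output directory; when NULL nothing is written.
#' @param params Pipeline parameters (see [pipeline_params()]).
#' @param seed Integer seed controlling the stochastic components
#'   (surrogate-count permutations, PWM background draws, swing
#'   permutations).
#' @return Invisibly, a list with `features`, per-plex preprocessing
#'   results, `phospho_results`, `protein_results`, `kinswing`,
#'   `known_substrates`, `regulatory_trends`, `ranked_lists`,
#'   `set_summary` and `manifest`.
#' @export
run_pipeline <- function(x, out_dir = NULL, params = pipeline_params(),
                         seed = 1L) {
  seed <- as.integer(seed)
  defaults <- pipeline_params()
  params <- utils::modifyList(defaults, params[intersect(names(params),
                                                         names(defaults))])

  ## ingest -----------------------------------------------------------------
  ing <- with_stage("ingest", {
    design <- if (is.character(x$design)) read_design(x$design) else x$design
    validate_design(design)
    fasta <- if (is.character(x$fasta) && length(x$fasta) == 1L &&
                 file.exists(x$fasta)) read_protein_fasta(x$fasta) else x$fasta
    records <- parse_phospho_table(x$phospho, design)
    records <- remap_windows(records, fasta)
    records <- filter_multiphospho(records)
    features <- collapse_duplicates(records)
    proteins <- if (!is.null(x$protein)) parse_protein_table(x$protein, design)
                else NULL
    list(design = design, features = features, proteins = proteins)
  })
  design <- ing$design
  features <- ing$features

  ## preprocess (per plex) --------------------------------------------------
  plexes <- unique(design$plex)
  prep <- with_stage("preprocess", {
    out <- list()
    for (px in plexes) {
      cols <- design$plex == px
      out[[px]] <- preprocess_plex(features$log2[, cols, drop = FALSE],
                                   design[cols, , drop = FALSE], params, seed)
    }
    out
  })
  prep_prot <- if (!is.null(ing$proteins)) with_stage("preprocess", {
    out <- list()
    for (px in plexes) {
      cols <- ing$proteins$design$plex == px
      out[[px]] <- preprocess_plex(
        ing$proteins$log2[, cols, drop = FALSE],
        ing$proteins$design[cols, , drop = FALSE], params, seed,
        screen_outliers = FALSE)
    }
    out
  }) else NULL

  analysis_matrix <- function(p) {
    if (params$sva.mode == "covariate") p$normalized else p$corrected
  }
  analysis_cov <- function(p) {
    if (params$sva.mode == "covariate") p$sv else NULL
  }

  ## differential -----------------------------------------------------------
  contrasts <- pipeline_contrasts(design)
  diff <- with_stage("differential", {
    phospho_res <- list()
    protein_res <- list()
    for (ct in contrasts) {
      p <- prep[[ct$plex]]
      r <- fit_moderated_test(analysis_matrix(p), p$design, ct,
                              covariates = analysis_cov(p),
                              sig_level = params$sig_level)
      r$gene <- features$info$gene[match(r$feature_id,
                                         features$info$feature_id)]
      r$sites <- features$info$positions[match(r$feature_id,
                                               features$info$feature_id)]
      phospho_res[[ct$label]] <- r
      if (!is.null(prep_prot)) {
        pp <- prep_prot[[ct$plex]]
        pr <- fit_moderated_test(analysis_matrix(pp), pp$design, ct,
                                 covariates = analysis_cov(pp),
                                 sig_level = params$sig_level)
        pr$gene <- pr$feature_id
        protein_res[[ct$label]] <- pr
      }
    }
    phospho_all <- do.call(rbind, phospho_res)
    rownames(phospho_all) <- NULL
    protein_all <- if (length(protein_res)) {
      pa <- do.call(rbind, protein_res); rownames(pa) <- NULL; pa
    } else NULL
    if (!is.null(protein_all)) {
      phospho_all <- exclude_protein_driven(phospho_all, protein_all,
                                            sig_level = params$sig_level)
    } else {
      phospho_all$protein_excluded <- FALSE
    }
    list(phospho = phospho_all, protein = protein_all)
  })

  ## kinase activity --------------------------------------------------------
  kins <- if (!is.null(x$ks_db)) with_stage("kinswing", {
    ks_db <- if (is.character(x$ks_db)) read_kinase_substrate_db(x$ks_db)
             else x$ks_db
    pwms <- build_pwm_set(ks_db, pseudocount = params$pseudocount)
    swing <- list(); known <- list()
    ci <- 0L
    for (ct in contrasts) {
      ci <- ci + 1L
      p <- prep[[ct$plex]]
      mat <- analysis_matrix(p)
      finfo <- features$info[match(rownames(mat), features$info$feature_id), ]
      feats <- data.frame(feature_id = finfo$feature_id,
                          gene = finfo$gene,
                          window = first_window(finfo),
                          stringsAsFactors = FALSE)
      dct <- diff$phospho[diff$phospho$contrast == ct$label, ]
      edges <- build_network(pwms, feats,
                             edge_p_threshold = params$edge_p,
                             n_draws = params$n_draws, seed = seed + 1000L * ci)
      swing[[ct$label]] <- tryCatch(
        compute_swing(edges, dct, pwms, fc_p_threshold = params$fc_p,
                      n_perm = params$n_perm, seed = seed + 1000L * ci + 1L),
        error = function(e) {
          # a contrast with no significant substrate movement has an
          # undefined z-transform; report an empty table rather than abort
          if (!grepl("z undefined", conditionMessage(e))) stop(e)
          warning(sprintf("kinase swing undefined for %s: %s", ct$label,
                          conditionMessage(e)), call. = FALSE)
          data.frame(kinase = character(0), n_edges = integer(0),
                     n_pos = integer(0), n_neg = integer(0),
                     p_pos_frac = numeric(0), p_neg_frac = numeric(0),
                     swing_raw = numeric(0), z = numeric(0),
                     perm_p_pos = numeric(0), perm_p_neg = numeric(0),
                     n_perm = integer(0), n_seqs = numeric(0),
                     stringsAsFactors = FALSE)
        })
      known[[ct$label]] <- known_substrate_average(
        dct, feats, ks_db, min_substrates = params$min_substrates,
        sig_level = params$sig_level)
    }
    list(swing = swing, known = known)
  }) else NULL

  ## regulatory-site trends and ranked lists --------------------------------
  reg <- if (!is.null(x$reg_db)) with_stage("annotation", {
    reg_db <- if (is.character(x$reg_db)) read_regulatory_db(x$reg_db)
              else x$reg_db
    out <- list()
    for (ct in contrasts) {
      p <- prep[[ct$plex]]
      mat <- analysis_matrix(p)
      finfo <- features$info[match(rownames(mat), features$info$feature_id), ]
      feats <- data.frame(feature_id = finfo$feature_id, gene = finfo$gene,
                          window = first_window(finfo),
                          stringsAsFactors = FALSE)
      dct <- diff$phospho[diff$phospho$contrast == ct$label, ]
      ann <- match_regulatory_sites(feats, dct, reg_db)
      out[[ct$label]] <- function_trends(ann)
    }
    out
  }) else NULL

  ranked <- with_stage("annotation", {
    bg <- if (!is.null(diff$protein)) {
      intersect(unique(diff$phospho$gene), unique(diff$protein$gene))
    } else unique(diff$phospho$gene)
    out <- list()
    for (ct in contrasts) {
      dct <- diff$phospho[diff$phospho$contrast == ct$label, ]
      for (dir in c("up", "down")) {
        out[[paste(ct$label, dir)]] <-
          build_ranked_gene_list(dct, dir, bg, contrast = ct$label)
      }
    }
    out
  })

  ## set summary ------------------------------------------------------------
  set_summary <- with_stage("summary", {
    tested <- lapply(plexes, function(px) rownames(prep[[px]]$normalized))
    names(tested) <- plexes
    sig_sets <- lapply(contrasts, function(ct) {
      d <- diff$phospho
      d$feature_id[d$contrast == ct$label & d$significant &
                     !d$protein_excluded]
    })
    names(sig_sets) <- vapply(contrasts, `[[`, character(1), "label")
    s <- list(detected = if (length(plexes) == 2L)
                persistence_and_overlap(tested[[1L]], tested[[2L]])
              else list(n_a = length(tested[[1L]])),
              significant_per_contrast = lapply(sig_sets, length))
    pm <- grep("^P/M", names(sig_sets), value = TRUE)
    if (length(pm) == 2L) {
      s$significant_persistence <- persistence_and_overlap(sig_sets[[pm[1L]]],
                                                           sig_sets[[pm[2L]]])
    }
    if (!is.null(diff$protein)) {
      prot_tested <- lapply(plexes, function(px)
        rownames(prep_prot[[px]]$normalized))
      if (length(plexes) == 2L) {
        s$protein_detected <- persistence_and_overlap(prot_tested[[1L]],
                                                      prot_tested[[2L]])
      }
    }
    s
  })

  manifest <- list(
    package = "phosphoswing",
    version = as.character(utils::packageVersion("phosphoswing")),
    seed = seed,
    params = params,
    n_records_retained = nrow(features$info),
    removed_outlier_samples = lapply(prep, `[[`, "removed_samples"),
    n_surrogates = lapply(prep, `[[`, "n_sv"),
    contrasts = vapply(contrasts, `[[`, character(1), "label"))

  result <- list(features = features, preprocess = prep,
                 preprocess_protein = prep_prot,
                 phospho_results = diff$phospho,
                 protein_results = diff$protein,
                 kinswing = if (is.null(kins)) NULL else kins$swing,
                 known_substrates = if (is.null(kins)) NULL else kins$known,
                 regulatory_trends = reg, ranked_lists = ranked,
                 set_summary = set_summary, manifest = manifest)

  if (!is.null(out_dir)) with_stage("write", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(d, f) utils::write.table(
      d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(diff$phospho, "results_phospho.tsv")
    if (!is.null(diff$protein)) wt(diff$protein, "results_protein.tsv")
    if (!is.null(kins)) {
      for (lbl in names(kins$swing)) {
        wt(kins$swing[[lbl]], sprintf("kinswing_%s.tsv", contrast_slug(lbl)))
        wt(kins$known[[lbl]],
           sprintf("known_substrates_%s.tsv", contrast_slug(lbl)))
      }
    }
    if (!is.null(reg)) {
      for (lbl in names(reg)) {
        wt(reg[[lbl]], sprintf("function_trends_%s.tsv", contrast_slug(lbl)))
      }
    }
    for (lbl in names(ranked)) {
      writeLines(ranked[[lbl]]$genes,
                 file.path(out_dir, sprintf("ranked_%s.txt",
                                            contrast_slug(gsub(" ", "_", lbl)))))
    }
    jsonlite::write_json(set_summary, file.path(out_dir, "set_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  invisible(result)
}

#' Build PWMs for every kinase in a kinase-substrate table
#'
#' Substrate windows are partitioned by acceptor residue class; kinases with
#' windows of both Ser/Thr and Tyr specificity are modeled twice (the
#' Tyr-class model is suffixed `_TYR` to keep kinase identifiers unique).
#'
#' @param ks_db Data.frame with `kinase` and `window` columns.
#' @param pseudocount PWM pseudocount.
#' @param min_seqs Minimum substrate windows per model (default 1).
#' @return List of `kinase_pwm` objects.
#' @export
build_pwm_set <- function(ks_db, pseudocount = 0.01, min_seqs = 1L) {
  pwms <- list()
  for (k in unique(ks_db$kinase)) {
    wins <- ks_db$window[ks_db$kinase == k]
    st <- wins[center_residue(wins) %in% c("S", "T")]
    ty <- wins[center_residue(wins) == "Y"]
    if (length(st) >= min_seqs && length(st) > 0L) {
      pwms[[length(pwms) + 1L]] <- build_pwm(st, pseudocount, kinase = k,
                                             residue_class = "ST")
    }
    if (length(ty) >= min_seqs && length(ty) > 0L) {
      nm <- if (length(st) > 0L) paste0(k, "_TYR") else k
      pwms[[length(pwms) + 1L]] <- build_pwm(ty, pseudocount, kinase = nm,
                                             residue_class = "Y")
    }
  }
  pwms
}
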