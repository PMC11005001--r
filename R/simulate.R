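# Synthetic-data generator: emits phosphosite and protein-group tables, a
# protein FASTA, kinase-substrate and regulatory-site flat files and a
# ground-truth record, so the whole pipeline can be exercised with planted
# effects and no external downloads.

SIM_FUNCTIONS <- c("translation", "apoptosis", "cell growth",
                   "cell motility", "transcription", "cell differentiation")

#' Simulation configuration
#'
#' Defaults mirror the emulated experiment: two 11-channel plexes (3
#' untreated + 4 mock + 4 pilocarpine each), log2-scale intensities with
#' within-group standard deviation 0.5, about 25% missing values imposed
#' preferentially at low intensity, one balanced batch vector, and planted
#' effects on roughly a quarter of the features (matching the fraction of
#' phosphopeptides a strong stimulus perturbs) plus one activated kinase and
#' a set of protein-level confounds.
#'
#' @param n_features Total phosphopeptide features (kinase substrates
#'   included).
#' @param n_background_genes Genes carrying the non-substrate features.
#' @param n_kinases Number of synthetic kinases.
#' @param n_substrates_per_kinase Substrate windows per kinase (PWM training
#'   set; each also becomes a detected feature).
#' @param frac_tyr_kinases Fraction of kinases with Tyr specificity.
#' @param design Sample design (default [default_design()]).
#' @param baseline_mean,baseline_sd Log2 baseline intensity distribution.
#' @param sd_within Within-group log2 standard deviation.
#' @param missing_rate Overall missing-value rate in (0, 1).
#' @param missing_mode `"intensity"` (logistic in intensity, emulating
#'   left-censoring) or `"mcar"`.
#' @param missing_slope Steepness of the intensity-dependent missingness.
#' @param n_batch Number of planted batch vectors (0, 1 or 2).
#' @param batch_sd Standard deviation of per-feature batch loadings.
#' @param batch_frac Fraction of features carrying each batch vector.
#' @param planted_frac Fraction of features given a direct group effect.
#' @param planted_lfc Magnitude of the planted log2 fold change (random
#'   sign), applied to the pilocarpine group in both plexes.
#' @param activated_kinases Number of kinases whose substrates are shifted.
#' @param kinase_lfc Log2 shift of activated kinases' substrates.
#' @param n_protein_changes Genes with a planted protein-level change (the
#'   change propagates to all of the gene's phosphopeptides and its protein
#'   feature, exercising the protein-level exclusion rule).
#' @param protein_lfc Magnitude of planted protein changes (random sign).
#' @param protein_detect_frac Fraction of genes detected at protein level.
#' @param frac_multi Fraction of background features that are
#'   doubly-phosphorylated.
#' @param dup_frac Fraction of features emitted twice (charge variants).
#' @param loc_fail_frac Fraction of (effect-free) features whose
#'   localization probabilities fail the 0.5/0.75 retention rule.
#' @param motif_noise Per-position substitution probability of substrate
#'   windows relative to the kinase consensus.
#' @param reg_frac Fraction of kinase-substrate sites entered into the
#'   regulatory-site file.
#' @param seed Default RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_features = 4000L, n_background_genes = 600L,
                       n_kinases = 12L, n_substrates_per_kinase = 40L,
                       frac_tyr_kinases = 0.25, design = default_design(),
                       baseline_mean = 20, baseline_sd = 2, sd_within = 0.5,
                       missing_rate = 0.25,
                       missing_mode = c("intensity", "mcar"),
                       missing_slope = 2,
                       n_batch = 1L, batch_sd = 0.5, batch_frac = 0.4,
                       planted_frac = 0.25, planted_lfc = 1.0,
                       activated_kinases = 1L, kinase_lfc = 1.0,
                       n_protein_changes = 20L, protein_lfc = 1.0,
                       protein_detect_frac = 0.7,
                       frac_multi = 0.3, dup_frac = 0.15,
                       loc_fail_frac = 0.1, motif_noise = 0.2,
                       reg_frac = 0.3, seed = 1L) {
  missing_mode <- match.arg(missing_mode)
  cfg <- list(n_features = as.integer(n_features),
              n_background_genes = as.integer(n_background_genes),
              n_kinases = as.integer(n_kinases),
              n_substrates_per_kinase = as.integer(n_substrates_per_kinase),
              frac_tyr_kinases = frac_tyr_kinases, design = design,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              sd_within = sd_within, missing_rate = missing_rate,
              missing_mode = missing_mode, missing_slope = missing_slope,
              n_batch = as.integer(n_batch), batch_sd = batch_sd,
              batch_frac = batch_frac, planted_frac = planted_frac,
              planted_lfc = planted_lfc,
              activated_kinases = as.integer(activated_kinases),
              kinase_lfc = kinase_lfc,
              n_protein_changes = as.integer(n_protein_changes),
              protein_lfc = protein_lfc,
              protein_detect_frac = protein_detect_frac,
              frac_multi = frac_multi, dup_frac = dup_frac,
              loc_fail_frac = loc_fail_frac, motif_noise = motif_noise,
              reg_frac = reg_frac, seed = as.integer(seed))
  rates <- c("frac_tyr_kinases", "missing_rate", "batch_frac", "planted_frac",
             "protein_detect_frac", "frac_multi", "dup_frac", "loc_fail_frac",
             "motif_noise", "reg_frac")
  for (r in rates) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop_format("config error: %s must be in [0, 1]", r)
    }
  }
  if (cfg$n_kinases < 2L) stop_format("config error: n_kinases must be >= 2")
  validate_design(cfg$design)
  class(cfg) <- "sim_config"
  cfg
}

random_window <- function(n, center_pool = c("S", "T", "Y"),
                          center_prob = c(0.75, 0.2, 0.05)) {
  flank <- function() {
    vapply(seq_len(n), function(i)
      paste(sample(AA20, 7L, replace = TRUE), collapse = ""), character(1))
  }
  paste0(flank(),
         sample(center_pool, n, replace = TRUE, prob = center_prob),
         flank())
}

mutate_windows <- function(consensus, n, noise, st_center) {
  chars <- strsplit(consensus, "")[[1]]
  vapply(seq_len(n), function(i) {
    w <- chars
    for (j in setdiff(seq_len(WINDOW_WIDTH), 8L)) {
      if (stats::runif(1) < noise) w[j] <- sample(AA20, 1L)
    }
    if (st_center) w[8L] <- sample(c("S", "T"), 1L, prob = c(0.7, 0.3))
    paste(w, collapse = "")
  }, character(1))
}

#' Generate a motif-coherent kinase-substrate database
#'
#' Each synthetic kinase receives a random consensus motif; its substrate
#' windows are noisy draws from that consensus, so the kinase's own
#' substrates score higher under its PWM than under other kinases' PWMs.
#' A fraction of the substrate sites is additionally entered into a
#' regulatory-site table with random functions and directions.
#'
#' @param config A [sim_config()] list.
#' @param seed Optional seed (NULL continues the current RNG stream).
#' @return List with `kinases` (kinase, class, consensus), `ks_table`
#'   (columns KINASE, SUB_GENE, SUB_POS, SITE_7_AA) and `reg_table`
#'   (columns GENE, POS, SITE_7_AA, FUNCTION, DIRECTION).
#' @export
generate_kinase_db <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_k <- config$n_kinases
  n_sub <- config$n_substrates_per_kinase
  n_tyr <- floor(config$frac_tyr_kinases * n_k)
  class <- c(rep("ST", n_k - n_tyr), rep("Y", n_tyr))
  kinase <- sprintf("KIN%02d", seq_len(n_k))
  consensus <- character(n_k)
  ks <- vector("list", n_k)
  for (k in seq_len(n_k)) {
    center <- if (class[k] == "ST") sample(c("S", "T"), 1L, prob = c(0.7, 0.3)) else "Y"
    consensus[k] <- paste0(
      paste(sample(AA20, 7L, replace = TRUE), collapse = ""), center,
      paste(sample(AA20, 7L, replace = TRUE), collapse = ""))
    wins <- mutate_windows(consensus[k], n_sub, config$motif_noise,
                           st_center = class[k] == "ST")
    ks[[k]] <- data.frame(KINASE = kinase[k],
                          SUB_GENE = sprintf("GK%02d_%03d", k, seq_len(n_sub)),
                          SUB_POS = 8L, SITE_7_AA = wins,
                          stringsAsFactors = FALSE)
  }
  ks_table <- do.call(rbind, ks)
  n_reg <- round(config$reg_frac * nrow(ks_table))
  reg_rows <- sort(sample.int(nrow(ks_table), n_reg))
  reg_table <- data.frame(
    GENE = ks_table$SUB_GENE[reg_rows],
    POS = ks_table$SUB_POS[reg_rows],
    SITE_7_AA = ks_table$SITE_7_AA[reg_rows],
    FUNCTION = sample(SIM_FUNCTIONS, n_reg, replace = TRUE),
    DIRECTION = sample(c("induced", "inhibited"), n_reg, replace = TRUE),
    stringsAsFactors = FALSE)
  list(kinases = data.frame(kinase = kinase, class = class,
                            consensus = consensus, stringsAsFactors = FALSE),
       ks_table = ks_table, reg_table = reg_table)
}

# solve for the logistic intercept giving the target mean missing rate
logistic_intercept <- function(z, slope, rate) {
  f <- function(a) mean(stats::plogis(a - slope * z)) - rate
  stats::uniroot(f, c(-50, 50))$root
}

#' Generate a complete synthetic experiment with ground truth
#'
#' Log2 intensities are baseline + planted group effects + batch component +
#' Gaussian noise. Planted kinase activations shift the kinase's substrate
#' features in the pilocarpine group; planted protein changes shift all of a
#' gene's phosphopeptides and its protein feature (exercising the
#' protein-level exclusion filter); missingness is imposed preferentially at
#' low intensity; localization probabilities are drawn so a configurable
#' fraction of effect-free features fails the 0.5/0.75 retention rule.
#'
#' @param config A [sim_config()] list.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param out_dir Optional directory: writes `phospho.tsv`, `protein.tsv`,
#'   `proteins.fasta`, `design.tsv`, `ks_db.tsv`, `reg_db.tsv` and
#'   `ground_truth.json`.
#' @return List with `phospho` (data.frame in the ingest dialect),
#'   `protein`, `fasta` (named character), `design`, `ks_db`, `reg_db`,
#'   `kinases` and `truth` (planting record).
#' @export
generate_experiment <- function(config, seed = config$seed, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  db <- generate_kinase_db(config, seed = NULL)
  design <- config$design
  n_s <- nrow(design)

  ## --- feature layout -----------------------------------------------------
  ks <- db$ks_table
  n_ks <- nrow(ks)
  n_bg <- config$n_features - n_ks
  if (n_bg < 0L) {
    stop_format("config error: n_features smaller than total kinase substrates")
  }
  bg_genes <- sprintf("G%04d", seq_len(config$n_background_genes))
  bg_gene <- rep(bg_genes, length.out = n_bg)
  bg_multi <- stats::runif(n_bg) < config$frac_multi

  # assign window slots per gene; protein sequence is the slot concatenation
  feat <- data.frame(
    gene = c(ks$SUB_GENE, bg_gene),
    multiplicity = c(rep(1L, n_ks), ifelse(bg_multi, 2L, 1L)),
    is_substrate = c(rep(TRUE, n_ks), rep(FALSE, n_bg)),
    kinase = c(ks$KINASE, rep(NA_character_, n_bg)),
    stringsAsFactors = FALSE)
  n_feat <- nrow(feat)
  win1 <- c(ks$SITE_7_AA, random_window(n_bg))
  win2 <- rep(NA_character_, n_feat)
  win2[feat$multiplicity == 2L] <- random_window(sum(feat$multiplicity == 2L))

  pos1 <- integer(n_feat)
  pos2 <- rep(NA_integer_, n_feat)
  fasta <- character(0)
  for (g in unique(feat$gene)) {
    rows <- which(feat$gene == g)
    slot <- 0L
    segs <- character(0)
    for (i in rows) {
      pos1[i] <- 8L + 15L * slot
      segs <- c(segs, win1[i])
      slot <- slot + 1L
      if (feat$multiplicity[i] == 2L) {
        pos2[i] <- 8L + 15L * slot
        segs <- c(segs, win2[i])
        slot <- slot + 1L
      }
    }
    fasta[g] <- paste(segs, collapse = "")
  }
  res1 <- center_residue(win1)
  res2 <- ifelse(is.na(win2), NA_character_, center_residue(win2))

  site_str <- ifelse(feat$multiplicity == 2L,
                     paste0(res1, pos1, ";", res2, pos2),
                     paste0(res1, pos1))
  feat$feature_id <- paste0(feat$gene, "_", site_str, "_M", feat$multiplicity)

  ## --- planted truth ------------------------------------------------------
  pil <- design$group == "pilocarpine"
  eff <- matrix(0, n_feat, n_s)

  act_kin <- character(0)
  if (config$activated_kinases > 0L) {
    st_kin <- db$kinases$kinase[db$kinases$class == "ST"]
    act_kin <- utils::head(st_kin, config$activated_kinases)
    act_rows <- which(feat$kinase %in% act_kin)
    eff[act_rows, pil] <- eff[act_rows, pil] + config$kinase_lfc
  }

  eligible <- which(!feat$is_substrate & feat$multiplicity == 1L)
  n_planted <- min(round(config$planted_frac * config$n_features),
                   length(eligible))
  planted_rows <- sort(sample(eligible, n_planted))
  planted_lfc <- config$planted_lfc *
    sample(c(-1, 1), n_planted, replace = TRUE)
  eff[planted_rows, pil] <- eff[planted_rows, pil] + planted_lfc

  conf_pool <- setdiff(bg_genes, feat$gene[planted_rows])
  n_conf <- min(config$n_protein_changes, length(conf_pool))
  conf_genes <- sort(sample(conf_pool, n_conf))
  conf_lfc <- stats::setNames(
    config$protein_lfc * sample(c(-1, 1), n_conf, replace = TRUE), conf_genes)
  for (g in conf_genes) {
    rows <- which(feat$gene == g)
    eff[rows, pil] <- eff[rows, pil] + conf_lfc[[g]]
  }

  ## --- batch structure ----------------------------------------------------
  batch_vectors <- NULL
  batch <- matrix(0, n_feat, n_s)
  if (config$n_batch > 0L) {
    batch_vectors <- matrix(0, n_s, config$n_batch,
                            dimnames = list(design$sample, NULL))
    # vector 1: replicate-parity split, balanced within each group
    batch_vectors[, 1L] <- ifelse(design$replicate %% 2L == 0L, 1, -1)
    if (config$n_batch > 1L) {
      for (b in 2L:config$n_batch) {
        batch_vectors[, b] <- sample(c(-1, 1), n_s, replace = TRUE)
      }
    }
    for (b in seq_len(config$n_batch)) {
      load_b <- numeric(n_feat)
      hit <- stats::runif(n_feat) < config$batch_frac
      load_b[hit] <- stats::rnorm(sum(hit), 0, config$batch_sd)
      batch <- batch + outer(load_b, batch_vectors[, b])
    }
  }

  ## --- intensities, duplicates, missingness -------------------------------
  baseline <- stats::rnorm(n_feat, config$baseline_mean, config$baseline_sd)
  value <- baseline + eff + batch +
    matrix(stats::rnorm(n_feat * n_s, 0, config$sd_within), n_feat, n_s)

  n_dup <- round(config$dup_frac * n_feat)
  dup_rows <- sort(sample.int(n_feat, n_dup))
  src <- c(seq_len(n_feat), dup_rows)
  charge <- c(rep(2L, n_feat), rep(3L, n_dup))
  value_all <- rbind(value,
                     value[dup_rows, , drop = FALSE] +
                       matrix(stats::rnorm(n_dup * n_s, 0, 0.1), n_dup, n_s))

  if (config$missing_rate > 0) {
    if (config$missing_mode == "intensity") {
      z <- as.vector(scale(as.vector(value_all)))
      a <- logistic_intercept(z, config$missing_slope, config$missing_rate)
      p_miss <- stats::plogis(a - config$missing_slope * z)
    } else {
      p_miss <- rep(config$missing_rate, length(value_all))
    }
    mask <- stats::runif(length(value_all)) < p_miss
    value_all[matrix(mask, nrow(value_all))] <- NA_real_
  }

  ## --- localization probabilities -----------------------------------------
  truth_rows <- sort(unique(c(planted_rows, which(feat$kinase %in% act_kin),
                              which(feat$gene %in% conf_genes))))
  fail_pool <- setdiff(seq_len(n_feat), truth_rows)
  n_fail <- min(round(config$loc_fail_frac * n_feat), length(fail_pool))
  fail_rows <- sort(sample(fail_pool, n_fail))
  groups <- unique(paste(design$plex, design$group, sep = "_"))
  n_g <- length(groups)
  loc1 <- matrix(stats::runif(n_feat * n_g, 0.85, 1), n_feat, n_g)
  loc2 <- matrix(stats::runif(n_feat * n_g, 0.3, 0.9), n_feat, n_g)
  best_g <- sample.int(n_g, n_feat, replace = TRUE)
  loc2[cbind(seq_len(n_feat), best_g)] <- stats::runif(n_feat, 0.8, 1)
  multi2 <- feat$multiplicity == 2L
  loc1[multi2, ] <- stats::runif(sum(multi2) * n_g, 0.6, 1)
  # failures: singles lose class-1 evidence; doubles lose the secondary site
  fail1 <- intersect(fail_rows, which(!multi2))
  loc1[fail1, ] <- stats::runif(length(fail1) * n_g, 0.2, 0.7)
  fail2 <- intersect(fail_rows, which(multi2))
  loc2[fail2, ] <- stats::runif(length(fail2) * n_g, 0.2, 0.7)

  loc_cols <- lapply(seq_len(n_g), function(gi) {
    ifelse(multi2[src],
           paste0(round(loc1[src, gi], 4), ";", round(loc2[src, gi], 4)),
           as.character(round(loc1[src, gi], 4)))
  })
  names(loc_cols) <- paste0("locprob_", groups)

  ## --- phospho table ------------------------------------------------------
  intensity <- 2^value_all
  intensity[is.na(intensity)] <- 0
  colnames(intensity) <- paste0("intensity_", design$sample)
  phospho <- data.frame(
    id = seq_along(src),
    gene = feat$gene[src],
    protein = feat$gene[src],
    positions = ifelse(multi2[src], paste0(pos1[src], ";", pos2[src]),
                       as.character(pos1[src])),
    residues = ifelse(multi2[src], paste0(res1[src], ";", res2[src]),
                      res1[src]),
    windows = ifelse(multi2[src], paste0(win1[src], ";", win2[src]),
                     win1[src]),
    multiplicity = feat$multiplicity[src],
    charge = charge,
    reverse = "",
    contaminant = "",
    stringsAsFactors = FALSE)
  phospho <- cbind(phospho, as.data.frame(loc_cols, check.names = FALSE),
                   as.data.frame(intensity, check.names = FALSE))

  ## --- protein table ------------------------------------------------------
  all_genes <- names(fasta)
  n_detect <- round(config$protein_detect_frac * length(all_genes))
  detected <- sort(unique(c(conf_genes,
                            sample(all_genes, n_detect))))
  n_p <- length(detected)
  p_base <- stats::rnorm(n_p, config$baseline_mean, config$baseline_sd)
  p_eff <- matrix(0, n_p, n_s)
  conf_idx <- match(conf_genes, detected)
  p_eff[conf_idx, pil] <- rep(conf_lfc, sum(pil))
  p_val <- p_base + p_eff +
    matrix(stats::rnorm(n_p * n_s, 0, 0.3), n_p, n_s)
  if (config$missing_rate > 0) {
    p_mask <- stats::runif(length(p_val)) < config$missing_rate * 0.3
    p_val[matrix(p_mask, n_p)] <- NA_real_
  }
  p_int <- 2^p_val
  p_int[is.na(p_int)] <- 0
  colnames(p_int) <- paste0("intensity_", design$sample)
  protein <- data.frame(
    protein_group_id = sprintf("PG%05d", seq_len(n_p)),
    genes = detected,
    n_unique_peptides = sample(2:20, n_p, replace = TRUE),
    reverse = "", contaminant = "",
    stringsAsFactors = FALSE)
  protein <- cbind(protein, as.data.frame(p_int, check.names = FALSE))

  ## --- ground truth -------------------------------------------------------
  truth <- list(
    planted_features = data.frame(feature_id = feat$feature_id[planted_rows],
                                  log2FC = planted_lfc,
                                  stringsAsFactors = FALSE),
    activated_kinases = data.frame(
      kinase = act_kin,
      log2FC = rep(config$kinase_lfc, length(act_kin)),
      n_substrates = rep(config$n_substrates_per_kinase, length(act_kin)),
      stringsAsFactors = FALSE),
    substrate_features = data.frame(
      feature_id = feat$feature_id[feat$is_substrate],
      kinase = feat$kinase[feat$is_substrate],
      stringsAsFactors = FALSE),
    protein_changes = data.frame(gene = conf_genes,
                                 log2FC = unname(conf_lfc),
                                 stringsAsFactors = FALSE),
    loc_failed_features = feat$feature_id[fail_rows],
    batch_vectors = batch_vectors,
    seed = seed,
    generator_version = as.character(utils::packageVersion("phosphoswing")))

  out <- list(phospho = phospho, protein = protein, fasta = fasta,
              design = design, ks_db = read_ks_df(db$ks_table),
              reg_db = read_reg_df(db$reg_table), kinases = db$kinases,
              truth = truth, config = config)
  if (!is.null(out_dir)) write_experiment(out, db, out_dir)
  out
}

read_ks_df <- function(ks_table) {
  data.frame(kinase = ks_table$KINASE, sub_gene = ks_table$SUB_GENE,
             sub_pos = ks_table$SUB_POS, window = ks_table$SITE_7_AA,
             stringsAsFactors = FALSE)
}

read_reg_df <- function(reg_table) {
  data.frame(gene = reg_table$GENE, pos = reg_table$POS,
             window = reg_table$SITE_7_AA, fun = reg_table$FUNCTION,
             direction = reg_table$DIRECTION, stringsAsFactors = FALSE)
}

write_experiment <- function(x, db, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(x$phospho, "phospho.tsv")
  wt(x$protein, "protein.tsv")
  wt(x$design, "design.tsv")
  wt(db$ks_table, "ks_db.tsv")
  wt(db$reg_table, "reg_db.tsv")
  writeLines(paste0(">", names(x$fasta), "\n", unname(x$fasta)),
             file.path(out_dir, "proteins.fasta"))
  truth <- x$truth
  truth$batch_vectors <- if (is.null(truth$batch_vectors)) NULL else
    as.data.frame(truth$batch_vectors)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
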