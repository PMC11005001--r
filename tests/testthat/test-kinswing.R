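# PWM substrate models, match calibration, network construction, the swing
# statistic with permutation significance, and known-substrate validation.

consensus_window <- function() "ARNDCQESGVHILKF"  # S-centered 15-mer

test_that("PWM frequencies follow the pseudocount formula", {
  w <- consensus_window()
  # unanimity with zero pseudocount
  pwm <- build_pwm(c(w, w), pseudocount = 0, kinase = "K1")
  expect_equal(unname(pwm$freq["A", 1L]), 1)
  expect_equal(unname(pwm$freq["R", 2L]), 1)
  expect_equal(pwm$n_seqs, 2L)  # duplicates count

  # single window, pseudocount 0.01: freq = 1.01 / 1.20
  pwm1 <- build_pwm(w, pseudocount = 0.01)
  expect_equal(unname(pwm1$freq["A", 1L]), 1.01 / 1.20)
  expect_equal(colSums(pwm1$freq), rep(1, 15), tolerance = 1e-9,
               ignore_attr = TRUE)

  # '_' padding contributes no counts and columns still sum to one
  wp <- paste0("_______", "S", "VHILKF_")
  pwmp <- build_pwm(c(w, wp), pseudocount = 0.01)
  expect_equal(colSums(pwmp$freq), rep(1, 15), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(unname(pwmp$freq["A", 1L]), 1.01 / 1.20)  # one observed residue

  expect_error(build_pwm("SHORT"), "length")
  expect_warning(expect_null(build_pwm(character(0), kinase = "KX")), "skipped")
})

test_that("window scoring is the summed log2 likelihood ratio", {
  w <- consensus_window()
  pwm <- build_pwm(w, pseudocount = 0)
  # consensus against its own unanimous PWM with uniform background
  expect_equal(score_window(pwm, w), 15 * log2(20), tolerance = 1e-12)
  # flat PWM equal to the background scores zero everywhere
  flat <- pwm
  flat$freq[] <- 1 / 20
  expect_equal(score_window(flat, w), 0, tolerance = 1e-12)
  # all-padding window scores only the center term
  pwm2 <- build_pwm(w, pseudocount = 0.01)
  pad <- paste0(strrep("_", 7), "S", strrep("_", 7))
  expect_equal(score_window(pwm2, pad),
               unname(log2(pwm2$freq["S", 8L] / (1 / 20))), tolerance = 1e-12)
  # incompatible center residue is not scored
  yw <- sub("^(.{7})S", "\\1Y", w)
  expect_true(is.na(score_window(pwm, yw)))
})

test_that("empirical match p-values hit their bounds and are monotone", {
  set.seed(41)
  pwm <- build_pwm(fixed_windows(20, seed = 2), pseudocount = 0.01, kinase = "K")
  bg <- fixed_windows(300, seed = 3)
  consensus <- AA_consensus <- apply(pwm$freq, 2, function(c) rownames(pwm$freq)[which.max(c)])
  top <- paste(AA_consensus, collapse = "")
  substr(top, 8, 8) <- "S"
  # a window scoring above every background draw attains the lower bound
  p_top <- match_pvalue(pwm, top, bg, n_draws = 1000, seed = 5)
  expect_equal(p_top, 1 / 1001)
  # p is non-increasing in the observed score at a fixed background seed
  probe <- vapply(c(bg[1:10], top), function(w)
    match_pvalue(pwm, w, bg, n_draws = 1000, seed = 5), numeric(1))
  sc <- score_windows(pwm, c(bg[1:10], top))
  ord <- order(sc)
  expect_true(all(diff(probe[ord]) <= 0))
})

test_that("network edges respect the threshold and the residue-class gate", {
  kinA <- fixed_windows(25, center = "S", seed = 6)
  kinB <- fixed_windows(25, center = "S", seed = 7)
  pwms <- list(build_pwm(kinA, kinase = "KA"), build_pwm(kinB, kinase = "KB"))
  feats <- data.frame(
    feature_id = c("fa", "fy"),
    window = c(kinA[1L], sub("^(.{7})S", "\\1Y", kinB[1L])),
    stringsAsFactors = FALSE)
  bg <- fixed_windows(500, seed = 8)
  edges <- build_network(pwms, feats, seed = 9, background_windows = bg)
  # fa matches its own kinase; fy has a Tyr center and no Ser/Thr edge
  expect_true(any(edges$kinase == "KA" & edges$feature_id == "fa"))
  expect_false("fy" %in% edges$feature_id)
  expect_true(all(edges$match_p <= 0.05))
  expect_equal(nrow(build_network(list(), feats, seed = 1)), 0L)
})

test_that("swing hits its formula endpoints and is antisymmetric", {
  edges <- data.frame(
    kinase = c(rep("K1", 4), rep("K2", 4)),
    feature_id = c(paste0("u", 1:4), paste0("m", 1:4)),
    match_score = 1, match_p = 0.01, stringsAsFactors = FALSE)
  d <- make_diff_results(
    c(paste0("u", 1:4), paste0("m", 1:4)),
    log2FC = c(rep(1, 4), c(1, 1, -1, -1)),
    p = 0.01)
  pwms <- list(build_pwm(fixed_windows(10, seed = 10), kinase = "K1"),
               build_pwm(fixed_windows(10, seed = 11), kinase = "K2"))
  sw <- compute_swing(edges, d, pwms, n_perm = 50, seed = 1)
  k1 <- sw[sw$kinase == "K1", ]
  expect_equal(k1$p_pos_frac, 1)
  expect_equal(k1$swing_raw, log(4 + 1) * log(10 + 1))
  # equal up and down significant substrates cancel exactly
  expect_equal(sw$swing_raw[sw$kinase == "K2"], 0)
  # z-scores are standardized across kinases
  expect_equal(mean(sw$z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(sw$z), 1, tolerance = 1e-12)

  # global sign flip of all fold changes negates the swing
  d_flip <- transform(d, log2FC = -log2FC)
  sw_flip <- compute_swing(edges, d_flip, pwms, n_perm = 50, seed = 1)
  expect_equal(sw_flip$swing_raw, -sw$swing_raw)

  # identical seeds reproduce the permutation p-values bit-exactly
  sw2 <- compute_swing(edges, d, pwms, n_perm = 50, seed = 1)
  expect_identical(sw, sw2)
})

test_that("known-substrate averages need four significant matches", {
  wins <- fixed_windows(6, seed = 12)
  feats <- data.frame(feature_id = paste0("f", 1:6),
                      gene = paste0("G", 1:6), window = wins,
                      stringsAsFactors = FALSE)
  # windows matching in the +/-4 core but differing at position +/-6 still match
  db_win <- wins
  substr(db_win, 2, 2) <- "A"
  ks <- data.frame(kinase = c(rep("K1", 4), rep("K2", 3)),
                   sub_gene = c(paste0("G", 1:4), paste0("G", 4:6)),
                   sub_pos = 8L,
                   window = c(db_win[1:4], db_win[4:6]),
                   stringsAsFactors = FALSE)
  d <- make_diff_results(paste0("f", 1:6),
                         log2FC = c(0.5, 0.5, 1.0, 2.0, 1, 1),
                         p = 0.001)
  out <- known_substrate_average(d, feats, ks)
  expect_equal(out$kinase, "K1")
  expect_equal(out$mean_log2FC, 1.0)   # mean of 0.5, 0.5, 1.0, 2.0
  expect_equal(out$n_substrates, 4L)   # K2 has only 3 matches: absent

  # duplicated (gene, window) rows in the database count once
  ks_dup <- rbind(ks, ks[1L, ])
  out2 <- known_substrate_average(d, feats, ks_dup)
  expect_identical(out2, out)
})

test_that("permutation p-values are near-uniform under a global null", {
  set.seed(43)
  cfg <- sim_config(n_kinases = 50, n_substrates_per_kinase = 30,
                    frac_tyr_kinases = 0, seed = 43)
  db <- generate_kinase_db(cfg, seed = 43)
  feats <- data.frame(feature_id = db$ks_table$SUB_GENE,
                      window = db$ks_table$SITE_7_AA, stringsAsFactors = FALSE)
  extra <- data.frame(feature_id = sprintf("BG%04d", 1:500),
                      window = phosphoswing:::random_window(500),
                      stringsAsFactors = FALSE)
  feats <- rbind(feats, extra)
  d <- make_diff_results(feats$feature_id, log2FC = rnorm(nrow(feats), 0, 0.5),
                         p = runif(nrow(feats)))
  pwms <- build_pwm_set(data.frame(kinase = db$ks_table$KINASE,
                                   window = db$ks_table$SITE_7_AA))
  edges <- build_network(pwms, feats, seed = 44)
  sw <- compute_swing(edges, d, pwms, n_perm = 1000, seed = 45)
  ks_stat <- suppressWarnings(stats::ks.test(sw$perm_p_pos, "punif"))$statistic
  expect_lt(unname(ks_stat), 0.15)
})
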