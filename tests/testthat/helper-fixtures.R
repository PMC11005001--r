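# Programmatic fixtures: tiny designs, phosphosite tables and FASTAs built in
# code at test time.

# minimal one-plex design: n_mock mock + n_pilo pilocarpine samples
two_group_design <- function(n_mock = 4L, n_pilo = 4L, plex = "4h") {
  data.frame(
    sample = c(sprintf("M_%s_%d", plex, seq_len(n_mock)),
               sprintf("P_%s_%d", plex, seq_len(n_pilo))),
    channel = as.character(seq_len(n_mock + n_pilo)),
    plex = plex,
    group = c(rep("mock", n_mock), rep("pilocarpine", n_pilo)),
    timepoint = 4,
    replicate = c(seq_len(n_mock), seq_len(n_pilo)),
    stringsAsFactors = FALSE)
}

pm_contrast <- function(plex = "4h") {
  list(label = sprintf("P/M(%s)", plex), plex = plex,
       treatment = "pilocarpine", control = "mock")
}

# build a phosphosite table data.frame in the ingest dialect
make_phospho_table <- function(design,
                               gene, protein = gene, positions, residues,
                               multiplicity = 1L, charge = 2L,
                               locprob = "0.99", intensity) {
  n <- length(gene)
  intensity <- matrix(intensity, nrow = n)
  colnames(intensity) <- paste0("intensity_", design$sample)
  groups <- unique(paste(design$plex, design$group, sep = "_"))
  tab <- data.frame(gene = gene, protein = protein,
                    positions = as.character(positions),
                    residues = residues,
                    multiplicity = multiplicity, charge = charge,
                    reverse = "", contaminant = "",
                    stringsAsFactors = FALSE)
  locprob <- matrix(locprob, nrow = n, ncol = length(groups))
  colnames(locprob) <- paste0("locprob_", groups)
  cbind(tab, as.data.frame(locprob, optional = TRUE),
        as.data.frame(intensity, optional = TRUE))
}

# deterministic random windows with a given center residue
fixed_windows <- function(n, center = "S", seed = 1) {
  withr::with_seed(seed, phosphoswing:::random_window(
    n, center_pool = center, center_prob = 1))
}

# a small diff-results data.frame for network/annotation tests
make_diff_results <- function(feature_id, log2FC, p = 0.01, adj_p = p,
                              significant = adj_p < 0.05) {
  data.frame(feature_id = feature_id, log2FC = log2FC, p = p, adj_p = adj_p,
             significant = significant, stringsAsFactors = FALSE)
}
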