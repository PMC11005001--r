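# Ingest: parse search-engine style phosphosite and protein-group exports,
# re-annotate sequence windows against the search FASTA, apply the
# multi-phosphopeptide localization retention rule and collapse duplicate
# peptide variants to unique phosphopeptide features.

#' Parse a phosphosite-level quantification table
#'
#' Reads a tab-separated phosphosite export (one row per peptide form) with
#' columns `gene`, `protein`, `positions`, `residues`, `multiplicity`,
#' optional `charge`/`windows`/`reverse`/`contaminant`, one
#' `locprob_<plex>_<group>` column per experimental group holding
#' semicolon-separated per-site class-1 localization probabilities, and one
#' `intensity_<sample>` reporter-intensity column per design sample.
#' Zero or absent reporter intensities are treated as missing (common TMT
#' convention). Rows flagged as reverse hits or contaminants are dropped.
#'
#' @param path Path to the tab-separated file (or a data.frame already read).
#' @param design Sample design data.frame (see [default_design()]).
#' @return A `phospho_records` object: list with `info` (site annotations),
#'   `locprob` (per-group localization probability strings), `intensity`
#'   (raw intensity matrix, rows = records, columns = design samples) and
#'   `design`.
#' @export
parse_phospho_table <- function(path, design) {
  validate_design(design)
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  mandatory <- c("gene", "protein", "positions", "residues", "multiplicity")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop_format("format error: missing mandatory column(s): %s",
                paste(miss, collapse = ", "))
  }
  loc_cols <- grep("^locprob_", names(tab), value = TRUE)
  if (length(loc_cols) == 0L) {
    stop_format("format error: missing mandatory column(s): locprob_<group>")
  }
  int_cols <- paste0("intensity_", design$sample)
  absent <- setdiff(int_cols, names(tab))
  if (length(absent)) {
    stop_format(
      "design error: intensity columns do not match the design channels (missing %s)",
      paste(absent, collapse = ", "))
  }

  drop <- rep(FALSE, nrow(tab))
  for (flag in c("reverse", "contaminant")) {
    if (flag %in% names(tab)) {
      drop <- drop | tab[[flag]] %in% c("+", "TRUE", "true", TRUE)
    }
  }
  tab <- tab[!drop, , drop = FALSE]

  intensity <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  intensity[!is.finite(intensity) | intensity <= 0] <- NA_real_
  colnames(intensity) <- design$sample

  info <- data.frame(
    gene = as.character(tab$gene),
    protein = as.character(tab$protein),
    positions = as.character(tab$positions),
    residues = as.character(tab$residues),
    multiplicity = as.integer(tab$multiplicity),
    charge = if ("charge" %in% names(tab)) as.integer(tab$charge) else NA_integer_,
    windows = if ("windows" %in% names(tab)) as.character(tab$windows) else NA_character_,
    stringsAsFactors = FALSE
  )
  locprob <- tab[, loc_cols, drop = FALSE]
  rownames(info) <- rownames(locprob) <- rownames(intensity) <- NULL

  structure(list(info = info, locprob = locprob, intensity = intensity,
                 design = design),
            class = "phospho_records")
}

#' @export
print.phospho_records <- function(x, ...) {
  cat(sprintf("phospho_records: %d records x %d samples\n",
              nrow(x$info), ncol(x$intensity)))
  invisible(x)
}

#' Read a protein FASTA as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}

#' Re-annotate sequence windows from the search FASTA
#'
#' Recomputes every record's site-centered +/-7 sequence window directly from
#' the protein sequence, padding with `_` where the protein terminates, and
#' verifies the stated site residue against the FASTA.
#'
#' @param records A `phospho_records` object.
#' @param fasta Named character vector of protein sequences (see
#'   [read_protein_fasta()]).
#' @return The records with recomputed `windows`.
#' @export
remap_windows <- function(records, fasta) {
  stopifnot(inherits(records, "phospho_records"))
  info <- records$info
  missing_acc <- setdiff(unique(info$protein), names(fasta))
  if (length(missing_acc)) {
    stop_format("lookup error: accession(s) absent from FASTA: %s",
                paste(utils::head(missing_acc, 5), collapse = ", "))
  }
  pos_l <- lapply(split_semi(info$positions), as.integer)
  res_l <- split_semi(info$residues)
  win_out <- character(nrow(info))
  conflicts <- character(0)
  for (i in seq_len(nrow(info))) {
    seq_i <- fasta[[info$protein[i]]]
    n <- nchar(seq_i)
    wins <- character(length(pos_l[[i]]))
    for (s in seq_along(pos_l[[i]])) {
      p <- pos_l[[i]][s]
      if (p < 1L || p > n) {
        conflicts <- c(conflicts, sprintf(
          "row %d (%s): position %d outside protein of length %d",
          i, info$gene[i], p, n))
        next
      }
      observed <- substr(seq_i, p, p)
      if (observed != res_l[[i]][s]) {
        conflicts <- c(conflicts, sprintf(
          "row %d (%s): stated residue %s != FASTA residue %s at position %d",
          i, info$gene[i], res_l[[i]][s], observed, p))
        next
      }
      lo <- max(1L, p - 7L)
      hi <- min(n, p + 7L)
      wins[s] <- paste0(strrep("_", 7L - (p - lo)),
                        substr(seq_i, lo, hi),
                        strrep("_", 7L - (hi - p)))
    }
    win_out[i] <- paste(wins, collapse = ";")
  }
  if (length(conflicts)) {
    stop_format("annotation-conflict error:\n%s",
                paste(utils::head(conflicts, 10), collapse = "\n"))
  }
  records$info$windows <- win_out
  records
}

#' Localization filter for mono- and multi-phosphorylated peptides
#'
#' A multi-phosphorylated peptide is retained if its primary site (the first
#' listed) has class-1 probability above 0.5 in at least one experimental
#' group and some other site has probability above 0.75 in at least one
#' group. Singly phosphorylated peptides are retained when their site
#' probability exceeds 0.75 in at least one group (class-1 convention).
#'
#' @param records A `phospho_records` object.
#' @param primary_threshold Probability floor for the primary site of
#'   multi-phosphorylated peptides (default 0.5).
#' @param class1_threshold Class-1 probability threshold (default 0.75).
#' @return The retained records.
#' @export
filter_multiphospho <- function(records, primary_threshold = 0.5,
                                class1_threshold = 0.75) {
  stopifnot(inherits(records, "phospho_records"))
  nr <- nrow(records$info)
  if (nr == 0L) return(records)
  prob_l <- lapply(seq_len(nr), function(i) {
    per_group <- lapply(records$locprob[i, , drop = TRUE],
                        function(s) as.numeric(strsplit(as.character(s), ";")[[1]]))
    do.call(cbind, per_group)  # sites x groups
  })
  keep <- vapply(seq_len(nr), function(i) {
    pm <- prob_l[[i]]
    site_max <- apply(pm, 1L, max, na.rm = TRUE)
    if (records$info$multiplicity[i] <= 1L || length(site_max) == 1L) {
      site_max[1L] > class1_threshold
    } else {
      site_max[1L] > primary_threshold && any(site_max[-1L] > class1_threshold)
    }
  }, logical(1))
  subset_records(records, keep)
}

subset_records <- function(records, keep) {
  records$info <- records$info[keep, , drop = FALSE]
  records$locprob <- records$locprob[keep, , drop = FALSE]
  records$intensity <- records$intensity[keep, , drop = FALSE]
  rownames(records$info) <- rownames(records$locprob) <- NULL
  records
}

#' Collapse duplicate peptide variants to unique phosphopeptide features
#'
#' Records sharing (gene, sorted site positions, multiplicity) -- e.g. charge
#' states or modification variants of one phosphopeptide -- are merged into a
#' single feature whose per-sample value is the median of the log2
#' intensities over non-missing duplicates. The merged form is the unique
#' phosphopeptide used for counting and all downstream analysis.
#'
#' @param records A `phospho_records` object.
#' @param log2_transform Log2-transform intensities before taking medians
#'   (set `FALSE` if values are already on the log2 scale).
#' @return A `phospho_features` object: list with `info` (feature_id, gene,
#'   positions, residues, windows, multiplicity) and `log2` matrix
#'   (features x samples).
#' @export
collapse_duplicates <- function(records, log2_transform = TRUE) {
  info <- records$info
  values <- if (!is.null(records$intensity)) records$intensity else records$log2
  if (log2_transform) values <- log2(values)

  pos_l <- lapply(split_semi(info$positions), as.integer)
  res_l <- split_semi(info$residues)
  ord_l <- lapply(pos_l, order)
  site_str <- vapply(seq_along(pos_l), function(i) {
    o <- ord_l[[i]]
    paste0(res_l[[i]][o], pos_l[[i]][o], collapse = ";")
  }, character(1))
  key <- paste0(info$gene, "_", site_str, "_M", info$multiplicity)

  first <- !duplicated(key)
  keys <- key[first]
  idx <- split(seq_len(nrow(info)), factor(key, levels = keys))

  log2_mat <- matrix(NA_real_, nrow = length(keys), ncol = ncol(values),
                     dimnames = list(keys, colnames(values)))
  for (f in seq_along(idx)) {
    rows <- idx[[f]]
    if (length(rows) == 1L) {
      log2_mat[f, ] <- values[rows, ]
    } else {
      log2_mat[f, ] <- apply(values[rows, , drop = FALSE], 2L, median_na)
    }
  }

  fi <- which(first)
  sorted_windows <- vapply(fi, function(i) {
    w <- split_semi(info$windows[i])[[1]]
    paste(w[ord_l[[i]]], collapse = ";")
  }, character(1))
  feat_info <- data.frame(
    feature_id = keys,
    gene = info$gene[fi],
    positions = vapply(fi, function(i)
      paste(pos_l[[i]][ord_l[[i]]], collapse = ";"), character(1)),
    residues = vapply(fi, function(i)
      paste(res_l[[i]][ord_l[[i]]], collapse = ";"), character(1)),
    windows = sorted_windows,
    multiplicity = info$multiplicity[fi],
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(list(info = feat_info, log2 = log2_mat, design = records$design),
            class = "phospho_features")
}

#' @export
print.phospho_features <- function(x, ...) {
  cat(sprintf("phospho_features: %d features x %d samples\n",
              nrow(x$info), ncol(x$log2)))
  invisible(x)
}

#' Parse a protein-group quantification table
#'
#' Reads a tab-separated protein-group export with columns
#' `protein_group_id`, `genes` (semicolon-separated; the first listed gene is
#' the representative), `n_unique_peptides`, optional `reverse`/`contaminant`
#' flags and one `intensity_<sample>` column per design sample. After
#' dropping flagged rows, protein groups mapping to the same representative
#' gene are deduplicated keeping the group with the most unique peptides, so
#' the result has one feature per non-redundant gene name.
#'
#' @param path Path to the tab-separated file (or a data.frame).
#' @param design Sample design data.frame.
#' @return A `protein_features` object: list with `info` (protein_group_id,
#'   gene, n_unique_peptides) and `log2` matrix.
#' @export
parse_protein_table <- function(path, design) {
  validate_design(design)
  tab <- if (is.data.frame(path)) path else {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  mandatory <- c("protein_group_id", "genes", "n_unique_peptides")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss)) {
    stop_format("format error: missing mandatory column(s): %s",
                paste(miss, collapse = ", "))
  }
  int_cols <- paste0("intensity_", design$sample)
  absent <- setdiff(int_cols, names(tab))
  if (length(absent)) {
    stop_format(
      "design error: intensity columns do not match the design channels (missing %s)",
      paste(absent, collapse = ", "))
  }
  drop <- rep(FALSE, nrow(tab))
  for (flag in c("reverse", "contaminant")) {
    if (flag %in% names(tab)) drop <- drop | tab[[flag]] %in% c("+", "TRUE", "true")
  }
  tab <- tab[!drop, , drop = FALSE]

  gene <- vapply(split_semi(tab$genes), `[`, character(1), 1L)
  if (any(!nzchar(gene) | is.na(gene))) {
    stop_format("format error: protein group with empty representative gene")
  }
  # one feature per gene: keep the group with most unique peptides
  ord <- order(-as.integer(tab$n_unique_peptides))
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)
  tab <- tab[keep, , drop = FALSE]
  gene <- gene[keep]

  intensity <- as.matrix(tab[, int_cols, drop = FALSE])
  storage.mode(intensity) <- "double"
  intensity[!is.finite(intensity) | intensity <= 0] <- NA_real_
  colnames(intensity) <- design$sample
  log2_mat <- log2(intensity)
  rownames(log2_mat) <- gene

  info <- data.frame(protein_group_id = as.character(tab$protein_group_id),
                     gene = gene,
                     n_unique_peptides = as.integer(tab$n_unique_peptides),
                     stringsAsFactors = FALSE, row.names = NULL)
  structure(list(info = info, log2 = log2_mat, design = design),
            class = "protein_features")
}

#' Write and re-read collapsed phosphopeptide features
#'
#' Tab-separated export of a feature set; log2 intensities are written with
#' 17 significant digits so a write/read round trip reproduces the values
#' bit-exactly.
#'
#' @param features A `phospho_features` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  vals <- trimws(apply(features$log2, 2L, formatC, format = "g", digits = 17))
  vals <- matrix(vals, nrow = nrow(features$log2),
                 dimnames = list(NULL, paste0("log2_",
                                              colnames(features$log2))))
  utils::write.table(cbind(features$info, as.data.frame(vals)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @param design Optional design to attach to the re-read feature set.
#' @export
read_features <- function(path, design = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  val_cols <- grep("^log2_", names(tab), value = TRUE)
  log2_mat <- as.matrix(tab[, val_cols, drop = FALSE])
  storage.mode(log2_mat) <- "double"
  dimnames(log2_mat) <- list(tab$feature_id, sub("^log2_", "", val_cols))
  info <- tab[, setdiff(names(tab), val_cols), drop = FALSE]
  info$positions <- as.character(info$positions)
  info$residues <- as.character(info$residues)
  structure(list(info = info, log2 = log2_mat, design = design),
            class = "phospho_features")
}
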