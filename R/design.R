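# Sample design: channel -> (plex, group, timepoint, replicate) mapping and the
# treatment contrasts derived from it.

#' Default two-plex TMT sample design
#'
#' Two 11-channel plexes (one per dissection timepoint), each holding three
#' pooled untreated control channels, four mock-injected (saline + diazepam)
#' replicates and four pilocarpine-injected replicates. Sample names encode
#' group, plex and replicate (e.g. `P_4h_2`).
#'
#' @return A data.frame with columns `sample`, `channel`, `plex`, `group`,
#'   `timepoint` (hours) and `replicate`.
#' @export
default_design <- function() {
  channels <- c("126", "127N", "127C", "128N", "128C", "129N",
                "129C", "130N", "130C", "131N", "131C")
  one_plex <- function(plex, tp) {
    group <- c(rep("untreated", 3), rep("mock", 4), rep("pilocarpine", 4))
    repl <- c(1:3, 1:4, 1:4)
    prefix <- c(untreated = "U", mock = "M", pilocarpine = "P")
    data.frame(
      sample = sprintf("%s_%s_%d", prefix[group], plex, repl),
      channel = channels,
      plex = plex,
      group = group,
      timepoint = ifelse(group == "untreated", 0, tp),
      replicate = repl,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  rbind(one_plex("4h", 4), one_plex("24h", 24))
}

#' Read a sample design from a tab-separated file
#'
#' @param path File with columns `sample`, `channel`, `plex`, `group`,
#'   `timepoint`, `replicate`.
#' @return Validated design data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  d$timepoint <- as.numeric(d$timepoint)
  d$replicate <- as.integer(d$replicate)
  validate_design(d)
  d
}

validate_design <- function(design) {
  need <- c("sample", "plex", "group", "timepoint", "replicate")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop_format("design error: missing design column(s): %s",
                paste(miss, collapse = ", "))
  }
  if (anyDuplicated(design$sample)) {
    stop_format("design error: duplicated sample names")
  }
  invisible(design)
}

#' Treatment contrasts implied by a design
#'
#' Per plex, the pilocarpine-vs-mock contrast (`P/M`) captures the effect of
#' status epilepticus over its control, and the mock-vs-untreated contrast
#' (`D/U`) captures the effect of the diazepam-containing mock injection.
#' Log2 fold changes are treatment minus control.
#'
#' @param design A design data.frame (see [default_design()]).
#' @return A list of contrasts, each a list with `label`, `plex`,
#'   `treatment` and `control` group names.
#' @export
pipeline_contrasts <- function(design) {
  out <- list()
  for (plex in unique(design$plex)) {
    groups <- unique(design$group[design$plex == plex])
    if (all(c("pilocarpine", "mock") %in% groups)) {
      out[[length(out) + 1L]] <- list(label = sprintf("P/M(%s)", plex),
                                      plex = plex, treatment = "pilocarpine",
                                      control = "mock")
    }
    if (all(c("mock", "untreated") %in% groups)) {
      out[[length(out) + 1L]] <- list(label = sprintf("D/U(%s)", plex),
                                      plex = plex, treatment = "mock",
                                      control = "untreated")
    }
  }
  out
}

# "P/M(4h)" -> comparison type "P/M" (used to match phospho and protein
# contrasts across timepoints for the protein-level exclusion rule)
contrast_type <- function(label) sub("\\(.*\\)$", "", label)

# file-system safe version of a contrast label
contrast_slug <- function(label) gsub("[/()]", "_", label)
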