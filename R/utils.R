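# Shared helpers: amino-acid alphabet, sequence-window accessors, small parsers.

# The 20 proteinogenic amino acids; '_' marks positions beyond a protein terminus.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WINDOW_WIDTH <- 15L  # site-centered +/-7 residues
CORE_START <- 4L     # +/-4 core used for database matching
CORE_END <- 12L

split_semi <- function(x) strsplit(as.character(x), ";", fixed = TRUE)

join_semi <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Central +/-4 core of a 15-residue sequence window
#'
#' Database matching (kinase-substrate and regulatory-site flat files) requires
#' identity of the gene name and of the sequence within four residues either
#' side of the phospho-acceptor; this extracts that 9-mer core.
#'
#' @param window Character vector of 15-character sequence windows.
#' @return Character vector of 9-character cores.
#' @export
window_core <- function(window) {
  stopifnot(all(nchar(window) == WINDOW_WIDTH))
  substr(window, CORE_START, CORE_END)
}

center_residue <- function(window) substr(window, 8L, 8L)

`%||%` <- function(a, b) if (is.null(a)) b else a

# median over non-missing values; all-missing stays missing
median_na <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) NA_real_ else stats::median(v)
}

stop_format <- function(...) stop(sprintf(...), call. = FALSE)
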