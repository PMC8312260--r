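# Standard genetic code, shared by the dN/dS machinery and the codon
# simulator. Stops are "*"; only the standard code is supported.

.codon_env <- new.env(parent = emptyenv())

#' Standard genetic code and sense codons
#'
#' `genetic_code()` returns the standard code as a named character vector
#' (codon to one-letter amino acid, stops as `"*"`); `sense_codons()` the 61
#' non-stop codons.
#'
#' @return named character vector of length 64, or character vector of 61.
#' @export
genetic_code <- function() {
  if (!is.null(.codon_env$code)) return(.codon_env$code)
  nts <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(nts, nts, paste0))), nts, paste0)))
  code <- setNames(aa, codons)
  .codon_env$code <- code
  code
}

#' @rdname genetic_code
#' @export
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

is_stop_codon <- function(codon) {
  unname(genetic_code()[codon] == "*")
}

translate_codon <- function(codon) unname(genetic_code()[codon])

# Split an aligned codon row into 3-character cells. Enforces the frame-gap
# invariant: each cell is either gap-free or "---".
codon_cells <- function(row) {
  n <- nchar(row)
  cells <- substring(row, seq(1L, n, 3L), seq(3L, n, 3L))
  mixed <- grepl("-", cells) & cells != "---"
  if (any(mixed)) stop("codon gaps not aligned to reading frame")
  cells
}

# Strip a terminal stop codon from every row that carries one (alignment-wide
# final codon column replaced by gaps when each row's last ungapped codon is a
# stop); internal stops are an error.
strip_terminal_stops <- function(msa) {
  cellm <- do.call(rbind, lapply(msa$rows, codon_cells))
  code <- genetic_code()
  for (i in seq_len(nrow(cellm))) {
    cells <- cellm[i, ]
    sense <- which(cells != "---")
    if (!length(sense)) next
    aas <- code[cells[sense]]
    stops <- which(!is.na(aas) & aas == "*")
    if (length(stops)) {
      if (any(stops != length(sense)))
        stop("internal stop codon in ", msa$ids[i])
      cellm[i, sense[length(sense)]] <- "---"
    }
  }
  rows <- apply(cellm, 1, paste, collapse = "")
  # drop all-gap trailing codon columns created by the strip
  while (ncol(cellm) > 0L && all(cellm[, ncol(cellm)] == "---")) {
    cellm <- cellm[, -ncol(cellm), drop = FALSE]
    rows <- apply(cellm, 1, paste, collapse = "")
  }
  gcg_msa(msa$ids, rows, "codon", msa$ref_id)
}

#' Translate a codon alignment to protein
#'
#' Gap codons (`---`) and any codon containing an ambiguous position become
#' `-` in the protein alignment; stop codons are an error.
#'
#' @param msa a codon-alphabet [gcg_msa()].
#' @return a protein-alphabet [gcg_msa()] with one column per codon.
#' @export
translate_msa <- function(msa) {
  stopifnot(msa$alphabet == "codon")
  code <- genetic_code()
  rows <- vapply(msa$rows, function(r) {
    cells <- codon_cells(r)
    aa <- code[cells]
    aa[is.na(aa)] <- "-"
    if (any(aa == "*")) stop("stop codon in translation")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  gcg_msa(msa$ids, rows, "protein", msa$ref_id)
}
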