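#' gcgevo: comparative evolution of proglucagon and its receptor genes
#'
#' Analysis toolkit for the mammalian proglucagon gene (Gcg) and the receptors
#' for proglucagon-derived peptides (Gcgr, Glp1r, Glp2r). See the methods
#' vignette (`vignette("gcgevo-methods")`) for the models and design choices.
#'
#' @importFrom stats rpois runif p.adjust phyper setNames ks.test fisher.test
#' @importFrom utils read.delim write.table combn head
#' @keywords internal
"_PACKAGE"

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT_ALPHABET <- c("A", "C", "G", "T")

#' Normalize a species identifier
#'
#' Identifiers are underscore-joined binomials (e.g. `"Homo_sapiens"`) and are
#' matched by exact string comparison everywhere in the package. The only
#' normalization applied is stripping of leading/trailing whitespace, to avoid
#' silent fuzzy joins between alignments, trees, and tables.
#'
#' @param x character vector of identifiers.
#' @return character vector with surrounding whitespace removed.
#' @export
normalize_id <- function(x) trimws(x)

#' Construct a multiple sequence alignment object
#'
#' The central alignment container: a set of equal-length aligned rows
#' (uppercase amino acids or nucleotides plus `-` for gaps) keyed by unique
#' species identifiers, with a designated reference species. Alignment columns
#' are 1-based throughout the package.
#'
#' @param ids character vector of unique species identifiers.
#' @param rows character vector of aligned sequences, same length as `ids`.
#' @param alphabet `"protein"` or `"codon"`.
#' @param ref_id identifier of the reference species (default
#'   `"Homo_sapiens"`); must be present in `ids`.
#' @return an object of class `gcg_msa` with fields `ids`, `rows`, `alphabet`,
#'   `ref_id`.
#' @export
gcg_msa <- function(ids, rows, alphabet = c("protein", "codon"),
                    ref_id = "Homo_sapiens") {
  alphabet <- match.arg(alphabet)
  ids <- normalize_id(as.character(ids))
  rows <- toupper(as.character(rows))
  if (length(ids) != length(rows) || length(ids) == 0L)
    stop("ids and rows must be non-empty and of equal length")
  if (anyDuplicated(ids))
    stop("duplicate species identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(rows))) stop("empty sequence")
  if (length(unique(nchar(rows))) != 1L) stop("unequal lengths")
  allowed <- c(if (alphabet == "protein") AA_ALPHABET else NT_ALPHABET, "-")
  bad <- setdiff(unique(strsplit(paste(rows, collapse = ""), "")[[1]]), allowed)
  if (length(bad))
    stop("characters outside the ", alphabet, " alphabet: ",
         paste(bad, collapse = " "))
  if (!ref_id %in% ids) stop("reference absent: ", ref_id)
  if (alphabet == "codon") {
    ungapped <- nchar(gsub("-", "", rows, fixed = TRUE))
    if (any(ungapped %% 3L != 0L)) stop("frame error")
    if (nchar(rows[1]) %% 3L != 0L) stop("frame error")
  }
  structure(list(ids = ids, rows = rows, alphabet = alphabet, ref_id = ref_id),
            class = "gcg_msa")
}

#' @export
print.gcg_msa <- function(x, ...) {
  cat(sprintf("<gcg_msa> %d sequences x %d columns (%s), reference %s\n",
              length(x$ids), nchar(x$rows[1]), x$alphabet, x$ref_id))
  invisible(x)
}

msa_ncol <- function(msa) nchar(msa$rows[1])

msa_row <- function(msa, id) {
  i <- match(id, msa$ids)
  if (is.na(i)) stop("unknown species: ", id)
  msa$rows[i]
}

msa_chars <- function(msa) {
  m <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(m) <- msa$ids
  m
}

#' Drop species from an alignment
#'
#' @param msa a [gcg_msa()] object.
#' @param species identifiers to remove; removing the reference is an error.
#' @return the reduced alignment.
#' @export
msa_exclude <- function(msa, species) {
  species <- normalize_id(species)
  if (msa$ref_id %in% species) stop("cannot exclude the reference species")
  keep <- !msa$ids %in% species
  gcg_msa(msa$ids[keep], msa$rows[keep], msa$alphabet, msa$ref_id)
}

#' Read an aligned FASTA file
#'
#' Reads a protein or in-frame codon alignment. Lowercase residues are
#' uppercased; characters outside the alphabet (other than `-`) are rejected.
#' For codon alignments a terminal stop codon present in every row's ungapped
#' sequence is stripped, and internal stop codons are an error.
#'
#' @param path FASTA file with `-` gaps.
#' @param alphabet `"protein"` or `"codon"`.
#' @param ref_id reference species identifier, default `"Homo_sapiens"`.
#' @return a [gcg_msa()] object; row order as in the file.
#' @export
read_alignment <- function(path, alphabet = c("protein", "codon"),
                           ref_id = "Homo_sapiens") {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  rows <- toupper(as.character(ss))
  ids <- normalize_id(names(ss))
  if (length(unique(nchar(rows))) != 1L) stop("unequal lengths")
  m <- gcg_msa(ids, rows, alphabet, ref_id)
  if (alphabet == "codon") m <- strip_terminal_stops(m)
  m
}

#' Write an alignment to FASTA
#'
#' @param msa a [gcg_msa()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  ss <- Biostrings::BStringSet(setNames(msa$rows, msa$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a rooted species tree from Newick
#'
#' Leaf labels are species identifiers matched exactly (after whitespace
#' stripping) against alignment ids. Missing branch lengths are set to 1.
#'
#' @param path Newick file.
#' @return an `ape::phylo` tree.
#' @export
read_species_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree in ", path)
  tree$tip.label <- normalize_id(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  tree
}

#' Read the run configuration
#'
#' A YAML file holding input paths, the random seed, species to exclude before
#' every stage, and analysis thresholds. Missing thresholds are filled with
#' package defaults: `tolerance_cut` 0.05, `delta_cut` -2.5, `coevo_fdr` 0.05,
#' `coevo_prob` 0.5. Relative paths are resolved against the config file's
#' directory and checked for existence.
#'
#' @param path YAML config file.
#' @return a named list of class `gcg_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- list(tolerance_cut = 0.05, delta_cut = -2.5,
                   coevo_fdr = 0.05, coevo_prob = 0.5)
  cfg$thresholds <- utils::modifyList(defaults,
                                      as.list(cfg$thresholds %||% list()))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$exclude_species <- as.character(cfg$exclude_species %||% character())
  path_keys <- c("region_map_path", "tree_path", "neighborhood_path")
  list_keys <- c("site_list_paths", "alignment_paths")
  resolve <- function(p) {
    p <- ifelse(grepl("^/", p), p, file.path(base, p))
    missing <- p[!file.exists(p)]
    if (length(missing)) stop("unresolvable path(s): ",
                              paste(missing, collapse = ", "))
    p
  }
  for (k in path_keys) if (!is.null(cfg[[k]])) cfg[[k]] <- resolve(cfg[[k]])
  for (k in list_keys) if (!is.null(cfg[[k]]))
    cfg[[k]] <- lapply(cfg[[k]], resolve)
  class(cfg) <- "gcg_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
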