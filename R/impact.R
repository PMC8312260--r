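#' Load a substitution score matrix
#'
#' Reads a plain-text square log-odds substitution matrix with a residue
#' header (the package ships BLOSUM62). The matrix must be symmetric with
#' each diagonal entry at least as large as the maximum off-diagonal entry in
#' its row.
#'
#' @param path matrix file; defaults to the bundled BLOSUM62.
#' @return 20 x 20 named numeric matrix.
#' @export
load_score_matrix <- function(path = system.file("extdata", "blosum62.txt",
                                                 package = "gcgevo")) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("score matrix must be square with matching residue labels")
  if (!isTRUE(all.equal(m, t(m)))) stop("score matrix must be symmetric")
  offmax <- vapply(seq_len(nrow(m)), function(i) max(m[i, -i]), numeric(1))
  if (any(diag(m) < offmax))
    stop("diagonal entries must dominate their rows")
  m
}

#' Column-frequency tolerance score for a substitution
#'
#' How tolerated residue `residue` is in an alignment column, expressed as a
#' pseudocounted frequency: `(count(residue) + pc) / (n + 20 * pc)` over the
#' non-gap residues of the column. The focal species' own residue should be
#' excluded from `column` by the caller to avoid self-support. Scores below
#' the tolerance cutoff (default 0.05) flag the substitution.
#'
#' @param column character vector of column residues (gaps allowed, removed).
#' @param residue the substituting residue.
#' @param pseudocount pseudocount per residue class, default 1.
#' @return score in (0, 1).
#' @export
tolerance_score <- function(column, residue, pseudocount = 1) {
  column <- column[column != "-"]
  if (!length(column)) stop("all-gap column")
  (sum(column == residue) + pseudocount) /
    (length(column) + 20 * pseudocount)
}

#' Mean score-matrix delta for a substitution
#'
#' The mean, over the non-gap residues `a` of the column, of
#' `m[a, residue] - m[a, ref_residue]`: how much worse (in log-odds units)
#' the substituting residue fits the column than the reference residue does.
#' Deltas at or below the delta cutoff (default -2.5) flag the substitution.
#'
#' @param column character vector of column residues (focal species excluded
#'   by the caller).
#' @param ref_residue the reference residue at the site.
#' @param residue the substituting residue.
#' @param m score matrix from [load_score_matrix()].
#' @return numeric delta; 0 when `residue == ref_residue`.
#' @export
matrix_delta_score <- function(column, ref_residue, residue,
                               m = load_score_matrix()) {
  column <- column[column != "-"]
  if (!length(column)) stop("all-gap column")
  mean(m[column, residue] - m[column, ref_residue])
}

#' Two-flag substitution impact category
#'
#' Combines the tolerance and delta scores into the category scheme used
#' throughout the package: `both_flagged` when the tolerance score is below
#' `tolerance_cut` AND the delta is at or below `delta_cut`; `one_flagged`
#' when exactly one flag is set; `neutral` otherwise.
#'
#' @param tol tolerance score.
#' @param delta matrix delta score.
#' @param thresholds list with `tolerance_cut` (default 0.05) and `delta_cut`
#'   (default -2.5).
#' @return list with `tolerance_flag`, `delta_flag`, `category`.
#' @export
classify_substitution <- function(tol, delta,
                                  thresholds = list(tolerance_cut = 0.05,
                                                    delta_cut = -2.5)) {
  stopifnot(is.finite(tol), is.finite(delta))
  tf <- tol < thresholds$tolerance_cut
  df <- delta <= thresholds$delta_cut
  cat <- if (tf && df) "both_flagged" else if (tf || df) "one_flagged"
    else "neutral"
  list(tolerance_flag = tf, delta_flag = df, category = cat)
}

#' Score every observed substitution in a region
#'
#' For each species and each position where it differs from the reference
#' (per [compare_to_reference()]), computes the tolerance and delta scores on
#' the column with the focal species' own residue removed, and assigns the
#' two-flag category.
#'
#' @inheritParams compare_to_reference
#' @param thresholds see [classify_substitution()].
#' @param m score matrix.
#' @return data.frame of impact calls: `species`, `region`, `substitution`,
#'   `position` (region-relative), `tolerance_score`, `delta_score`,
#'   `category`.
#' @export
screen_impacts <- function(msa, rm, region_name,
                           exclude_species = character(),
                           thresholds = list(tolerance_cut = 0.05,
                                             delta_cut = -2.5),
                           m = load_score_matrix(), precursor = TRUE) {
  if (length(exclude_species)) msa <- msa_exclude(msa, exclude_species)
  cols <- map_region_to_columns(msa, rm, region_name, precursor = precursor)
  cm <- msa_chars(msa)[, cols, drop = FALSE]
  ref <- cm[msa$ref_id, ]
  calls <- list()
  for (sp in setdiff(msa$ids, msa$ref_id)) {
    row <- cm[sp, ]
    diffs <- which(row != ref & row != "-" & ref != "-")
    for (p in diffs) {
      col <- cm[setdiff(msa$ids, sp), p]
      ts <- tolerance_score(col, row[p])
      ds <- matrix_delta_score(col, ref[p], row[p], m)
      cl <- classify_substitution(ts, ds, thresholds)
      calls[[length(calls) + 1L]] <- data.frame(
        species = sp, region = region_name,
        substitution = paste0(ref[p], p, row[p]), position = p,
        tolerance_score = ts, delta_score = ds, category = cl$category)
    }
  }
  if (!length(calls))
    return(data.frame(species = character(), region = character(),
                      substitution = character(), position = integer(),
                      tolerance_score = numeric(), delta_score = numeric(),
                      category = character()))
  do.call(rbind, calls)
}

#' Import / export impact calls as TSV
#'
#' The import path lets externally computed substitution-impact annotations
#' (e.g. from dedicated variant-effect web services) be slotted into the
#' pipeline in place of the built-in alignment-based scores.
#'
#' @param path TSV with columns `species`, `region`, `substitution`,
#'   `position`, `tolerance_score`, `delta_score`, `category`.
#' @return data.frame of impact calls.
#' @export
read_impact_calls <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "region", "substitution", "category")
  if (!all(need %in% names(x)))
    stop("impact call table must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname read_impact_calls
#' @param calls data.frame of impact calls.
#' @export
write_impact_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
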