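#' Per-species differences from the reference over a peptide region
#'
#' Compares every non-reference species to the reference across the alignment
#' columns of one region. Columns where either the reference or the species
#' carries a gap are tallied as `n_gap_cols` and never counted as
#' substitutions (the statistics count amino acid substitutions only).
#'
#' @param msa a protein [gcg_msa()].
#' @param rm a [region_map()].
#' @param region_name region to profile.
#' @param exclude_species identifiers to drop before the comparison (the
#'   "excluding platypus" mode); may be empty.
#' @param numbering `"region"` (default) labels substitutions with
#'   region-relative positions (e.g. `"S2A"` in glucagon numbering);
#'   `"precursor"` uses mature-precursor numbering (e.g. `"R69L"`).
#' @param precursor passed to [map_region_to_columns()].
#' @return an object of class `difference_table`: a data.frame with one row
#'   per non-reference species (`species`, `n_diff`, `n_gap_cols`,
#'   `substitutions` as a list-column of `"X<pos>Y"` strings) and attributes
#'   `region` and `peptide_len`.
#' @export
compare_to_reference <- function(msa, rm, region_name,
                                 exclude_species = character(),
                                 numbering = c("region", "precursor"),
                                 precursor = TRUE) {
  numbering <- match.arg(numbering)
  if (length(exclude_species)) msa <- msa_exclude(msa, exclude_species)
  cols <- map_region_to_columns(msa, rm, region_name, precursor = precursor)
  cm <- msa_chars(msa)[, cols, drop = FALSE]
  ref <- cm[msa$ref_id, ]
  others <- setdiff(msa$ids, msa$ref_id)
  pos_label <- if (numbering == "region") seq_along(cols) else
    seq(rm$regions[[region_name]][1], rm$regions[[region_name]][2])
  res <- lapply(others, function(sp) {
    row <- cm[sp, ]
    gap <- row == "-" | ref == "-"
    diff <- !gap & row != ref
    list(n_diff = sum(diff), n_gap = sum(gap),
         subs = paste0(ref[diff], pos_label[diff], row[diff]))
  })
  out <- data.frame(species = others,
                    n_diff = vapply(res, `[[`, integer(1), "n_diff"),
                    n_gap_cols = vapply(res, `[[`, integer(1), "n_gap"))
  out$substitutions <- lapply(res, `[[`, "subs")
  attr(out, "region") <- region_name
  attr(out, "peptide_len") <- length(cols)
  class(out) <- c("difference_table", "data.frame")
  out
}

#' Summarize variability of one peptide region
#'
#' Computes the variability metric bundle for a region from its difference
#' table: number of species compared, number identical to the reference, the
#' range of per-species difference counts, the average number of
#' substitutions among the sequences that differ, the per-residue substitution
#' rate (total substitutions over all compared species divided by
#' `n_species * peptide_len`), the number of region positions that accepted at
#' least one substitution in any species, and the number of distinct
#' substitution types.
#'
#' @param dt a `difference_table` from [compare_to_reference()].
#' @param peptide_len region length; defaults to the table's attribute.
#' @return one-row data.frame with columns `region`, `peptide_len`,
#'   `n_species`, `n_identical`, `diff_min`, `diff_max`, `avg_diff_differing`
#'   (`NA` when all species are identical), `per_residue_rate`,
#'   `n_variable_sites`, `n_substitution_types`.
#' @export
summarize_region_variability <- function(dt,
                                         peptide_len = attr(dt, "peptide_len")) {
  if (nrow(dt) == 0L) stop("empty difference table")
  if (is.null(peptide_len) || peptide_len < 1L) stop("peptide_len must be >= 1")
  n_species <- nrow(dt)
  n_identical <- sum(dt$n_diff == 0L)
  subs <- unlist(dt$substitutions, use.names = FALSE)
  if (n_identical == n_species) {
    avg <- NA_real_
    rate <- 0
    n_var <- 0L
    n_types <- 0L
  } else {
    avg <- mean(dt$n_diff[dt$n_diff > 0L])
    rate <- sum(dt$n_diff) / (n_species * peptide_len)
    n_var <- length(unique(as.integer(gsub("[A-Z]", "", subs))))
    n_types <- length(unique(subs))
  }
  data.frame(region = attr(dt, "region") %||% NA_character_,
             peptide_len = as.integer(peptide_len),
             n_species = n_species,
             n_identical = n_identical,
             diff_min = min(dt$n_diff),
             diff_max = max(dt$n_diff),
             avg_diff_differing = avg,
             per_residue_rate = rate,
             n_variable_sites = n_var,
             n_substitution_types = n_types)
}

#' Variability table across all regions
#'
#' Convenience wrapper running [compare_to_reference()] and
#' [summarize_region_variability()] for every region of a map.
#'
#' @inheritParams compare_to_reference
#' @param regions region names; defaults to all regions of `rm`.
#' @return data.frame with one row per region.
#' @export
region_variability_table <- function(msa, rm, regions = names(rm$regions),
                                     exclude_species = character(),
                                     precursor = TRUE) {
  do.call(rbind, lapply(regions, function(r)
    summarize_region_variability(
      compare_to_reference(msa, rm, r, exclude_species = exclude_species,
                           precursor = precursor))))
}

#' Per-column residue frequencies (consensus matrix)
#'
#' For each alignment column, the frequency of each of the 20 amino acids and
#' the gap fraction; frequencies plus gap fraction sum to 1. This is the
#' tabular equivalent of a sequence logo.
#'
#' @param msa a protein [gcg_msa()].
#' @param columns optional subset of column indices; default all.
#' @return 21 x ncol numeric matrix, rows named by the 20 amino acids plus
#'   `"-"`.
#' @export
consensus_matrix <- function(msa, columns = NULL) {
  cm <- msa_chars(msa)
  if (!is.null(columns)) cm <- cm[, columns, drop = FALSE]
  lev <- c(AA_ALPHABET, "-")
  out <- apply(cm, 2, function(col) table(factor(col, levels = lev)))
  out <- out / length(msa$ids)
  rownames(out) <- lev
  colnames(out) <- if (is.null(columns)) seq_len(ncol(out)) else columns
  out
}
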