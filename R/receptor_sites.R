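#' Construct an interaction-site set
#'
#' A list of receptor residues implicated in ligand or G-protein interaction,
#' given as 1-based ungapped positions on the reference sequence together
#' with their Wootten structural labels (e.g. `"3.44"`). Labels are opaque
#' strings used for matching and reporting only.
#'
#' @param receptor receptor name (e.g. `"Gcgr"`).
#' @param role `"ligand"` or `"gprotein"`.
#' @param positions unique 1-based reference residue indices.
#' @param labels Wootten labels, same length as `positions`.
#' @param note optional provenance note per site.
#' @return object of class `site_set` (a data.frame with attributes
#'   `receptor` and `role`).
#' @export
site_set <- function(receptor, role = c("ligand", "gprotein"), positions,
                     labels, note = NA_character_) {
  role <- match.arg(role)
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stop("duplicate site positions")
  if (length(labels) != length(positions)) stop("labels/positions mismatch")
  out <- data.frame(ref_position = positions,
                    wootten_label = as.character(labels),
                    note = note)
  attr(out, "receptor") <- receptor
  attr(out, "role") <- role
  class(out) <- c("site_set", "data.frame")
  out
}

#' Read / write interaction-site lists as TSV
#'
#' @param path TSV with columns `receptor`, `role`, `ref_position`,
#'   `wootten_label` (one receptor/role per file).
#' @return a `site_set`.
#' @export
read_site_list <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(wootten_label = "character"))
  need <- c("receptor", "role", "ref_position", "wootten_label")
  if (!all(need %in% names(x)))
    stop("site list must have columns: ", paste(need, collapse = ", "))
  if (length(unique(x$receptor)) != 1L || length(unique(x$role)) != 1L)
    stop("site list must hold one receptor and one role")
  site_set(x$receptor[1], x$role[1], x$ref_position, x$wootten_label,
           x$note %||% NA_character_)
}

#' @rdname read_site_list
#' @param sites a `site_set`.
#' @export
write_site_list <- function(sites, path) {
  out <- data.frame(receptor = attr(sites, "receptor"),
                    role = attr(sites, "role"),
                    ref_position = sites$ref_position,
                    wootten_label = sites$wootten_label,
                    note = sites$note)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Lift ungapped reference positions to alignment columns.
sites_to_columns <- function(msa, positions) {
  refchars <- strsplit(msa_row(msa, msa$ref_id), "")[[1]]
  ungapped_cols <- which(refchars != "-")
  bad <- positions[positions > length(ungapped_cols) | positions < 1L]
  if (length(bad))
    stop("unmappable site position(s): ", paste(bad, collapse = ", "))
  ungapped_cols[positions]
}

#' Categorize interaction sites by observed variability
#'
#' Each site is assigned exactly one category, with precedence
#' `impact_flagged > multi_variant > unique_variant > invariant`:
#' `impact_flagged` when at least one substitution at the site carries a
#' `both_flagged` impact call; `multi_variant` when more than one species
#' varies (or several amino acid states occur); `unique_variant` when exactly
#' one species varies; `invariant` otherwise. Gapped residues are ignored.
#'
#' @param msa protein [gcg_msa()] of receptor sequences.
#' @param sites a [site_set()].
#' @param impact_calls optional impact-call data.frame (see
#'   [screen_impacts()] / [read_impact_calls()]) whose `position` column is in
#'   reference numbering for this receptor.
#' @return data.frame of class `site_category_table`: `ref_position`,
#'   `wootten_label`, `category`, `n_species_varying`, `substitutions`
#'   (comma-joined `"X<pos>Y"` types).
#' @export
categorize_sites <- function(msa, sites, impact_calls = NULL) {
  cols <- sites_to_columns(msa, sites$ref_position)
  cm <- msa_chars(msa)[, cols, drop = FALSE]
  ref <- cm[msa$ref_id, ]
  flagged_pos <- if (!is.null(impact_calls) && nrow(impact_calls))
    unique(impact_calls$position[impact_calls$category == "both_flagged"])
  else integer()
  rows <- lapply(seq_along(cols), function(k) {
    col <- cm[, k]
    varying <- col != "-" & col != ref[k]
    n_var <- sum(varying)
    subs <- if (n_var) unique(paste0(ref[k], sites$ref_position[k],
                                     col[varying])) else character(0)
    category <- if (sites$ref_position[k] %in% flagged_pos) "impact_flagged"
      else if (n_var > 1L || length(subs) > 1L) "multi_variant"
      else if (n_var == 1L) "unique_variant"
      else "invariant"
    data.frame(ref_position = sites$ref_position[k],
               wootten_label = sites$wootten_label[k],
               category = category, n_species_varying = n_var,
               substitutions = paste(subs, collapse = ","))
  })
  out <- do.call(rbind, rows)
  attr(out, "receptor") <- attr(sites, "receptor")
  attr(out, "role") <- attr(sites, "role")
  class(out) <- c("site_category_table", "data.frame")
  out
}

#' Summary counts for a site category table
#'
#' @param tbl a `site_category_table` from [categorize_sites()].
#' @param impact_calls the impact calls used for flagging (optional; needed
#'   for the flagged-substitution count).
#' @return one-row data.frame: `receptor`, `role`, `n_sites`, `n_variable`
#'   (sites with any substitution), `n_unique` (sites varying in exactly one
#'   species), `n_sites_with_flagged`, `n_substitution_types`,
#'   `n_flagged_substitutions`.
#' @export
summarize_site_table <- function(tbl, impact_calls = NULL) {
  if (nrow(tbl) == 0L) stop("empty site table")
  subs <- unlist(strsplit(tbl$substitutions[tbl$substitutions != ""], ","))
  n_flagged_subs <- if (!is.null(impact_calls) && nrow(impact_calls)) {
    flagged <- impact_calls[impact_calls$category == "both_flagged" &
                              impact_calls$position %in% tbl$ref_position, ]
    length(unique(flagged$substitution))
  } else 0L
  data.frame(receptor = attr(tbl, "receptor") %||% NA_character_,
             role = attr(tbl, "role") %||% NA_character_,
             n_sites = nrow(tbl),
             n_variable = sum(tbl$n_species_varying > 0L),
             n_unique = sum(tbl$category == "unique_variant"),
             n_sites_with_flagged = sum(tbl$category == "impact_flagged"),
             n_substitution_types = length(unique(subs)),
             n_flagged_substitutions = n_flagged_subs)
}

#' Per-species difference counts over a site set
#'
#' For each species, the number of interaction sites at which it differs
#' from the reference (gapped residues excluded). Bounded by the number of
#' sites; the reference scores 0 by construction.
#'
#' @inheritParams categorize_sites
#' @return data.frame with columns `species`, `n_diff`.
#' @export
per_species_site_diffs <- function(msa, sites) {
  cols <- sites_to_columns(msa, sites$ref_position)
  cm <- msa_chars(msa)[, cols, drop = FALSE]
  ref <- cm[msa$ref_id, ]
  n <- apply(cm, 1, function(row) sum(row != "-" & ref != "-" & row != ref))
  data.frame(species = msa$ids, n_diff = unname(n))
}

#' Intersect site sets by shared Wootten label
#'
#' Restricts analyses to the sites shared (by label) across receptors, e.g.
#' the ligand-interacting sites common to all three receptors. All inputs
#' must carry the same role; positions are taken from the first set; output
#' is ordered by label.
#'
#' @param sets list of two or more [site_set()] objects of the same role.
#' @return a `site_set` of the shared sites (possibly empty, with a warning).
#' @export
intersect_site_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least two site sets")
  roles <- vapply(sets, attr, character(1), "role")
  if (length(unique(roles)) != 1L) stop("mixed roles")
  shared <- Reduce(intersect, lapply(sets, `[[`, "wootten_label"))
  if (!length(shared)) warning("no shared sites")
  first <- sets[[1]]
  keep <- first[first$wootten_label %in% shared, , drop = FALSE]
  keep <- keep[order(keep$wootten_label), , drop = FALSE]
  site_set(paste(vapply(sets, attr, character(1), "receptor"),
                 collapse = "+"),
           roles[1], keep$ref_position, keep$wootten_label, keep$note)
}
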