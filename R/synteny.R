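#' Read a gene-neighborhood table
#'
#' One row per species and focal gene, recording whether the two expected
#' flanking genes were found adjacent to the focal gene in that species'
#' assembly, whether the focal gene sits at a contig edge, and how many genes
#' the contig holds. Optional boolean columns `left_elsewhere` /
#' `right_elsewhere` record that a missing flank was found elsewhere in the
#' assembly (translocation evidence).
#'
#' @param path TSV with header: `species`, `focal_gene`, `expected_left`,
#'   `expected_right`, `left_found`, `right_found`, `at_contig_edge` (one of
#'   `none`, `left`, `right`, `both`), `contig_gene_count`.
#' @return data.frame of neighborhood records.
#' @export
read_neighborhood_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "focal_gene", "expected_left", "expected_right",
            "left_found", "right_found", "at_contig_edge",
            "contig_gene_count")
  if (!all(need %in% names(x)))
    stop("neighborhood table must have columns: ",
         paste(need, collapse = ", "))
  x$left_found <- as.logical(x$left_found)
  x$right_found <- as.logical(x$right_found)
  bad <- setdiff(unique(x$at_contig_edge), c("none", "left", "right", "both"))
  if (length(bad)) stop("invalid at_contig_edge value: ",
                        paste(bad, collapse = ", "))
  x
}

#' Classify one gene neighborhood
#'
#' The conservation class comes from the flank presence flags alone:
#' `both_flanks`, `left_only`, `right_only`, or `none`. Contig-edge
#' information never changes the class; it only sets the assembly-artifact
#' caveat, which is raised when a missing flank coincides with a contig edge
#' on that side, or when a non-`both_flanks` gene sits on a short contig
#' (at most `short_contig_genes` genes). A missing flank with no edge that
#' was found elsewhere in the assembly is annotated as relocated.
#'
#' @param rec one-row data.frame or list with the fields of
#'   [read_neighborhood_table()].
#' @param short_contig_genes contigs with at most this many genes count as
#'   short; default 3.
#' @return list with `class`, `caveat` (logical), `relocated` (logical).
#' @export
classify_neighborhood <- function(rec, short_contig_genes = 3L) {
  lf <- isTRUE(as.logical(rec$left_found))
  rf <- isTRUE(as.logical(rec$right_found))
  cls <- if (lf && rf) "both_flanks" else if (lf) "left_only"
    else if (rf) "right_only" else "none"
  edge <- as.character(rec$at_contig_edge %||% "none")
  edge_left <- edge %in% c("left", "both")
  edge_right <- edge %in% c("right", "both")
  caveat <- (!lf && edge_left) || (!rf && edge_right) ||
    (cls != "both_flanks" &&
       isTRUE(rec$contig_gene_count <= short_contig_genes))
  relocated <-
    (!lf && !edge_left && isTRUE(as.logical(rec$left_elsewhere %||% FALSE))) ||
    (!rf && !edge_right && isTRUE(as.logical(rec$right_elsewhere %||% FALSE)))
  list(class = cls, caveat = caveat, relocated = relocated)
}

#' Classify and tally neighborhoods per focal gene
#'
#' @param records data.frame of neighborhood records.
#' @param short_contig_genes see [classify_neighborhood()].
#' @return list with `records` (input plus `class`, `caveat`, `relocated`
#'   columns) and `counts` (one row per focal gene with the four class counts,
#'   summing to the number of that gene's records, plus caveat and relocation
#'   tallies).
#' @export
summarize_neighborhoods <- function(records, short_contig_genes = 3L) {
  if (nrow(records) == 0L) stop("no neighborhood records")
  cls <- lapply(seq_len(nrow(records)), function(i)
    classify_neighborhood(records[i, ], short_contig_genes))
  records$class <- vapply(cls, `[[`, character(1), "class")
  records$caveat <- vapply(cls, `[[`, logical(1), "caveat")
  records$relocated <- vapply(cls, `[[`, logical(1), "relocated")
  lev <- c("both_flanks", "left_only", "right_only", "none")
  counts <- do.call(rbind, lapply(split(records, records$focal_gene),
                                  function(g) {
    tab <- table(factor(g$class, levels = lev))
    data.frame(focal_gene = g$focal_gene[1],
               both_flanks = as.integer(tab["both_flanks"]),
               left_only = as.integer(tab["left_only"]),
               right_only = as.integer(tab["right_only"]),
               none = as.integer(tab["none"]),
               n_caveat = sum(g$caveat),
               n_relocated = sum(g$relocated))
  }))
  rownames(counts) <- NULL
  list(records = records, counts = counts)
}
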