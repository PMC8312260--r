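# Nei-Gojobori (1986) counting estimator of dN/dS with pathway averaging and
# Jukes-Cantor correction, plus a column-permutation test for between-gene
# differences in selection intensity. Per-codon site counts and per-codon-pair
# pathway counts are memoized so that permutations over pooled codon columns
# reduce to column-subset sums.

syn_site_table <- function() {
  if (!is.null(.codon_env$syn_sites)) return(.codon_env$syn_sites)
  code <- genetic_code()
  sense <- sense_codons()
  syn <- vapply(sense, function(codon) {
    chars <- strsplit(codon, "")[[1]]
    nsyn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
        mut <- chars
        mut[pos] <- nt
        mutc <- paste(mut, collapse = "")
        # mutations to stops are never synonymous
        if (code[mutc] != "*" && code[mutc] == code[codon]) nsyn <- nsyn + 1
      }
    }
    nsyn / 3
  }, numeric(1))
  .codon_env$syn_sites <- syn
  syn
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' Counts follow the Nei-Gojobori scheme: each of the 9 single-nucleotide
#' mutants of the codon contributes 1/3 of a site at its position, classed
#' synonymous when it preserves the encoded amino acid; mutations to stop
#' codons are never counted as synonymous. The two counts always sum to 3.
#'
#' @param codon a 3-letter unambiguous sense codon.
#' @return named numeric vector `c(syn, nonsyn)`.
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  code <- genetic_code()
  if (is.na(code[codon])) stop("ambiguous base or invalid codon: ", codon)
  if (code[codon] == "*") stop("stop codon: ", codon)
  s <- unname(syn_site_table()[codon])
  c(syn = s, nonsyn = 3 - s)
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons, over all orderings of the single-nucleotide steps; pathways passing
# through a stop codon are excluded. If every pathway is blocked (does not
# occur for sense-sense pairs under the standard code) all pathways are used.
ng86_path_counts <- function(a, b) {
  key <- paste(a, b, sep = "|")
  if (!is.null(.codon_env$paths[[key]])) return(.codon_env$paths[[key]])
  code <- genetic_code()
  ach <- strsplit(a, "")[[1]]
  bch <- strsplit(b, "")[[1]]
  diff <- which(ach != bch)
  perms <- if (length(diff) == 1L) list(diff) else {
    out <- list()
    gen <- function(left, acc) {
      if (!length(left)) out[[length(out) + 1L]] <<- acc
      else for (i in seq_along(left))
        gen(left[-i], c(acc, left[i]))
    }
    gen(diff, integer())
    out
  }
  walk <- function(order) {
    cur <- ach
    sd <- 0
    nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- bch[pos]
      aa1 <- code[paste(cur, collapse = "")]
      aa2 <- code[paste(nxt, collapse = "")]
      if (aa2 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  counts <- Filter(Negate(is.null), lapply(perms, walk))
  if (!length(counts)) {
    # fallback: average over all orderings, counting steps into stops as
    # nonsynonymous
    walk_all <- function(order) {
      cur <- ach; sd <- 0; nd <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- bch[pos]
        aa1 <- code[paste(cur, collapse = "")]
        aa2 <- code[paste(nxt, collapse = "")]
        if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    counts <- lapply(perms, walk_all)
  }
  res <- colMeans(do.call(rbind, counts))
  if (is.null(.codon_env$paths)) .codon_env$paths <- new.env(parent = emptyenv())
  .codon_env$paths[[key]] <- res
  res
}

jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}

# Per-pair, per-codon-column NG86 components for an alignment: average site
# counts (ss, ns) and pathway-averaged difference counts (sd, nd), NA where a
# codon is not comparable (gap or non-sense in either row). Rows index
# unordered sequence pairs, columns index codon columns.
ng86_components <- function(msa) {
  stopifnot(msa$alphabet == "codon")
  cells <- do.call(rbind, lapply(msa$rows, codon_cells))
  syn <- syn_site_table()
  sense <- matrix(cells %in% names(syn), nrow = nrow(cells))
  pairs <- combn(length(msa$ids), 2)
  P <- ncol(pairs)
  C <- ncol(cells)
  ss <- sd <- nd <- matrix(NA_real_, P, C)
  for (p in seq_len(P)) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    ok <- sense[i, ] & sense[j, ]
    ss[p, ok] <- (syn[cells[i, ok]] + syn[cells[j, ok]]) / 2
    sd[p, ok] <- 0
    nd[p, ok] <- 0
    dif <- which(ok & cells[i, ] != cells[j, ])
    for (k in dif) {
      pc <- ng86_path_counts(cells[i, k], cells[j, k])
      sd[p, k] <- pc[1]
      nd[p, k] <- pc[2]
    }
  }
  list(ss = ss, sd = sd, nd = nd, pairs = pairs, ids = msa$ids)
}

# dN/dS summary from components over a column subset. Pairs with no
# comparable codons, dS = 0, or saturated (NA) distances are dropped from the
# means; the dropped count is reported.
omega_from_components <- function(comp, cols = NULL) {
  ss <- comp$ss
  sd <- comp$sd
  nd <- comp$nd
  if (!is.null(cols)) {
    ss <- ss[, cols, drop = FALSE]
    sd <- sd[, cols, drop = FALSE]
    nd <- nd[, cols, drop = FALSE]
  }
  S <- rowSums(ss, na.rm = TRUE)
  n_comp <- rowSums(!is.na(ss))
  N <- 3 * n_comp - S
  Sd <- rowSums(sd, na.rm = TRUE)
  Nd <- rowSums(nd, na.rm = TRUE)
  usable <- n_comp > 0 & S > 0 & N > 0
  pS <- Sd[usable] / S[usable]
  pN <- Nd[usable] / N[usable]
  dS <- jc_correct(pS)
  dN <- jc_correct(pN)
  keep <- !is.na(dS) & !is.na(dN) & dS > 0
  n_dropped <- nrow(ss) - sum(keep)
  if (!sum(keep))
    return(list(dN = NA_real_, dS = NA_real_, omega = NA_real_,
                n_pairs = 0L, n_dropped = n_dropped))
  mdN <- mean(dN[keep])
  mdS <- mean(dS[keep])
  list(dN = mdN, dS = mdS, omega = mdN / mdS,
       n_pairs = sum(keep), n_dropped = n_dropped)
}

#' Pairwise NG86 proportions and distances for two codon sequences
#'
#' Codon positions gapped or non-sense in either row are skipped pairwise.
#' Multi-difference codons are averaged over all orderings of single steps
#' (pathways through stop codons excluded), and the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - 4p/3)` is applied; `d` is `NA` when `p >= 3/4`.
#'
#' @param rowA,rowB aligned codon sequences of equal length (strings).
#' @return named numeric vector `c(pN, pS, dN, dS)`.
#' @export
ng86_pairwise <- function(rowA, rowB) {
  rowA <- toupper(rowA)
  rowB <- toupper(rowB)
  if (nchar(rowA) != nchar(rowB) || nchar(rowA) %% 3L != 0L)
    stop("frame mismatch")
  cellsA <- codon_cells(rowA)
  cellsB <- codon_cells(rowB)
  syn <- syn_site_table()
  ok <- cellsA %in% names(syn) & cellsB %in% names(syn)
  if (!any(ok)) stop("no comparable codons")
  S <- sum((syn[cellsA[ok]] + syn[cellsB[ok]]) / 2)
  N <- 3 * sum(ok) - S
  Sd <- 0
  Nd <- 0
  for (k in which(ok & cellsA != cellsB)) {
    pc <- ng86_path_counts(cellsA[k], cellsB[k])
    Sd <- Sd + pc[1]
    Nd <- Nd + pc[2]
  }
  pS <- Sd / S
  pN <- Nd / N
  c(pN = pN, pS = pS, dN = unname(jc_correct(pN)), dS = unname(jc_correct(pS)))
}

#' Gene-level mean dN, dS and omega
#'
#' Averages pairwise NG86 distances over all unordered sequence pairs of a
#' codon alignment; `omega` is the ratio of the mean dN to the mean dS (not
#' the mean of per-pair ratios). Pairs with `dS = 0` or saturated distances
#' are dropped from the means and counted in `n_dropped`.
#'
#' @param aln a codon [gcg_msa()] with at least 2 sequences.
#' @param gene optional gene label carried into the result.
#' @return list of class `selection_result`: `gene`, `dN`, `dS`, `omega`
#'   (`NA` when no pair has `dS > 0`), `n_pairs`, `n_dropped`.
#' @export
gene_mean_omega <- function(aln, gene = NA_character_) {
  if (length(aln$ids) < 2L) stop("need at least 2 sequences")
  res <- omega_from_components(ng86_components(aln))
  structure(c(list(gene = gene), res), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: dN=%.4f dS=%.4f omega=%.4f (%d pairs, %d dropped)\n",
              x$gene, x$dN, x$dS, x$omega, x$n_pairs, x$n_dropped))
  invisible(x)
}

#' Permutation test for a between-gene difference in omega
#'
#' Tests whether two genes sharing a species set differ in selection
#' intensity. The observed statistic is `|omegaA - omegaB|` from
#' [gene_mean_omega()]. The null is built by pooling the codon columns of
#' both alignments and randomly reassigning columns to two pseudo-genes of
#' the original codon lengths, recomputing the omega difference for each
#' permutation; `p = (1 + #(null >= observed)) / (n_perm + 1)`. Species
#' structure is shared between the pseudo-genes, so the tree-induced
#' covariance of pairwise distances is approximately preserved.
#'
#' @param alnA,alnB codon [gcg_msa()] objects over the same species set.
#' @param n_perm number of permutations, default 1000.
#' @param seed integer seed; results are bit-for-bit reproducible given it.
#' @param geneA,geneB labels for reporting.
#' @return list of class `gene_comparison`: `geneA`, `geneB`, `omegaA`,
#'   `omegaB`, `observed_diff`, `p_value`, `n_permutations`, `seed`.
#' @export
compare_gene_omegas <- function(alnA, alnB, n_perm = 1000L, seed = 1L,
                                geneA = "geneA", geneB = "geneB") {
  if (!setequal(alnA$ids, alnB$ids)) stop("species sets differ")
  ord <- match(alnA$ids, alnB$ids)
  alnB <- gcg_msa(alnB$ids[ord], alnB$rows[ord], "codon", alnB$ref_id)
  compA <- ng86_components(alnA)
  compB <- ng86_components(alnB)
  oA <- omega_from_components(compA)
  oB <- omega_from_components(compB)
  if (is.na(oA$omega) || is.na(oB$omega))
    stop("omega undefined for one of the genes")
  observed <- abs(oA$omega - oB$omega)
  nA <- ncol(compA$ss)
  nB <- ncol(compB$ss)
  pooled <- list(ss = cbind(compA$ss, compB$ss),
                 sd = cbind(compA$sd, compB$sd),
                 nd = cbind(compA$nd, compB$nd))
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nA + nB)
    o1 <- omega_from_components(pooled, idx[seq_len(nA)])
    o2 <- omega_from_components(pooled, idx[nA + seq_len(nB)])
    if (is.na(o1$omega) || is.na(o2$omega)) return(NA_real_)
    abs(o1$omega - o2$omega)
  }, numeric(1))
  null <- null[!is.na(null)]
  p <- (1 + sum(null >= observed)) / (length(null) + 1)
  structure(list(geneA = geneA, geneB = geneB,
                 omegaA = oA$omega, omegaB = oB$omega,
                 observed_diff = observed, p_value = p,
                 n_permutations = length(null), seed = seed),
            class = "gene_comparison")
}

#' @export
print.gene_comparison <- function(x, ...) {
  cat(sprintf("<gene_comparison> %s (omega=%.4f) vs %s (omega=%.4f): |diff|=%.4f, p=%.4g [%d perms, seed %d]\n",
              x$geneA, x$omegaA, x$geneB, x$omegaB, x$observed_diff,
              x$p_value, x$n_permutations, x$seed))
  invisible(x)
}
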