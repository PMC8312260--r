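# Parsimony-based screen for pairs of alignment sites whose substitutions
# fall on the same branches of the species tree. Each column is mapped to its
# minimum-change branch set by Fitch parsimony with a deterministic
# resolution of ambiguous ancestral states; pairs of columns are then tested
# for branch-set overlap with a hypergeometric (Fisher) test and BH FDR
# control, with the per-pair concordance score both/(both + i_only + j_only).

# Postorder/preorder traversal orders for an ape tree, cached per call.
tree_orders <- function(tree) {
  post <- ape::reorder.phylo(tree, "postorder")
  list(post_edges = post$edge, n_tip = length(tree$tip.label),
       n_node = tree$Nnode, root = length(tree$tip.label) + 1L)
}

#' Fitch substitution map of one alignment column
#'
#' Runs the Fitch down-pass (set intersection, else union with a change
#' counted) and a deterministic up-pass: the root takes the alphabetically
#' smallest member of its state set; every other node inherits its parent's
#' resolved state when that state lies in the node's set, otherwise takes its
#' set's alphabetically smallest member. Gap leaves are treated as missing
#' data (the full state set). A branch is in the substitution set iff the
#' resolved parent and child states differ; the branch-set size equals the
#' Fitch parsimony score.
#'
#' @param msa a protein [gcg_msa()] whose ids are the tree's leaf labels.
#' @param tree rooted `ape::phylo` tree.
#' @param column alignment column index.
#' @return list of class `substitution_map`: `column`, `branches` (indices
#'   into `tree$edge` rows), `score`, `states` (resolved state per node).
#' @export
fitch_substitution_map <- function(msa, tree, column) {
  if (!all(tree$tip.label %in% msa$ids))
    stop("species mismatch between alignment and tree")
  chars <- substr(msa$rows, column, column)
  names(chars) <- msa$ids
  leaf_states <- chars[tree$tip.label]
  observed <- sort(unique(leaf_states[leaf_states != "-"]))
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  if (length(observed) <= 1L) {
    st <- rep(if (length(observed)) observed else NA_character_, n_nodes)
    return(structure(list(column = column, branches = integer(),
                          score = 0L, states = st),
                     class = "substitution_map"))
  }
  full <- observed  # restriction to observed states preserves minimum changes
  sets <- vector("list", n_nodes)
  for (i in seq_len(n_tip))
    sets[[i]] <- if (leaf_states[i] == "-") full else leaf_states[i]
  post <- ape::reorder.phylo(tree, "postorder")$edge
  score <- 0L
  # down-pass: children combined pairwise in postorder
  kids <- split(post[, 2], post[, 1])
  internal_post <- unique(post[, 1])  # parents in postorder completion order
  for (node in internal_post) {
    s <- NULL
    for (ch in kids[[as.character(node)]]) {
      if (is.null(s)) {
        s <- sets[[ch]]
      } else {
        inter <- intersect(s, sets[[ch]])
        if (length(inter)) s <- inter
        else {
          s <- union(s, sets[[ch]])
          score <- score + 1L
        }
      }
    }
    sets[[node]] <- sort(s)
  }
  root <- n_tip + 1L
  states <- rep(NA_character_, n_nodes)
  states[root] <- sets[[root]][1]
  pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]
    child <- pre[e, 2]
    states[child] <- if (states[parent] %in% sets[[child]]) states[parent]
      else sets[[child]][1]
  }
  branches <- which(states[tree$edge[, 1]] != states[tree$edge[, 2]])
  stopifnot(length(branches) == score)
  structure(list(column = column, branches = branches, score = score,
                 states = states),
            class = "substitution_map")
}

#' Branch-overlap test for one pair of substitution maps
#'
#' Builds the 2x2 branch table (both, i-only, j-only, neither) for two
#' columns' substitution branch sets and computes the one-sided
#' hypergeometric (Fisher exact) p-value for enrichment of shared branches,
#' together with the concordance score `both / (both + i_only + j_only)`.
#'
#' @param map_i,map_j `substitution_map` objects from the same tree.
#' @param n_branches total number of branches in the tree.
#' @return list of class `cosub_pair`: `column_i`, `column_j`, `both`,
#'   `i_only`, `j_only`, `neither`, `p_value`, `concordance`.
#' @export
cosub_pair_test <- function(map_i, map_j, n_branches) {
  bi <- map_i$branches
  bj <- map_j$branches
  if (n_branches < length(union(bi, bj)))
    stop("n_branches smaller than the branch-set union")
  both <- length(intersect(bi, bj))
  i_only <- length(bi) - both
  j_only <- length(bj) - both
  neither <- n_branches - both - i_only - j_only
  p <- phyper(both - 1, length(bi), n_branches - length(bi), length(bj),
              lower.tail = FALSE)
  conc <- if (both + i_only + j_only == 0) NA_real_ else
    both / (both + i_only + j_only)
  structure(list(column_i = map_i$column, column_j = map_j$column,
                 both = both, i_only = i_only, j_only = j_only,
                 neither = neither, p_value = p, concordance = conc),
            class = "cosub_pair")
}

#' Screen all column pairs for co-substitution
#'
#' Maps every alignment column to its substitution branch set and tests all
#' unordered pairs whose maps are both non-empty (pairs with an empty map are
#' untestable and skipped). P-values are BH-adjusted over the tested pairs;
#' a pair is reported when `q <= fdr` or `concordance >= prob`. With a second
#' alignment the two are concatenated column-wise and, when
#' `cross_only = TRUE`, testing is restricted to cross-partition pairs (one
#' column from each input); pair identities always track the original inputs.
#' Codon alignments are translated to protein first.
#'
#' @param msa protein or codon [gcg_msa()].
#' @param tree rooted `ape::phylo` covering the alignment's species.
#' @param msa2 optional second alignment over the same species.
#' @param cross_only restrict to cross-partition pairs (needs `msa2`).
#' @param fdr BH FDR threshold, default 0.05.
#' @param prob concordance threshold, default 0.5.
#' @return data.frame with one row per tested pair: `partition_i`,
#'   `column_i`, `partition_j`, `column_j`, `both`, `i_only`, `j_only`,
#'   `neither`, `concordance`, `p_value`, `q_value`, `reported`.
#' @export
screen_pairs <- function(msa, tree, msa2 = NULL, cross_only = FALSE,
                         fdr = 0.05, prob = 0.5) {
  if (msa$alphabet == "codon") msa <- translate_msa(msa)
  if (!is.null(msa2) && msa2$alphabet == "codon") msa2 <- translate_msa(msa2)
  if (!setequal(tree$tip.label, msa$ids))
    stop("species mismatch between alignment and tree")
  if (!is.null(msa2) && !setequal(msa2$ids, msa$ids))
    stop("species mismatch between alignments")
  if (cross_only && is.null(msa2)) stop("cross_only requires msa2")
  n1 <- msa_ncol(msa)
  n2 <- if (is.null(msa2)) 0L else msa_ncol(msa2)
  maps <- c(lapply(seq_len(n1), function(k)
              fitch_substitution_map(msa, tree, k)),
            if (n2) lapply(seq_len(n2), function(k)
              fitch_substitution_map(msa2, tree, k)))
  partition <- rep(c("A", "B"), c(n1, n2))
  orig_col <- c(seq_len(n1), seq_len(n2))
  nb <- nrow(tree$edge)
  nonempty <- which(vapply(maps, function(m) length(m$branches) > 0,
                           logical(1)))
  if (length(nonempty) < 2L)
    return(data.frame(partition_i = character(), column_i = integer(),
                      partition_j = character(), column_j = integer(),
                      both = integer(), i_only = integer(),
                      j_only = integer(), neither = integer(),
                      concordance = numeric(), p_value = numeric(),
                      q_value = numeric(), reported = logical()))
  idx <- combn(nonempty, 2)
  if (cross_only) {
    keep <- partition[idx[1, ]] != partition[idx[2, ]]
    idx <- idx[, keep, drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]
    j <- idx[2, k]
    t <- cosub_pair_test(maps[[i]], maps[[j]], nb)
    data.frame(partition_i = partition[i], column_i = orig_col[i],
               partition_j = partition[j], column_j = orig_col[j],
               both = t$both, i_only = t$i_only, j_only = t$j_only,
               neither = t$neither, concordance = t$concordance,
               p_value = t$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$reported <- out$q_value <= fdr | out$concordance >= prob
  out
}
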