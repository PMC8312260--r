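# Small in-code fixture builders shared across the suite.

# Alignment from named sequences; first id is the reference unless given.
make_msa <- function(..., alphabet = "protein", ref_id = NULL) {
  seqs <- c(...)
  gcg_msa(names(seqs), unname(seqs), alphabet,
          ref_id = ref_id %||% names(seqs)[1])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Four-taxon balanced tree used throughout the co-substitution tests.
quartet_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# A mature-only (no signal peptide) single-region map for toy comparisons.
toy_region_map <- function(len = 5L)
  region_map(regions = list(pep = c(1L, len)), signal_peptide_len = 0L,
             mature_len = len)

# Gapless precursor alignment where every row equals the reference except for
# listed edits; edits is a list(species = list(c(col, "X"), ...)).
edited_precursor_msa <- function(n_species = 4, seed = 42, edits = list()) {
  set.seed(seed)
  ref <- paste(sample(c("A", "G", "S", "T", "H", "Q"), 180, replace = TRUE),
               collapse = "")
  ids <- c("Homo_sapiens", sprintf("sp%02d", seq_len(n_species - 1)))
  rows <- rep(ref, n_species)
  names(rows) <- ids
  for (sp in names(edits)) for (e in edits[[sp]])
    substr(rows[sp], as.integer(e[1]), as.integer(e[1])) <- e[2]
  gcg_msa(ids, unname(rows), "protein", ref_id = "Homo_sapiens")
}

# Hand-built difference table (bypasses alignments) for summary arithmetic.
make_diff_table <- function(n_diff, substitutions, region = "pep",
                            peptide_len = 10L) {
  dt <- data.frame(species = sprintf("s%d", seq_along(n_diff)),
                   n_diff = as.integer(n_diff),
                   n_gap_cols = 0L)
  dt$substitutions <- substitutions
  attr(dt, "region") <- region
  attr(dt, "peptide_len") <- peptide_len
  class(dt) <- c("difference_table", "data.frame")
  dt
}

# Independent oracle: NG86-style site/difference counts computed from
# Biostrings' genetic code, structured differently from the package path.
oracle_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

oracle_site_counts <- function(codon) {
  code <- oracle_code()
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
    mut <- chars; mut[pos] <- nt
    mutc <- paste(mut, collapse = "")
    if (code[mutc] != "*" && code[mutc] == code[codon]) syn <- syn + 1
  }
  c(syn / 3, 3 - syn / 3)
}

# Brute-force pathway enumeration between two sense codons.
oracle_path_counts <- function(a, b) {
  code <- oracle_code()
  ach <- strsplit(a, "")[[1]]; bch <- strsplit(b, "")[[1]]
  diff <- which(ach != bch)
  if (!length(diff)) return(c(0, 0))
  perm <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perm(v[-i]), function(p) c(v[i], p))))
  res <- list()
  for (ord in perm(diff)) {
    cur <- ach; sd <- 0; nd <- 0; okpath <- TRUE
    for (pos in ord) {
      nxt <- cur; nxt[pos] <- bch[pos]
      if (code[paste(nxt, collapse = "")] == "*") { okpath <- FALSE; break }
      if (code[paste(cur, collapse = "")] ==
          code[paste(nxt, collapse = "")]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (okpath) res[[length(res) + 1]] <- c(sd, nd)
  }
  if (!length(res)) return(NULL)
  colMeans(do.call(rbind, res))
}

# Exhaustive minimum-change count for one column on a rooted binary tree.
oracle_parsimony_score <- function(tree, leaf_states) {
  states <- sort(unique(leaf_states[leaf_states != "-"]))
  if (length(states) <= 1) return(0L)
  n_tip <- length(tree$tip.label)
  internal <- n_tip + seq_len(tree$Nnode)
  grids <- rep(list(states), length(internal))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- character(n_tip + tree$Nnode)
    lab[seq_len(n_tip)] <- leaf_states[tree$tip.label]
    lab[internal] <- unlist(combos[r, ])
    changes <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (lab[ch] == "-") next  # missing leaf: free
      if (lab[p] != lab[ch]) changes <- changes + 1L
    }
    best <- min(best, changes)
  }
  as.integer(best)
}
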