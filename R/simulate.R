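# Seeded generators for every input the pipeline consumes, with known ground
# truth for recovery tests. All generators are pure functions of their
# arguments and seed: identical calls give byte-identical outputs.

#' Simulate a Yule species tree
#'
#' A pure-birth tree on `n_taxa` leaves, rescaled to unit height so that
#' `base_rate` in the sequence simulators reads as expected substitutions per
#' site from root to tip. Tips are labelled `sp01`, `sp02`, ...
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @return rooted ultrametric `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  if (n_taxa < 2L) stop("n_taxa must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%02d", seq_len(n_taxa))
  tree
}

# Edges ordered parents-before-children (reverse postorder).
preorder_edges <- function(tree) {
  post <- ape::reorder.phylo(tree, "postorder")
  idx <- rev(seq_len(nrow(post$edge)))
  list(edge = post$edge[idx, , drop = FALSE],
       length = post$edge.length[idx])
}

#' Simulate a precursor protein alignment along a tree
#'
#' A Poisson substitution process with per-site rate multipliers taken from a
#' region map: each region named in `region_rates` evolves at
#' `multiplier * base_rate` expected substitutions per site over a unit-height
#' tree; unassigned positions (including the signal peptide) use multiplier 1.
#' Replacement residues are drawn uniformly over the 19 non-identical amino
#' acids, and multiple events on one branch collapse to a single visible
#' change.
#' Optional coupled column pairs force the second column of a pair to
#' substitute on exactly the branches where the first does. The reference row
#' is a designated extant leaf; rows are full precursors (signal + mature).
#'
#' @param tree `ape::phylo` species tree.
#' @param rm a [region_map()]; simulated length is
#'   `signal_peptide_len + mature_len`.
#' @param region_rates named list/vector of rate multipliers by region name.
#' @param base_rate expected substitutions/site over the tree for rate-1
#'   sites; default 0.3.
#' @param seed integer seed.
#' @param ref_id reference leaf; default the first tip.
#' @param coupled_pairs list of `c(i, j)` alignment column pairs (precursor
#'   numbering) forced to co-substitute.
#' @return a protein [gcg_msa()] with attribute `truth` (site rates, coupled
#'   pairs, per-branch substitution columns).
#' @export
simulate_precursor_alignment <- function(tree, rm = region_map(),
                                         region_rates = list(),
                                         base_rate = 0.3, seed = 1L,
                                         ref_id = NULL,
                                         coupled_pairs = list()) {
  L <- rm$signal_peptide_len + rm$mature_len
  rates <- rep(1, L)
  for (nm in names(region_rates)) {
    r <- rm$regions[[nm]]
    if (is.null(r)) stop("unknown region in region_rates: ", nm)
    rates[(r[1]:r[2]) + rm$signal_peptide_len] <- region_rates[[nm]]
  }
  for (cp in coupled_pairs)
    if (length(cp) != 2L || any(cp < 1L) || any(cp > L))
      stop("invalid coupled pair")
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  seqs <- matrix(NA_character_, n_nodes, L)
  root <- n_tip + 1L
  seqs[root, ] <- sample(AA_ALPHABET, L, replace = TRUE)
  pre <- preorder_edges(tree)
  sub_branches <- vector("list", nrow(pre$edge))
  for (e in seq_len(nrow(pre$edge))) {
    parent <- pre$edge[e, 1]
    child <- pre$edge[e, 2]
    k <- rpois(L, rates * base_rate * pre$length[e])
    for (cp in coupled_pairs) k[cp[2]] <- as.integer(k[cp[1]] > 0L)
    hit <- k > 0L
    row <- seqs[parent, ]
    # replacement drawn uniformly from the 19 other residues: a substitution
    # event always changes the residue
    cur <- match(row[hit], AA_ALPHABET)
    off <- sample.int(19L, sum(hit), replace = TRUE)
    row[hit] <- AA_ALPHABET[off + (off >= cur)]
    seqs[child, ] <- row
    sub_branches[[e]] <- which(hit)
  }
  rows <- apply(seqs[seq_len(n_tip), , drop = FALSE], 1, paste, collapse = "")
  out <- gcg_msa(tree$tip.label, rows, "protein",
                 ref_id %||% tree$tip.label[1])
  attr(out, "truth") <- list(site_rates = rates, base_rate = base_rate,
                             coupled_pairs = coupled_pairs,
                             branch_substitutions = sub_branches)
  out
}

#' Simulate a codon alignment with a target dN/dS
#'
#' A proposal/acceptance scheme along the tree: nucleotide proposals arrive
#' at rate `base_rate` per site, the mutant nucleotide is drawn with
#' transition:transversion weighting `kappa`, proposals creating stop codons
#' are rejected, synonymous proposals are always accepted, and nonsynonymous
#' proposals are accepted with probability `min(1, omega)`. This is not an
#' exact M0 process; recovery tests use ordering and interval checks.
#'
#' @param tree `ape::phylo` species tree.
#' @param n_codons number of codons.
#' @param omega nonsynonymous acceptance probability (> 0).
#' @param kappa transition/transversion proposal weight, default 2.
#' @param base_rate proposal rate per nucleotide site per unit branch length,
#'   default 0.4.
#' @param seed integer seed.
#' @param ref_id reference leaf; default the first tip.
#' @return a codon [gcg_msa()] with attribute `truth` (omega, kappa,
#'   accepted substitution counts).
#' @export
simulate_codon_alignment <- function(tree, n_codons, omega, kappa = 2,
                                     base_rate = 0.4, seed = 1L,
                                     ref_id = NULL) {
  if (omega < 0) stop("omega must be >= 0")
  set.seed(seed)
  code <- genetic_code()
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  root <- n_tip + 1L
  seqs <- vector("list", n_nodes)
  seqs[[root]] <- sample(sense_codons(), n_codons, replace = TRUE)
  pre <- preorder_edges(tree)
  n_syn_acc <- 0L
  n_nonsyn_acc <- 0L
  for (e in seq_len(nrow(pre$edge))) {
    codons <- seqs[[pre$edge[e, 1]]]
    n_prop <- rpois(1, base_rate * 3 * n_codons * pre$length[e])
    if (n_prop > 0) for (dummy in seq_len(n_prop)) {
      pos <- sample.int(3L * n_codons, 1L)
      ci <- (pos - 1L) %/% 3L + 1L
      off <- (pos - 1L) %% 3L + 1L
      codon <- codons[ci]
      cur <- substr(codon, off, off)
      alts <- setdiff(c("A", "C", "G", "T"), cur)
      w <- ifelse(alts == transitions[cur], kappa, 1)
      nt <- sample(alts, 1L, prob = w)
      mut <- codon
      substr(mut, off, off) <- nt
      if (code[mut] == "*") next
      if (code[mut] == code[codon]) {
        codons[ci] <- mut
        n_syn_acc <- n_syn_acc + 1L
      } else if (runif(1) < min(1, omega)) {
        codons[ci] <- mut
        n_nonsyn_acc <- n_nonsyn_acc + 1L
      }
    }
    seqs[[pre$edge[e, 2]]] <- codons
  }
  rows <- vapply(seqs[seq_len(n_tip)], paste, character(1), collapse = "")
  out <- gcg_msa(tree$tip.label, rows, "codon", ref_id %||% tree$tip.label[1])
  attr(out, "truth") <- list(omega = omega, kappa = kappa,
                             n_syn_accepted = n_syn_acc,
                             n_nonsyn_accepted = n_nonsyn_acc)
  out
}

#' Simulate gene-neighborhood records
#'
#' Each record starts with both expected flanks present. Independently per
#' side, the flank is lost to contig truncation with probability
#' `truncation_prob` (setting the contig edge on that side and a small contig
#' gene count), otherwise lost to relocation with probability
#' `relocation_prob` (flank absent with no contig edge, and recorded as found
#' elsewhere in the assembly).
#'
#' @param n number of records (species).
#' @param truncation_prob per-side probability of contig truncation.
#' @param relocation_prob per-side probability of relocation given no
#'   truncation.
#' @param seed integer seed.
#' @param focal_gene,expected_left,expected_right gene symbols for the
#'   records; defaults mirror the proglucagon neighborhood (FAP, DPP4).
#' @return data.frame of neighborhood records with attribute `truth`
#'   (the probabilities and the expected both-flank fraction
#'   `((1-t)(1-r))^2`).
#' @export
simulate_neighborhoods <- function(n, truncation_prob = 0.05,
                                   relocation_prob = 0, seed = 1L,
                                   focal_gene = "Gcg",
                                   expected_left = "FAP",
                                   expected_right = "DPP4") {
  stopifnot(truncation_prob >= 0, truncation_prob <= 1,
            relocation_prob >= 0, relocation_prob <= 1)
  set.seed(seed)
  side_state <- function(n) {
    u <- runif(n)
    v <- runif(n)
    ifelse(u < truncation_prob, "truncated",
           ifelse(v < relocation_prob, "relocated", "present"))
  }
  left <- side_state(n)
  right <- side_state(n)
  edge <- ifelse(left == "truncated" & right == "truncated", "both",
                 ifelse(left == "truncated", "left",
                        ifelse(right == "truncated", "right", "none")))
  any_trunc <- edge != "none"
  count <- integer(n)
  count[any_trunc] <- sample(1:3, sum(any_trunc), replace = TRUE)
  count[!any_trunc] <- sample(10:50, sum(!any_trunc), replace = TRUE)
  out <- data.frame(species = sprintf("sim_sp%04d", seq_len(n)),
                    focal_gene = focal_gene,
                    expected_left = expected_left,
                    expected_right = expected_right,
                    left_found = left == "present",
                    right_found = right == "present",
                    at_contig_edge = edge,
                    contig_gene_count = count,
                    left_elsewhere = left == "relocated",
                    right_elsewhere = right == "relocated")
  p_side <- (1 - truncation_prob) * (1 - relocation_prob)
  attr(out, "truth") <- list(truncation_prob = truncation_prob,
                             relocation_prob = relocation_prob,
                             expected_both_fraction = p_side^2)
  out
}

#' Inject a processing-site disruption into one species
#'
#' Replaces the residue(s) at chosen positions of a processing site with a
#' given residue for a single species, leaving every other cell untouched, so
#' that [check_site_integrity()] subsequently reports `disrupted` for exactly
#' that species. Injecting a residue of the site's required class is a no-op
#' disruption and warns.
#'
#' @param msa protein [gcg_msa()] of precursors.
#' @param species target species identifier.
#' @param spec a [site_spec()].
#' @param replacement single replacement residue.
#' @param rm a [region_map()].
#' @param which_positions region-relative positions to overwrite; default all
#'   positions of the spec. Must be a subset of `spec$positions`.
#' @param precursor passed to [map_region_to_columns()].
#' @return the modified alignment.
#' @export
inject_disruption <- function(msa, species, spec, replacement,
                              rm = region_map(),
                              which_positions = spec$positions,
                              precursor = TRUE) {
  i <- match(normalize_id(species), msa$ids)
  if (is.na(i)) stop("unknown species: ", species)
  if (!all(which_positions %in% spec$positions))
    stop("which_positions must be a subset of the site's positions")
  replacement <- toupper(replacement)
  if (replacement %in% spec$required_class)
    warning("no-op disruption: replacement residue is in the required class")
  cols <- map_region_to_columns(msa, rm, spec$region, precursor = precursor)
  for (p in which_positions)
    substr(msa$rows[i], cols[p], cols[p]) <- replacement
  msa
}

#' Write a complete synthetic input bundle
#'
#' Generates and writes every input the pipeline consumes: a species tree, a
#' precursor protein alignment with region-rate heterogeneity, intact
#' processing sites in every species except injected disruptions in chosen
#' taxa, three codon alignments with distinct omegas
#' (constraint ordering mirroring Glp1r < Gcgr < Glp2r), a neighborhood
#' table, synthetic ligand/G-protein site lists, the region map, a run config,
#' and a ground-truth JSON.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving every generator.
#' @param n_taxa taxa in the tree, default 16.
#' @param n_codons codons per receptor gene, default 200.
#' @param omegas named vector of per-gene omegas, default
#'   `c(Glp1r = 0.05, Gcgr = 0.10, Glp2r = 0.25)`.
#' @param region_rates region rate multipliers, default glucagon 0.5,
#'   GLP-1 7-37 0.4, GLP-2 3.0.
#' @param disrupt_species species (by index) receiving a miniglucagon-site
#'   disruption, default the last tip.
#' @return named list of written paths plus the `truth` list, invisibly.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, n_taxa = 16L,
                            n_codons = 200L,
                            omegas = c(Glp1r = 0.05, Gcgr = 0.10,
                                       Glp2r = 0.25),
                            region_rates = list(glucagon = 0.5,
                                                `GLP-1_7-37` = 0.4,
                                                `GLP-2` = 3.0),
                            disrupt_species = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rm <- region_map()
  tree <- simulate_tree(n_taxa, seed = seed)
  gcg <- simulate_precursor_alignment(tree, rm, region_rates = region_rates,
                                      seed = seed + 1L)
  # give every species intact processing sites, then disrupt the chosen ones
  for (s in default_site_specs()) {
    cols <- map_region_to_columns(gcg, rm, s$region)
    for (i in seq_along(gcg$ids)) {
      substr(gcg$rows[i], cols[s$positions[1]], cols[s$positions[1]]) <- "K"
      substr(gcg$rows[i], cols[s$positions[2]], cols[s$positions[2]]) <- "R"
    }
  }
  spec <- default_site_specs()[[1]]
  disrupt_species <- disrupt_species %||% tree$tip.label[n_taxa]
  for (sp in disrupt_species)
    gcg <- inject_disruption(gcg, sp, spec, "L", rm,
                             which_positions = 18L)
  genes <- names(omegas)
  alns <- lapply(seq_along(omegas), function(i)
    simulate_codon_alignment(tree, n_codons, omegas[[i]],
                             seed = seed + 1L + i))
  names(alns) <- genes
  nbr <- simulate_neighborhoods(200L, truncation_prob = 0.05,
                                relocation_prob = 0.02, seed = seed + 10L)
  # synthetic interaction-site lists on the first receptor's translation
  prot_len <- n_codons
  set.seed(seed + 20L)
  lig_pos <- sort(sample.int(prot_len, 25L))
  gp_pos <- sort(sample.int(prot_len, 17L))
  wootten <- function(p) sprintf("%d.%02d", (p %% 7) + 1L, p %% 60)
  lig <- site_set(genes[1], "ligand", lig_pos, wootten(lig_pos),
                  note = "synthetic")
  gp <- site_set(genes[1], "gprotein", gp_pos, wootten(gp_pos),
                 note = "synthetic")
  paths <- list(tree = file.path(out_dir, "tree.nwk"),
                gcg = file.path(out_dir, "gcg_precursor.fasta"),
                region_map = file.path(out_dir, "region_map.yaml"),
                neighborhoods = file.path(out_dir, "neighborhoods.tsv"),
                ligand_sites = file.path(out_dir, "ligand_sites.tsv"),
                gprotein_sites = file.path(out_dir, "gprotein_sites.tsv"),
                config = file.path(out_dir, "config.yaml"),
                truth = file.path(out_dir, "truth.json"))
  for (g in genes)
    paths[[g]] <- file.path(out_dir, paste0(tolower(g), "_codon.fasta"))
  ape::write.tree(tree, paths$tree)
  write_alignment(gcg, paths$gcg)
  write_region_map(rm, paths$region_map, sites = default_site_specs())
  write.table(nbr, paths$neighborhoods, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_site_list(lig, paths$ligand_sites)
  write_site_list(gp, paths$gprotein_sites)
  for (g in genes) write_alignment(alns[[g]], paths[[g]])
  truth <- list(seed = seed, omegas = as.list(omegas),
                region_rates = region_rates,
                disrupted_species = as.list(disrupt_species),
                neighborhood = attr(nbr, "truth"))
  cfg <- list(seed = seed,
              tree_path = "tree.nwk",
              region_map_path = "region_map.yaml",
              alignment_paths = c(list(Gcg = "gcg_precursor.fasta"),
                                  setNames(as.list(paste0(tolower(genes),
                                                          "_codon.fasta")),
                                           genes)),
              site_list_paths = list(ligand = "ligand_sites.tsv",
                                     gprotein = "gprotein_sites.tsv"),
              neighborhood_path = "neighborhoods.tsv",
              exclude_species = list(),
              thresholds = list(tolerance_cut = 0.05, delta_cut = -2.5,
                                coevo_fdr = 0.05, coevo_prob = 0.5))
  yaml::write_yaml(cfg, paths$config)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(truth_data = truth)))
}
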