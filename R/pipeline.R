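#' Run the full analysis pipeline from one configuration
#'
#' Executes the requested stages in dependency order against the inputs named
#' in the config and returns a report bundle of tables mirroring the
#' package's headline outputs: per-region variability, processing-site
#' integrity, neighborhood class counts, between-gene selection comparisons,
#' co-substitution pairs, and interaction-site summaries. The
#' `exclude_species` list is applied to every alignment before any stage.
#' Identical config and seed reproduce every table bit-for-bit.
#'
#' @param config a `gcg_config` from [read_run_config()], or an equivalent
#'   named list with resolved paths.
#' @param stages subset of `c("profile", "regions", "synteny", "dnds",
#'   "coevolve", "sites")`; default all.
#' @param n_perm permutations for the between-gene omega test, default 200.
#' @return list of class `report_bundle`: one element per executed stage plus
#'   `meta` (seed, thresholds, config hash, package version).
#' @export
run_pipeline <- function(config,
                         stages = c("profile", "regions", "synteny", "dnds",
                                    "coevolve", "sites"),
                         n_perm = 200L) {
  stages <- match.arg(stages, several.ok = TRUE)
  th <- config$thresholds %||% list(tolerance_cut = 0.05, delta_cut = -2.5,
                                    coevo_fdr = 0.05, coevo_prob = 0.5)
  seed <- as.integer(config$seed %||% 1L)
  excl <- as.character(config$exclude_species %||% character())
  fail <- function(stage, msg) stop(sprintf("[%s] %s", stage, msg),
                                    call. = FALSE)
  load_stage <- function(stage, expr) tryCatch(expr, error = function(e)
    fail(stage, conditionMessage(e)))
  bundle <- list()

  needs_gcg <- any(c("profile", "regions", "coevolve") %in% stages)
  if (needs_gcg) {
    rm_in <- load_stage("precursor_regions",
                        read_region_map(config$region_map_path))
    rm <- rm_in$region_map
    sites_specs <- if (length(rm_in$sites)) rm_in$sites else
      default_site_specs()
    gcg_path <- config$alignment_paths[["Gcg"]] %||%
      config$alignment_paths[[1]]
    gcg <- load_stage("core_io",
                      read_alignment(gcg_path, "protein",
                                     ref_id = config$ref_id %||%
                                       default_ref(gcg_path)))
    if (length(excl)) gcg <- msa_exclude(gcg, excl)
  }

  if ("profile" %in% stages)
    bundle$variability <- load_stage("variability_profile",
                                     region_variability_table(gcg, rm))

  if ("regions" %in% stages)
    bundle$site_integrity <- load_stage("precursor_regions",
      do.call(rbind, lapply(sites_specs, function(s)
        check_site_integrity(gcg, rm, s))))

  if ("synteny" %in% stages) {
    recs <- load_stage("synteny_neighborhood",
                       read_neighborhood_table(config$neighborhood_path))
    if (length(excl)) recs <- recs[!recs$species %in% excl, , drop = FALSE]
    bundle$synteny <- load_stage("synteny_neighborhood",
                                 summarize_neighborhoods(recs)$counts)
  }

  gene_names <- setdiff(names(config$alignment_paths %||% list()), "Gcg")
  if ("dnds" %in% stages) {
    if (length(gene_names) < 2L) fail("selection_dnds",
                                      "need at least two receptor genes")
    alns <- load_stage("selection_dnds", lapply(gene_names, function(g)
      read_alignment(config$alignment_paths[[g]], "codon",
                     ref_id = default_ref(config$alignment_paths[[g]]))))
    names(alns) <- gene_names
    if (length(excl)) alns <- lapply(alns, msa_exclude, species = excl)
    sel <- do.call(rbind, lapply(gene_names, function(g) {
      r <- gene_mean_omega(alns[[g]], gene = g)
      data.frame(gene = g, dN = r$dN, dS = r$dS, omega = r$omega,
                 n_pairs = r$n_pairs, n_dropped = r$n_dropped)
    }))
    prs <- combn(gene_names, 2)
    cmp <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      a <- prs[1, k]
      b <- prs[2, k]
      r <- compare_gene_omegas(alns[[a]], alns[[b]], n_perm = n_perm,
                               seed = seed + k, geneA = a, geneB = b)
      data.frame(geneA = a, geneB = b, omegaA = r$omegaA, omegaB = r$omegaB,
                 observed_diff = r$observed_diff, p_value = r$p_value,
                 n_permutations = r$n_permutations, seed = r$seed)
    }))
    # raw permutation p for up to 3 gene pairs; BH across pairs beyond that
    cmp$p_adjusted <- if (ncol(prs) > 3L) p.adjust(cmp$p_value, "BH") else
      cmp$p_value
    bundle$selection <- sel
    bundle$selection_comparisons <- cmp
  }

  if ("coevolve" %in% stages) {
    tree <- load_stage("coevolution_screen",
                       read_species_tree(config$tree_path))
    if (length(excl)) tree <- ape::drop.tip(tree, excl)
    bundle$cosubstitution <- load_stage("coevolution_screen", {
      miss <- setdiff(tree$tip.label, gcg$ids)
      if (length(miss)) stop("tree leaves absent from alignment: ",
                             paste(miss, collapse = ", "))
      res <- screen_pairs(gcg, tree, fdr = th$coevo_fdr,
                          prob = th$coevo_prob)
      res[res$reported, , drop = FALSE]
    })
  }

  if ("sites" %in% stages) {
    if (is.null(config$site_list_paths)) fail("receptor_sites",
                                              "no site lists configured")
    rec_gene <- gene_names[1]
    rec_aln <- load_stage("receptor_sites",
      translate_msa(read_alignment(config$alignment_paths[[rec_gene]],
                                   "codon",
                                   ref_id = default_ref(
                                     config$alignment_paths[[rec_gene]]))))
    if (length(excl)) rec_aln <- msa_exclude(rec_aln, excl)
    bundle$site_summaries <- load_stage("receptor_sites",
      do.call(rbind, lapply(config$site_list_paths, function(p) {
        ss <- read_site_list(p)
        tbl <- categorize_sites(rec_aln, ss)
        summarize_site_table(tbl)
      })))
  }

  bundle$meta <- list(seed = seed, thresholds = th,
                      config_hash = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("gcgevo")),
                      stages = stages)
  class(bundle) <- "report_bundle"
  bundle
}

# First sequence id of a FASTA file, used as the reference for synthetic
# bundles where no explicit ref_id is configured.
default_ref <- function(path) {
  hdr <- readLines(path, n = 1L)
  normalize_id(sub("^>", "", hdr))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

#' Write a report bundle to disk
#'
#' One TSV per table plus a JSON run summary carrying the seed, thresholds,
#' and config hash.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- setdiff(names(bundle), "meta")
  paths <- character()
  for (nm in tables) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    tab <- bundle[[nm]]
    tab[] <- lapply(tab, function(col)
      if (is.list(col)) vapply(col, paste, character(1), collapse = ",")
      else col)
    write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[nm] <- p
  }
  jp <- file.path(dir, "run_summary.json")
  jsonlite::write_json(bundle$meta, jp, auto_unbox = TRUE, digits = NA)
  paths["meta"] <- jp
  invisible(paths)
}
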