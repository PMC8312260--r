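#' Proglucagon peptide region map
#'
#' Named peptide regions as 1-based inclusive intervals on the ungapped mature
#' reference precursor (human numbering). The default table covers the
#' classical proglucagon-derived peptides: GRPP, glicentin, glucagon,
#' miniglucagon (glucagon 19-29), oxyntomodulin (OXM), IP-1, GLP-1 (1-37 and
#' 7-37 forms), IP-2, GLP-2, and the major proglucagon fragment (MPGF). The
#' signal peptide is handled as a single fixed offset (default 20 residues)
#' applied when lifting regions onto full-precursor alignments.
#'
#' @param regions named list of `c(start, end)` integer pairs (mature
#'   numbering). Defaults to the standard human annotation.
#' @param signal_peptide_len signal peptide length in residues, default 20.
#' @param mature_len length of the mature reference precursor, default 160.
#' @return an object of class `region_map`.
#' @export
region_map <- function(regions = NULL, signal_peptide_len = 20L,
                       mature_len = 160L) {
  if (is.null(regions)) {
    regions <- list(
      GRPP           = c(1L, 30L),
      glicentin      = c(1L, 69L),
      glucagon       = c(33L, 61L),
      miniglucagon   = c(51L, 61L),
      OXM            = c(33L, 69L),
      `IP-1`         = c(62L, 69L),
      `GLP-1_1-37`   = c(72L, 108L),
      `GLP-1_7-37`   = c(78L, 108L),
      `IP-2`         = c(111L, 122L),
      `GLP-2`        = c(126L, 158L),
      MPGF           = c(72L, 158L))
  }
  regions <- lapply(regions, function(r) as.integer(r[1:2]))
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (is.na(r[1]) || is.na(r[2]) || r[1] < 1L || r[1] > r[2])
      stop("invalid interval for region ", nm)
    if (r[2] > mature_len)
      stop("region out of range: ", nm, " extends past the mature reference")
  }
  contains <- function(outer, inner)
    regions[[outer]][1] <= regions[[inner]][1] &&
      regions[[outer]][2] >= regions[[inner]][2]
  if (all(c("glucagon", "miniglucagon") %in% names(regions)) &&
      !contains("glucagon", "miniglucagon"))
    stop("miniglucagon must be nested in glucagon")
  if (all(c("OXM", "glucagon", "IP-1") %in% names(regions))) {
    ok <- regions$OXM[1] == regions$glucagon[1] &&
      regions$OXM[2] == regions$`IP-1`[2] &&
      regions$`IP-1`[1] == regions$glucagon[2] + 1L
    if (!ok) stop("OXM must be the union of glucagon and IP-1")
  }
  if (all(c("glicentin", "GRPP", "glucagon", "IP-1") %in% names(regions)) &&
      !(contains("glicentin", "GRPP") && contains("glicentin", "glucagon") &&
        contains("glicentin", "IP-1")))
    stop("glicentin must contain GRPP, glucagon, and IP-1")
  structure(list(signal_peptide_len = as.integer(signal_peptide_len),
                 mature_len = as.integer(mature_len),
                 regions = regions),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("<region_map> signal %d aa, mature %d aa, %d regions\n",
              x$signal_peptide_len, x$mature_len, length(x$regions)))
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %3d-%3d\n", nm, x$regions[[nm]][1],
                x$regions[[nm]][2]))
  invisible(x)
}

#' Read / write a region map as YAML
#'
#' @param path YAML file with keys `signal_peptide_len`, `mature_len`,
#'   `regions` (name to `[start, end]`), and optionally `sites` (a list of
#'   processing-site specs).
#' @return `read_region_map`: a list with elements `region_map` and `sites`
#'   (possibly empty); `write_region_map`: `path`, invisibly.
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  rm <- region_map(regions = y$regions,
                   signal_peptide_len = y$signal_peptide_len %||% 20L,
                   mature_len = y$mature_len %||% 160L)
  sites <- lapply(y$sites %||% list(), function(s)
    site_spec(s$name, s$region, unlist(s$positions),
              unlist(s$required_class %||% c("K", "R"))))
  list(region_map = rm, sites = sites)
}

#' @rdname read_region_map
#' @param rm a [region_map()].
#' @param sites optional list of [site_spec()] objects.
#' @export
write_region_map <- function(rm, path, sites = list()) {
  y <- list(signal_peptide_len = rm$signal_peptide_len,
            mature_len = rm$mature_len,
            regions = rm$regions,
            sites = lapply(sites, function(s)
              list(name = s$name, region = s$region,
                   positions = s$positions,
                   required_class = s$required_class)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Processing-site specification
#'
#' A named set of region-relative residue positions that must all hold a
#' residue of a required class (default the basic residues K/R) for a
#' proteolytic processing site to be considered intact. The bundled defaults
#' describe the dibasic site at glucagon residues 17-18 required for
#' miniglucagon production, and the basic pair immediately following GLP-1
#' required for GLP-1 C-terminal processing.
#'
#' @param name site name.
#' @param region region (in a [region_map()]) the positions refer to.
#' @param positions 1-based region-relative residue indices.
#' @param required_class residue class, default `c("K", "R")`.
#' @return an object of class `site_spec`.
#' @export
site_spec <- function(name, region, positions, required_class = c("K", "R")) {
  structure(list(name = name, region = region,
                 positions = as.integer(positions),
                 required_class = toupper(required_class)),
            class = "site_spec")
}

#' Default processing-site specs
#'
#' @return list of [site_spec()]: the miniglucagon dibasic site (glucagon
#'   17-18) and the GLP-1 C-terminal basic pair (the two residues immediately
#'   after GLP-1 1-37, i.e. MPGF positions 38-39).
#' @export
default_site_specs <- function() {
  list(site_spec("miniglucagon_cleavage", "glucagon", c(17L, 18L)),
       site_spec("glp1_cterm_cleavage", "MPGF", c(38L, 39L)))
}

#' Lift a peptide region onto alignment columns
#'
#' Returns, in order, the alignment columns holding the reference species'
#' ungapped residues `start..end` of the region. When the alignment holds
#' full precursors (the default), the signal-peptide offset of the region map
#' is applied first.
#'
#' @param msa a protein [gcg_msa()].
#' @param rm a [region_map()].
#' @param region_name region to lift.
#' @param precursor if `TRUE` (default) rows are full precursors and the
#'   signal-peptide offset is applied; if `FALSE` rows are mature sequences.
#' @return integer vector of alignment column indices, one per region residue.
#' @export
map_region_to_columns <- function(msa, rm, region_name, precursor = TRUE) {
  r <- rm$regions[[region_name]]
  if (is.null(r)) stop("unknown region: ", region_name)
  offset <- if (precursor) rm$signal_peptide_len else 0L
  target <- (r[1]:r[2]) + offset
  refchars <- strsplit(msa_row(msa, msa$ref_id), "")[[1]]
  ungapped_cols <- which(refchars != "-")
  if (max(target) > length(ungapped_cols))
    stop("region out of range: ", region_name)
  ungapped_cols[target]
}

#' Extract a peptide from an ungapped mature precursor
#'
#' @param precursor ungapped mature precursor sequence (single string).
#' @param rm a [region_map()].
#' @param region_name region to extract.
#' @return the peptide sequence; its length is `end - start + 1`.
#' @export
extract_peptide <- function(precursor, rm, region_name) {
  r <- rm$regions[[region_name]]
  if (is.null(r)) stop("unknown region: ", region_name)
  if (r[2] > nchar(precursor)) stop("region out of range: ", region_name)
  substr(precursor, r[1], r[2])
}

#' Scan a sequence for dibasic convertase sites
#'
#' Reports every adjacent pair of basic residues (K/R), including overlapping
#' pairs, in ascending order. This is the motif-level signal prohormone
#' convertases require; no machine-learned cleavage prediction is attempted.
#'
#' @param seq ungapped protein sequence (single string).
#' @return data.frame with columns `pos1`, `pos2` (`pos2 = pos1 + 1`); zero
#'   rows when no dibasic pair is present.
#' @export
scan_dibasic_sites <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  basic <- chars %in% c("K", "R")
  i <- which(basic[-length(basic)] & basic[-1])
  data.frame(pos1 = i, pos2 = i + 1L)
}

#' Check processing-site integrity per species
#'
#' A site is `intact` for a species when every specified position holds a
#' residue of the required class, `disrupted` when some position holds a
#' non-class residue, and `indeterminate` when any position is a gap (gaps
#' usually reflect incomplete assemblies, never evidence of disruption).
#'
#' @param msa a protein [gcg_msa()] of precursors.
#' @param rm a [region_map()].
#' @param spec a [site_spec()].
#' @param precursor passed to [map_region_to_columns()].
#' @return data.frame with columns `species`, `site`, `status`, `residues`.
#' @export
check_site_integrity <- function(msa, rm, spec, precursor = TRUE) {
  cols <- map_region_to_columns(msa, rm, spec$region, precursor = precursor)
  if (any(spec$positions > length(cols)))
    stop("site positions exceed region length: ", spec$name)
  site_cols <- cols[spec$positions]
  cm <- msa_chars(msa)[, site_cols, drop = FALSE]
  status <- apply(cm, 1, function(res) {
    if (any(res == "-")) "indeterminate"
    else if (all(res %in% spec$required_class)) "intact"
    else "disrupted"
  })
  data.frame(species = msa$ids, site = spec$name,
             status = unname(status),
             residues = apply(cm, 1, paste, collapse = ""),
             row.names = NULL)
}
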