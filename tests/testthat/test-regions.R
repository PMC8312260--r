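test_that("default region map encodes the canonical peptide intervals", {
  rm <- region_map()
  expect_equal(rm$regions$glucagon, c(33L, 61L))
  expect_equal(rm$regions$miniglucagon, c(51L, 61L))
  # structural invariants are enforced
  expect_error(region_map(regions = list(glucagon = c(33, 61),
                                         miniglucagon = c(30, 40)),
                          mature_len = 160),
               "nested")
  expect_error(region_map(regions = list(pep = c(150, 170)),
                          mature_len = 160),
               "out of range")
})

test_that("region-to-column lift handles gapless and gapped references", {
  m <- edited_precursor_msa()
  cols <- map_region_to_columns(m, region_map(), "glucagon")
  expect_identical(cols, 53:81)

  # mature-only alignment with a gap in the reference before column 10:
  # brute-force oracle scans the reference's ungapped index per column
  rows <- c(Homo_sapiens = "ABCD-EFGHIK", sp1 = "ABCDXEFGHIK")
  rows <- gsub("B", "G", rows)  # keep to the amino-acid alphabet
  rows <- gsub("X", "S", rows)
  m2 <- gcg_msa(names(rows), unname(rows), "protein", "Homo_sapiens")
  rm2 <- region_map(regions = list(pep = c(1L, 5L)), signal_peptide_len = 0L,
                    mature_len = 10L)
  got <- map_region_to_columns(m2, rm2, "pep", precursor = FALSE)
  refchars <- strsplit(m2$rows[1], "")[[1]]
  oracle <- which(cumsum(refchars != "-") %in% 1:5 & refchars != "-")
  expect_identical(got, oracle)
  expect_identical(got, c(1:4, 6L))

  # region past the end of the reference's ungapped length
  rm4 <- region_map(regions = list(pep = c(1L, 15L)), signal_peptide_len = 0L,
                    mature_len = 15L)
  expect_error(map_region_to_columns(m2, rm4, "pep", precursor = FALSE),
               "out of range")
})

test_that("extracted peptides have the documented lengths", {
  seq <- paste(rep("A", 160), collapse = "")
  rm <- region_map()
  lens <- vapply(names(rm$regions), function(r)
    nchar(extract_peptide(seq, rm, r)), integer(1))
  expect_equal(unname(lens[c("glucagon", "GLP-1_7-37", "GLP-2",
                             "glicentin", "OXM", "miniglucagon")]),
               c(29L, 31L, 33L, 69L, 37L, 11L))
  full <- region_map(regions = list(all = c(1L, 160L)), mature_len = 160L)
  expect_identical(extract_peptide(seq, full, "all"), seq)
  # peptide length always equals the number of lifted columns
  m <- edited_precursor_msa()
  mature <- substr(m$rows[1], 21, 180)
  for (r in names(rm$regions))
    expect_length(map_region_to_columns(m, rm, r),
                  nchar(extract_peptide(mature, rm, r)))
})

test_that("dibasic scanning reports all overlapping pairs in order", {
  expect_equal(scan_dibasic_sites("AAKRAA"), data.frame(pos1 = 3L, pos2 = 4L))
  expect_equal(scan_dibasic_sites("AKRRA"),
               data.frame(pos1 = c(2L, 3L), pos2 = c(3L, 4L)))
  expect_equal(nrow(scan_dibasic_sites("AAAAA")), 0L)
  # invariant to appending non-basic residues
  expect_equal(scan_dibasic_sites("AKRRA"),
               scan_dibasic_sites("AKRRAGGTS"))
})

test_that("site integrity distinguishes intact, disrupted, indeterminate", {
  rm <- region_map()
  spec <- default_site_specs()[[1]]  # glucagon 17-18 dibasic
  cols <- map_region_to_columns(edited_precursor_msa(), rm, "glucagon")
  p17 <- cols[17]
  p18 <- cols[18]
  m <- edited_precursor_msa(n_species = 4, edits = list(
    Homo_sapiens = list(c(p17, "K"), c(p18, "R")),
    sp01 = list(c(p17, "K"), c(p18, "R")),
    sp02 = list(c(p17, "K"), c(p18, "L")),
    sp03 = list(c(p17, "K"), c(p18, "-"))))
  res <- check_site_integrity(m, rm, spec)
  got <- setNames(res$status, res$species)
  expect_identical(unname(got[c("sp01", "sp02", "sp03")]),
                   c("intact", "disrupted", "indeterminate"))
  expect_identical(unname(got["Homo_sapiens"]), "intact")
})

test_that("an alignment of identical intact rows is intact everywhere", {
  rm <- region_map()
  spec <- default_site_specs()[[1]]
  cols <- map_region_to_columns(edited_precursor_msa(), rm, "glucagon")
  m <- edited_precursor_msa(n_species = 6)
  edits <- lapply(setNames(m$ids, m$ids), function(sp)
    list(c(cols[17], "K"), c(cols[18], "R")))
  m <- edited_precursor_msa(n_species = 6, edits = edits)
  res <- check_site_integrity(m, rm, spec)
  expect_true(all(res$status == "intact"))
})
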