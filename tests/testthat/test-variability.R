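test_that("reference comparison counts substitutions and gap columns", {
  rm <- toy_region_map(5)
  m <- make_msa(Homo_sapiens = "HSQGT", s1 = "HAQGT", s2 = "HSQGT",
                s3 = "H-QGT")
  dt <- compare_to_reference(m, rm, "pep", precursor = FALSE)
  expect_setequal(dt$species, c("s1", "s2", "s3"))
  expect_equal(dt$n_diff[dt$species == "s1"], 1L)
  expect_identical(dt$substitutions[dt$species == "s1"][[1]], "S2A")
  expect_equal(dt$n_diff[dt$species == "s2"], 0L)
  # gap column counts as gap, never as a difference
  expect_equal(dt$n_gap_cols[dt$species == "s3"], 1L)
  expect_equal(dt$n_diff[dt$species == "s3"], 0L)
})

test_that("precursor numbering mode labels substitutions on the precursor", {
  rm <- region_map()
  m <- edited_precursor_msa()
  cols <- map_region_to_columns(m, rm, "glucagon")
  ref18 <- substr(m$rows[1], cols[18], cols[18])
  m <- edited_precursor_msa(edits = list(sp01 = list(c(cols[18], "L"))))
  reg <- compare_to_reference(m, rm, "glucagon")
  pre <- compare_to_reference(m, rm, "glucagon", numbering = "precursor")
  expect_identical(reg$substitutions[reg$species == "sp01"][[1]],
                   paste0(ref18, 18, "L"))
  expect_identical(pre$substitutions[pre$species == "sp01"][[1]],
                   paste0(ref18, 50, "L"))  # glucagon 18 = mature residue 50
})

test_that("region summary arithmetic matches hand computation", {
  dt <- make_diff_table(c(0, 0, 2, 4),
                        list(character(), character(),
                             c("S2A", "S2T"), c("K4R", "A5G", "S2A", "H7Q")))
  s <- summarize_region_variability(dt, peptide_len = 10)
  expect_equal(s$n_species, 4L)
  expect_equal(s$n_identical, 2L)
  expect_equal(s$avg_diff_differing, 3.0)
  expect_equal(s$per_residue_rate, 0.15)
  expect_equal(c(s$diff_min, s$diff_max), c(0L, 4L))

  dt2 <- make_diff_table(c(1, 1, 1),
                         list("S2A", "S2T", "K4R"))
  s2 <- summarize_region_variability(dt2, peptide_len = 10)
  expect_equal(s2$n_variable_sites, 2L)
  expect_equal(s2$n_substitution_types, 3L)

  all_same <- make_diff_table(c(0, 0), list(character(), character()))
  s3 <- summarize_region_variability(all_same, peptide_len = 10)
  expect_true(is.na(s3$avg_diff_differing))
  expect_equal(s3$n_variable_sites, 0L)
  expect_equal(s3$per_residue_rate, 0)

  expect_error(summarize_region_variability(all_same[0, ]), "empty")
})

test_that("adding a reference-identical species only grows the denominators", {
  rm <- toy_region_map(5)
  m <- make_msa(Homo_sapiens = "HSQGT", s1 = "HAQGT", s2 = "HSQGA")
  m_plus <- make_msa(Homo_sapiens = "HSQGT", s1 = "HAQGT", s2 = "HSQGA",
                     s3 = "HSQGT")
  a <- summarize_region_variability(compare_to_reference(m, rm, "pep",
                                                         precursor = FALSE))
  b <- summarize_region_variability(compare_to_reference(m_plus, rm, "pep",
                                                         precursor = FALSE))
  expect_equal(b$n_species, a$n_species + 1L)
  expect_equal(b$n_identical, a$n_identical + 1L)
  expect_equal(b$n_variable_sites, a$n_variable_sites)
  expect_equal(b$n_substitution_types, a$n_substitution_types)
  expect_equal(b$avg_diff_differing, a$avg_diff_differing)
  expect_equal(b$per_residue_rate * b$n_species,
               a$per_residue_rate * a$n_species)
})

test_that("excluding a species equals deleting its row", {
  rm <- region_map()
  tr <- simulate_tree(10, seed = 3)
  m <- simulate_precursor_alignment(tr, rm, list(`GLP-2` = 3.0), seed = 4)
  excl <- "sp07"
  a <- compare_to_reference(m, rm, "GLP-2", exclude_species = excl)
  keep <- m$ids != excl
  m2 <- gcg_msa(m$ids[keep], m$rows[keep], "protein", m$ref_id)
  b <- compare_to_reference(m2, rm, "GLP-2")
  expect_identical(a$species, b$species)
  expect_identical(a$n_diff, b$n_diff)
  expect_identical(a$substitutions, b$substitutions)
})

test_that("consensus frequencies sum to one and count gaps", {
  m <- make_msa(Homo_sapiens = "HHG", s1 = "HQG", s2 = "HQ-",
                s3 = "HQG", s4 = "HH-")
  cm <- consensus_matrix(m)
  expect_equal(unname(colSums(cm)), rep(1, 3))
  expect_equal(unname(cm["H", 1]), 1.0)
  expect_equal(unname(cm["H", 2]), 0.4)
  expect_equal(unname(cm["Q", 2]), 0.6)
  expect_equal(unname(cm["-", 3]), 0.4)
  sub <- consensus_matrix(m, columns = 2:3)
  expect_equal(ncol(sub), 2L)
  expect_equal(unname(sub["-", 2]), 0.4)
})
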