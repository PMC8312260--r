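# 12-column receptor fixture: 8 species, reference "Homo_sapiens".
receptor_fixture <- function() {
  base <- "HSQGTFTSDYSK"
  rows <- c(Homo_sapiens = base,
            s1 = base, s2 = base, s3 = base,
            s4 = "HSQGTFTADYSK",          # unique variant at site 8 (S->A)
            s5 = "HAQGTFTSDYSK",          # variant at site 2
            s6 = "HAQGTFTSDYSK",          # same variant at site 2 (multi)
            s7 = "HSQGTFTSDYS-")          # gap at site 12
  gcg_msa(names(rows), unname(rows), "protein", "Homo_sapiens")
}

lig_set <- function() site_set("GcgrSynth", "ligand",
                               c(2L, 5L, 8L, 12L),
                               c("1.47", "2.64", "3.44", "6.37"))

test_that("sites are categorized with the documented precedence", {
  m <- receptor_fixture()
  tbl <- categorize_sites(m, lig_set())
  got <- setNames(tbl$category, tbl$wootten_label)
  expect_identical(unname(got["2.64"]), "invariant")
  expect_identical(unname(got["3.44"]), "unique_variant")
  expect_identical(unname(got["1.47"]), "multi_variant")
  # gap is not variation
  expect_identical(unname(got["6.37"]), "invariant")

  # an impact call at a site wins over its variant status
  calls <- data.frame(species = "s4", region = "receptor",
                      substitution = "S8A", position = 8L,
                      tolerance_score = 0.01, delta_score = -4,
                      category = "both_flagged")
  tbl2 <- categorize_sites(m, lig_set(), impact_calls = calls)
  expect_identical(tbl2$category[tbl2$ref_position == 8L], "impact_flagged")
  # categories are exclusive and cover all sites
  expect_equal(sum(table(tbl2$category)), nrow(tbl2))
})

test_that("site-table summaries tally variability and flags", {
  m <- receptor_fixture()
  calls <- data.frame(species = c("s5", "s6"), region = "receptor",
                      substitution = c("S2A", "S2A"), position = 2L,
                      tolerance_score = 0.01, delta_score = -4,
                      category = "both_flagged")
  tbl <- categorize_sites(m, lig_set(), impact_calls = calls)
  s <- summarize_site_table(tbl, impact_calls = calls)
  expect_equal(s$n_sites, 4L)
  expect_equal(s$n_variable, 2L)
  expect_equal(s$n_unique, 1L)
  expect_equal(s$n_sites_with_flagged, 1L)
  expect_equal(s$n_flagged_substitutions, 1L)

  flat <- categorize_sites(m, site_set("x", "ligand", c(1L, 3L),
                                       c("1.50", "2.50")))
  sf <- summarize_site_table(flat)
  expect_equal(sf$n_variable, 0L)
  expect_equal(sf$n_substitution_types, 0L)
})

test_that("per-species difference counts are bounded and reference-zero", {
  m <- receptor_fixture()
  d <- per_species_site_diffs(m, lig_set())
  got <- setNames(d$n_diff, d$species)
  expect_equal(unname(got["Homo_sapiens"]), 0L)
  expect_equal(unname(got["s4"]), 1L)
  expect_equal(unname(got["s5"]), 1L)
  expect_equal(unname(got["s7"]), 0L)  # gap excluded
  expect_true(all(d$n_diff <= 4L))
})

test_that("site sets intersect by Wootten label within one role", {
  a <- site_set("Gcgr", "ligand", c(10L, 20L, 30L),
                c("1.47", "2.64", "3.44"))
  b <- site_set("Glp1r", "ligand", c(12L, 22L, 40L),
                c("2.64", "3.44", "6.37"))
  shared <- intersect_site_sets(list(a, b))
  expect_identical(shared$wootten_label, c("2.64", "3.44"))
  expect_identical(shared$ref_position, c(20L, 30L))  # first set's positions
  expect_identical(intersect_site_sets(list(a, a))$wootten_label,
                   sort(a$wootten_label))
  g <- site_set("Gcgr", "gprotein", 5L, "8.47")
  expect_error(intersect_site_sets(list(a, g)), "mixed roles")
  disj <- site_set("Glp2r", "ligand", 7L, "7.49")
  expect_warning(intersect_site_sets(list(a, disj)), "no shared sites")
})

test_that("removing the only varying species makes a site invariant", {
  m <- receptor_fixture()
  m2 <- msa_exclude(m, "s4")
  tbl <- categorize_sites(m2, lig_set())
  expect_identical(tbl$category[tbl$ref_position == 8L], "invariant")
})
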