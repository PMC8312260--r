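test_that("FASTA round-trip preserves ids and sequences exactly", {
  m <- make_msa(Homo_sapiens = "MKTA-YHSQG", Mus_musculus = "MKTAGYHSQG",
                Rattus_norvegicus = "MKSAGYHSQG")
  p <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(m, p)
  m2 <- read_alignment(p, "protein")
  expect_identical(m2$ids, m$ids)
  expect_identical(m2$rows, m$rows)
  expect_identical(m2$ref_id, "Homo_sapiens")
})

test_that("alignment invariants are enforced on read", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Homo_sapiens", "MKTAYHSQGT", ">sp2", "MKTAYHSQGTF"), p)
  expect_error(read_alignment(p, "protein"), "unequal lengths")

  writeLines(c(">sp1", "MKTAY", ">sp2", "MKTAY"), p)
  expect_error(read_alignment(p, "protein"), "reference absent")

  writeLines(c(">Homo_sapiens", "ATGAAACCCG"), p)
  expect_error(read_alignment(p, "codon"), "frame error")

  writeLines(c(">Homo_sapiens", "MKTAX"), p)
  expect_error(read_alignment(p, "protein"), "outside")

  expect_error(gcg_msa(c("a", "a"), c("MK", "MT"), ref_id = "a"),
               "duplicate")
})

test_that("lowercase residues are uppercased on read", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Homo_sapiens", "mkta-y"), p)
  m <- read_alignment(p, "protein")
  expect_identical(m$rows, "MKTA-Y")
})

test_that("codon alignments strip terminal stops and reject internal ones", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">Homo_sapiens", "ATGAAATAA", ">sp2", "ATGAAGTGA"), p)
  m <- read_alignment(p, "codon")
  expect_identical(m$rows, c("ATGAAA", "ATGAAG"))

  writeLines(c(">Homo_sapiens", "ATGTAAAAA"), p)
  expect_error(read_alignment(p, "codon"), "internal stop")
})

test_that("Newick reading fills defaults and rejects duplicate leaves", {
  p <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1);", p)
  tr <- read_species_tree(p)
  expect_s3_class(tr, "phylo")
  expect_length(tr$tip.label, 4)

  writeLines("((A,B),(C,D));", p)
  tr <- read_species_tree(p)
  expect_true(all(tr$edge.length == 1))

  writeLines("((A,B),(A,C));", p)
  expect_error(read_species_tree(p), "duplicate leaf")
})

test_that("run config fills threshold defaults and checks paths", {
  d <- withr::local_tempdir()
  writeLines("x", file.path(d, "tree.nwk"))
  yaml::write_yaml(list(seed = 7, tree_path = "tree.nwk",
                        thresholds = list(coevo_fdr = 0.1)),
                   file.path(d, "cfg.yaml"))
  cfg <- read_run_config(file.path(d, "cfg.yaml"))
  expect_identical(cfg$seed, 7L)
  expect_equal(cfg$thresholds$coevo_fdr, 0.1)
  expect_equal(cfg$thresholds$tolerance_cut, 0.05)
  expect_equal(cfg$thresholds$delta_cut, -2.5)

  yaml::write_yaml(list(seed = 1, tree_path = "missing.nwk"),
                   file.path(d, "cfg.yaml"))
  expect_error(read_run_config(file.path(d, "cfg.yaml")), "unresolvable")
})

test_that("every fixture written by the simulator loads without error", {
  d <- withr::local_tempdir()
  paths <- simulate_bundle(d, seed = 11, n_taxa = 8, n_codons = 60)
  expect_s3_class(read_alignment(paths$gcg, "protein",
                                 ref_id = "sp01"), "gcg_msa")
  for (g in c("Glp1r", "Gcgr", "Glp2r"))
    expect_s3_class(read_alignment(paths[[g]], "codon", ref_id = "sp01"),
                    "gcg_msa")
  expect_s3_class(read_species_tree(paths$tree), "phylo")
  expect_s3_class(read_region_map(paths$region_map)$region_map, "region_map")
  expect_s3_class(read_neighborhood_table(paths$neighborhoods), "data.frame")
  expect_s3_class(read_site_list(paths$ligand_sites), "site_set")
  cfg <- read_run_config(paths$config)
  expect_identical(cfg$seed, 11L)
})
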