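col_msa <- function(states, alphabet = "protein") {
  gcg_msa(names(states), unname(states), alphabet, names(states)[1])
}

test_that("Fitch mapping places substitutions deterministically", {
  tr <- quartet_tree()
  # one internal change separating the two cherries
  m <- col_msa(c(A = "H", B = "H", C = "Q", D = "Q"))
  sm <- fitch_substitution_map(m, tr, 1)
  expect_equal(sm$score, 1L)
  expect_length(sm$branches, 1L)
  # the changed branch is internal (its child is not a tip)
  expect_true(all(tr$edge[sm$branches, 2] > length(tr$tip.label)))

  # invariant column: empty map, not an error
  m2 <- col_msa(c(A = "H", B = "H", C = "H", D = "H"))
  sm2 <- fitch_substitution_map(m2, tr, 1)
  expect_equal(sm2$score, 0L)
  expect_length(sm2$branches, 0L)

  # incongruent column: two terminal-branch changes under the rule
  m3 <- col_msa(c(A = "H", B = "Q", C = "H", D = "Q"))
  sm3 <- fitch_substitution_map(m3, tr, 1)
  expect_equal(sm3$score, 2L)
  tips <- tr$edge[sm3$branches, 2]
  expect_true(all(tips <= length(tr$tip.label)))
})

test_that("Fitch scores agree with an independent parsimony implementation", {
  set.seed(99)
  for (i in 1:20) {
    tr <- ape::rtree(8)
    states <- sample(c("H", "Q", "S", "A"), 8, replace = TRUE)
    names(states) <- tr$tip.label
    m <- gcg_msa(names(states), unname(states), "protein", tr$tip.label[1])
    sm <- fitch_substitution_map(m, tr, 1)
    pd <- phangorn::phyDat(as.matrix(states), type = "AA")
    expect_equal(sm$score, phangorn::fitch(tr, pd), info = i)
  }
})

test_that("gap leaves are treated as missing data", {
  tr <- quartet_tree()
  m <- col_msa(c(A = "H", B = "-", C = "Q", D = "Q"))
  sm <- fitch_substitution_map(m, tr, 1)
  expect_equal(sm$score, 1L)
})

test_that("branch-overlap p-values match the hypergeometric form", {
  mk <- function(branches, column = 1L)
    structure(list(column = column, branches = branches,
                   score = length(branches)),
              class = "substitution_map")
  t1 <- cosub_pair_test(mk(c(1L, 2L, 3L)), mk(c(1L, 2L, 3L), 2L), 20L)
  expect_equal(t1$concordance, 1.0)
  expect_equal(t1$p_value, 1 / choose(20, 3))
  expect_equal(t1$both + t1$i_only + t1$j_only + t1$neither, 20L)

  t2 <- cosub_pair_test(mk(1:3), mk(4:6, 2L), 20L)
  expect_equal(t2$concordance, 0)

  expect_error(cosub_pair_test(mk(1:5), mk(6:10, 2L), 8L), "n_branches")

  # agrees with Fisher's exact test on random branch tables
  set.seed(5)
  for (i in 1:20) {
    n <- 30L
    bi <- sample.int(n, sample(2:8, 1))
    bj <- sample.int(n, sample(2:8, 1))
    t <- cosub_pair_test(mk(bi), mk(bj, 2L), n)
    ft <- fisher.test(matrix(c(t$both, t$i_only, t$j_only, t$neither), 2),
                      alternative = "greater")
    expect_equal(t$p_value, ft$p.value, tolerance = 1e-9)
  }
})

test_that("screening reports coupled columns and skips untestable pairs", {
  tr <- simulate_tree(64, seed = 51)
  rmr <- region_map(regions = list(all = c(1L, 30L)), signal_peptide_len = 0L,
                    mature_len = 30L)
  m <- simulate_precursor_alignment(tr, rmr, base_rate = 0.2, seed = 52,
                                    coupled_pairs = list(c(10L, 25L)))
  res <- screen_pairs(m, tr)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  hit <- res[res$column_i == 10 & res$column_j == 25, ]
  expect_equal(nrow(hit), 1L)
  expect_true(hit$reported)
  # a fully invariant alignment screens to an empty result
  flat <- gcg_msa(tr$tip.label, rep(strrep("HSQG", 5), 64), "protein",
                  tr$tip.label[1])
  expect_equal(nrow(screen_pairs(flat, tr)), 0L)
})

test_that("screen output tracks original column indices under permutation", {
  tr <- simulate_tree(10, seed = 61)
  m <- simulate_precursor_alignment(tr, region_map(), base_rate = 0.4,
                                    seed = 62)
  sub <- gcg_msa(m$ids, substr(m$rows, 1, 40), "protein", m$ref_id)
  perm <- c(21:40, 1:20)
  permuted <- gcg_msa(m$ids,
                      vapply(strsplit(substr(m$rows, 1, 40), ""),
                             function(ch) paste(ch[perm], collapse = ""),
                             character(1)),
                      "protein", m$ref_id)
  a <- screen_pairs(sub, tr)
  b <- screen_pairs(permuted, tr)
  key <- function(df, map = identity)
    sort(paste(pmin(map(df$column_i), map(df$column_j)),
               pmax(map(df$column_i), map(df$column_j)),
               signif(df$p_value, 10)))
  expect_identical(key(a), key(b, function(i) perm[i]))
})

test_that("cross-partition mode tests exactly the cross pairs", {
  tr <- simulate_tree(8, seed = 71)
  a <- simulate_precursor_alignment(tr, toy_region_map(12), base_rate = 0.8,
                                    seed = 72)
  b <- simulate_precursor_alignment(tr, toy_region_map(12), base_rate = 0.8,
                                    seed = 73)
  res <- screen_pairs(a, tr, msa2 = b, cross_only = TRUE)
  expect_true(all(res$partition_i == "A" & res$partition_j == "B"))
  na <- sum(vapply(seq_len(nchar(a$rows[1])), function(k)
    fitch_substitution_map(a, tr, k)$score > 0, logical(1)))
  nb <- sum(vapply(seq_len(nchar(b$rows[1])), function(k)
    fitch_substitution_map(b, tr, k)$score > 0, logical(1)))
  expect_equal(nrow(res), na * nb)
})
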