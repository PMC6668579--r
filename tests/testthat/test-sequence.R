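test_that("identical sequences align without gaps at 100% identity", {
  r <- global_align("MKVLTTAYGW", "MKVLTTAYGW")
  expect_equal(r$n_identical, 10L)
  expect_false(grepl("-", r$aligned_a))
  expect_false(grepl("-", r$aligned_b))
  for (den in c("aligned_columns_nongap", "shorter_seq", "alignment_length"))
    expect_equal(percent_identity(r, den), 100)
})

test_that("optimal score matches exhaustive enumeration on tiny strings", {
  cases <- list(c("ACDEFG", "ACEFG"), c("WYYW", "WW"), c("MKV", "MV"),
                c("AAAA", "AGA"))
  for (cs in cases) {
    r <- global_align(cs[1], cs[2])
    expect_equal(r$score, enumerate_best_alignment(cs[1], cs[2]),
                 tolerance = 1e-9)
  }
  # the single-gap case lands where enumeration says it must
  r <- global_align("ACDEFG", "ACEFG")
  expect_equal(sum(is.na(r$columns$pos_b)), 1L)
  expect_equal(sum(is.na(r$columns$pos_a)), 0L)
})

test_that("reported score is reproducible from the alignment columns", {
  seqs <- c("MKVLTTAYGWQQR", "MKVTTAYGWR", "MKLLTTGYGWQER")
  for (i in 1:2) for (j in (i + 1):3) {
    r <- global_align(seqs[i], seqs[j])
    expect_equal(r$score, recompute_alignment_score(r), tolerance = 1e-9)
  }
})

test_that("X never counts as identical and empty sequences error", {
  r <- global_align("AXA", "AXA")
  expect_equal(r$n_identical, 2L)
  expect_error(global_align("", "AC"), "non-empty")
})

test_that("percent identity is symmetric and respects the denominator", {
  a <- "MKVLTTAYGWQQRDD"; b <- "MKVTTAYGWLLR"
  r_ab <- global_align(a, b)
  r_ba <- global_align(b, a)
  expect_equal(percent_identity(r_ab), percent_identity(r_ba),
               tolerance = 1e-9)
  # hand-checked: 5 identities over 10 non-gap columns = 50%
  r <- structure(list(
    columns = data.frame(pos_a = c(1:10, NA, NA), pos_b = c(1:10, 11, 12)),
    n_identical = 5L), class = "alignment_result")
  expect_equal(percent_identity(r, "aligned_columns_nongap"), 50)
  expect_equal(percent_identity(r, "alignment_length"), 100 * 5 / 12)
  expect_equal(percent_identity(r, "shorter_seq"), 50)
})

test_that("residue maps translate anchor positions across homologs", {
  # deletion of positions 3-4 in the homolog shifts later positions by -2
  anchor <- "MKVLTTAYGWQQR"
  homolog <- "MKTTAYGWQQR"
  m <- residue_map(global_align(anchor, homolog, ids = c("anchor", "hom")))
  expect_equal(m$anchor_id, "anchor")
  expect_equal(map_residue(m, 1), 1L)
  expect_equal(map_residue(m, 13), 11L)
  expect_true(anyNA(map_residue(m, 3:4)))
  expect_equal(map_residue(m, 99), NA_integer_)
  # mapping is derived only from non-gap columns
  expect_true(all(stats::na.omit(m$mapping) %in% 1:11))
})

test_that("protein mass reproduces free amino acids and is additive", {
  expect_equal(protein_mass("G"), 75.07, tolerance = 0.01)
  expect_equal(protein_mass("GG"), 132.12, tolerance = 0.01)
  s1 <- "MKVLT"; s2 <- "AYGW"
  expect_equal(protein_mass(paste0(s1, s2)),
               protein_mass(s1) + protein_mass(s2) - 18.01528,
               tolerance = 1e-6)
  expect_error(protein_mass("AZB"), "mass")
})

test_that("distance matrix is symmetric with zero diagonal", {
  seqs <- c(a = "MKVLTTAYGW", b = "MKVLTTAYGW", c = "MKVCTTGYGW")
  d <- distance_matrix(seqs)
  expect_equal(d["a", "b"], 0)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_equal(d, t(d))
  expect_equal(d["a", "c"], 0.2, tolerance = 1e-9)  # 8/10 identical
  dk <- distance_matrix(seqs, correction = "kimura")
  expect_gt(dk["a", "c"], d["a", "c"])  # correction inflates distances
})

test_that("neighbor joining is exact on additive 4- and 5-taxon matrices", {
  for (txt in c("((A:1,B:2):1,(C:3,D:4):2);",
                "(((A:0.5,B:1):0.7,C:2):0.4,(D:1.5,E:0.8):0.6);")) {
    true_tree <- ape::read.tree(text = txt)
    d <- ape::cophenetic.phylo(true_tree)
    d <- d[order(rownames(d)), order(colnames(d))]
    nj <- nj_tree(d)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), nj), 0,
                 ignore_attr = TRUE)
    # branch lengths exact: path distances reproduce the input matrix
    d_nj <- ape::cophenetic.phylo(nj)[rownames(d), colnames(d)]
    expect_equal(d_nj, d, tolerance = 1e-8)
  }
})

test_that("nj_tree validates its input matrix", {
  d <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "asymmetric")
  d3b <- matrix(c(0.5, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3b), "diagonal")
})

test_that("NJ recovers the planted topology of a simulated family", {
  true_tree <- ape::read.tree(
    text = "(((t1:0.08,t2:0.1):0.05,t3:0.12):0.04,((t4:0.09,t5:0.07):0.06,t6:0.1):0.03);")
  fam <- make_sequence_family(true_tree, n_sites = 600, seed = 99)
  d <- distance_matrix(fam$sequences, correction = "kimura")
  nj <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(true_tree), nj), 0,
               ignore_attr = TRUE)
})
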