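test_that("an exact rotated+translated copy superposes to zero RMSD", {
  p <- make_toy_peptide("AYGKCDE", jitter_sd = 0.3, seed = 11)
  mc <- make_rotated_copy(p, noise_sd = 0, seed = 2)
  pairs <- pair_by_order(p, mc$structure)
  fit <- kabsch_fit(pairs)
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(rmsd_no_cutoff(pairs), 1e-6)
  # recovered transform matches the planted one
  expect_equal(fit$rotation, mc$manifest$rotation, tolerance = 1e-6)
  expect_equal(fit$translation, mc$manifest$translation, tolerance = 1e-6)
})

test_that("rotation is always proper orthonormal and RMSD symmetric", {
  for (seed in 1:6) {
    pairs <- make_cloud_pair(n = 25, noise_sd = 0.7, seed = seed)
    fit <- kabsch_fit(pairs)
    expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    swapped <- paired_coords(pairs$b, pairs$a)
    expect_equal(kabsch_fit(swapped)$rmsd, fit$rmsd, tolerance = 1e-6)
  }
})

test_that("a reflected copy still yields det(R) = +1 (reflection guard)", {
  p <- make_toy_peptide("AYGKCDEF", jitter_sd = 0.4, seed = 3)
  xyz <- atom_coords(p$atoms)
  mirrored <- xyz %*% diag(c(-1, 1, 1))
  pairs <- paired_coords(xyz, mirrored)
  fit <- kabsch_fit(pairs)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_gt(fit$rmsd, 0.1)  # a proper rotation cannot undo a reflection
})

test_that("displaced-corner square matches the brute-force rotation oracle", {
  sq <- matrix(c(0, 0, 0, 2, 0, 0, 2, 2, 0, 0, 2, 0), 4, 3, byrow = TRUE)
  sq_b <- sq
  sq_b[3, 3] <- 1  # one corner lifted 1 A out of plane
  pairs <- paired_coords(sq, sq_b)
  fit <- kabsch_fit(pairs)
  oracle <- oracle_best_rmsd(pairs, seed = 5)
  expect_lt(abs(fit$rmsd - oracle$rmsd), 0.01)
  expect_lte(fit$rmsd, oracle$rmsd + 1e-9)
})

test_that("noisy 50-point cloud matches the oracle on the exact realization", {
  pairs <- make_cloud_pair(n = 50, noise_sd = 0.5, seed = 42)
  fit <- kabsch_fit(pairs)
  oracle <- oracle_best_rmsd(pairs, seed = 6)
  expect_lt(abs(fit$rmsd - oracle$rmsd), 0.1)
})

test_that("degenerate (collinear) point sets raise a geometry error", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(paired_coords(line, line + 1)), "degenerate")
  expect_error(kabsch_fit(paired_coords(line[1:2, ], line[1:2, ])), ">= 3")
})

test_that("trimming leaves all-inlier fits untouched and recovers planted outliers", {
  p <- make_toy_peptide(strrep("AK", 10), jitter_sd = 0.3, seed = 9)  # 20 res
  ca_only <- gale_structure("ca", select_atoms(p, atom = "CA"))
  # no outliers: trimmed == plain fit, everything retained
  clean <- make_rotated_copy(ca_only, noise_sd = 0.2, seed = 13)
  pairs <- pair_by_order(ca_only, clean$structure)
  tfit <- trimmed_superpose(pairs, cutoff = 2.0)
  expect_true(all(tfit$retained))
  expect_equal(tfit$rmsd, kabsch_fit(pairs)$rmsd, tolerance = 1e-9)
  # 5 planted 5-A outliers among 20 pairs: exactly the clean 20... i.e. 15
  out <- make_rotated_copy(ca_only, noise_sd = 0, n_outliers = 5,
                           outlier_mag = 5, seed = 21)
  pairs2 <- pair_by_order(ca_only, out$structure)
  tfit2 <- trimmed_superpose(pairs2, cutoff = 2.0)
  expect_equal(which(!tfit2$retained), out$manifest$outlier_idx)
  expect_lt(tfit2$rmsd, 1e-6)
  # trimmed rmsd never exceeds untrimmed; final deviations all within cutoff
  expect_lte(tfit2$rmsd, rmsd_no_cutoff(pairs2) + 1e-9)
  expect_true(all(tfit2$per_pair_dev[tfit2$retained] <= 2.0))
})

test_that("trimmed RMSD <= untrimmed RMSD across random fixtures", {
  for (seed in 1:8) {
    pairs <- make_cloud_pair(n = 30, noise_sd = 1.0, seed = seed + 100)
    tfit <- trimmed_superpose(pairs, cutoff = 2.0)
    expect_lte(tfit$rmsd, rmsd_no_cutoff(pairs) + 1e-9)
    expect_true(all(tfit$per_pair_dev[tfit$retained] <= 2.0))
  }
})

test_that("trimming errors when fewer than 3 pairs survive the cutoff", {
  pairs <- make_cloud_pair(n = 10, noise_sd = 8, seed = 77)
  expect_error(trimmed_superpose(pairs, cutoff = 0.01), "convergence")
})

test_that("alignment-driven pairing counts columns and honors gaps", {
  a <- make_toy_peptide("ACDEFGHIKL", id = "a")
  b <- make_toy_peptide("ACDEFGHIKL", id = "b")
  aln <- global_align(chain_sequence(a, "A"), chain_sequence(b, "A"))
  pairs <- pair_calpha_by_alignment(a, b, aln)
  expect_equal(length(pairs), 10L)
  # two residues deleted in the second chain -> 8 pairs
  b2 <- make_toy_peptide("ACDFGHIL", id = "b2")
  aln2 <- global_align(chain_sequence(a, "A"), chain_sequence(b2, "A"))
  pairs2 <- pair_calpha_by_alignment(a, b2, aln2)
  expect_equal(length(pairs2), 8L)
  expect_error(
    pair_calpha_by_alignment(
      make_toy_peptide("AC"), make_toy_peptide("AC"),
      global_align("AC", "AC")),
    "insufficient pairs")
})

test_that("kabsch RMSD is never beaten by random proper rotations", {
  pairs <- make_cloud_pair(n = 40, noise_sd = 0.6, seed = 202)
  fit <- kabsch_fit(pairs)
  set.seed(303)
  rots <- random_rotations(1000L)
  rand_rmsds <- vapply(rots, function(R) rmsd_given_rotation(pairs, R),
                       numeric(1))
  expect_true(all(fit$rmsd <= rand_rmsds + 1e-9))
})
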