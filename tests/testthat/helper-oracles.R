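# Independent oracles used across the suite. None of these share code with
# the implementation paths they check.

# RMSD for a *given* rotation with the translation chosen optimally
# (centroid match) — the textbook reduction of the rigid-body problem.
rmsd_given_rotation <- function(p, R) {
  Ac <- sweep(p$a, 2, colMeans(p$a))
  Bc <- sweep(p$b, 2, colMeans(p$b))
  sqrt(mean(rowSums((Ac %*% t(R) - Bc)^2)))
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Brute-force search over rotation space: random multi-start followed by
# shrinking axis-angle perturbation. Independent of the SVD solution.
oracle_best_rmsd <- function(p, n_start = 300L, n_rounds = 80L, seed = 1L) {
  set.seed(seed)
  best_r <- diag(3)
  best <- rmsd_given_rotation(p, best_r)
  for (i in seq_len(n_start)) {
    R <- galescope::random_rotations(1L)[[1L]]
    v <- rmsd_given_rotation(p, R)
    if (v < best) { best <- v; best_r <- R }
  }
  scale <- 0.4
  for (round in seq_len(n_rounds)) {
    improved <- FALSE
    for (k in 1:20) {
      Rp <- rotation_about_axis(rnorm(3), rnorm(1, sd = scale)) %*% best_r
      v <- rmsd_given_rotation(p, Rp)
      if (v < best - 1e-12) { best <- v; best_r <- Rp; improved <- TRUE }
    }
    if (!improved) scale <- scale * 0.6
    if (scale < 1e-5) break
  }
  list(rmsd = best, rotation = best_r)
}

# Monte-Carlo surface-area estimator with RNG-drawn sphere points — a
# sampling scheme independent of the deterministic golden-spiral set.
mc_sasa_total <- function(atoms, probe = 1.4, n_mc = 4000L, seed = 1L,
                          radii = galescope::default_vdw_radii()) {
  set.seed(seed)
  r <- radii[atoms$element] + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  total <- 0
  n <- nrow(atoms)
  for (i in seq_len(n)) {
    pts <- matrix(rnorm(3 * n_mc), n_mc, 3)
    pts <- pts / sqrt(rowSums(pts^2)) * r[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_mc)
    for (j in seq_len(n)[-i]) {
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dd >= r[j]^2
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}

# Exhaustive enumeration of all global alignments of two tiny sequences
# under affine gap scoring; returns the maximum score.
enumerate_best_alignment <- function(a, b, matrix = "BLOSUM62",
                                     gap_open = 10, gap_extend = 0.5) {
  submat <- galescope:::get_submatrix(matrix)
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  score_cols <- function(cols) {
    s <- 0
    gap_run <- 0
    for (col in cols) {
      if (col[1] == "-" || col[2] == "-") {
        gap_run <- gap_run + 1
      } else {
        if (gap_run > 0) { s <- s - gap_open - gap_extend * gap_run; gap_run <- 0 }
        s <- s + submat[col[1], col[2]]
      }
    }
    if (gap_run > 0) s <- s - gap_open - gap_extend * gap_run
    s
  }
  best <- -Inf
  recurse <- function(i, j, cols) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score_cols(cols)); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      recurse(i + 1, j + 1, c(cols, list(c(ca[i], cb[j]))))
    if (i <= length(ca)) recurse(i + 1, j, c(cols, list(c(ca[i], "-"))))
    if (j <= length(cb)) recurse(i, j + 1, c(cols, list(c("-", cb[j]))))
  }
  recurse(1L, 1L, list())
  best
}

# Recompute an alignment score from its reported columns (affine gaps,
# per-run penalty open + extend * length).
recompute_alignment_score <- function(r) {
  submat <- galescope:::get_submatrix(r$params$matrix)
  ca <- strsplit(r$aligned_a, "")[[1]]
  cb <- strsplit(r$aligned_b, "")[[1]]
  s <- 0; run <- 0
  for (k in seq_along(ca)) {
    if (ca[k] == "-" || cb[k] == "-") run <- run + 1
    else {
      if (run > 0) {
        s <- s - r$params$gap_open - r$params$gap_extend * run
        run <- 0
      }
      s <- s + submat[ca[k], cb[k]]
    }
  }
  if (run > 0) s <- s - r$params$gap_open - r$params$gap_extend * run
  s
}

# Random point cloud pairing fixture: cloud A, proper rotation + translation
# + Gaussian noise. Ground truth retained for oracle comparison.
make_cloud_pair <- function(n = 30L, noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  A <- matrix(rnorm(3 * n, sd = 6), n, 3)
  R <- galescope::random_rotations(1L)[[1L]]
  t_vec <- rnorm(3, sd = 10)
  B <- A %*% t(R) + matrix(t_vec, n, 3, byrow = TRUE) +
    matrix(rnorm(3 * n, sd = noise_sd), n, 3)
  galescope::paired_coords(A, B)
}

# Location of user-supplied deposited PDB entries / reference sequences for
# the reproduction tests (not shipped; see tests/testthat/deposited/README).
deposited_file <- function(name) {
  local <- testthat::test_path("deposited", name)
  if (file.exists(local)) return(local)
  inst <- system.file("extdata", "deposited", name, package = "galescope")
  if (nzchar(inst) && file.exists(inst)) return(inst)
  ""
}

# One expectation per reproduction test: either all named inputs exist (and
# their paths are returned) or the test records a single informative failure
# and the caller returns early.
deposited_available <- function(names) {
  paths <- vapply(names, deposited_file, character(1))
  missing <- names[!nzchar(paths)]
  testthat::expect_true(
    length(missing) == 0L,
    info = paste0("deposited input(s) ", paste(missing, collapse = ", "),
                  " not found under tests/testthat/deposited/ or ",
                  "inst/extdata/deposited/; download them to run this ",
                  "reproduction (see tests/testthat/deposited/README.md)"))
  if (length(missing)) NULL else as.list(paths)
}
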