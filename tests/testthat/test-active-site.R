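rigid_move <- function(s, seed = 1) {
  set.seed(seed)
  R <- random_rotations(1)[[1]]
  t_vec <- rnorm(3, sd = 20)
  xyz <- atom_coords(s$atoms) %*% t(R) +
    matrix(t_vec, nrow(s$atoms), 3, byrow = TRUE)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

reflect <- function(s) {
  s$atoms$x <- -s$atoms$x
  s
}

test_that("atom_distance is Euclidean and matches planted placements", {
  expect_equal(atom_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  tc <- make_toy_complex(c4c4 = 3.4)
  g <- catalytic_c4c4(tc$structure, tc$roles)
  expect_equal(atom_distance(g$c4_sugar, g$c4_nicotinamide), 3.4,
               tolerance = 1e-9)
})

test_that("hydrogen-bond detection respects dmax and finds planted pairs", {
  hb <- make_hbond_set(distances = c(2.8, 3.2, 5.0), seed = 2)
  found <- detect_hbonds(hb$group_a, hb$group_b, dmax = 3.5)
  expect_equal(nrow(found), 2L)
  expect_equal(sort(found$distance), c(2.8, 3.2), tolerance = 1e-9)
  # sorted by distance
  expect_equal(found$distance, sort(found$distance))
  # nothing within range
  far <- make_hbond_set(distances = 5.0, seed = 3)
  expect_equal(nrow(detect_hbonds(far$group_a, far$group_b, dmax = 3.5)), 0L)
})

test_that("hydrogen-bond count is monotone non-decreasing in dmax", {
  hb <- make_hbond_set(distances = c(2.5, 2.9, 3.3, 3.8, 4.4), seed = 4)
  counts <- vapply(c(2.0, 2.6, 3.0, 3.5, 4.0, 4.5),
                   function(d) nrow(detect_hbonds(hb$group_a, hb$group_b, d)),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], 5L)
})

test_that("carbon atoms never form hydrogen bonds", {
  a <- data.frame(atom = "CA", element = "C", x = 0, y = 0, z = 0,
                  resname = "ALA", resno = 1, chain = "A", is_het = FALSE,
                  is_water = FALSE, occ = 1, bfac = 0, alt = "", icode = "")
  b <- data.frame(atom = "O", element = "O", x = 2.8, y = 0, z = 0,
                  resname = "GLY", resno = 2, chain = "A", is_het = FALSE,
                  is_water = FALSE, occ = 1, bfac = 0, alt = "", icode = "")
  expect_equal(nrow(detect_hbonds(a, b, 3.5)), 0L)
  expect_equal(nrow(detect_hbonds(b, a, 3.5)), 0L)
})

test_that("salt bridges pair basic and acidic atoms within dmax", {
  mk <- function(atom, element, resname, x) {
    data.frame(atom = atom, element = element, x = x, y = 0, z = 0,
               resname = resname, resno = 1, chain = "A", is_het = FALSE,
               is_water = FALSE, occ = 1, bfac = 0, alt = "", icode = "")
  }
  lys <- mk("NZ", "N", "LYS", 0)
  asp <- mk("OD1", "O", "ASP", 3.2)
  expect_equal(nrow(detect_salt_bridges(lys, asp, dmax = 4.0)), 1L)
  expect_equal(detect_salt_bridges(lys, asp, 4.0)$distance, 3.2)
  asp_far <- mk("OD1", "O", "ASP", 5.5)
  expect_equal(nrow(detect_salt_bridges(lys, asp_far, dmax = 4.0)), 0L)
  # direction-agnostic: acidic group may sit in either argument
  expect_equal(nrow(detect_salt_bridges(asp, lys, dmax = 4.0)), 1L)
  # phosphate-like het oxygens count as acidic partners
  po <- mk("O1A", "O", "UDP", 3.0); po$is_het <- TRUE
  arg <- mk("NH1", "N", "ARG", 0)
  expect_equal(nrow(detect_salt_bridges(arg, po, dmax = 4.0)), 1L)
})

test_that("C4-C4 distance, productive flag and boundary inclusivity", {
  g <- catalytic_c4c4(make_toy_complex(3.4)$structure,
                      make_toy_complex(3.4)$roles, tyr_resno = 150)
  expect_equal(g$distance, 3.4, tolerance = 1e-9)
  expect_true(g$productive)
  expect_equal(g$o4_tyr_oh_distance, 2.6, tolerance = 1e-9)
  # nonproductive displaced mode (the 9.4-A case)
  far <- make_toy_complex(9.4)
  expect_false(catalytic_c4c4(far$structure, far$roles)$productive)
  # inclusive bounds at both ends
  lo <- make_toy_complex(3.0)
  hi <- make_toy_complex(3.7)
  expect_true(catalytic_c4c4(lo$structure, lo$roles)$productive)
  expect_true(catalytic_c4c4(hi$structure, hi$roles)$productive)
  just_out <- make_toy_complex(3.75)
  expect_false(catalytic_c4c4(just_out$structure, just_out$roles)$productive)
})

test_that("missing ligands or atoms raise descriptive errors", {
  tc <- make_toy_complex()
  bad_roles <- tc$roles
  bad_roles$udp_sugar$code <- "XXX"
  expect_error(catalytic_c4c4(tc$structure, bad_roles), "not found")
  bad_roles2 <- tc$roles
  bad_roles2$udp_sugar$c4 <- "C99"
  expect_error(catalytic_c4c4(tc$structure, bad_roles2), "C99")
})

test_that("ring face reports the planted side and flips under reflection", {
  s_std <- make_toy_complex(face = "pro_S")
  expect_equal(as.character(ring_face(s_std$structure, s_std$roles)),
               "standard")
  s_flip <- make_toy_complex(face = "pro_R")
  expect_equal(as.character(ring_face(s_flip$structure, s_flip$roles)),
               "flipped")
  # mirror image of a standard complex is flipped
  expect_equal(as.character(ring_face(reflect(s_std$structure), s_std$roles)),
               "flipped")
  # proper rigid motion leaves the call unchanged
  expect_equal(as.character(ring_face(rigid_move(s_std$structure, 5),
                                      s_std$roles)), "standard")
})

test_that("Asn swing conformer is called from the planted rotamer", {
  s_in <- make_toy_complex(asn_rotamer = "in")
  call_in <- classify_c2_swing(s_in$structure, 200, roles = s_in$roles)
  expect_equal(call_in$asn_swing, "swing_in")
  s_out <- make_toy_complex(asn_rotamer = "out")
  call_out <- classify_c2_swing(s_out$structure, 200, roles = s_out$roles)
  expect_equal(call_out$asn_swing, "swing_out")
  # chi angles are reported and differ between the rotamers
  expect_true(is.finite(call_in$chi1) && is.finite(call_in$chi2))
  expect_false(isTRUE(all.equal(call_in$chi2, call_out$chi2)))
  # wrong residue type is an error
  expect_error(classify_c2_swing(s_in$structure, 150, roles = s_in$roles),
               "not an asparagine")
})

test_that("distances and categorical calls are rigid-motion invariant", {
  tc <- make_toy_complex(c4c4 = 3.5, face = "pro_S", asn_rotamer = "in")
  base_g <- catalytic_c4c4(tc$structure, tc$roles, tyr_resno = 150)
  base_sw <- classify_c2_swing(tc$structure, 200, roles = tc$roles)
  for (seed in 1:5) {
    moved <- rigid_move(tc$structure, seed)
    g <- catalytic_c4c4(moved, tc$roles, tyr_resno = 150)
    expect_equal(g$distance, base_g$distance, tolerance = 1e-6)
    expect_equal(g$o4_tyr_oh_distance, base_g$o4_tyr_oh_distance,
                 tolerance = 1e-6)
    expect_equal(g$productive, base_g$productive)
    sw <- classify_c2_swing(moved, 200, roles = tc$roles)
    expect_equal(sw$asn_swing, base_sw$asn_swing)
    expect_equal(sw$carboxamide_pocket_distance,
                 base_sw$carboxamide_pocket_distance, tolerance = 1e-6)
  }
})
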