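test_that("a single-record PDB file parses to one chain, residue and atom", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00 10.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_s3_class(s, "gale_structure")
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(structure_chains(s), "A")
  expect_equal(s$atoms$atom, "CA")
  expect_equal(as.numeric(s$atoms[1, c("x", "y", "z")]), c(1, 2, 3))
})

test_that("write/read round-trips coordinates to 3 decimals and is idempotent", {
  p <- make_toy_peptide("AYGKC", start_resno = 10, jitter_sd = 0.2, seed = 4)
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(p, f1)
  r1 <- read_structure(f1)
  expect_lt(max(abs(atom_coords(r1$atoms) - atom_coords(p$atoms))), 1e-3)
  expect_equal(r1$atoms$atom, p$atoms$atom)
  expect_equal(r1$atoms$resname, p$atoms$resname)
  expect_equal(r1$atoms$resno, p$atoms$resno)
  # read-write-read: second generation identical to the first
  write_structure(r1, f2)
  r2 <- read_structure(f2)
  expect_identical(r1$atoms[, c("atom", "resname", "resno", "chain")],
                   r2$atoms[, c("atom", "resname", "resno", "chain")])
  expect_equal(atom_coords(r2$atoms), atom_coords(r1$atoms), tolerance = 1e-9)
})

test_that("atom counts match the generator's declared counts", {
  p <- make_toy_peptide("AYG")
  man <- attr(p, "manifest")
  expect_equal(nrow(p$atoms), man$n_atoms)
  expect_equal(nrow(select_atoms(p, atom = "CA")), man$n_calpha)
})

test_that("mmCIF input parses and altlocs resolve to highest occupancy", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOY", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.0 2.0 3.0 1.00 10.0 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.0 2.5 3.2 1.00 10.0 ? 1 ALA A CA 1",
    "ATOM 3 C CA A ALA A 1 2 ? 5.0 2.5 3.2 0.40 10.0 ? 2 ALA A CA 1",
    "ATOM 4 C CA B ALA A 1 2 ? 5.4 2.5 3.2 0.60 10.0 ? 2 ALA A CA 1",
    "HETATM 5 MG MG . MG B 2 . ? 9.0 9.0 9.0 1.00 20.0 ? 101 MG A MG 1"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 4L)             # one altloc dropped
  res2 <- select_atoms(s, resno = 2, atom = "CA")
  expect_equal(res2$alt, "B")                 # occupancy 0.6 wins
  expect_equal(res2$x, 5.4)
  expect_equal(nrow(select_atoms(s, het = TRUE)), 1L)
})

test_that("altloc ties resolve by altloc letter order", {
  atoms <- data.frame(
    atom = c("CA", "CA"), element = "C", x = c(1, 2), y = 0, z = 0,
    occ = c(0.5, 0.5), alt = c("B", "A"), resname = "ALA", resno = 1,
    chain = "A", stringsAsFactors = FALSE)
  s <- gale_structure("tie", atoms)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(s$atoms$alt, "A")
})

test_that("selection filters combine and report malformed selectors", {
  p <- make_toy_peptide("AYG", start_resno = 148)
  expect_equal(nrow(select_atoms(p, atom = "CA", chain = "A")), 3L)
  oh <- select_atoms(p, resno = 149, atom = "OH")
  expect_equal(nrow(oh), 1L)
  expect_equal(oh$resname, "TYR")
  expect_equal(nrow(select_atoms(p, resno = 999)), 0L)
  expect_error(select_atoms(p, atom = character(0)), "malformed selector")
  expect_error(select_atoms(p, predicate = function(a) TRUE),
               "malformed selector")
})

test_that("selection finds a planted cofactor atom in the toy complex", {
  tc <- make_toy_complex(c4c4 = 3.4)
  hit <- select_atoms(tc$structure, resname = "NCA", atom = "C4", het = TRUE)
  expect_equal(nrow(hit), 1L)
  expect_equal(as.numeric(hit[1, c("x", "y", "z")]), tc$manifest$nic_c4,
               tolerance = 1e-9)
})

test_that("ligand extraction handles absent and ambiguous codes", {
  tc <- make_toy_complex()
  lig <- extract_ligand(tc$structure, "NCA")
  expect_equal(nrow(lig), 6L)
  expect_error(extract_ligand(tc$structure, "XYZ"), "not found")
  dup <- tc$structure
  extra <- dup$atoms[dup$atoms$resname == "NCA", ]
  extra$resno <- 500L
  dup$atoms <- rbind(dup$atoms, extra)
  expect_error(extract_ligand(dup, "NCA"), "instance")
  expect_equal(nrow(extract_ligand(dup, "NCA", instance = 2)), 6L)
})

test_that("unreadable files and unknown formats raise descriptive errors", {
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines("garbage", f)
  expect_error(read_structure(f), "format")
})
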