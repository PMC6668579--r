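#' Seeded synthetic fixtures
#'
#' Deterministic generators for every fixture the test surface needs:
#' rotated/perturbed coordinate copies with known superposition relations,
#' toy ternary complexes with planted active-site geometry, sphere-cluster
#' "dimers" with analytically checkable burial, planted hydrogen-bond pairs,
#' and sequence families evolved along a known tree. Each generator returns
#' its ground truth in a `manifest` so oracles never consult generator
#' internals at run time; the same seed always reproduces the same fixture.
#'
#' @name synthetic_data
NULL

#' Toy peptide structure
#'
#' Minimal extended-chain peptide: N, CA, C, O per residue, CB for
#' non-glycine residues and the phenol OH for tyrosines (so selections like
#' "the hydroxyl of Tyr150" have a target). Geometry is idealized (the
#' geometric operations read names and coordinates only).
#'
#' @param sequence one-letter sequence (default `"AAA"`).
#' @param start_resno first author residue number.
#' @param chain chain identifier.
#' @param id structure identifier.
#' @param jitter_sd optional Gaussian coordinate jitter (angstrom).
#' @param seed RNG seed for the jitter.
#' @return A [gale_structure]; attribute `manifest` records atom counts.
#' @export
make_toy_peptide <- function(sequence = "AAA", start_resno = 1L, chain = "A",
                             id = "toy_peptide", jitter_sd = 0, seed = 1L) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  rows <- list()
  for (i in seq_along(aa)) {
    base <- c(3.5 * (i - 1), 2 * (i %% 2), 0)
    res3 <- bio3d::aa123(aa[i])
    atoms <- rbind(
      N  = base + c(-0.9, 0.8, 0.2),
      CA = base,
      C  = base + c(1.3, 0.6, -0.2),
      O  = base + c(1.6, 1.8, -0.3))
    if (aa[i] != "G") atoms <- rbind(atoms, CB = base + c(0.3, -1.4, 0.6))
    if (aa[i] == "Y") atoms <- rbind(atoms, OH = base + c(0.8, -4.9, 1.8))
    rows[[i]] <- data.frame(atom = rownames(atoms),
                            element = substr(rownames(atoms), 1, 1),
                            x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
                            resname = res3, resno = start_resno + i - 1L,
                            chain = chain, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  if (jitter_sd > 0)
    atoms[, c("x", "y", "z")] <- with_seed(seed,
      atoms[, c("x", "y", "z")] + rnorm(3 * nrow(atoms), sd = jitter_sd))
  s <- gale_structure(id, atoms)
  attr(s, "manifest") <- list(n_res = length(aa), n_atoms = nrow(atoms),
                              sequence = sequence,
                              n_calpha = length(aa))
  s
}

#' Rotated, perturbed copy of a structure
#'
#' Applies a proper rotation and translation, adds optional isotropic
#' Gaussian noise, and optionally displaces a chosen number of atoms by a
#' fixed magnitude in random directions (planted outliers for trimming
#' tests). The manifest records the transform, the realized coordinates and
#' the outlier indices, so RMSD oracles are exact for the realization.
#'
#' @param base a [gale_structure].
#' @param rotation 3 x 3 proper rotation; default: a seeded random rotation.
#' @param translation length-3 vector (default `c(5, -3, 8)`).
#' @param noise_sd Gaussian noise standard deviation per coordinate
#'   (angstrom).
#' @param n_outliers number of planted outlier atoms.
#' @param outlier_mag displacement magnitude for outliers (angstrom).
#' @param seed RNG seed.
#' @return List with `structure` (the transformed copy) and `manifest`
#'   (rotation, translation, `coords_true` — transformed coordinates before
#'   perturbation —, `coords_realized`, `outlier_idx`).
#' @export
make_rotated_copy <- function(base, rotation = NULL,
                              translation = c(5, -3, 8), noise_sd = 0,
                              n_outliers = 0L, outlier_mag = 5, seed = 1L) {
  stopifnot(inherits(base, "gale_structure"))
  with_seed(seed, {
    rotation <- rotation %||% random_rotations(1L)[[1]]
    xyz <- atom_coords(base$atoms)
    true <- xyz %*% t(rotation) +
      matrix(translation, nrow(xyz), 3, byrow = TRUE)
    realized <- true
    if (noise_sd > 0)
      realized <- realized + matrix(rnorm(length(true), sd = noise_sd),
                                    nrow(true), 3)
    outlier_idx <- integer()
    if (n_outliers > 0L) {
      outlier_idx <- sort(sample.int(nrow(true), n_outliers))
      dir <- matrix(rnorm(3 * n_outliers), n_outliers, 3)
      dir <- dir / sqrt(rowSums(dir^2))
      realized[outlier_idx, ] <- realized[outlier_idx, ] + outlier_mag * dir
    }
    s <- base
    s$id <- paste0(base$id, "_moved")
    s$atoms$x <- realized[, 1]; s$atoms$y <- realized[, 2]
    s$atoms$z <- realized[, 3]
    list(structure = s,
         manifest = list(rotation = rotation, translation = translation,
                         noise_sd = noise_sd, coords_true = true,
                         coords_realized = realized,
                         outlier_idx = outlier_idx,
                         outlier_mag = outlier_mag, seed = seed))
  })
}

#' Paired coordinates between a structure and its moved copy
#'
#' Pairs atoms by file order (the generators preserve atom order), yielding
#' the exact correspondence for superposition oracles.
#'
#' @param base a [gale_structure].
#' @param moved the `structure` element of [make_rotated_copy()].
#' @return A [paired_coords].
#' @export
pair_by_order <- function(base, moved) {
  paired_coords(atom_coords(base$atoms), atom_coords(moved$atoms),
                paste0(base$atoms$resno, "/", base$atoms$atom))
}

#' Toy ternary complex with planted active-site geometry
#'
#' Builds a minimal NAD-like/UDP-sugar-like complex: a planar six-membered
#' ring labelled as the nicotinamide (het code `NCA`, ring atoms
#' N1,C2,C3,C4,C5,C6 ordered so the ring normal points to the planted pro-S
#' side), a pyranose-like ring (het code `SUG`) whose C4 sits at the
#' prescribed C4-C4 distance on the requested face, an O4 substituent with
#' a tyrosine OH planted 2.6 A away, an O2 substituent marking the
#' C2-substituent pocket, and an asparagine whose carboxamide is planted
#' either against the O2 pocket (`"in"`) or rotated away (`"out"`).
#' Bond lengths are idealized (~1.4-1.5 A ring bonds).
#'
#' @param c4c4 planted sugar-C4 to nicotinamide-C4 distance (angstrom).
#' @param face `"pro_S"` (standard conformation) or `"pro_R"` (flipped).
#' @param asn_rotamer `"in"` or `"out"`.
#' @param tyr_oh_o4 planted Tyr OH to sugar O4 distance (default 2.6).
#' @param seed RNG seed (reserved; the construction is deterministic).
#' @param id structure identifier.
#' @return List with `structure`, `roles` (a [ligand_roles()] map matching
#'   the toy component codes) and `manifest` (all planted values).
#' @export
make_toy_complex <- function(c4c4 = 3.4, face = c("pro_S", "pro_R"),
                             asn_rotamer = c("in", "out"), tyr_oh_o4 = 2.6,
                             seed = 1L, id = "toy_complex") {
  face <- match.arg(face)
  asn_rotamer <- match.arg(asn_rotamer)
  sgn <- if (face == "pro_S") 1 else -1
  # nicotinamide-like ring in the z = 0 plane, counterclockwise from +x so
  # the ordered-ring normal is +z
  ring_r <- 1.40
  ang <- (seq_len(6) - 1) * pi / 3
  nic <- data.frame(atom = c("N1", "C2", "C3", "C4", "C5", "C6"),
                    element = c("N", rep("C", 5)),
                    x = ring_r * cos(ang), y = ring_r * sin(ang), z = 0,
                    resname = "NCA", resno = 401L, chain = "A",
                    is_het = TRUE, stringsAsFactors = FALSE)
  nic_c4 <- as.numeric(nic[nic$atom == "C4", c("x", "y", "z")])  # (-1.4, 0, 0)
  # sugar ring parallel to the nicotinamide plane, its C4 directly above
  # (pro-S) or below (pro-R) the nicotinamide C4
  zs <- sgn * c4c4
  sug_r <- 1.45
  sug_center <- nic_c4 + c(sug_r, 0, 0) + c(0, 0, zs)
  sug_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  sug_ang <- c(0, 60, 120, 180, 240, 300) * pi / 180
  sug <- data.frame(atom = sug_names,
                    element = c(rep("C", 5), "O"),
                    x = sug_center[1] + sug_r * cos(sug_ang),
                    y = sug_center[2] + sug_r * sin(sug_ang),
                    z = sug_center[3],
                    resname = "SUG", resno = 402L, chain = "A",
                    is_het = TRUE, stringsAsFactors = FALSE)
  sug_c4 <- as.numeric(sug[sug$atom == "C4", c("x", "y", "z")])
  sug_c2 <- as.numeric(sug[sug$atom == "C2", c("x", "y", "z")])
  o4 <- sug_c4 + c(-1.43, 0, 0)
  o2_dir <- (sug_c2 - sug_center) / sqrt(sum((sug_c2 - sug_center)^2))
  o2 <- sug_c2 + 1.43 * o2_dir
  sug <- rbind(sug,
    data.frame(atom = c("O4", "O2"), element = "O",
               x = c(o4[1], o2[1]), y = c(o4[2], o2[2]),
               z = c(o4[3], o2[3]), resname = "SUG", resno = 402L,
               chain = "A", is_het = TRUE, stringsAsFactors = FALSE))
  # tyrosine with OH planted at tyr_oh_o4 from the sugar O4
  oh <- o4 + c(-tyr_oh_o4, 0, 0)
  tyr <- data.frame(
    atom = c("N", "CA", "CB", "OH"), element = c("N", "C", "C", "O"),
    x = oh[1] + c(-5.5, -4.3, -3.0, 0), y = oh[2] + c(0.8, 0.2, 0.9, 0),
    z = oh[3] + c(0.3, 0.1, -0.2, 0),
    resname = "TYR", resno = 150L, chain = "A", is_het = FALSE,
    stringsAsFactors = FALSE)
  # asparagine: backbone fixed, carboxamide toward (in) or away from (out)
  # the O2 pocket center
  cb <- o2 + c(0.4, 4.5, 0.5)
  n_ca_off <- c(1.2, 1.1, 0.4)
  ca <- cb + c(0.5, 1.4, 0.3)
  nn <- ca + n_ca_off
  if (asn_rotamer == "in") {
    cg <- o2 + c(0.2, 3.0, 0.4)
    od1 <- o2 + c(-0.9, 2.4, 0.2)
    nd2 <- o2 + c(1.2, 2.3, 0.5)
  } else {
    cg <- cb + c(0.4, 1.5, 0.2)
    od1 <- cg + c(-1.0, 0.7, 0.1)
    nd2 <- cg + c(1.1, 0.7, 0.3)
  }
  asn_xyz <- rbind(N = nn, CA = ca, CB = cb, CG = cg, OD1 = od1, ND2 = nd2)
  asn <- data.frame(atom = rownames(asn_xyz),
                    element = substr(rownames(asn_xyz), 1, 1),
                    x = asn_xyz[, 1], y = asn_xyz[, 2], z = asn_xyz[, 3],
                    resname = "ASN", resno = 200L, chain = "A",
                    is_het = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(nic, sug, tyr, asn)
  rownames(atoms) <- NULL
  s <- gale_structure(id, atoms)
  roles <- ligand_roles(
    nicotinamide_cofactor = list(code = "NCA",
                                 ring = c("N1", "C2", "C3", "C4", "C5", "C6"),
                                 c4 = "C4"),
    udp_sugar = list(code = "SUG", c4 = "C4", o4 = "O4",
                     c2_substituent = "O2"),
    uridine_nucleotide = list(code = "UDP"))
  list(structure = s, roles = roles,
       manifest = list(c4c4 = c4c4, face = face, asn_rotamer = asn_rotamer,
                       tyr_oh_o4 = tyr_oh_o4, tyr_resno = 150L,
                       asn_resno = 200L, o2_pocket_center = o2,
                       nic_c4 = nic_c4, sug_c4 = sug_c4))
}

#' Two-cluster "dimer" for interface-burial oracles
#'
#' Two chains of atoms separated along x. With one atom per protomer the
#' buried area has the two-sphere closed form ([two_sphere_sasa_exact()]);
#' with clusters, lattice-integration oracles apply. Atoms are written as
#' glycine C-alphas so the result is a valid two-chain protein for
#' [interface_report()].
#'
#' @param n_atoms atoms per protomer.
#' @param separation center-to-center distance along x (angstrom).
#' @param cluster_radius radius of the uniform ball each cluster is drawn
#'   from (ignored for `n_atoms = 1`).
#' @param element element symbol for all atoms (default `"C"`).
#' @param seed RNG seed.
#' @return List with `structure` and `manifest` (coordinates per protomer).
#' @export
make_dimer_spheres <- function(n_atoms = 1L, separation = 6, cluster_radius = 3,
                               element = "C", seed = 1L) {
  draw <- function(center) {
    if (n_atoms == 1L) return(matrix(center, 1, 3))
    m <- matrix(rnorm(3 * n_atoms), n_atoms, 3)
    m <- m / sqrt(rowSums(m^2)) * cluster_radius * runif(n_atoms)^(1 / 3)
    sweep(m, 2, center, "+")
  }
  with_seed(seed, {
    xa <- draw(c(0, 0, 0))
    xb <- draw(c(separation, 0, 0))
    mk <- function(xyz, ch) data.frame(
      atom = "CA", element = element, x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], resname = "GLY", resno = seq_len(nrow(xyz)),
      chain = ch, is_het = FALSE, stringsAsFactors = FALSE)
    s <- gale_structure("dimer_spheres", rbind(mk(xa, "A"), mk(xb, "B")))
    list(structure = s,
         manifest = list(coords_A = xa, coords_B = xb,
                         separation = separation, seed = seed))
  })
}

#' Planted polar-atom pairs for hydrogen-bond detection
#'
#' Two atom groups: group A holds serine OG donors, group B backbone
#' carbonyl O acceptors, pair `i` planted at `distances[i]`. Pairs are
#' spaced far apart (50 A) so only the planted partner is in range.
#'
#' @param distances planted donor-acceptor distances (angstrom).
#' @param seed RNG seed (orientation of each planted pair).
#' @return List with `group_a`, `group_b` atom tables and `manifest`.
#' @export
make_hbond_set <- function(distances = c(2.8, 3.2), seed = 1L) {
  with_seed(seed, {
    n <- length(distances)
    rows_a <- rows_b <- vector("list", n)
    for (i in seq_len(n)) {
      base <- c(50 * (i - 1), 0, 0)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      pa <- base
      pb <- base + distances[i] * dir
      rows_a[[i]] <- data.frame(atom = "OG", element = "O", x = pa[1],
                                y = pa[2], z = pa[3], resname = "SER",
                                resno = i, chain = "A", is_het = FALSE,
                                stringsAsFactors = FALSE)
      rows_b[[i]] <- data.frame(atom = "O", element = "O", x = pb[1],
                                y = pb[2], z = pb[3], resname = "GLY",
                                resno = i, chain = "B", is_het = FALSE,
                                stringsAsFactors = FALSE)
    }
    ga <- gale_structure("hbond_A", do.call(rbind, rows_a))$atoms
    gb <- gale_structure("hbond_B", do.call(rbind, rows_b))$atoms
    list(group_a = ga, group_b = gb,
         manifest = list(distances = distances, seed = seed))
  })
}

#' Sequence family evolved along a known tree
#'
#' Simulates protein sequences down a rooted `phylo` tree under a simple
#' Poisson substitution model: along a branch of length `b` (expected
#' substitutions per site), each site receives `Poisson(b)` replacement
#' events, each drawn uniformly from the 20 residues (so a fraction 1/20 of
#' events is silent). Branch lengths therefore match pairwise divergence in
#' expectation; the manifest records the realized sequences at every node
#' so oracles are exact.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param n_sites sequence length (sites).
#' @param seed RNG seed.
#' @return List with `sequences` (named character vector over the leaves),
#'   `tree` (the input tree) and `manifest` (root sequence, per-edge
#'   substitution-event counts).
#' @export
make_sequence_family <- function(tree, n_sites = 500L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    node_seq <- vector("list", max(tree$edge))
    node_seq[[root]] <- sample(AA20, n_sites, replace = TRUE)
    edge_events <- integer(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      seq_c <- node_seq[[parent]]
      b <- tree$edge.length[e]
      n_events <- rpois(1L, b * n_sites)
      if (n_events > 0L) {
        sites <- sample.int(n_sites, n_events, replace = TRUE)
        repl <- sample(AA20, n_events, replace = TRUE)
        for (k in seq_len(n_events)) seq_c[sites[k]] <- repl[k]
      }
      edge_events[e] <- n_events
      node_seq[[child]] <- seq_c
    }
    leaves <- vapply(seq_len(n_tip),
                     function(i) paste(node_seq[[i]], collapse = ""),
                     character(1))
    names(leaves) <- tree$tip.label
    list(sequences = leaves, tree = tree,
         manifest = list(root_sequence = paste(node_seq[[root]], collapse = ""),
                         edge_events = edge_events, n_sites = n_sites,
                         seed = seed))
  })
}
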