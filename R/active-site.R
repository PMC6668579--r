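#' Euclidean distance between two atoms
#'
#' @param a,b single atom rows (one-row data frames with `x`, `y`, `z`) or
#'   numeric xyz vectors.
#' @return Distance in angstrom.
#' @export
atom_distance <- function(a, b) {
  pa <- if (is.data.frame(a)) as.numeric(a[1, c("x", "y", "z")]) else as.numeric(a)
  pb <- if (is.data.frame(b)) as.numeric(b[1, c("x", "y", "z")]) else as.numeric(b)
  sqrt(sum((pa - pb)^2))
}

# Donor/acceptor chemistry tables (heavy atoms only; the crystal structures
# carry no hydrogens, so plausibility is judged by residue chemistry).
DONOR_SIDECHAIN <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), ASN = "ND2",
  GLN = "NE2", TRP = "NE1")
ACCEPTOR_SIDECHAIN <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
  CYS = "SG")

is_donor_atom <- function(atoms) {
  side <- mapply(function(rn, an) an %in% (DONOR_SIDECHAIN[[rn]] %||% character()),
                 atoms$resname, atoms$atom)
  backbone_n <- !atoms$is_het & atoms$atom == "N"
  # het groups (cofactor, UDP-sugar, waters): any N/O/S treated as donor-capable
  het_polar <- atoms$is_het & atoms$element %in% c("N", "O", "S")
  backbone_n | side | het_polar | atoms$is_water
}

is_acceptor_atom <- function(atoms) {
  side <- mapply(function(rn, an) an %in% (ACCEPTOR_SIDECHAIN[[rn]] %||% character()),
                 atoms$resname, atoms$atom)
  backbone_o <- !atoms$is_het & atoms$atom %in% c("O", "OXT")
  het_polar <- atoms$is_het & atoms$element %in% c("N", "O", "S")
  side | backbone_o | het_polar | atoms$is_water
}

all_pair_distances <- function(ga, gb) {
  pa <- atom_coords(ga); pb <- atom_coords(gb)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  sqrt(pmax(d2, 0))
}

atom_tag <- function(atoms) {
  paste0(atoms$chain, "/", atoms$resname, atoms$resno, "/", atoms$atom)
}

#' Detect hydrogen bonds between two atom groups
#'
#' Geometric criterion: heavy-atom donor-acceptor pairs (N/O/S vs N/O/S, at
#' least one partner donor-capable and the other acceptor-capable by residue
#' chemistry) within `dmax`. No angular term is applied because the input
#' structures carry no hydrogens. Bonds are returned sorted by distance.
#'
#' @param group_a,group_b disjoint atom tables.
#' @param dmax heavy-atom distance cutoff in angstrom (default 3.5).
#' @return Data frame of class `hbond_list` with donor/acceptor tags and
#'   distances (possibly zero rows).
#' @export
detect_hbonds <- function(group_a, group_b, dmax = 3.5) {
  polar_a <- group_a[group_a$element %in% c("N", "O", "S"), , drop = FALSE]
  polar_b <- group_b[group_b$element %in% c("N", "O", "S"), , drop = FALSE]
  empty <- data.frame(donor = character(), acceptor = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(polar_a) == 0L || nrow(polar_b) == 0L)
    return(structure(empty, class = c("hbond_list", "data.frame")))
  d <- all_pair_distances(polar_a, polar_b)
  don_a <- is_donor_atom(polar_a); acc_a <- is_acceptor_atom(polar_a)
  don_b <- is_donor_atom(polar_b); acc_b <- is_acceptor_atom(polar_b)
  ok <- d <= dmax & (outer(don_a, acc_b, "&") | outer(acc_a, don_b, "&"))
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(structure(empty, class = c("hbond_list", "data.frame")))
  a_is_donor <- don_a[idx[, 1]]
  res <- data.frame(
    donor = ifelse(a_is_donor, atom_tag(polar_a)[idx[, 1]],
                   atom_tag(polar_b)[idx[, 2]]),
    acceptor = ifelse(a_is_donor, atom_tag(polar_b)[idx[, 2]],
                      atom_tag(polar_a)[idx[, 1]]),
    distance = d[idx], stringsAsFactors = FALSE)
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("hbond_list", "data.frame"))
}

BASIC_ATOMS <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                    HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
# phosphate-like oxygens of nucleotide het groups (UDP: O1A/O2A/O3A, O1B/...)
PHOSPHATE_O_REGEX <- "^(O[0-9][ABG]|OP[0-9]|O[0-9]P)$"

is_basic_atom <- function(atoms) {
  mapply(function(rn, an) an %in% (BASIC_ATOMS[[rn]] %||% character()),
         atoms$resname, atoms$atom)
}
is_acidic_atom <- function(atoms) {
  side <- mapply(function(rn, an) an %in% (ACIDIC_ATOMS[[rn]] %||% character()),
                 atoms$resname, atoms$atom)
  phos <- atoms$is_het & atoms$element == "O" & grepl(PHOSPHATE_O_REGEX, atoms$atom)
  cterm <- atoms$atom == "OXT"
  side | phos | cterm
}

#' Detect salt bridges between two atom groups
#'
#' Charged-group heavy-atom contacts within `dmax`: basic atoms are Lys NZ,
#' Arg NE/NH1/NH2 and His ND1/NE2; acidic atoms are Asp OD1/OD2, Glu OE1/OE2,
#' the C-terminal OXT, and phosphate oxygens of het groups (O1A-style names).
#'
#' @param group_a,group_b disjoint atom tables.
#' @param dmax distance cutoff in angstrom (default 4.0).
#' @return Data frame of class `saltbridge_list` with basic/acidic atom tags
#'   and distances.
#' @export
detect_salt_bridges <- function(group_a, group_b, dmax = 4.0) {
  find <- function(basic, acidic) {
    b <- basic[is_basic_atom(basic), , drop = FALSE]
    a <- acidic[is_acidic_atom(acidic), , drop = FALSE]
    if (nrow(b) == 0L || nrow(a) == 0L)
      return(data.frame(basic = character(), acidic = character(),
                        distance = numeric(), stringsAsFactors = FALSE))
    d <- all_pair_distances(b, a)
    idx <- which(d <= dmax, arr.ind = TRUE)
    data.frame(basic = atom_tag(b)[idx[, 1]], acidic = atom_tag(a)[idx[, 2]],
               distance = d[idx], stringsAsFactors = FALSE)
  }
  res <- rbind(find(group_a, group_b), find(group_b, group_a))
  res <- res[order(res$distance), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("saltbridge_list", "data.frame"))
}

#' Ligand role map
#'
#' Chemical-component dictionaries use distinct het codes and atom names for
#' the nicotinamide cofactor and the different UDP-sugars, so the pipeline
#' maps ligand *roles* to codes/atom names rather than hard-coding them.
#' Defaults follow the wwPDB components NAD (nicotinamide ring atoms
#' N1N..C6N) and primed sugar-atom names; synthetic fixtures override them.
#'
#' @param nicotinamide_cofactor,udp_sugar,uridine_nucleotide lists with
#'   entries `code` (het code) and, where relevant, `ring` (ordered ring atom
#'   names), `c4`, `o4`, `c2_substituent` (atom names).
#' @return A named list of roles.
#' @export
ligand_roles <- function(
    nicotinamide_cofactor = list(code = "NAD",
                                 ring = c("N1N", "C2N", "C3N", "C4N", "C5N", "C6N"),
                                 c4 = "C4N"),
    udp_sugar = list(code = "UPG", c4 = "C4'", o4 = "O4'",
                     c2_substituent = "O2'"),
    uridine_nucleotide = list(code = "UDP")) {
  list(nicotinamide_cofactor = nicotinamide_cofactor,
       udp_sugar = udp_sugar,
       uridine_nucleotide = uridine_nucleotide)
}

role_atom <- function(s, role, atom_name, what) {
  lig <- extract_ligand(s, role$code)
  at <- lig[lig$atom == atom_name, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(what, ": atom '", atom_name, "' not found in het group '",
         role$code, "' of ", s$id)
  at[1, , drop = FALSE]
}

#' Catalytic C4-C4 geometry and productive-mode call
#'
#' Measures the distance between the sugar-ring C4 atom and the nicotinamide
#' C4 atom — the hydride donor/acceptor pair of the GalE mechanism — and
#' flags the geometry as productive when the distance lies within
#' `productive_range` (bounds inclusive). When `tyr_resno` is given, the
#' distance from that tyrosine's OH to the sugar O4 (the proton-transfer
#' partner of the catalytic base) is reported as well.
#'
#' @param s a [gale_structure] containing the cofactor and UDP-sugar.
#' @param roles a [ligand_roles()] map.
#' @param productive_range inclusive bounds in angstrom, default `c(3.0, 3.7)`
#'   (the hydride-transfer-compatible range).
#' @param tyr_resno author residue number of the catalytic tyrosine in this
#'   structure's numbering, or `NULL` to skip the OH-O4 measurement.
#' @param chain chain holding the tyrosine (default: first polymer chain).
#' @return An object of class `catalytic_geometry`: list with `distance`,
#'   `productive`, `o4_tyr_oh_distance` (`NA` if not measured), the two C4
#'   atom rows, and the range used.
#' @export
catalytic_c4c4 <- function(s, roles = ligand_roles(),
                           productive_range = c(3.0, 3.7),
                           tyr_resno = NULL, chain = NULL) {
  c4_nic <- role_atom(s, roles$nicotinamide_cofactor,
                      roles$nicotinamide_cofactor$c4, "cofactor C4")
  c4_sug <- role_atom(s, roles$udp_sugar, roles$udp_sugar$c4, "sugar C4")
  d <- atom_distance(c4_sug, c4_nic)
  o4_tyr <- NA_real_
  if (!is.null(tyr_resno)) {
    chain <- chain %||% structure_chains(s)[1L]
    oh <- select_atoms(s, chain = chain, resno = tyr_resno, atom = "OH",
                       het = FALSE)
    o4 <- extract_ligand(s, roles$udp_sugar$code)
    o4 <- o4[o4$atom == roles$udp_sugar$o4, , drop = FALSE]
    if (nrow(oh) == 1L && nrow(o4) == 1L)
      o4_tyr <- atom_distance(oh, o4)
  }
  structure(list(c4_sugar = c4_sug, c4_nicotinamide = c4_nic, distance = d,
                 productive = d >= productive_range[1] & d <= productive_range[2],
                 o4_tyr_oh_distance = o4_tyr,
                 productive_range = productive_range),
            class = "catalytic_geometry")
}

#' @export
print.catalytic_geometry <- function(x, ...) {
  cat(sprintf("<catalytic_geometry> C4-C4 = %.1f A (%sproductive, range [%.1f, %.1f])",
              x$distance, if (x$productive) "" else "non-", x$productive_range[1],
              x$productive_range[2]))
  if (!is.na(x$o4_tyr_oh_distance))
    cat(sprintf("; Tyr OH - O4 = %.1f A", x$o4_tyr_oh_distance))
  cat("\n")
  invisible(x)
}

ring_normal <- function(ring_coords) {
  ctr <- colMeans(ring_coords)
  v <- sweep(ring_coords, 2, ctr)
  n <- c(0, 0, 0)
  k <- nrow(v)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    n <- n + c(v[i, 2] * v[j, 3] - v[i, 3] * v[j, 2],
               v[i, 3] * v[j, 1] - v[i, 1] * v[j, 3],
               v[i, 1] * v[j, 2] - v[i, 2] * v[j, 1])
  }
  list(center = ctr, normal = n / sqrt(sum(n^2)))
}

#' Sugar ring-face call: standard vs flipped conformation
#'
#' Determines on which face of the nicotinamide ring plane the sugar C4 atom
#' lies. The plane normal is fixed by the ring-atom ordering of the
#' component dictionary (N1, C2, C3, C4, C5, C6): with the ring traversed in
#' that order, the normal is the right-handed sum of consecutive
#' cross-products about the ring centroid, and the positive-normal side is
#' taken as the pro-S (B) face. A sugar C4 on the pro-S side corresponds to
#' the "standard" conformation (H4 facing pro-S); the opposite side is the
#' "flipped" conformation. The call inverts under coordinate reflection and
#' is invariant under proper rigid motion.
#'
#' @param s a [gale_structure].
#' @param roles a [ligand_roles()] map (uses the cofactor `ring` ordering and
#'   the sugar `c4` atom).
#' @return `"standard"` or `"flipped"`, with attribute `signed_distance`
#'   (angstrom; positive = pro-S side).
#' @export
ring_face <- function(s, roles = ligand_roles()) {
  nic <- extract_ligand(s, roles$nicotinamide_cofactor$code)
  ring_names <- roles$nicotinamide_cofactor$ring
  ring <- nic[match(ring_names, nic$atom), , drop = FALSE]
  if (anyNA(ring$x))
    stop("cofactor ring atoms missing: ",
         paste(ring_names[is.na(ring$x)], collapse = ", "))
  pl <- ring_normal(atom_coords(ring))
  c4 <- role_atom(s, roles$udp_sugar, roles$udp_sugar$c4, "sugar C4")
  h <- sum((as.numeric(c4[1, c("x", "y", "z")]) - pl$center) * pl$normal)
  face <- if (h > 0) "standard" else "flipped"
  attr(face, "signed_distance") <- h
  face
}

dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Classify the C2-pocket asparagine swing conformer
#'
#' The C2-pocket Asn adopts two conformers: "swing in" (carboxamide packed
#' against the sugar C2 substituent, as seen with a C2 hydroxy group) and
#' "swing out" (side chain displaced to admit the bulkier 2-N-acetyl group).
#' The primary discriminant is the distance from the carboxamide centroid
#' (midpoint of OD1/ND2) to the C2-substituent pocket center; chi1
#' (N-CA-CB-CG) and chi2 (CA-CB-CG-OD1) are reported for transparency but do
#' not drive the call.
#'
#' @param s a [gale_structure].
#' @param asn_resnum author residue number of the asparagine.
#' @param chain chain identifier (default: first polymer chain).
#' @param pocket_center xyz of the pocket center; default: the sugar
#'   C2-substituent atom from `roles`.
#' @param roles a [ligand_roles()] map (used only for the default pocket
#'   center).
#' @param threshold swing-in distance threshold in angstrom (default 5.0,
#'   calibrated on the two B. longum ternary complexes; configurable).
#' @return An object of class `conformer_calls`: list with `asn_swing`
#'   (`"swing_in"`/`"swing_out"`), `chi1`, `chi2` (degrees),
#'   `carboxamide_pocket_distance` and `threshold`.
#' @export
classify_c2_swing <- function(s, asn_resnum, chain = NULL,
                              pocket_center = NULL, roles = ligand_roles(),
                              threshold = 5.0) {
  chain <- chain %||% structure_chains(s)[1L]
  res <- select_atoms(s, chain = chain, resno = asn_resnum, het = FALSE)
  if (nrow(res) == 0L || res$resname[1] != "ASN")
    stop("residue ", asn_resnum, " in chain ", chain,
         " is not an asparagine (found: ",
         if (nrow(res)) res$resname[1] else "nothing", ")")
  need <- c("N", "CA", "CB", "CG", "OD1", "ND2")
  at <- lapply(need, function(nm) {
    row <- res[res$atom == nm, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("asparagine ", asn_resnum, " lacks side-chain atom ", nm)
    as.numeric(row[1, c("x", "y", "z")])
  })
  names(at) <- need
  if (is.null(pocket_center)) {
    sub_at <- role_atom(s, roles$udp_sugar, roles$udp_sugar$c2_substituent,
                        "sugar C2 substituent")
    pocket_center <- as.numeric(sub_at[1, c("x", "y", "z")])
  }
  centroid <- (at$OD1 + at$ND2) / 2
  d <- sqrt(sum((centroid - pocket_center)^2))
  structure(list(
    asn_swing = if (d <= threshold) "swing_in" else "swing_out",
    chi1 = dihedral(at$N, at$CA, at$CB, at$CG),
    chi2 = dihedral(at$CA, at$CB, at$CG, at$OD1),
    carboxamide_pocket_distance = d, threshold = threshold),
    class = "conformer_calls")
}

#' @export
print.conformer_calls <- function(x, ...) {
  cat(sprintf("<conformer_calls> %s (carboxamide-pocket %.1f A, threshold %.1f; chi1 %.0f, chi2 %.0f)\n",
              x$asn_swing, x$carboxamide_pocket_distance, x$threshold,
              x$chi1, x$chi2))
  invisible(x)
}
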