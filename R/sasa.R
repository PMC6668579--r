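#' Default van der Waals radii
#'
#' Element-keyed radii (angstrom) for protein heavy atoms plus common
#' cofactor/ligand elements. Interface-analysis software does not publish a
#' single canonical table; these are conventional values and can be
#' overridden wholesale or per element.
#'
#' @return Named numeric vector of radii.
#' @export
default_vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    MG = 1.73, F = 1.47, CL = 1.75, `NA` = 2.27, K = 2.75, ZN = 1.39,
    FE = 1.52, MN = 1.61)
}

#' Deterministic golden-spiral points on the unit sphere
#'
#' Near-uniform point set generated by the golden-angle spiral; fully
#' deterministic (no RNG), so surface areas are bit-reproducible.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point sampling: each atom's van der Waals sphere is
#' expanded by the probe radius and sampled with a deterministic
#' golden-spiral point set; points falling inside any neighboring expanded
#' sphere are occluded, and the accessible fraction scales the expanded
#' sphere area 4*pi*(r + probe)^2. Hydrogens are ignored.
#'
#' @param atoms atom table (rows of a [gale_structure] atom table) or a
#'   `gale_structure` (all non-water atoms used).
#' @param probe probe radius in angstrom (default 1.4, a water-sized probe).
#' @param n_points sampling points per atom (default 960).
#' @param radii element-keyed vdW radius table (see [default_vdw_radii()]).
#' @return An object of class `sasa_result`: list with `per_atom` (angstrom^2
#'   per atom, zero for skipped hydrogens), `total`, `probe_radius`,
#'   `n_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L,
                               radii = default_vdw_radii()) {
  if (inherits(atoms, "gale_structure"))
    atoms <- atoms$atoms[!atoms$atoms$is_water, , drop = FALSE]
  per_atom <- numeric(nrow(atoms))
  heavy <- atoms$element != "H"
  a <- atoms[heavy, , drop = FALSE]
  if (nrow(a)) {
    unknown <- setdiff(unique(a$element), names(radii))
    if (length(unknown))
      stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "),
           "; extend the radius table")
    r <- radii[a$element] + probe
    xyz <- atom_coords(a)
    pts <- golden_spiral_points(n_points)
    n <- nrow(a)
    d <- all_pair_distances(a, a)
    area <- numeric(n)
    for (i in seq_len(n)) {
      nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
      if (length(nb) == 0L) {
        area[i] <- 4 * pi * r[i]^2
        next
      }
      sp <- pts * r[i]
      sp <- sweep(sp, 2, xyz[i, ], "+")
      # occluded if within any neighbor's expanded radius
      acc <- rep(TRUE, n_points)
      for (j in nb[order(d[i, nb])]) {
        if (!any(acc)) break
        dd <- (sp[acc, 1] - xyz[j, 1])^2 + (sp[acc, 2] - xyz[j, 2])^2 +
              (sp[acc, 3] - xyz[j, 3])^2
        acc[acc] <- dd >= r[j]^2
      }
      area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
    }
    per_atom[heavy] <- area
  }
  structure(list(per_atom = per_atom, total = sum(per_atom),
                 probe_radius = probe, n_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total = %.1f A^2 (%d atoms, probe %.1f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Dimer-interface burial report
#'
#' Computes the solvent-accessible surface area of each isolated protomer
#' and of the assembled dimer. Burial conventions: `buried_total` =
#' SASA(A) + SASA(B) - SASA(AB), the area lost over both protomers;
#' `buried_half` = `buried_total` / 2, the "interface area" convention of
#' assembly-analysis servers (half-sum over the two protomers). Both are
#' reported. Interface residues are those losing accessible area on
#' assembly; inter-chain hydrogen bonds and salt bridges use the geometric
#' detectors of the active-site module.
#'
#' @param dimer a [gale_structure] with exactly two polymer chains.
#' @param probe probe radius (default 1.4).
#' @param n_points sampling points per atom (default 960).
#' @param dmax_hbond,dmax_salt contact cutoffs in angstrom.
#' @param include_het include non-water het groups with their chain
#'   (default `FALSE`: protein atoms only, matching the protomer-surface
#'   convention).
#' @param radii vdW radius table.
#' @return An object of class `interface_report`: list with `sasa_A`,
#'   `sasa_B`, `sasa_AB`, `buried_total`, `buried_half`,
#'   `interface_residues` (per-chain data frames with buried area per
#'   residue), `hbonds`, `salt_bridges`, and the parameters used.
#' @export
interface_report <- function(dimer, probe = 1.4, n_points = 960L,
                             dmax_hbond = 3.5, dmax_salt = 4.0,
                             include_het = FALSE,
                             radii = default_vdw_radii()) {
  stopifnot(inherits(dimer, "gale_structure"))
  chains <- structure_chains(dimer)
  if (length(chains) != 2L)
    stop("interface_report needs exactly 2 polymer chains, found ",
         length(chains), " (", paste(chains, collapse = ","), ")")
  get_chain <- function(ch) {
    a <- dimer$atoms
    keep <- a$chain == ch & !a$is_water &
      (!a$is_het | (include_het & a$is_het))
    a[keep, , drop = FALSE]
  }
  atoms_a <- get_chain(chains[1]); atoms_b <- get_chain(chains[2])
  sasa_a <- shrake_rupley_sasa(atoms_a, probe, n_points, radii)
  sasa_b <- shrake_rupley_sasa(atoms_b, probe, n_points, radii)
  both <- rbind(atoms_a, atoms_b)
  sasa_ab <- shrake_rupley_sasa(both, probe, n_points, radii)
  buried_total <- sasa_a$total + sasa_b$total - sasa_ab$total
  per_atom_iso <- c(sasa_a$per_atom, sasa_b$per_atom)
  lost <- per_atom_iso - sasa_ab$per_atom
  res_key <- paste(both$chain, both$resno, both$icode, both$resname)
  by_res <- tapply(lost, res_key, sum)
  iface <- data.frame(residue = names(by_res),
                      buried = as.numeric(by_res),
                      stringsAsFactors = FALSE)
  iface <- iface[iface$buried > 1e-6, , drop = FALSE]
  iface <- iface[order(-iface$buried), , drop = FALSE]
  rownames(iface) <- NULL
  structure(list(
    sasa_A = sasa_a$total, sasa_B = sasa_b$total, sasa_AB = sasa_ab$total,
    buried_total = buried_total, buried_half = buried_total / 2,
    interface_residues = iface,
    hbonds = detect_hbonds(atoms_a, atoms_b, dmax_hbond),
    salt_bridges = detect_salt_bridges(atoms_a, atoms_b, dmax_salt),
    probe = probe, n_points = n_points,
    dmax_hbond = dmax_hbond, dmax_salt = dmax_salt),
    class = "interface_report")
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf(paste0("<interface_report> SASA A %.0f + B %.0f = %.0f isolated; ",
                     "assembly %.0f; buried %.0f A^2 (half %.0f)\n",
                     "  %d interface residue(s), %d H-bond(s) <= %.1f A, ",
                     "%d salt bridge(s) <= %.1f A\n"),
              x$sasa_A, x$sasa_B, x$sasa_A + x$sasa_B, x$sasa_AB,
              x$buried_total, x$buried_half, nrow(x$interface_residues),
              nrow(x$hbonds), x$dmax_hbond, nrow(x$salt_bridges), x$dmax_salt))
  invisible(x)
}

#' Closed-form accessible area of two intersecting probe-expanded spheres
#'
#' Analytic reference for the two-sphere case: with expanded radii
#' `R1 = r1 + probe`, `R2 = r2 + probe` and center distance `d`, each
#' sphere loses the spherical cap cut off by the radical plane
#' (cap area 2*pi*R*h). Used as the independent oracle for Shrake-Rupley
#' burial.
#'
#' @param r1,r2 vdW radii.
#' @param d center distance.
#' @param probe probe radius.
#' @return List with `total` accessible area and `buried_total`
#'   (area lost relative to the isolated spheres).
#' @export
two_sphere_sasa_exact <- function(r1, r2, d, probe = 1.4) {
  R1 <- r1 + probe; R2 <- r2 + probe
  iso <- 4 * pi * (R1^2 + R2^2)
  if (d >= R1 + R2) return(list(total = iso, buried_total = 0))
  if (d <= abs(R1 - R2)) {
    big <- max(R1, R2)
    return(list(total = 4 * pi * big^2, buried_total = iso - 4 * pi * big^2))
  }
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  h1 <- R1 - x1
  h2 <- R2 - (d - x1)
  cap <- 2 * pi * (R1 * h1 + R2 * h2)
  list(total = iso - cap, buried_total = cap)
}
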