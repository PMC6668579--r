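#' Macromolecular structure container
#'
#' A `gale_structure` is a light container around a flat atom table: one row
#' per atom with columns `atom` (label, e.g. `"CA"`, `"C4"`), `element`,
#' `x`, `y`, `z` (angstrom), `occ`, `bfac`, `alt`, `resname` (3-letter code),
#' `resno` (author numbering), `icode`, `chain`, `is_het` and `is_water`.
#' Alternate locations are resolved at construction time: for each
#' (chain, resno, icode, atom) group the highest-occupancy conformer is kept,
#' ties broken by altloc letter order.
#'
#' @param id entry identifier.
#' @param atoms data frame with the columns listed above (missing auxiliary
#'   columns are filled with defaults).
#' @param metadata optional list (title, space group text, ...).
#' @return An object of class `gale_structure`.
#' @export
gale_structure <- function(id, atoms, metadata = list()) {
  required <- c("atom", "resname", "resno", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  defaults <- list(element = NA_character_, occ = 1, bfac = 0,
                   alt = "", icode = "", is_het = FALSE)
  for (col in names(defaults))
    if (is.null(atoms[[col]])) atoms[[col]] <- rep(defaults[[col]], n)
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  if (anyNA(atoms$element) || any(!nzchar(atoms$element)))
    atoms$element <- ifelse(is.na(atoms$element) | !nzchar(atoms$element),
                            guess_element(atoms$atom), atoms$element)
  atoms$element <- toupper(atoms$element)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom table")
  if (any(atoms$occ < 0 | atoms$occ > 1))
    stop("occupancies must lie in [0, 1]")
  atoms$is_water <- atoms$resname %in% c("HOH", "WAT", "DOD", "H2O")
  atoms <- resolve_altloc(atoms)
  structure(list(id = id, atoms = atoms, metadata = metadata),
            class = "gale_structure")
}

# Keep the highest-occupancy altloc per atom site; ties by letter order.
resolve_altloc <- function(atoms) {
  if (all(!nzchar(atoms$alt))) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$atom, sep = "\r")
  keep <- unsplit(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(TRUE)
    o <- order(-atoms$occ[idx], atoms$alt[idx])
    seq_along(idx) == o[1L]
  }), key)
  atoms[keep, , drop = FALSE]
}

guess_element <- function(atom_names) {
  two <- c("MG", "ZN", "FE", "MN", "NA", "CL", "CA", "BR")
  vapply(atom_names, function(a) {
    a <- toupper(gsub("[^A-Za-z]", "", a))
    if (a %in% two) a else substr(a, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.gale_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<gale_structure> %s: %d atoms, chains [%s], %d het group(s), %d water(s)\n",
              x$id, nrow(a), paste(unique(a$chain), collapse = ","),
              length(unique(paste(a$chain, a$resno)[a$is_het & !a$is_water])),
              sum(a$is_water)))
  invisible(x)
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses all ATOM/HETATM records of the first model. Alternate locations are
#' reduced to the highest-occupancy conformer (ties by altloc letter order);
#' waters are retained but flagged via the `is_water` column.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"pdb"`, `"cif"` or `"auto"` (by file extension).
#' @param id entry identifier; defaults to the file base name.
#' @return A [gale_structure].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer structure format from extension '",
                          ext, "'; pass format explicitly"))
  }
  parsed <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else suppressWarnings(
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  atoms <- data.frame(
    atom = at$elety, element = at$elesy,
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    bfac = ifelse(is.na(at$b), 0, at$b),
    alt = ifelse(is.na(at$alt), "", at$alt),
    resname = at$resid, resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    chain = ifelse(is.na(at$chain), "A", at$chain),
    is_het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  gale_structure(id %||% tools::file_path_sans_ext(basename(path)), atoms)
}

#' Write a structure in PDB fixed-column format
#'
#' Coordinates are written to three decimals; the emitted file re-parses to an
#' equal structure at that precision.
#'
#' @param s a [gale_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "gale_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$is_het, "HETATM", "ATOM"),
                   eleno = seq_len(nrow(a)), elety = a$atom,
                   resid = a$resname, chain = a$chain, resno = a$resno,
                   insert = ifelse(nzchar(a$icode), a$icode, ""),
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = a$bfac, elesy = a$element)
  invisible(path)
}

#' Select atoms by chain, residue and atom-name predicates
#'
#' Filters the atom table; all supplied criteria are combined with AND.
#' Matching atoms are returned in file order; an empty selection returns a
#' zero-row table.
#'
#' @param s a [gale_structure].
#' @param chain,resno,resname,atom,element vectors of accepted values
#'   (`NULL` = no constraint).
#' @param het `NULL` for both, `TRUE` for het groups only, `FALSE` for polymer
#'   only.
#' @param water include waters? (default `FALSE`).
#' @param predicate optional function taking the atom table and returning a
#'   logical vector.
#' @return Data frame of matching atom rows.
#' @export
select_atoms <- function(s, chain = NULL, resno = NULL, resname = NULL,
                         atom = NULL, element = NULL, het = NULL,
                         water = FALSE, predicate = NULL) {
  stopifnot(inherits(s, "gale_structure"))
  for (arg in list(chain, resno, resname, atom, element))
    if (!is.null(arg) && (!is.atomic(arg) || length(arg) == 0L))
      stop("malformed selector: criteria must be non-empty atomic vectors")
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resno))   keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(atom))    keep <- keep & a$atom %in% atom
  if (!is.null(element)) keep <- keep & a$element %in% toupper(element)
  if (!is.null(het))     keep <- keep & a$is_het == het
  if (!water)            keep <- keep & !a$is_water
  if (!is.null(predicate)) {
    if (!is.function(predicate)) stop("malformed selector: predicate must be a function")
    p <- predicate(a)
    if (!is.logical(p) || length(p) != nrow(a))
      stop("malformed selector: predicate must return one logical per atom")
    keep <- keep & p
  }
  a[keep, , drop = FALSE]
}

#' Extract a het group (ligand) by component code
#'
#' @param s a [gale_structure].
#' @param het_code 3-letter chemical component code (e.g. `"NAD"`, `"UDP"`).
#' @param instance which copy to return when several are present (1-based,
#'   in file order); required if the code occurs more than once.
#' @return Data frame with the ligand's atom rows.
#' @export
extract_ligand <- function(s, het_code, instance = NULL) {
  lig <- select_atoms(s, resname = het_code, het = TRUE)
  if (nrow(lig) == 0L) stop("het group '", het_code, "' not found in ", s$id)
  copies <- unique(paste(lig$chain, lig$resno, lig$icode, sep = "\r"))
  if (length(copies) > 1L) {
    if (is.null(instance))
      stop("het group '", het_code, "' present ", length(copies),
           " times in ", s$id, "; pass instance = <index>")
    if (instance < 1L || instance > length(copies))
      stop("instance out of range for het group '", het_code, "'")
    copies <- copies[instance]
  }
  key <- paste(lig$chain, lig$resno, lig$icode, sep = "\r")
  lig[key == copies, , drop = FALSE]
}

#' Polymer chains and sequences
#'
#' `structure_chains()` lists chain identifiers containing polymer (non-het)
#' residues. `chain_sequence()` returns the one-letter sequence of a chain's
#' polymer residues in file order; non-standard residues become `X`.
#' `chain_calpha()` returns one row per polymer residue with its C-alpha
#' coordinates (`NA` when absent) and `seqpos`, the residue's 1-based index in
#' the chain sequence (the coordinate frame used by alignment-driven pairing).
#'
#' @param s a [gale_structure].
#' @param chain chain identifier.
#' @return See description.
#' @export
structure_chains <- function(s) {
  stopifnot(inherits(s, "gale_structure"))
  unique(s$atoms$chain[!s$atoms$is_het & !s$atoms$is_water])
}

#' @rdname structure_chains
#' @export
chain_sequence <- function(s, chain) {
  res <- chain_residue_table(s, chain)
  paste(res$code1, collapse = "")
}

#' @rdname structure_chains
#' @export
chain_calpha <- function(s, chain) {
  res <- chain_residue_table(s, chain)
  a <- select_atoms(s, chain = chain, het = FALSE, atom = "CA")
  key_res <- paste(res$resno, res$icode, sep = "\r")
  key_ca <- paste(a$resno, a$icode, sep = "\r")
  idx <- match(key_res, key_ca)
  res$x <- a$x[idx]; res$y <- a$y[idx]; res$z <- a$z[idx]
  res
}

chain_residue_table <- function(s, chain) {
  a <- select_atoms(s, chain = chain, het = FALSE)
  if (nrow(a) == 0L) stop("no polymer residues in chain '", chain, "' of ", s$id)
  key <- paste(a$resno, a$icode, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(resno = a$resno[first], icode = a$icode[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  res$seqpos <- seq_len(nrow(res))
  code1 <- suppressWarnings(bio3d::aa321(res$resname))
  res$code1 <- ifelse(is.na(code1), "X", code1)
  res
}

#' Coordinate matrix of an atom table
#'
#' @param atoms atom table (rows of a `gale_structure` atom table).
#' @return Numeric n x 3 matrix of coordinates in angstrom.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}
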