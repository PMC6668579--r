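#' Anchor functional positions (B. longum GalE numbering)
#'
#' The reference positions used throughout the analysis, in the numbering of
#' the B. longum enzyme: Lys85 (pyrophosphate contact), the SDR catalytic
#' triad Ser125/Tyr150/Lys154, the invariant Asn180 (O6 recognition), the
#' C2-pocket position 200 and the C5-pocket position 299.
#'
#' @return Named integer vector.
#' @export
anchor_positions <- function() {
  c(lys85 = 85L, ser125 = 125L, tyr150 = 150L, lys154 = 154L,
    asn180 = 180L, c2 = 200L, c5 = 299L)
}

# side-chain size classes used by the two-pocket rule; the characterized
# enzymes fix Cys/Ser as small and Tyr/Leu/His as bulky, the remaining
# residues are assigned by side-chain volume.
C5_BULKY <- c("Y", "F", "L", "I", "M", "W", "H")
C5_SMALL <- c("C", "S", "G", "A", "T")
C2_SMALL <- c("A", "G", "S")
C2_LARGE <- c("H", "F", "Y", "W", "R", "K")

code3to1 <- function(code) {
  one <- suppressWarnings(bio3d::aa321(code))
  ifelse(is.na(one), "X", one)
}

#' Derive a C2/C5 pocket profile
#'
#' Reads the residue identities at the anchor functional positions from a
#' structure, a sequence, or a homology model, using a cross-homolog
#' [residue_map()] to translate anchor numbering into the subject's own
#' positions. The C2 pocket (anchor position 200) accommodates the sugar C2
#' hydroxy or N-acetyl group; the C5 pocket (anchor 299) the C5 ring atom
#' during ring rotation; the triad (125/150/154) is expected to be the
#' conserved SDR Ser-Tyr-Lys motif (deviations are flagged, not fatal).
#'
#' @param subject a [gale_structure], or a protein sequence (character
#'   scalar).
#' @param anchor_map a [residue_map] from the anchor to the subject, or
#'   `NULL` when the subject *is* the anchor (identity mapping).
#' @param id subject identifier (defaults to the map's homolog id or the
#'   structure id).
#' @param chain chain to read residues from (structures only).
#' @param source provenance tag: `"structure"`, `"sequence"` or `"model"`;
#'   inferred from the subject type when omitted.
#' @param positions anchor positions (default [anchor_positions()]).
#' @return An object of class `pocket_profile`: list with `id`, `c2_residue`
#'   and `c5_residue` (each `list(anchor_pos, subject_pos, code)` with
#'   one-letter `code`, `NA` when unmapped), `triad` (codes at the
#'   125/150/154 equivalents), `triad_ok`, `n180_ok`, `residues` (full
#'   table) and `source`.
#' @export
pocket_profile <- function(subject, anchor_map = NULL, id = NULL,
                           chain = NULL, source = NULL,
                           positions = anchor_positions()) {
  is_struct <- inherits(subject, "gale_structure")
  source <- source %||% if (is_struct) "structure" else "sequence"
  if (is_struct) {
    chain <- chain %||% structure_chains(subject)[1L]
    res_tab <- chain_residue_table(subject, chain)
    subj_code <- function(pos) {
      row <- res_tab[res_tab$seqpos == pos, , drop = FALSE]
      if (nrow(row) == 0L) NA_character_ else row$code1[1]
    }
    subj_label <- function(pos) {
      row <- res_tab[res_tab$seqpos == pos, , drop = FALSE]
      if (nrow(row) == 0L) NA_integer_ else row$resno[1]
    }
    id <- id %||% subject$id
  } else {
    if (!is.character(subject) || length(subject) != 1L)
      stop("subject must be a gale_structure or a single protein sequence")
    aa <- strsplit(toupper(subject), "")[[1]]
    subj_code <- function(pos) if (pos <= length(aa)) aa[pos] else NA_character_
    subj_label <- function(pos) pos
    id <- id %||% (if (!is.null(anchor_map)) anchor_map$homolog_id else "subject")
  }
  mapped <- if (is.null(anchor_map)) positions
            else setNames(map_residue(anchor_map, positions), names(positions))
  grab <- function(key) {
    pos <- mapped[[key]]
    if (is.na(pos))
      return(list(anchor_pos = positions[[key]], subject_pos = NA_integer_,
                  code = NA_character_))
    list(anchor_pos = positions[[key]], subject_pos = subj_label(pos),
         code = subj_code(pos))
  }
  residues <- lapply(setNames(names(positions), names(positions)), grab)
  triad <- vapply(residues[c("ser125", "tyr150", "lys154")],
                  function(r) r$code %||% NA_character_, character(1))
  structure(list(
    id = id,
    c2_residue = residues$c2, c5_residue = residues$c5,
    triad = unname(triad),
    triad_ok = identical(unname(triad), c("S", "Y", "K")),
    n180_ok = identical(residues$asn180$code, "N"),
    residues = residues, source = source),
    class = "pocket_profile")
}

#' Construct a pocket profile from known residue identities
#'
#' Convenience constructor when the pocket residues are already known (e.g.
#' from a published structure description) rather than derived from
#' coordinates or an alignment.
#'
#' @param id subject identifier.
#' @param c2,c5 one-letter codes at the C2- and C5-pocket positions.
#' @param triad one-letter codes at the triad positions (default the
#'   canonical S/Y/K).
#' @param n180_ok is the invariant Asn present?
#' @param source provenance tag (default `"sequence"`).
#' @param c2_pos,c5_pos subject-numbering positions (optional).
#' @return A `pocket_profile`.
#' @export
pocket_profile_manual <- function(id, c2, c5, triad = c("S", "Y", "K"),
                                  n180_ok = TRUE, source = "sequence",
                                  c2_pos = NA_integer_, c5_pos = NA_integer_) {
  structure(list(
    id = id,
    c2_residue = list(anchor_pos = 200L, subject_pos = c2_pos, code = toupper(c2)),
    c5_residue = list(anchor_pos = 299L, subject_pos = c5_pos, code = toupper(c5)),
    triad = toupper(triad),
    triad_ok = identical(toupper(triad), c("S", "Y", "K")),
    n180_ok = n180_ok, residues = NULL, source = source),
    class = "pocket_profile")
}

#' @export
print.pocket_profile <- function(x, ...) {
  fmt <- function(r) paste0(r$code,
                            if (is.na(r$subject_pos)) "" else r$subject_pos)
  cat(sprintf("<pocket_profile> %s [%s]: C2 = %s, C5 = %s, triad %s%s\n",
              x$id, x$source, fmt(x$c2_residue), fmt(x$c5_residue),
              paste(x$triad, collapse = "/"),
              if (x$triad_ok) "" else " (non-canonical!)"))
  invisible(x)
}

#' Classify a GalE into substrate-specificity groups by the two-pocket rule
#'
#' Rule cascade on the C2/C5 pocket residues. The C5 pocket is the primary
#' determinant: a bulky residue there (Tyr/Phe/Leu/Ile/Met/Trp/His) leaves a
#' small C5 pocket and yields group 1 (UDP-Glc/Gal preferring); a small
#' residue (Cys/Ser/Gly/Ala/Thr) leaves a large C5 pocket that admits the
#' rotating N-acetyl sugar, and the C2 pocket then separates group 2
#' (C2 = Asn, dual specificity) from group 3 (small C2 = Ala/Gly/Ser,
#' UDP-GlcNAc/GalNAc preferring). Within group 1 the C2 residue refines the
#' subgroup (large His-like residue: 1a; Asn: 1b) unless a phylogenetic
#' clade assignment is supplied, which takes precedence — the 1a/1b split is
#' defined by tree separation, not pocket chemistry. Group 1b and group 2
#' both carry Asn at C2; the (Asn, small C5) profile is reported as group 2
#' with an explicit caveat in the rule trace, since pocket identity alone
#' cannot exclude a hypothetical 1b-like enzyme there.
#'
#' @param p a [pocket_profile].
#' @param clade optional phylogenetic override for the group-1 subgroup:
#'   `"1a"` or `"1b"`.
#' @return An object of class `group_prediction`: list with `group`
#'   (`"1a"`, `"1b"`, `"1"`, `"2"`, `"3"`, `"unknown"`), `substrate_call`
#'   (`"Glc/Gal preferring"`, `"dual"`, `"GlcNAc/GalNAc preferring"`,
#'   `"unknown"`) and `rule_trace` (ordered character vector of fired
#'   rules).
#' @export
classify_group <- function(p, clade = NULL) {
  stopifnot(inherits(p, "pocket_profile"))
  c2 <- p$c2_residue$code; c5 <- p$c5_residue$code
  trace <- character()
  note <- function(msg) trace <<- c(trace, msg)
  if (is.na(c5)) {
    note("C5 residue unknown: no decisive rule")
    return(structure(list(group = "unknown", substrate_call = "unknown",
                          rule_trace = trace), class = "group_prediction"))
  }
  if (!p$triad_ok && !is.null(p$triad) && !all(is.na(p$triad)))
    note(paste0("caveat: non-canonical catalytic triad (",
                paste(p$triad, collapse = "/"), "), expected S/Y/K"))
  group <- "unknown"; call <- "unknown"
  if (c5 %in% C5_BULKY) {
    note(paste0("C5 = ", c5, " (bulky): small C5 pocket -> group 1 ",
                "(Glc/Gal preferring)"))
    group <- "1"; call <- "Glc/Gal preferring"
    if (!is.null(clade)) {
      clade <- match.arg(clade, c("1a", "1b"))
      group <- clade
      note(paste0("phylogenetic clade assignment overrides subgroup: ", clade))
    } else if (!is.na(c2) && c2 %in% C2_LARGE) {
      group <- "1a"
      note(paste0("C2 = ", c2, " (large, His-like) -> subgroup 1a"))
    } else if (identical(c2, "N")) {
      group <- "1b"
      note("C2 = N (Asn) -> subgroup 1b")
    } else {
      note(paste0("C2 = ", if (is.na(c2)) "unknown" else c2,
                  ": subgroup 1a/1b not resolved by pocket identity"))
    }
  } else if (c5 %in% C5_SMALL) {
    note(paste0("C5 = ", c5, " (small): large C5 pocket -> group 2 or 3"))
    if (identical(c2, "N")) {
      group <- "2"; call <- "dual"
      note("C2 = N (Asn, flexible) -> group 2 (dual specificity)")
      note(paste0("caveat: group 1b enzymes also carry Asn at C2; pocket ",
                  "identity alone cannot exclude a 1b-like enzyme with a ",
                  "small C5 residue"))
    } else if (!is.na(c2) && c2 %in% C2_SMALL) {
      group <- "3"; call <- "GlcNAc/GalNAc preferring"
      note(paste0("C2 = ", c2, " (small) -> group 3 (GlcNAc/GalNAc preferring)"))
    } else {
      note(paste0("C2 = ", if (is.na(c2)) "unknown" else c2,
                  ": no decisive C2 rule; group unresolved"))
    }
  } else {
    note(paste0("C5 = ", c5, ": outside the bulky/small classes; ",
                "no decisive rule"))
  }
  structure(list(group = group, substrate_call = call, rule_trace = trace),
            class = "group_prediction")
}

#' @export
print.group_prediction <- function(x, ...) {
  cat(sprintf("<group_prediction> group %s (%s)\n", x$group, x$substrate_call))
  for (r in x$rule_trace) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Reclassify after an in-silico pocket point mutation
#'
#' Swaps the residue at the C2 or C5 pocket position and re-runs the
#' classifier — the computational analogue of the specificity-switching
#' pocket mutants (e.g. a C5 Tyr-to-Cys swap enlarging the C5 pocket).
#'
#' @param p a [pocket_profile].
#' @param position `"c2"` or `"c5"`.
#' @param new_code one-letter code of the replacement residue.
#' @param clade optional clade override, as in [classify_group()].
#' @return A `group_prediction` for the mutated profile; the mutated profile
#'   itself is attached as attribute `"profile"`.
#' @export
mutate_and_reclassify <- function(p, position = c("c2", "c5"), new_code,
                                  clade = NULL) {
  position <- match.arg(position)
  new_code <- toupper(new_code)
  if (!new_code %in% AA20) stop("invalid residue code: ", new_code)
  field <- if (position == "c2") "c2_residue" else "c5_residue"
  old <- p[[field]]$code
  p[[field]]$code <- new_code
  p$id <- paste0(p$id, "(", toupper(position), " ", old, "->", new_code, ")")
  pred <- classify_group(p, clade = clade)
  pred$rule_trace <- c(paste0("in-silico mutation ", toupper(position), ": ",
                              old, " -> ", new_code), pred$rule_trace)
  attr(pred, "profile") <- p
  pred
}
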