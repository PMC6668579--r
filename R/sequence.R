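#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Pairwise global alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment via [Biostrings::pairwiseAlignment()]. Defaults
#' (BLOSUM62, gap open 10, gap extend 0.5) are conventional protein-alignment
#' parameters; no alignment method is canonical for the printed GalE
#' identities, so parameters are exposed and recorded in the result.
#' `X` is tolerated in input but never scores as identical.
#'
#' @param a,b protein sequences (character scalars).
#' @param ids length-2 identifier vector.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return An object of class `alignment_result`: list with `seq_ids`,
#'   `aligned_a`/`aligned_b` (gapped strings), `columns` (data frame
#'   `pos_a`, `pos_b`, `NA` at gaps), `n_identical`, `score`, `params`.
#' @export
global_align <- function(a, b, ids = c("A", "B"), matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  submat <- get_submatrix(matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  ident <- ca == cb & ca != "-" & ca != "X"
  structure(list(
    seq_ids = ids, aligned_a = ga, aligned_b = gb,
    columns = data.frame(pos_a = pos_a, pos_b = pos_b),
    n_identical = sum(ident), score = as.numeric(Biostrings::score(aln)),
    params = list(matrix = matrix, gap_open = gap_open,
                  gap_extend = gap_extend)),
    class = "alignment_result")
}

get_submatrix <- function(matrix) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(matrix, envir = e))
    stop("unknown substitution matrix: ", matrix)
  get(matrix, envir = e)
}

#' @export
print.alignment_result <- function(x, ...) {
  ncol_aln <- nrow(x$columns)
  cat(sprintf("<alignment_result> %s vs %s: %d columns, %d identical, score %.1f\n",
              x$seq_ids[1], x$seq_ids[2], ncol_aln, x$n_identical, x$score))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' @param r an [global_align()] result.
#' @param denominator identity denominator: `"aligned_columns_nongap"`
#'   (columns where both sequences have a residue; default),
#'   `"shorter_seq"`, or `"alignment_length"`.
#' @return Percent identity (0-100).
#' @export
percent_identity <- function(r, denominator = c("aligned_columns_nongap",
                                                "shorter_seq",
                                                "alignment_length")) {
  denominator <- match.arg(denominator)
  cols <- r$columns
  len_a <- max(cols$pos_a, na.rm = TRUE)
  len_b <- max(cols$pos_b, na.rm = TRUE)
  den <- switch(denominator,
    aligned_columns_nongap = sum(!is.na(cols$pos_a) & !is.na(cols$pos_b)),
    shorter_seq = min(len_a, len_b),
    alignment_length = nrow(cols))
  100 * r$n_identical / den
}

#' Cross-homolog residue map
#'
#' Builds a position map from an anchor sequence to a homolog from the
#' non-gap columns of their global alignment, so functional positions stated
#' in anchor numbering (e.g. the catalytic triad) can be located in any
#' homolog.
#'
#' @param r an [global_align()] result; sequence A is taken as the anchor
#'   unless `anchor = "b"`.
#' @param anchor `"a"` or `"b"`.
#' @return An object of class `residue_map`: list with `anchor_id`,
#'   `homolog_id` and `mapping`, an integer vector indexed by anchor
#'   position (`NA` where the homolog has a gap).
#' @export
residue_map <- function(r, anchor = c("a", "b")) {
  anchor <- match.arg(anchor)
  cols <- r$columns
  if (anchor == "b") cols <- data.frame(pos_a = cols$pos_b, pos_b = cols$pos_a)
  ids <- if (anchor == "a") r$seq_ids else rev(r$seq_ids)
  len_anchor <- max(cols$pos_a, na.rm = TRUE)
  mapping <- rep(NA_integer_, len_anchor)
  use <- !is.na(cols$pos_a) & !is.na(cols$pos_b)
  mapping[cols$pos_a[use]] <- cols$pos_b[use]
  structure(list(anchor_id = ids[1], homolog_id = ids[2], mapping = mapping),
            class = "residue_map")
}

#' Map an anchor position to the homolog
#'
#' @param m a [residue_map].
#' @param anchor_pos position(s) in anchor numbering.
#' @return Homolog position(s), `NA` where absent (gap in homolog).
#' @export
map_residue <- function(m, anchor_pos) {
  stopifnot(inherits(m, "residue_map"))
  out <- rep(NA_integer_, length(anchor_pos))
  ok <- anchor_pos >= 1 & anchor_pos <= length(m$mapping)
  out[ok] <- m$mapping[anchor_pos[ok]]
  out
}

#' Average molecular mass of a protein sequence
#'
#' Sum of average residue masses plus one water (the peptide's termini).
#'
#' @param seq protein sequence (one-letter codes).
#' @return Mass in daltons.
#' @export
protein_mass <- function(seq) {
  aa <- strsplit(toupper(seq), "")[[1]]
  unknown <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(unknown))
    stop("cannot assign mass to residue(s): ", paste(unknown, collapse = ", "))
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Pairwise distance matrix from global alignments
#'
#' Distances are `1 - fractional identity` over non-gap aligned columns
#' (matching a "percent sequence divergence" scale), optionally with the
#' Kimura correction for multiple substitutions,
#' `d = -ln(1 - p - 0.2 p^2)`.
#'
#' @param seqs named character vector of sequences (>= 2).
#' @param correction `"none"` (default) or `"kimura"`.
#' @param ... alignment parameters passed to [global_align()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(seqs, correction = c("none", "kimura"), ...) {
  correction <- match.arg(correction)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)) || anyNA(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- global_align(seqs[[i]], seqs[[j]],
                      ids = names(seqs)[c(i, j)], ...)
    p <- 1 - percent_identity(r, "aligned_columns_nongap") / 100
    dij <- if (correction == "kimura") {
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0) stop("Kimura correction undefined for divergence ", p)
      -log(arg)
    } else p
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (via [ape::nj()]) on a symmetric distance
#' matrix; exact on additive distances. Negative branch-length estimates are
#' clamped to zero with a warning (standard practice). Use
#' [ape::write.tree()] for Newick output.
#'
#' @param d symmetric numeric matrix, zero diagonal, >= 3 taxa.
#' @param tol asymmetry tolerance (default 1e-8).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix is asymmetric beyond tolerance ", tol)
  if (max(abs(diag(d))) > tol) stop("distance matrix diagonal must be zero")
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < 0)) {
    warning("negative neighbor-joining branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
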