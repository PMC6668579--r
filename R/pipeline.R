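#' Run the full comparative-analysis pipeline
#'
#' Orchestrates all stages for a configured set of subjects: sequence
#' alignment to the anchor and residue mapping, pocket profiling and
#' specificity classification, pairwise superpositions (trimmed and
#' untrimmed), active-site geometry for structures with the configured
#' ligands, interface analysis for dimers, an identity matrix and a
#' neighbor-joining tree, all collected in one machine-readable report.
#' Failures are isolated per subject/comparison: an error in one analysis
#' becomes an error record in the report and the remaining analyses run.
#'
#' @section Configuration schema:
#' A list (or YAML/JSON file) with:
#' \describe{
#'   \item{anchor}{`id`; `sequence` or `sequence_file`; optional `positions`
#'     (named integer vector, default [anchor_positions()]); optional
#'     `roles` (see [ligand_roles()]).}
#'   \item{subjects}{list of entries with `id` and at least one of
#'     `structure` (file path), `sequence` / `sequence_file`; optional
#'     `chain`, `dimer` (logical), `tyr_resno`, `asn_resno`, `roles`,
#'     `clade`.}
#'   \item{comparisons}{optional list of `c(idA, idB)` pairs to superpose
#'     (both must have structures).}
#'   \item{options}{optional: `cutoff` (2.0), `max_iter` (20), `probe`
#'     (1.4), `n_points` (960), `dmax_hbond` (3.5), `dmax_salt` (4.0),
#'     `gap_open` (10), `gap_extend` (0.5), `matrix` ("BLOSUM62"),
#'     `productive_range` (c(3.0, 3.7)), `swing_threshold` (5.0),
#'     `tree` (TRUE), `tree_correction` ("none").}
#' }
#'
#' @param config configuration list, or path to a YAML or JSON file.
#' @param out optional path for the JSON report.
#' @return An object of class `gale_report` (nested list); written to `out`
#'   as JSON when requested.
#' @export
run_report <- function(config, out = NULL) {
  cfg <- load_config(config)
  opt <- cfg$options
  anchor_seq <- cfg$anchor$sequence
  positions <- cfg$anchor$positions
  report <- list(
    anchor = list(id = cfg$anchor$id, n_residues = nchar(anchor_seq),
                  positions = as.list(positions)),
    subjects = list(), superpositions = list(),
    identity_matrix = NULL, tree_newick = NULL,
    provenance = list(package = "galescope",
                      version = as.character(packageVersion("galescope")),
                      options = opt, timestamp = format(Sys.time(), tz = "UTC")))
  structures <- list()
  sequences <- c(setNames(anchor_seq, cfg$anchor$id))

  for (sub in cfg$subjects) {
    rec <- list(id = sub$id, errors = list())
    res <- tryCatch({
      subj_seq <- NULL
      if (!is.null(sub$sequence)) subj_seq <- toupper(sub$sequence)
      if (is.null(subj_seq) && !is.null(sub$sequence_file))
        subj_seq <- unname(read_fasta(sub$sequence_file)[1])
      s <- NULL
      if (!is.null(sub$structure)) {
        s <- read_structure(sub$structure, id = sub$id)
        structures[[sub$id]] <- list(structure = s, chain = sub$chain)
        if (is.null(subj_seq))
          subj_seq <- chain_sequence(s, sub$chain %||% structure_chains(s)[1L])
      }
      if (is.null(subj_seq)) stop("subject '", sub$id,
                                  "' has neither structure nor sequence")
      sequences[sub$id] <- subj_seq
      aln <- global_align(anchor_seq, subj_seq,
                          ids = c(cfg$anchor$id, sub$id),
                          matrix = opt$matrix, gap_open = opt$gap_open,
                          gap_extend = opt$gap_extend)
      amap <- residue_map(aln)
      prof <- pocket_profile(if (!is.null(s)) s else subj_seq,
                             anchor_map = if (identical(subj_seq, anchor_seq))
                               NULL else amap,
                             id = sub$id, chain = sub$chain,
                             positions = positions)
      pred <- classify_group(prof, clade = sub$clade)
      rec$percent_identity_to_anchor <- percent_identity(aln)
      rec$pocket_profile <- unclass_deep(prof[c("id", "c2_residue",
                                                "c5_residue", "triad",
                                                "triad_ok", "n180_ok",
                                                "source")])
      rec$group_prediction <- unclass_deep(pred)
      rec
    }, error = function(e) {
      rec$errors$profile <- conditionMessage(e)
      rec
    })
    rec <- res
    if (!is.null(sub$structure) && !is.null(structures[[sub$id]])) {
      s <- structures[[sub$id]]$structure
      roles <- parse_roles(sub$roles) %||% cfg$anchor$roles
      rec <- run_active_site(rec, s, sub, roles, opt)
      if (isTRUE(sub$dimer)) {
        rec$interface <- tryCatch(
          unclass_report(interface_report(
            s, probe = opt$probe, n_points = opt$n_points,
            dmax_hbond = opt$dmax_hbond, dmax_salt = opt$dmax_salt)),
          error = function(e) list(error = conditionMessage(e)))
      }
    }
    report$subjects[[sub$id]] <- rec
  }

  for (cmp in cfg$comparisons) {
    key <- paste(cmp[1], cmp[2], sep = "|")
    report$superpositions[[key]] <- tryCatch({
      sa <- structures[[cmp[1]]]; sb <- structures[[cmp[2]]]
      if (is.null(sa) || is.null(sb))
        stop("comparison ", key, ": both subjects need structures")
      ca <- sa$chain %||% structure_chains(sa$structure)[1L]
      cb <- sb$chain %||% structure_chains(sb$structure)[1L]
      aln <- global_align(chain_sequence(sa$structure, ca),
                          chain_sequence(sb$structure, cb),
                          ids = cmp, matrix = opt$matrix,
                          gap_open = opt$gap_open, gap_extend = opt$gap_extend)
      pairs <- pair_calpha_by_alignment(sa$structure, sb$structure, aln,
                                        ca, cb)
      trimmed <- trimmed_superpose(pairs, cutoff = opt$cutoff,
                                   max_iter = opt$max_iter)
      list(pair = cmp,
           rmsd_no_cutoff = rmsd_no_cutoff(pairs),
           n_pairs_total = length(pairs),
           rmsd_trimmed = trimmed$rmsd,
           n_pairs_retained = trimmed$n_pairs_used,
           cutoff = opt$cutoff, iterations = trimmed$iterations)
    }, error = function(e) list(pair = cmp, error = conditionMessage(e)))
  }

  if (isTRUE(opt$tree) && length(sequences) >= 3L) {
    tr <- tryCatch({
      d <- distance_matrix(sequences, correction = opt$tree_correction,
                           matrix = opt$matrix, gap_open = opt$gap_open,
                           gap_extend = opt$gap_extend)
      list(identity = round(100 * (1 - d), 2),
           newick = ape::write.tree(nj_tree(d)))
    }, error = function(e) list(error = conditionMessage(e)))
    report$identity_matrix <- tr$identity
    report$tree_newick <- tr$newick
    report$tree_error <- tr$error
  }

  class(report) <- "gale_report"
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass_deep(report), out, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

run_active_site <- function(rec, s, sub, roles, opt) {
  has_ligands <- !is.null(roles) &&
    nrow(select_atoms(s, resname = roles$nicotinamide_cofactor$code,
                      het = TRUE)) > 0 &&
    nrow(select_atoms(s, resname = roles$udp_sugar$code, het = TRUE)) > 0
  if (!has_ligands) return(rec)
  rec$active_site <- tryCatch({
    geom <- catalytic_c4c4(s, roles, productive_range = opt$productive_range,
                           tyr_resno = sub$tyr_resno, chain = sub$chain)
    out <- list(c4c4 = geom$distance, productive = geom$productive,
                o4_tyr_oh = geom$o4_tyr_oh_distance,
                ring_face = as.character(ring_face(s, roles)))
    if (!is.null(sub$asn_resno)) {
      sw <- classify_c2_swing(s, sub$asn_resno, chain = sub$chain,
                              roles = roles, threshold = opt$swing_threshold)
      out$asn_swing <- sw$asn_swing
      out$chi1 <- sw$chi1; out$chi2 <- sw$chi2
    }
    out
  }, error = function(e) list(error = conditionMessage(e)))
  rec
}

pipeline_defaults <- function() {
  list(cutoff = 2.0, max_iter = 20L, probe = 1.4, n_points = 960L,
       dmax_hbond = 3.5, dmax_salt = 4.0, gap_open = 10, gap_extend = 0.5,
       matrix = "BLOSUM62", productive_range = c(3.0, 3.7),
       swing_threshold = 5.0, tree = TRUE, tree_correction = "none")
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  if (is.null(config$anchor)) stop("config error: 'anchor' block is required")
  anchor <- config$anchor
  if (is.null(anchor$id)) stop("config error: anchor$id is required")
  if (is.null(anchor$sequence)) {
    if (is.null(anchor$sequence_file))
      stop("config error: anchor needs 'sequence' or 'sequence_file'")
    anchor$sequence <- unname(read_fasta(anchor$sequence_file)[1])
  }
  anchor$sequence <- toupper(anchor$sequence)
  anchor$positions <- if (is.null(anchor$positions)) anchor_positions()
    else {
      p <- unlist(anchor$positions)
      if (is.null(names(p)) || !all(names(anchor_positions()) %in% names(p)))
        stop("config error: anchor$positions must name all of: ",
             paste(names(anchor_positions()), collapse = ", "))
      storage.mode(p) <- "integer"
      p[names(anchor_positions())]
    }
  anchor$roles <- parse_roles(anchor$roles) %||% ligand_roles()
  if (is.null(config$subjects) || !length(config$subjects))
    stop("config error: at least one subject is required")
  subjects <- lapply(config$subjects, function(sub) {
    if (is.null(sub$id)) stop("config error: every subject needs an 'id'")
    if (is.null(sub$structure) && is.null(sub$sequence) &&
        is.null(sub$sequence_file))
      stop("config error: subject '", sub$id,
           "' needs a structure or a sequence")
    sub
  })
  ids <- vapply(subjects, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("config error: duplicate subject ids")
  comparisons <- lapply(config$comparisons %||% list(), function(cmp) {
    cmp <- unlist(cmp)
    if (length(cmp) != 2L) stop("config error: comparisons must be id pairs")
    cmp
  })
  list(anchor = anchor, subjects = subjects, comparisons = comparisons,
       options = modifyList(pipeline_defaults(), config$options %||% list()))
}

parse_roles <- function(roles) {
  if (is.null(roles)) return(NULL)
  do.call(ligand_roles, roles)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (!is.null(attributes(x)) && !is.null(attr(x, "class"))) unclass(x) else x
}

unclass_report <- function(x) {
  x <- unclass(x)
  x$hbonds <- as.data.frame(x$hbonds)
  x$salt_bridges <- as.data.frame(x$salt_bridges)
  x
}

#' @export
print.gale_report <- function(x, ...) {
  cat(sprintf("<gale_report> anchor %s; %d subject(s), %d superposition(s)%s\n",
              x$anchor$id, length(x$subjects), length(x$superpositions),
              if (!is.null(x$tree_newick)) ", tree built" else ""))
  invisible(x)
}
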