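# Threshold-consensus library design: per-algorithm energy thresholds select
# candidate stabilizing mutations, the per-algorithm libraries are merged by
# union (a mutation enters the library when any one algorithm selects it),
# and an MSA consensus designer contributes sequence-based candidates.

#' Per-algorithm selection thresholds
#'
#' Defaults follow the standard operating points for the three structure-based
#' predictors: FoldX -1.5 kcal/mol, Rosetta -1.0 REU, ABACUS -2.5 AEU. A
#' mutation passes an algorithm when its score is at or below the threshold
#' (boundary inclusive by default).
#'
#' @param ... named thresholds overriding or extending the defaults, e.g.
#'   `contact = -2`.
#' @param boundary_inclusive select scores equal to the threshold (default
#'   `TRUE`).
#' @return an object of class `threshold_config` (named numeric vector of
#'   cutoffs plus the boundary rule).
#' @export
threshold_config <- function(..., boundary_inclusive = TRUE) {
  thresholds <- c(foldx = -1.5, rosetta = -1.0, abacus = -2.5)
  extra <- c(...)
  if (length(extra) > 0) {
    stopifnot(!is.null(names(extra)), all(names(extra) != ""))
    thresholds[names(extra)] <- extra
  }
  structure(list(thresholds = thresholds, boundary_inclusive = boundary_inclusive),
            class = "threshold_config")
}

#' Apply per-algorithm thresholds to score predictions
#'
#' Groups predictions by mutation and selects every mutation whose score
#' passes at least one algorithm's threshold; `selected_by` records exactly
#' the passing algorithms.
#'
#' @param predictions data frame with columns `mutation`, `algorithm`,
#'   `score` (e.g. from [score_library()] or [read_predictions()]); rows from
#'   several algorithms may be concatenated.
#' @param config a [threshold_config()]; every algorithm present in
#'   `predictions` must have a threshold.
#' @return data frame of selected mutations: `mutation`, `wt`, `position`,
#'   `mut`, one score column per algorithm, and `selected_by`
#'   (semicolon-joined algorithm names).
#' @export
apply_thresholds <- function(predictions, config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  algos <- unique(predictions$algorithm)
  unknown <- setdiff(algos, names(config$thresholds))
  if (length(unknown) > 0)
    stopf("no threshold configured for algorithm(s): %s",
          paste(unknown, collapse = ", "))
  muts <- unique(predictions$mutation)
  score_mat <- matrix(NA_real_, length(muts), length(algos),
                      dimnames = list(muts, algos))
  for (i in seq_len(nrow(predictions)))
    score_mat[predictions$mutation[i], predictions$algorithm[i]] <- predictions$score[i]
  thr <- config$thresholds[algos]
  pass <- if (config$boundary_inclusive) {
    sweep(score_mat, 2, thr, "<=")
  } else {
    sweep(score_mat, 2, thr, "<")
  }
  pass[is.na(pass)] <- FALSE
  sel <- rowSums(pass) > 0
  if (!any(sel)) {
    out <- data.frame(mutation = character(0), wt = character(0),
                      position = integer(0), mut = character(0))
    for (al in algos) out[[paste0("score_", al)]] <- numeric(0)
    out$selected_by <- character(0)
    return(out)
  }
  out <- data.frame(mutation = muts[sel], stringsAsFactors = FALSE)
  parsed <- lapply(out$mutation, parse_mutation)
  out$wt <- vapply(parsed, function(m) m$wt_aa, character(1))
  out$position <- vapply(parsed, function(m) m$position, integer(1))
  out$mut <- vapply(parsed, function(m) m$mut_aa, character(1))
  for (al in algos) out[[paste0("score_", al)]] <- score_mat[sel, al]
  out$selected_by <- apply(pass[sel, , drop = FALSE], 1, function(p)
    paste(algos[p], collapse = ";"))
  rownames(out) <- NULL
  out[order(out$position, out$mut), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

selected_by_sets <- function(library) strsplit(library$selected_by, ";", fixed = TRUE)

#' Merge per-algorithm candidate libraries
#'
#' Union keyed by mutation identity; `selected_by` sets and score columns are
#' merged. Conflicting wild-type residues at the same position across inputs
#' indicate inconsistent input data and raise an error.
#'
#' @param libraries list of selected-library data frames from
#'   [apply_thresholds()].
#' @return a single merged library, sorted by position then mutant residue.
#' @export
merge_libraries <- function(libraries) {
  libraries <- Filter(function(l) !is.null(l) && nrow(l) > 0, libraries)
  if (length(libraries) == 0)
    return(data.frame(mutation = character(0), wt = character(0),
                      position = integer(0), mut = character(0),
                      selected_by = character(0)))
  all_rows <- do.call(rbind, lapply(libraries, function(l)
    l[, c("mutation", "wt", "position", "mut", "selected_by")]))
  wt_by_pos <- unique(all_rows[, c("position", "wt")])
  dup <- wt_by_pos$position[duplicated(wt_by_pos$position)]
  if (length(dup) > 0)
    stopf("conflicting wild-type residues at position(s): %s",
          paste(unique(dup), collapse = ", "))
  score_cols <- unique(unlist(lapply(libraries, function(l)
    grep("^score_", names(l), value = TRUE))))
  muts <- unique(all_rows$mutation)
  out <- all_rows[match(muts, all_rows$mutation), c("mutation", "wt", "position", "mut")]
  for (sc in score_cols) out[[sc]] <- NA_real_
  sel_by <- stats::setNames(vector("list", length(muts)), muts)
  for (l in libraries) {
    for (i in seq_len(nrow(l))) {
      m <- l$mutation[i]
      sel_by[[m]] <- union(sel_by[[m]], strsplit(l$selected_by[i], ";")[[1]])
      for (sc in intersect(score_cols, names(l)))
        if (is.na(out[[sc]][out$mutation == m]) && !is.na(l[[sc]][i]))
          out[[sc]][out$mutation == m] <- l[[sc]][i]
    }
  }
  out$selected_by <- vapply(out$mutation, function(m)
    paste(sort(sel_by[[m]]), collapse = ";"), character(1))
  out <- out[order(out$position, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-algorithm exclusivity report
#'
#' Quantifies the complementarity of the algorithms: how many selected
#' mutations each algorithm contributed exclusively versus shared with others.
#'
#' @param library a selected library from [apply_thresholds()] or
#'   [merge_libraries()].
#' @return data frame `algorithm`, `exclusive`, `shared`, `total`.
#' @export
exclusivity_report <- function(library) {
  sets <- selected_by_sets(library)
  algos <- sort(unique(unlist(sets)))
  if (length(algos) == 0)
    return(data.frame(algorithm = character(0), exclusive = integer(0),
                      shared = integer(0), total = integer(0)))
  data.frame(
    algorithm = algos,
    exclusive = vapply(algos, function(a)
      sum(vapply(sets, function(s) length(s) == 1 && s == a, logical(1))), integer(1)),
    shared = vapply(algos, function(a)
      sum(vapply(sets, function(s) a %in% s && length(s) > 1, logical(1))), integer(1)),
    total = vapply(algos, function(a)
      sum(vapply(sets, function(s) a %in% s, logical(1))), integer(1)),
    row.names = NULL)
}

#' Consensus design from a multiple sequence alignment
#'
#' For each position of the target sequence whose aligned column has a modal
#' non-gap residue differing from the target, with frequency at least
#' `min_frequency` (computed over non-gap symbols) and at least `min_depth`
#' non-gap sequences, proposes the back-to-consensus substitution. Positions
#' where the target row is gapped are never proposed (no insertion design).
#'
#' @param msa aligned FASTA path, or a character matrix of aligned residues
#'   (rows = sequences).
#' @param target_sequence the target's 1-letter sequence; must match one MSA
#'   row after removing gaps (the anchor row).
#' @param min_frequency modal-residue frequency cutoff (default 0.6).
#' @param min_depth minimum non-gap column depth (default 10).
#' @param chain chain identifier attached to the proposed mutations.
#' @return list of [mutation()] objects, positions numbered along
#'   `target_sequence` (1-based).
#' @export
consensus_design <- function(msa, target_sequence, min_frequency = 0.6,
                             min_depth = 10, chain = "A") {
  ali <- if (is.matrix(msa)) toupper(msa) else toupper(bio3d::read.fasta(msa)$ali)
  gap <- c("-", ".", "X")
  ungapped <- apply(ali, 1, function(r) paste(r[!(r %in% gap)], collapse = ""))
  anchor <- which(ungapped == toupper(target_sequence))
  if (length(anchor) == 0)
    stopf("target sequence does not match any MSA row after degapping")
  anchor <- anchor[1]
  anchor_row <- ali[anchor, ]
  target_cols <- which(!(anchor_row %in% gap))
  out <- list()
  for (p in seq_along(target_cols)) {
    col <- ali[, target_cols[p]]
    col <- col[!(col %in% gap) & col %in% AA1]
    if (length(col) < min_depth) next
    tab <- sort(table(col), decreasing = TRUE)
    modal <- names(tab)[1]
    if (tab[1] / length(col) < min_frequency) next
    wt <- anchor_row[target_cols[p]]
    if (modal != wt)
      out[[length(out) + 1]] <- mutation(wt, p, modal, chain = chain)
  }
  out
}

#' Write a selected library to CSV
#'
#' Mirrors the six-column results-table layout (mutation identity, the
#' algorithms that selected it, and their energies).
#'
#' @param library data frame from [apply_thresholds()] / [merge_libraries()].
#' @param path output CSV path.
#' @export
write_library <- function(library, path) {
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}
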