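# Pluggable stability scorers. A scorer maps (structure, mutation) to a
# single energy-like score under the shared convention "more negative = more
# stabilizing". External predictors (FoldX, Rosetta, ABACUS, ...) enter the
# pipeline as score tables in this convention; two built-in scorers keep the
# whole pipeline runnable offline.

#' Create a stability scorer
#'
#' @param name algorithm name (e.g. `"foldx"`); used to look up thresholds.
#' @param fn function `(structure, mutation) -> numeric score`; more negative
#'   means more stabilizing.
#' @param unit score unit label (e.g. `"kcal/mol"`, `"REU"`, `"AEU"`).
#' @return an object of class `stability_scorer`.
#' @export
stability_scorer <- function(name, fn, unit = "arbitrary") {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  structure(list(name = name, fn = fn, unit = unit), class = "stability_scorer")
}

#' Table-driven ("planted") scorer
#'
#' Returns a fixed score per canonical mutation name, with a default for
#' unlisted mutations. Used to inject known effects into pipeline tests and to
#' represent an external predictor's report as a scorer.
#'
#' @param effects named numeric vector, names are canonical mutation names.
#' @param default score for mutations absent from `effects` (default `+1`).
#' @inheritParams stability_scorer
#' @return a [stability_scorer()].
#' @export
scorer_planted <- function(effects, default = 1, name = "planted",
                           unit = "arbitrary") {
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  stability_scorer(name, function(structure, mut) {
    nm <- format(mut)
    if (nm %in% names(effects)) unname(effects[[nm]]) else default
  }, unit = unit)
}

#' Heavy-atom contact-count scorer
#'
#' A deliberately simple structure-based score: minus the change in the number
#' of heavy-atom contacts (within `radius` Angstrom) between the mutated
#' residue's side chain and the rest of the structure, mutant versus wild
#' type. Gaining packing contacts scores negative (stabilizing). Deterministic
#' given the structure.
#'
#' @param radius contact radius in Angstrom (default 4.5).
#' @return a [stability_scorer()] named `"contact"`.
#' @export
scorer_contact <- function(radius = 4.5) {
  count_side_contacts <- function(s, key) {
    a <- s$atoms
    side <- which(a$reskey == key & !a$is_backbone)
    other <- which(a$reskey != key)
    if (length(side) == 0 || length(other) == 0) return(0L)
    xyz_s <- as.matrix(a[side, c("x", "y", "z")])
    xyz_o <- as.matrix(a[other, c("x", "y", "z")])
    n <- 0L
    for (r in seq_len(nrow(xyz_s)))
      n <- n + sum(rowSums(sweep(xyz_o, 2, xyz_s[r, ])^2) <= radius^2)
    n
  }
  stability_scorer("contact", function(structure, mut) {
    key <- paste(mut$chain, mut$position, mut$insert, sep = "|")
    mutant <- build_mutant(structure, mut)
    -(count_side_contacts(mutant, key) - count_side_contacts(structure, key))
  }, unit = "arbitrary")
}

#' Score a mutation library with one scorer
#'
#' Applies the scorer to every mutation; a scorer failure on an individual
#' mutation is recorded as a missing score rather than aborting the run, and
#' the failed mutations are summarized in the `failures` attribute.
#'
#' @param structure wild-type [protein_structure()].
#' @param mutations list of [mutation()] objects (or canonical name strings).
#' @param scorer a [stability_scorer()].
#' @return data frame `mutation`, `algorithm`, `score`, `unit` (one row per
#'   mutation; failed scores are `NA`), with attribute `failures`.
#' @export
score_library <- function(structure, mutations, scorer) {
  stopifnot(inherits(scorer, "stability_scorer"))
  mutations <- lapply(mutations, function(m)
    if (is.character(m)) parse_mutation(m, chain = chain_ids(structure)[1]) else m)
  n <- length(mutations)
  scores <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    s <- tryCatch(scorer$fn(structure, mutations[[i]]), error = function(e) e)
    if (inherits(s, "error")) {
      failures <- c(failures, sprintf("%s: %s", format(mutations[[i]]), conditionMessage(s)))
    } else scores[i] <- s
  }
  out <- data.frame(mutation = vapply(mutations, format, character(1)),
                    algorithm = rep(scorer$name, n), score = scores,
                    unit = rep(scorer$unit, n), stringsAsFactors = FALSE)
  attr(out, "failures") <- failures
  out
}

#' Read/write the predictions interchange CSV
#'
#' Columns `mutation`, `algorithm`, `score`, `unit` — the format through which
#' external predictor adapters hand scores to the library-design stage.
#'
#' @param path CSV path.
#' @return data frame of predictions.
#' @export
read_predictions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mutation", "algorithm", "score")
  if (!all(need %in% names(out)))
    stopf("predictions CSV must have columns %s", paste(need, collapse = ", "))
  if (!"unit" %in% names(out)) out$unit <- "arbitrary"
  out
}

#' @rdname read_predictions
#' @param predictions data frame as returned by [score_library()].
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE)
  invisible(path)
}
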