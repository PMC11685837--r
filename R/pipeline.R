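# Pipeline stages tying the workflow together: configuration-driven library
# design with a human-inspection report, and a fully offline end-to-end demo
# on generated fixtures (structure -> library -> measurement -> clustering ->
# greedy accumulation).

POLAR_SET <- c("D", "E", "K", "R", "N", "Q", "H")

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

# Burial proxy: number of CA atoms within 10 Angstrom of the residue's CA.
ca_neighbor_count <- function(structure, reskey, radius = 10) {
  ca_all <- structure$atoms[structure$atoms$name == "CA", ]
  self <- ca_all[ca_all$reskey == reskey, c("x", "y", "z")]
  d2 <- rowSums(sweep(as.matrix(ca_all[, c("x", "y", "z")]), 2,
                      as.numeric(self[1, ]))^2)
  sum(d2 <= radius^2) - 1L
}

#' Inspection report for a candidate library
#'
#' The flag-don't-drop replacement for manual structural inspection of mutant
#' models: every candidate gets its hydrogen-bond change, hydrophobic-contact
#' change and entropy flag, plus heuristic warning flags (`hbond_loss` when
#' the mutant loses hydrogen bonds, `buried_polar` when a polar/charged
#' residue is introduced at a buried position). Candidates are never
#' auto-rejected; the flags guide human review.
#'
#' @param library selected library from [apply_thresholds()].
#' @param structure wild-type [protein_structure()].
#' @return the library with extra columns `hbond`, `hydrophobic`, `entropy`,
#'   `flags`.
#' @export
inspection_report <- function(library, structure) {
  flags <- character(nrow(library))
  hb <- integer(nrow(library)); ph <- integer(nrow(library))
  en <- integer(nrow(library))
  for (i in seq_len(nrow(library))) {
    mut <- parse_mutation(library$mutation[i], chain = chain_ids(structure)[1])
    fv <- compute_features(structure, mut, delta_tm = NA_real_)
    hb[i] <- fv$hbond; ph[i] <- fv$hydrophobic; en[i] <- fv$entropy
    fl <- character(0)
    if (fv$hbond < 0) fl <- c(fl, "hbond_loss")
    key <- paste(mut$chain, mut$position, mut$insert, sep = "|")
    if (mut$mut_aa %in% POLAR_SET && !(mut$wt_aa %in% POLAR_SET) &&
        ca_neighbor_count(structure, key) >= 10)
      fl <- c(fl, "buried_polar")
    flags[i] <- paste(fl, collapse = ";")
  }
  cbind(library, data.frame(hbond = hb, hydrophobic = ph, entropy = en,
                            flags = flags))
}

write_manifest <- function(out_dir, config, files) {
  sums <- tools::md5sum(file.path(out_dir, files))
  names(sums) <- files
  jsonlite::write_json(list(config = config, checksums = as.list(sums)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the library-design stage from a configuration
#'
#' Reads the structure, selects the chain, enumerates candidate mutations,
#' scores them with the configured scorers and/or external prediction tables,
#' applies the per-algorithm thresholds, and writes the selected library with
#' its inspection report and a run manifest. Configuration errors (e.g. a
#' scorer without a threshold) abort before any computation.
#'
#' @param config a list or YAML file path with fields: `pdb` (path), `chain`,
#'   `scorers` (character vector of built-ins: `"contact"`), `predictions`
#'   (optional paths to external prediction CSVs, see [read_predictions()]),
#'   `thresholds` (named list overriding [threshold_config()] defaults),
#'   `exclude_positions` (optional), `out_dir`, `seed`.
#' @return list with `library` and `inspection` data frames (file paths in
#'   attribute `files`), invisibly.
#' @export
run_design_stage <- function(config) {
  config <- load_run_config(config)
  for (field in c("pdb", "out_dir"))
    if (is.null(config[[field]])) stopf("config field '%s' is required", field)
  thr <- do.call(threshold_config, as.list(config$thresholds %||% list()))
  scorer_names <- config$scorers %||% character(0)
  ext_algos <- character(0)
  for (p in config$predictions %||% character(0))
    ext_algos <- union(ext_algos, unique(read_predictions(p)$algorithm))
  need_thr <- c(scorer_names, ext_algos)
  missing_thr <- setdiff(need_thr, names(thr$thresholds))
  if (length(missing_thr) > 0)
    stopf("configuration error: no threshold for scorer(s) %s",
          paste(missing_thr, collapse = ", "))

  wt <- read_pdb(config$pdb)
  chain <- config$chain %||% chain_ids(wt)[1]
  wt <- select_chain(wt, chain)
  cands <- enumerate_candidate_mutations(
    wt, chain, exclude_positions = config$exclude_positions %||% integer(0))
  preds <- list()
  for (nm in scorer_names) {
    scorer <- switch(nm,
      contact = scorer_contact(),
      stopf("unknown built-in scorer \"%s\"", nm))
    preds[[length(preds) + 1]] <- score_library(wt, cands, scorer)
  }
  for (p in config$predictions %||% character(0))
    preds[[length(preds) + 1]] <- read_predictions(p)
  if (length(preds) == 0) stopf("no scorers or prediction tables configured")
  predictions <- do.call(rbind, preds)
  library <- apply_thresholds(predictions, thr)
  inspection <- inspection_report(library, wt)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_library(library, file.path(config$out_dir, "library.csv"))
  utils::write.csv(inspection, file.path(config$out_dir, "inspection.csv"),
                   row.names = FALSE)
  write_manifest(config$out_dir,
                 config[setdiff(names(config), c("pdb", "out_dir", "predictions"))],
                 c("library.csv", "inspection.csv"))
  out <- list(library = library, inspection = inspection)
  attr(out, "files") <- file.path(config$out_dir,
                                  c("library.csv", "inspection.csv", "manifest.json"))
  invisible(out)
}

#' Run the full workflow end-to-end on generated fixtures
#'
#' An offline demonstration of the complete cycle: generates a toy helix,
#' plants a ground-truth epistatic landscape over its candidate mutations,
#' emulates three complementary predictors as noisy linear readouts of the
#' true effects, designs the thresholded library, "measures" the selected
#' singles on the landscape, filters at the stabilization criterion
#' (delta-Tm >= 1.5 degrees C), computes features, clusters, runs greedy
#' accumulation per cluster, and merges the cluster winners. All artifacts
#' are written to `out_dir`; everything is reproducible from `seed`.
#'
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @param n_residues size of the toy protein (default 36).
#' @param n_true number of planted true stabilizing mutations (default 14).
#' @param noise_sd measurement noise on delta-Tm evaluations (default 0.5
#'   degrees C).
#' @return summary list: candidate/library/validated counts, cluster count,
#'   best single and final delta-Tm, final variant.
#' @export
run_full_demo <- function(seed, out_dir, n_residues = 36, n_true = 14,
                          noise_sd = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- make_toy_pdb(n_residues, "helix", seed = seed)
  cands <- enumerate_candidate_mutations(wt)
  cand_names <- vapply(cands, format, character(1))

  # ground truth: a small set of genuinely stabilizing mutations at distinct
  # positions, mild pairwise epistasis among them, everything else neutral to
  # destabilizing
  landscape <- with_seed(seed + 1L, {
    positions <- vapply(cands, function(m) m$position, integer(1))
    true_pos <- sample(unique(positions), n_true)
    true_idx <- vapply(true_pos, function(p) sample(which(positions == p), 1), integer(1))
    a <- stats::rnorm(length(cands), -2.0, 1.5)
    a[true_idx] <- stats::rnorm(n_true, 2.5, 1.0)
    names(a) <- cand_names
    true_names <- cand_names[true_idx]
    pairs <- utils::combn(true_names, 2)
    pick <- stats::runif(ncol(pairs)) < 0.3
    epi <- if (any(pick)) data.frame(m1 = pairs[1, pick], m2 = pairs[2, pick],
                                     e = stats::rnorm(sum(pick), 0, 1.0)) else NULL
    epistatic_landscape(a, epi, noise_sd = noise_sd)
  })

  # three emulated predictors: noisy negatively-scaled readouts of the true
  # additive effect, on each algorithm's native scale
  predictions <- with_seed(seed + 2L, {
    a <- landscape$additive
    emul <- function(alg, scale, sd, unit) data.frame(
      mutation = cand_names, algorithm = alg,
      score = -scale * a + stats::rnorm(length(a), 0, sd), unit = unit)
    rbind(emul("foldx", 0.6, 0.9, "kcal/mol"),
          emul("rosetta", 0.35, 0.55, "REU"),
          emul("abacus", 1.0, 1.4, "AEU"))
  })
  library <- apply_thresholds(predictions, threshold_config())

  # "measure" the selected singles, keep those clearing the 1.5 C criterion
  singles <- with_seed(seed + 3L, data.frame(
    mutation = library$mutation,
    delta_tm = vapply(library$mutation, function(m)
      evaluate_landscape(landscape, m), numeric(1))))
  singles$validated <- singles$delta_tm >= 1.5
  validated <- singles[singles$validated, c("mutation", "delta_tm")]
  rownames(validated) <- NULL

  features <- feature_table(validated, wt)
  if (nrow(features) < 2)
    stopf("demo produced %d validated mutation(s); need at least 2 to cluster (try another seed)",
          nrow(features))
  assignment <- if (nrow(features) >= 4) {
    cluster_mutations(features, k = "auto", seed = seed)
  } else {
    cluster_mutations(features, k = 1, seed = seed)
  }
  report <- cluster_report(assignment)

  # greedy accumulation within each cluster, members in dTm-descending order
  paths <- list()
  for (i in seq_len(nrow(report))) {
    members <- strsplit(report$members[i], ";")[[1]]
    paths[[i]] <- with_seed(seed + 10L + i, greedy_accumulate(
      members, function(s) evaluate_landscape(landscape, s),
      min_improvement = 1.5))
  }

  # one substitution per site before the cross-cluster merge: if two clusters
  # accepted different mutations at one position, keep the better single
  accepted_all <- unlist(lapply(paths, function(p) p$accepted))
  pos_of <- vapply(accepted_all, function(m) parse_mutation(m)$position, integer(1))
  drop <- character(0)
  for (p in unique(pos_of[duplicated(pos_of)])) {
    at_p <- accepted_all[pos_of == p]
    best <- at_p[which.max(singles$delta_tm[match(at_p, singles$mutation)])]
    drop <- c(drop, setdiff(at_p, best))
  }
  if (length(drop) > 0)
    paths <- lapply(paths, function(p) {
      keep <- !(p$accepted %in% drop)
      p$accepted <- p$accepted[keep]; p$values <- p$values[keep]; p
    })

  final <- with_seed(seed + 20L, combine_cluster_winners(
    paths, function(s) evaluate_landscape(landscape, s), min_improvement = 1.5))

  # artifacts
  write_pdb(wt, file.path(out_dir, "wild_type.pdb"))
  write_predictions(predictions, file.path(out_dir, "predictions.csv"))
  write_library(library, file.path(out_dir, "library.csv"))
  utils::write.csv(singles, file.path(out_dir, "singles.csv"), row.names = FALSE)
  utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write_clusters(assignment, file.path(out_dir, "clusters.csv"))
  utils::write.csv(report, file.path(out_dir, "cluster_summary.csv"), row.names = FALSE)
  path_rows <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    if (length(p$accepted) == 0) return(NULL)
    data.frame(cluster = report$cluster[i], step = seq_along(p$accepted),
               mutation = p$accepted, delta_tm = p$values)
  }))
  if (is.null(path_rows))
    path_rows <- data.frame(cluster = integer(0), step = integer(0),
                            mutation = character(0), delta_tm = numeric(0))
  utils::write.csv(path_rows, file.path(out_dir, "greedy_paths.csv"), row.names = FALSE)

  best_single <- if (nrow(validated) > 0) max(validated$delta_tm) else 0
  summary <- list(
    seed = seed, n_residues = n_residues,
    n_candidates = length(cands),
    n_library = nrow(library),
    n_validated = nrow(validated),
    k_clusters = assignment$k,
    best_single_delta_tm = best_single,
    final_variant = paste(sort(final$final), collapse = "+"),
    final_delta_tm = final$final_value,
    true_optimum_delta_tm = brute_force_best_restricted(landscape, validated$mutation)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 6)
  write_manifest(out_dir, list(seed = seed, n_residues = n_residues,
                               n_true = n_true, noise_sd = noise_sd),
                 c("wild_type.pdb", "predictions.csv", "library.csv",
                   "singles.csv", "features.csv", "clusters.csv",
                   "cluster_summary.csv", "greedy_paths.csv", "summary.json"))
  summary
}

# Exhaustive optimum restricted to the validated mutation set (kept feasible
# by the size of the validated library).
brute_force_best_restricted <- function(landscape, subset_names) {
  if (length(subset_names) == 0) return(0)
  if (length(subset_names) > 20) subset_names <- subset_names[seq_len(20)]
  sub <- epistatic_landscape(
    landscape$additive[subset_names],
    landscape$epistasis[landscape$epistasis$m1 %in% subset_names &
                          landscape$epistasis$m2 %in% subset_names, , drop = FALSE],
    noise_sd = 0)
  brute_force_best(sub)$value
}
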