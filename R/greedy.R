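# Greedy accumulation of stabilizing mutations: steepest-ascent rounds in
# which every one-mutation extension of the current best variant is measured
# and the best extension is accepted only when it improves the measured
# delta-Tm by at least the improvement tolerance (default 1.5 degrees C, the
# single-mutant stabilization criterion reused as the combination bar).

#' Greedy accumulation of mutations
#'
#' Round-based steepest ascent. Starting from the best single mutant (or the
#' empty variant), each round measures the addition of every remaining
#' candidate to the current accepted set and accepts the best one if it beats
#' the current value by at least `min_improvement`; otherwise the path stops.
#' For a candidate list of size k this uses at most `k(k+1)/2` evaluations.
#'
#' @param candidates character vector of mutation names (the cluster members,
#'   typically in descending single-mutant delta-Tm order).
#' @param evaluate function `(character subset) -> measured delta-Tm`.
#' @param start `"best_single"` (default) measures all singles in the first
#'   round and starts the path from the best one; `"empty"` starts from the
#'   wild type. Both apply the same acceptance bar to the first step (the
#'   first accepted variant must clear `min_improvement` over the wild type),
#'   so the first round is identical; the option is kept for interface
#'   symmetry with the experiment planner.
#' @param min_improvement acceptance bar per step in degrees C (default 1.5).
#' @param budget optional cap on the number of evaluations (>= 1).
#' @return an object of class `accumulation_path`: `accepted` (mutations in
#'   acceptance order), `values` (measured delta-Tm after each acceptance),
#'   `evaluations` (log of every evaluation: variant and measured value),
#'   `evaluations_used`, and `stop_reason`
#'   (`"no_improvement"`, `"exhausted"`, or `"budget"`).
#' @export
greedy_accumulate <- function(candidates, evaluate,
                              start = c("best_single", "empty"),
                              min_improvement = 1.5, budget = NULL) {
  start <- match.arg(start)
  stopifnot(length(candidates) > 0, is.function(evaluate))
  if (!is.null(budget) && (!is_count(budget) || budget < 1))
    stopf("budget must be a positive integer")
  log_var <- character(0); log_val <- numeric(0)
  used <- 0L
  measure <- function(subset) {
    v <- evaluate(subset)
    used <<- used + 1L
    log_var <<- c(log_var, paste(subset, collapse = "+"))
    log_val <<- c(log_val, v)
    v
  }
  out_of_budget <- function() !is.null(budget) && used >= budget
  current <- character(0); current_value <- 0
  accepted <- character(0); values <- numeric(0)
  remaining <- candidates
  stop_reason <- NULL

  repeat {
    if (length(remaining) == 0) { stop_reason <- "exhausted"; break }
    trial_values <- rep(NA_real_, length(remaining))
    for (i in seq_along(remaining)) {
      if (out_of_budget()) break
      trial_values[i] <- measure(c(current, remaining[i]))
    }
    if (all(is.na(trial_values))) { stop_reason <- "budget"; break }
    best_i <- which.max(trial_values)
    if (trial_values[best_i] >= current_value + min_improvement) {
      current <- c(current, remaining[best_i])
      current_value <- trial_values[best_i]
      accepted <- c(accepted, remaining[best_i])
      values <- c(values, current_value)
      remaining <- remaining[-best_i]
      if (out_of_budget() && length(remaining) > 0) { stop_reason <- "budget"; break }
    } else {
      stop_reason <- if (out_of_budget() && any(is.na(trial_values)))
        "budget" else "no_improvement"
      break
    }
  }
  structure(list(accepted = accepted, values = values,
                 evaluations = data.frame(variant = log_var, delta_tm = log_val),
                 evaluations_used = used, stop_reason = stop_reason,
                 min_improvement = min_improvement),
            class = "accumulation_path")
}

#' @export
print.accumulation_path <- function(x, ...) {
  cat(sprintf("<accumulation_path> %d accepted, final dTm %.2f C, %d evaluations (%s)\n",
              length(x$accepted),
              if (length(x$values)) x$values[length(x$values)] else 0,
              x$evaluations_used, x$stop_reason))
  invisible(x)
}

#' Plan the next experimental round per cluster
#'
#' The offline/wet-lab interface to the greedy strategy: given cluster
#' assignments and every combination measured so far, reconstructs the greedy
#' state of each cluster and proposes the variants the next round should
#' measure, without calling any evaluator. Combination variants are named by
#' joining mutation names with `+`.
#'
#' @param clusters data frame `mutation`, `cluster` (see [read_clusters()]).
#' @param results data frame `variant`, `delta_tm` of measurements so far
#'   (may be empty). A measured subset mixing clusters is ignored for
#'   within-cluster planning, with a warning.
#' @param min_improvement acceptance bar per step (default 1.5 degrees C).
#' @return data frame `cluster`, `variant` (one row per proposed measurement;
#'   clusters with no rows have converged), with attribute `status` naming
#'   each cluster's state (`proposing` or `converged`).
#' @export
plan_experiment <- function(clusters, results = NULL, min_improvement = 1.5) {
  stopifnot(all(c("mutation", "cluster") %in% names(clusters)))
  if (is.null(results))
    results <- data.frame(variant = character(0), delta_tm = numeric(0))
  stopifnot(all(c("variant", "delta_tm") %in% names(results)))
  split_variant <- function(v) sort(strsplit(v, "+", fixed = TRUE)[[1]])
  measured <- stats::setNames(results$delta_tm,
                              vapply(results$variant, function(v)
                                paste(split_variant(v), collapse = "+"), character(1)))
  lookup <- function(subset) {
    key <- paste(sort(subset), collapse = "+")
    if (key %in% names(measured)) unname(measured[key]) else NA_real_
  }
  cluster_of <- stats::setNames(clusters$cluster, clusters$mutation)
  # measured subsets spanning clusters carry no within-cluster information
  for (v in results$variant) {
    parts <- split_variant(v)
    cls <- unique(cluster_of[parts[parts %in% names(cluster_of)]])
    if (length(cls) > 1)
      warning(sprintf("measured variant %s spans clusters; ignored for within-cluster planning", v),
              call. = FALSE)
  }
  proposals <- list(); status <- character(0)
  for (cl in sort(unique(clusters$cluster))) {
    members <- clusters$mutation[clusters$cluster == cl]
    singles <- vapply(members, function(m) lookup(m), numeric(1))
    if (any(is.na(singles))) {
      proposals[[as.character(cl)]] <- members[is.na(singles)]
      status <- c(status, stats::setNames("proposing", cl))
      next
    }
    current <- members[which.max(singles)]
    current_value <- max(singles)
    if (current_value < min_improvement) {
      # no single clears the bar; nothing to accumulate
      proposals[[as.character(cl)]] <- character(0)
      status <- c(status, stats::setNames("converged", cl))
      next
    }
    repeat {
      remaining <- setdiff(members, current)
      if (length(remaining) == 0) {
        proposals[[as.character(cl)]] <- character(0)
        status <- c(status, stats::setNames("converged", cl)); break
      }
      ext_values <- vapply(remaining, function(m) lookup(c(current, m)), numeric(1))
      if (any(is.na(ext_values))) {
        proposals[[as.character(cl)]] <- vapply(remaining[is.na(ext_values)],
                                                function(m) paste(sort(c(current, m)), collapse = "+"),
                                                character(1))
        status <- c(status, stats::setNames("proposing", cl)); break
      }
      best_i <- which.max(ext_values)
      if (ext_values[best_i] >= current_value + min_improvement) {
        current <- c(current, remaining[best_i])
        current_value <- ext_values[best_i]
      } else {
        proposals[[as.character(cl)]] <- character(0)
        status <- c(status, stats::setNames("converged", cl)); break
      }
    }
  }
  out <- do.call(rbind, lapply(names(proposals), function(cl)
    if (length(proposals[[cl]]) > 0)
      data.frame(cluster = cl, variant = unname(proposals[[cl]]))
    else NULL))
  if (is.null(out)) out <- data.frame(cluster = character(0), variant = character(0))
  attr(out, "status") <- status
  out
}

#' Monte-Carlo benchmark of the greedy strategy
#'
#' Repeatedly simulates landscapes, runs greedy accumulation with noisy
#' measurements, and scores the chosen variant (noise-free) against the
#' exhaustive optimum.
#'
#' @param repetitions number of simulated campaigns.
#' @param n mutations per landscape (<= 20, oracle-feasible).
#' @param effect_mean,effect_sd,epistasis_fraction,epistasis_sd,noise_sd
#'   landscape parameters, see [simulate_landscape()].
#' @param min_improvement greedy acceptance bar (degrees C).
#' @param seed integer seed; repetition r uses landscape seed `seed + r`.
#' @return one-row data frame: `mean_regret` (oracle value minus the true
#'   value of the greedy variant, averaged), `mean_evaluations`,
#'   `fraction_optimal`.
#' @export
greedy_benchmark <- function(repetitions, n = 8, effect_mean = 1, effect_sd = 2,
                             epistasis_fraction = 0.3, epistasis_sd = 1,
                             noise_sd = 0, min_improvement = 1.5, seed = 0) {
  stopifnot(is_count(repetitions), repetitions >= 1, n <= 20)
  regret <- numeric(repetitions); evals <- integer(repetitions)
  optimal <- logical(repetitions)
  for (r in seq_len(repetitions)) {
    ls <- simulate_landscape(n, effect_mean, effect_sd, epistasis_fraction,
                             epistasis_sd, noise_sd, seed = seed + r)
    path <- with_seed(seed * 1000L + r, greedy_accumulate(
      names(ls$additive), function(s) evaluate_landscape(ls, s),
      min_improvement = min_improvement))
    true_value <- evaluate_landscape(ls, path$accepted, noisy = FALSE)
    oracle <- brute_force_best(ls)
    regret[r] <- oracle$value - true_value
    evals[r] <- path$evaluations_used
    optimal[r] <- isTRUE(all.equal(true_value, oracle$value, tolerance = 1e-9))
  }
  data.frame(mean_regret = mean(regret), mean_evaluations = mean(evals),
             fraction_optimal = mean(optimal))
}

#' Combine converged per-cluster winners
#'
#' The optional cross-cluster final stage: proposes the union of the accepted
#' sets of all cluster paths, measures it, then greedily re-checks each
#' cross-cluster addition on top of the best single-cluster endpoint under the
#' same improvement bar. Clusters proposing different substitutions at the
#' same residue position conflict and raise an error.
#'
#' @param paths list of [greedy_accumulate()] results, one per cluster.
#' @param evaluate function `(character subset) -> measured delta-Tm`.
#' @param min_improvement acceptance bar (default 1.5 degrees C).
#' @return list with `union_variant` (character vector), `union_value`
#'   (its measured delta-Tm), `final` (the greedily re-checked variant) and
#'   `final_value`.
#' @export
combine_cluster_winners <- function(paths, evaluate, min_improvement = 1.5) {
  stopifnot(length(paths) >= 1,
            all(vapply(paths, inherits, logical(1), "accumulation_path")))
  accepted_sets <- lapply(paths, function(p) p$accepted)
  all_muts <- unlist(accepted_sets)
  pos <- vapply(all_muts, function(m) parse_mutation(m)$position, integer(1))
  if (anyDuplicated(pos)) {
    coll <- split(all_muts, pos)
    coll <- coll[vapply(coll, function(x) length(unique(x)) > 1, logical(1))]
    if (length(coll) > 0)
      stopf("conflicting mutations at position(s): %s",
            paste(vapply(coll, paste, character(1), collapse = "/"), collapse = ", "))
    all_muts <- unique(all_muts)
  }
  if (length(paths) == 1) {
    p <- paths[[1]]
    v <- if (length(p$values)) p$values[length(p$values)] else 0
    return(list(union_variant = p$accepted, union_value = v,
                final = p$accepted, final_value = v))
  }
  union_variant <- unique(all_muts)
  union_value <- evaluate(union_variant)
  endpoints <- vapply(paths, function(p)
    if (length(p$values)) p$values[length(p$values)] else 0, numeric(1))
  best_cluster <- which.max(endpoints)
  current <- accepted_sets[[best_cluster]]
  current_value <- endpoints[best_cluster]
  remaining <- setdiff(union_variant, current)
  while (length(remaining) > 0) {
    ext <- unname(vapply(remaining, function(m) evaluate(c(current, m)), numeric(1)))
    best_i <- which.max(ext)
    if (ext[best_i] >= current_value + min_improvement) {
      current <- c(current, remaining[best_i])
      current_value <- ext[best_i]
      remaining <- remaining[-best_i]
    } else break
  }
  list(union_variant = union_variant, union_value = union_value,
       final = current, final_value = current_value)
}
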