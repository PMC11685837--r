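# Synthetic epistatic landscapes: the ground-truth stand-in for wet-lab
# melting-temperature measurements of combination variants. The combined
# effect of a mutation subset S is
#   dTm(S) = sum_{m in S} a_m + sum_{{m,n} subset S} e_mn + noise,
# with additive effects a_m, pairwise epistasis e_mn on a configurable
# fraction of pairs, and i.i.d. Gaussian measurement noise per evaluation.

#' Construct an epistatic landscape
#'
#' @param additive named numeric vector of additive effects `a_m`
#'   (degrees C), names are mutation identifiers.
#' @param epistasis data frame with columns `m1`, `m2`, `e` (pairwise terms,
#'   degrees C), or `NULL` for a purely additive landscape.
#' @param noise_sd measurement noise standard deviation (degrees C).
#' @return an object of class `epistatic_landscape`.
#' @seealso [simulate_landscape()], [evaluate_landscape()]
#' @export
epistatic_landscape <- function(additive, epistasis = NULL, noise_sd = 0) {
  stopifnot(is.numeric(additive), !is.null(names(additive)), noise_sd >= 0)
  if (!is.null(epistasis) && nrow(epistasis) > 0) {
    stopifnot(all(c("m1", "m2", "e") %in% names(epistasis)))
    stopifnot(all(c(epistasis$m1, epistasis$m2) %in% names(additive)))
  } else epistasis <- data.frame(m1 = character(0), m2 = character(0), e = numeric(0))
  structure(list(additive = additive, epistasis = epistasis, noise_sd = noise_sd),
            class = "epistatic_landscape")
}

#' Simulate a random epistatic landscape
#'
#' Additive effects are drawn from a normal distribution; a random
#' `epistasis_fraction` of mutation pairs receives a pairwise term drawn from
#' `N(0, epistasis_sd)`. Reproducible for a given seed.
#'
#' @param n number of mutations (>= 1); they are named `m1..mn`.
#' @param effect_mean,effect_sd mean and sd of the additive effects
#'   (degrees C); defaults 1 and 2 give a library in which roughly a third of
#'   single mutations clear a 1.5 degree stabilization bar.
#' @param epistasis_fraction fraction of pairs carrying an epistatic term, in
#'   `[0, 1]`.
#' @param epistasis_sd sd of the pairwise terms (degrees C).
#' @param noise_sd per-evaluation measurement noise sd (degrees C).
#' @param seed integer seed.
#' @return an [epistatic_landscape()].
#' @export
simulate_landscape <- function(n, effect_mean = 1, effect_sd = 2,
                               epistasis_fraction = 0.3, epistasis_sd = 1,
                               noise_sd = 0, seed = 0) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  if (epistasis_fraction < 0 || epistasis_fraction > 1)
    stopf("epistasis_fraction must be in [0, 1]")
  if (epistasis_sd < 0 || noise_sd < 0) stopf("standard deviations must be >= 0")
  with_seed(seed, {
    mut_names <- paste0("m", seq_len(n))
    a <- stats::setNames(stats::rnorm(n, effect_mean, effect_sd), mut_names)
    epi <- NULL
    if (n >= 2) {
      pairs <- utils::combn(mut_names, 2)
      pick <- stats::runif(ncol(pairs)) < epistasis_fraction
      if (any(pick))
        epi <- data.frame(m1 = pairs[1, pick], m2 = pairs[2, pick],
                          e = stats::rnorm(sum(pick), 0, epistasis_sd))
    }
    epistatic_landscape(a, epi, noise_sd = noise_sd)
  })
}

#' Evaluate a mutation subset on a landscape
#'
#' @param landscape an [epistatic_landscape()].
#' @param subset character vector of mutation names (possibly empty).
#' @param noisy draw measurement noise (default `TRUE`); `FALSE` returns the
#'   exact value.
#' @return measured (or exact) combined delta-Tm in degrees C.
#' @export
evaluate_landscape <- function(landscape, subset, noisy = TRUE) {
  stopifnot(inherits(landscape, "epistatic_landscape"))
  subset <- unique(subset)
  bad <- setdiff(subset, names(landscape$additive))
  if (length(bad) > 0)
    stopf("unknown mutation(s) in subset: %s", paste(bad, collapse = ", "))
  value <- sum(landscape$additive[subset])
  epi <- landscape$epistasis
  if (nrow(epi) > 0 && length(subset) >= 2) {
    inset <- epi$m1 %in% subset & epi$m2 %in% subset
    value <- value + sum(epi$e[inset])
  }
  if (noisy && landscape$noise_sd > 0)
    value <- value + stats::rnorm(1, 0, landscape$noise_sd)
  value
}

#' Exhaustive optimum of a landscape
#'
#' Enumerates all subsets (noise-free evaluation) and returns the best; the
#' oracle against which the greedy accumulation strategy is benchmarked.
#'
#' @param landscape an [epistatic_landscape()].
#' @param max_n refuse enumeration beyond this size (default 20).
#' @return list with `subset` (character vector) and `value` (degrees C; the
#'   empty set with value 0 when nothing helps).
#' @export
brute_force_best <- function(landscape, max_n = 20) {
  stopifnot(inherits(landscape, "epistatic_landscape"))
  muts <- names(landscape$additive)
  n <- length(muts)
  if (n > max_n) stopf("landscape too large for exhaustive search (%d > %d)", n, max_n)
  codes <- seq_len(2^n) - 1L
  member <- outer(codes, 2^(seq_len(n) - 1L), function(cd, bit) bitwAnd(cd, bit) > 0)
  values <- as.numeric(member %*% landscape$additive)
  epi <- landscape$epistasis
  if (nrow(epi) > 0) {
    i1 <- match(epi$m1, muts); i2 <- match(epi$m2, muts)
    for (r in seq_len(nrow(epi)))
      values <- values + epi$e[r] * (member[, i1[r]] & member[, i2[r]])
  }
  best_i <- which.max(values)
  value <- values[best_i]
  if (value <= 0) return(list(subset = character(0), value = 0))
  list(subset = muts[member[best_i, ]], value = value)
}
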