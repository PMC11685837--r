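test_that("simulated landscapes are additive when epistasis and noise vanish", {
  ls <- simulate_landscape(5, epistasis_fraction = 0, noise_sd = 0, seed = 3)
  a <- ls$additive
  expect_equal(evaluate_landscape(ls, character(0)), 0)
  for (pair in utils::combn(names(a), 2, simplify = FALSE))
    expect_equal(evaluate_landscape(ls, pair), sum(a[pair]))

  # full-set value decomposes into planted parameters
  ls2 <- simulate_landscape(6, epistasis_fraction = 0.3, noise_sd = 0, seed = 42)
  expect_equal(evaluate_landscape(ls2, names(ls2$additive)),
               sum(ls2$additive) + sum(ls2$epistasis$e))
  # reproducibility
  ls3 <- simulate_landscape(6, epistasis_fraction = 0.3, noise_sd = 0, seed = 42)
  expect_identical(ls2, ls3)
  expect_error(simulate_landscape(3, epistasis_fraction = 2), "fraction")
  expect_error(evaluate_landscape(ls, "nope"), "unknown")
})

test_that("greedy accumulation follows forced additive paths", {
  a <- c(up2 = 2, up1 = 1, down = -1)
  ls <- epistatic_landscape(a)
  path <- greedy_accumulate(names(a), function(s) evaluate_landscape(ls, s),
                            min_improvement = 0.5)
  expect_equal(path$accepted, c("up2", "up1"))
  expect_equal(path$values, c(2, 3))
  expect_equal(path$stop_reason, "no_improvement")

  neg <- epistatic_landscape(c(m1 = -1, m2 = -2))
  path_neg <- greedy_accumulate(names(neg$additive),
                                function(s) evaluate_landscape(neg, s))
  expect_length(path_neg$accepted, 0)
  expect_equal(path_neg$stop_reason, "no_improvement")

  # accepted values increase by at least the tolerance at each step
  expect_true(all(diff(c(0, path$values)) >= 0.5))
})

test_that("greedy value never exceeds the exhaustive oracle", {
  for (seed in 1:10) {
    ls <- simulate_landscape(6, epistasis_fraction = 0.3, epistasis_sd = 2,
                             noise_sd = 0, seed = seed)
    path <- greedy_accumulate(names(ls$additive),
                              function(s) evaluate_landscape(ls, s),
                              min_improvement = 0)
    greedy_value <- evaluate_landscape(ls, path$accepted, noisy = FALSE)
    oracle <- brute_force_best(ls)
    expect_lte(greedy_value, oracle$value + 1e-12)
    expect_lte(path$evaluations_used, 6 * 7 / 2)
  }
  triv <- epistatic_landscape(c(a = 2, b = 1, c = -1))
  best <- brute_force_best(triv)
  expect_setequal(best$subset, c("a", "b"))
  expect_equal(best$value, 3)
  expect_equal(brute_force_best(epistatic_landscape(c(a = -5, b = -1)))$value, 0)
  expect_error(brute_force_best(simulate_landscape(25, seed = 1)), "too large")
})

test_that("the evaluation budget caps the search", {
  ls <- simulate_landscape(8, epistasis_fraction = 0, noise_sd = 0,
                           effect_mean = 3, effect_sd = 0.5, seed = 2)
  path <- greedy_accumulate(names(ls$additive),
                            function(s) evaluate_landscape(ls, s),
                            min_improvement = 0, budget = 10)
  expect_lte(path$evaluations_used, 10)
  expect_equal(path$stop_reason, "budget")
  expect_error(greedy_accumulate("m1", identity, budget = 0), "budget")
})

test_that("experiment planning reconstructs the greedy rounds from results", {
  clusters <- data.frame(mutation = c("A1G", "C2W", "D3K"), cluster = 0L)
  # round 1: nothing measured -> all singles
  r1 <- plan_experiment(clusters, NULL)
  expect_setequal(r1$variant, c("A1G", "C2W", "D3K"))
  # round 2: best single (+3) combined with each remaining member
  res1 <- data.frame(variant = c("A1G", "C2W", "D3K"), delta_tm = c(3, 2, 1.2))
  r2 <- plan_experiment(clusters, res1)
  expect_setequal(r2$variant, c("A1G+C2W", "A1G+D3K"))
  # convergence: no extension clears the bar
  res2 <- rbind(res1, data.frame(variant = c("A1G+C2W", "A1G+D3K"),
                                 delta_tm = c(3.9, 2.5)))
  r3 <- plan_experiment(clusters, res2)
  expect_equal(nrow(r3), 0)
  expect_equal(unname(attr(r3, "status")["0"]), "converged")
  # acceptance: extension clears the bar, next round builds on it
  res2b <- rbind(res1, data.frame(variant = c("A1G+C2W", "A1G+D3K"),
                                  delta_tm = c(5.1, 2.5)))
  r4 <- plan_experiment(clusters, res2b)
  expect_setequal(r4$variant, "A1G+C2W+D3K")
  # cross-cluster measurements warn and are ignored
  clusters2 <- data.frame(mutation = c("A1G", "C2W"), cluster = c(0L, 1L))
  expect_warning(plan_experiment(clusters2,
                                 data.frame(variant = "A1G+C2W", delta_tm = 9)),
                 "spans clusters")
})

test_that("greedy benchmarking is exact on additive landscapes and reproducible", {
  b <- greedy_benchmark(20, n = 6, epistasis_fraction = 0, noise_sd = 0,
                        min_improvement = 0, seed = 5)
  expect_equal(b$fraction_optimal, 1.0)
  expect_equal(b$mean_regret, 0)
  expect_lte(b$mean_evaluations, 6 * 7 / 2)
  b2 <- greedy_benchmark(20, n = 6, epistasis_fraction = 0, noise_sd = 0,
                         min_improvement = 0, seed = 5)
  expect_identical(b, b2)
})

test_that("benchmark summaries reproduce frozen reference values", {
  # greedy vs exhaustive oracle on mildly epistatic landscapes: with no
  # acceptance bar and exact measurements, greedy is near-optimal
  b0 <- greedy_benchmark(200, n = 8, epistasis_fraction = 0.3, epistasis_sd = 1,
                         noise_sd = 0, min_improvement = 0, seed = 7)
  expect_equal(b0$mean_regret, 0.02817872, tolerance = 1e-6)
  expect_equal(b0$fraction_optimal, 0.95, tolerance = 1e-9)
  # with the 1.5 C acceptance bar and 1 C measurement noise the search stops
  # earlier and forfeits more of the optimum
  b1 <- greedy_benchmark(200, n = 8, epistasis_fraction = 0.3, epistasis_sd = 1,
                         noise_sd = 1.0, min_improvement = 1.5, seed = 7)
  expect_equal(b1$mean_regret, 4.119227, tolerance = 1e-6)
  expect_lt(b1$mean_evaluations, b0$mean_evaluations)
})

test_that("cluster winners merge with conflict detection", {
  lsA <- epistatic_landscape(c(A1G = 2, C2W = 2, D9K = 2))
  eval_fn <- function(s) evaluate_landscape(lsA, s)
  pA <- greedy_accumulate(c("A1G", "C2W"), eval_fn, min_improvement = 0.5)
  pC <- greedy_accumulate("D9K", eval_fn, min_improvement = 0.5)
  comb <- combine_cluster_winners(list(pA, pC), eval_fn)
  expect_setequal(comb$union_variant, c("A1G", "C2W", "D9K"))
  expect_equal(comb$final_value, 6)
  single <- combine_cluster_winners(list(pA), eval_fn)
  expect_equal(single$final, pA$accepted)
  expect_equal(single$final_value, 4)

  lsB <- epistatic_landscape(c(A123G = 2, A123S = 2))
  p1 <- greedy_accumulate("A123G", function(s) evaluate_landscape(lsB, s))
  p2 <- greedy_accumulate("A123S", function(s) evaluate_landscape(lsB, s))
  expect_error(combine_cluster_winners(list(p1, p2), identity), "conflict")
})
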