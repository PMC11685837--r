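test_that("planted and contact scorers behave as documented", {
  s <- make_toy_pdb(5, "helix", "GAGAG", seed = 0)
  muts <- list(parse_mutation("A2G"), parse_mutation("G3A"), parse_mutation("A4C"))
  sc <- scorer_planted(c(G3A = -2.0), default = 1, name = "foldx", unit = "kcal/mol")
  pred <- score_library(s, muts, sc)
  expect_equal(pred$score, c(1, -2, 1))
  expect_equal(unique(pred$algorithm), "foldx")
  expect_equal(nrow(score_library(s, list(), sc)), 0)

  contact <- scorer_contact()
  p1 <- score_library(s, muts, contact)
  p2 <- score_library(s, muts, contact)
  expect_identical(p1, p2)

  # a failing scorer records a missing score instead of aborting
  bad <- stability_scorer("bad", function(st, m)
    if (format(m) == "G3A") stop("boom") else 0)
  pb <- score_library(s, muts, bad)
  expect_equal(is.na(pb$score), c(FALSE, TRUE, FALSE))
  expect_match(attr(pb, "failures"), "G3A")
})

test_that("thresholding selects on score <= cutoff with inclusive boundary", {
  pred <- data.frame(
    mutation = c("S121E", "S121E", "S121E", "A3G", "A3G", "A3G", "K7M"),
    algorithm = c("foldx", "rosetta", "abacus", "foldx", "rosetta", "abacus", "foldx"),
    score = c(-2.0, -0.5, -1.0, -1.0, -0.5, -2.0, -1.5))
  sel <- apply_thresholds(pred, threshold_config())
  expect_setequal(sel$mutation, c("S121E", "K7M"))
  expect_equal(sel$selected_by[sel$mutation == "S121E"], "foldx")
  # exact boundary is selected by default, excluded when exclusive
  expect_equal(sel$selected_by[sel$mutation == "K7M"], "foldx")
  sel2 <- apply_thresholds(pred, threshold_config(boundary_inclusive = FALSE))
  expect_false("K7M" %in% sel2$mutation)
  # every algorithm needs a threshold
  expect_error(apply_thresholds(data.frame(mutation = "A1G", algorithm = "mystery",
                                           score = -9), threshold_config()),
               "mystery")
})

test_that("library merge is a union with merged selected_by", {
  mk <- function(names, alg) {
    pred <- data.frame(mutation = names, algorithm = alg, score = -5)
    cfg <- do.call(threshold_config, stats::setNames(list(-1), alg))
    apply_thresholds(pred, cfg)
  }
  l1 <- mk(c("A3G", "C5W"), "foldx")
  l2 <- mk(c("C5W", "D7K"), "rosetta")
  m <- merge_libraries(list(l1, l2))
  expect_setequal(m$mutation, c("A3G", "C5W", "D7K"))
  expect_equal(m$selected_by[m$mutation == "C5W"], "foldx;rosetta")
  expect_equal(nrow(merge_libraries(list(mk(c("A1G", "A2G", "A3G"), "foldx"),
                                         mk(c("C5W", "C6W", "C7W", "C8W"), "rosetta")))), 7)
  expect_equal(merge_libraries(list(l1, l1))$mutation, l1$mutation)
  expect_error(merge_libraries(list(mk("A3G", "foldx"), mk("S3G", "rosetta"))),
               "conflicting wild-type")
})

test_that("exclusivity report partitions the library per algorithm", {
  pred <- rbind(
    data.frame(mutation = "A1G", algorithm = c("foldx", "rosetta", "abacus"),
               score = -9),
    data.frame(mutation = c("C2W", "D3K", "E4M"),
               algorithm = c("foldx", "rosetta", "abacus"), score = -9))
  sel <- apply_thresholds(pred, threshold_config())
  rep <- exclusivity_report(sel)
  expect_equal(rep$exclusive, c(1, 1, 1))
  expect_equal(rep$shared, c(1, 1, 1))
  expect_equal(rep$total, c(2, 2, 2))
  empty <- apply_thresholds(data.frame(mutation = "A1G", algorithm = "foldx",
                                       score = 9), threshold_config())
  expect_equal(nrow(exclusivity_report(empty)), 0)
})

test_that("thresholds are monotone: tightening never adds mutations", {
  for (seed in 1:20) {
    pred <- stabmut:::with_seed(seed, data.frame(
      mutation = paste0("A", 1:30, "G"),
      algorithm = sample(c("foldx", "rosetta", "abacus"), 30, replace = TRUE),
      score = stats::rnorm(30, -1, 1.5)))
    loose <- apply_thresholds(pred, threshold_config())
    tight <- apply_thresholds(pred, threshold_config(
      foldx = -1.5 - seed / 10, rosetta = -1.0 - seed / 20, abacus = -2.5 - seed / 10))
    expect_true(all(tight$mutation %in% loose$mutation))
  }
})

test_that("consensus design proposes modal residues above frequency and depth gates", {
  target <- "QAKL"
  msa <- rbind(matrix(strsplit("QAKL", "")[[1]], 1),
               do.call(rbind, replicate(18, strsplit("EAKL", "")[[1]], simplify = FALSE)),
               strsplit("EGKL", "")[[1]])
  props <- consensus_design(msa, target, min_frequency = 0.6, min_depth = 10)
  expect_equal(vapply(props, format, character(1)), "Q1E")
  # position 2: modal A equals the target -> no proposal; position 3/4 identical

  # depth gate: 3 informative rows only
  msa_small <- msa[1:3, ]
  expect_length(consensus_design(msa_small, target, min_depth = 10), 0)

  # row order must not matter
  shuffled <- msa[stabmut:::with_seed(1, sample(nrow(msa))), ]
  expect_equal(vapply(consensus_design(shuffled, target), format, character(1)),
               "Q1E")

  # gapped anchor columns are never proposed
  msa_gap <- rbind(c("Q", "-", "K", "L"),
                   do.call(rbind, replicate(15, c("E", "W", "K", "L"), simplify = FALSE)))
  props_gap <- consensus_design(msa_gap, "QKL", min_depth = 10)
  expect_equal(vapply(props_gap, format, character(1)), "Q1E")

  expect_error(consensus_design(msa, "WWWW"), "does not match")
})

test_that("consensus design reads aligned FASTA", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(rbind(c(">t", paste0(">s", 1:12)), c("QAKL", rep("EAKL", 12)))), f)
  props <- consensus_design(f, "QAKL", min_depth = 10)
  expect_equal(vapply(props, format, character(1)), "Q1E")
})
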