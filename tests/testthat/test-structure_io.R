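test_that("toy structures round-trip through PDB text", {
  s <- make_toy_pdb(5, "helix", "AAAAA", seed = 0)
  expect_equal(nrow(residue_table(s)), 5)
  expect_equal(get_sequence(s), "AAAAA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  # PDB precision is 3 decimals; a second round trip is then exact
  expect_equal(s2$atoms$x, round(s$atoms$x, 3))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s2, f2)
  expect_equal(read_pdb(f2)$atoms, s2$atoms)
})

test_that("read_pdb drops waters and refuses residues without CA", {
  s <- make_toy_pdb(4, "helix", "ARND", seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  lines <- readLines(f)
  water <- "HETATM 9999  O   HOH A 901      10.000  10.000  10.000  1.00  0.00           O"
  writeLines(append(lines, water, after = length(lines) - 1), f)
  s2 <- expect_silent(read_pdb(f))
  expect_equal(nrow(residue_table(s2)), 4)
  expect_false(any(s2$atoms$resname == "HOH"))

  # excise residue 2's CA
  lines2 <- readLines(f)
  ca2 <- grepl("^ATOM", lines2) & grepl(" CA ", lines2) & grepl(" A   2 ", lines2)
  writeLines(lines2[!ca2], f)
  expect_error(read_pdb(f), "A:2.*CA")
})

test_that("multi-model files are refused under model_policy = error", {
  s <- make_toy_pdb(3, "helix", "AAA", seed = 0)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, f)
  body <- grep("^ATOM", readLines(f), value = TRUE)
  writeLines(c("MODEL     1", body, "ENDMDL", "MODEL     2", body, "ENDMDL", "END"), f)
  expect_error(read_pdb(f, model_policy = "error"), "multi-model")
})

test_that("select_chain isolates a chain and reports available IDs on miss", {
  s <- two_chain_fixture()
  a_only <- select_chain(s, "A")
  expect_equal(chain_ids(a_only), "A")
  expect_equal(nrow(residue_table(a_only)), 5)
  expect_equal(residue_table(a_only)$resno, 1:5)
  expect_error(select_chain(s, "Z"), "A, B")
  single <- make_toy_pdb(4, "helix", seed = 0)
  expect_equal(select_chain(single, "A")$atoms, single$atoms)
})

test_that("candidate enumeration is a full 19-fold saturation scan", {
  s <- make_toy_pdb(10, "helix", seed = 2)
  muts <- enumerate_candidate_mutations(s)
  expect_length(muts, 190)
  expect_length(enumerate_candidate_mutations(s, exclude_positions = 1:10), 0)
  s2 <- make_toy_pdb(2, "helix", "GA", seed = 0)
  muts2 <- vapply(enumerate_candidate_mutations(s2), format, character(1))
  expect_equal(muts2[1:3], c("G1A", "G1C", "G1D"))
  expect_length(muts2, 38)
  # ordered by position, then alphabetically by mutant residue
  pos <- as.integer(gsub("[A-Z]", "", muts2))
  expect_true(!is.unsorted(pos))
  for (p in unique(pos)) {
    mm <- substr(muts2[pos == p], 3, 3)
    expect_equal(mm, sort(mm))
  }
})

test_that("build_mutant swaps exactly one side chain", {
  s <- make_toy_pdb(6, "helix", "LKLFLK", seed = 0)
  mu <- build_mutant(s, parse_mutation("F4G"))
  expect_equal(nrow(residue_table(mu)), 6)
  res4 <- mu$atoms[mu$atoms$resno == 4, ]
  expect_setequal(res4$name, c("N", "CA", "C", "O"))
  expect_equal(unique(res4$resname), "GLY")
  # all other residues untouched
  others_wt <- s$atoms[s$atoms$resno != 4, ]
  others_mu <- mu$atoms[mu$atoms$resno != 4, ]
  expect_equal(others_mu, others_wt, ignore_attr = TRUE)
  # backbone of the mutated residue unchanged
  bb_wt <- s$atoms[s$atoms$resno == 4 & s$atoms$is_backbone, c("name", "x", "y", "z")]
  bb_mu <- res4[res4$is_backbone, c("name", "x", "y", "z")]
  expect_equal(bb_mu, bb_wt, ignore_attr = TRUE)

  expect_error(mutation("A", 1, "A"), "must change")
  expect_error(build_mutant(s, parse_mutation("S4G")), "expected S, found F")
})

test_that("template side chains carry the full heavy-atom complement", {
  n_side <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5, G = 0, H = 6,
              I = 4, L = 4, K = 5, M = 4, F = 7, P = 3, S = 2, T = 3, W = 10,
              Y = 8, V = 3)
  s <- make_toy_pdb(4, "strand", "GGGG", seed = 0)
  for (aa in names(n_side)[-8]) {
    mu <- build_mutant(s, mutation("G", 2, aa))
    expect_equal(sum(mu$atoms$resno == 2), 4 + n_side[[aa]],
                 info = paste("residue", aa))
  }
})

test_that("toy generator is seed-deterministic with near-ideal CA spacing", {
  s1 <- make_toy_pdb(12, "coil", seed = 7)
  s2 <- make_toy_pdb(12, "coil", seed = 7)
  expect_identical(s1$atoms, s2$atoms)
  expect_false(identical(make_toy_pdb(12, "coil", seed = 8)$atoms, s1$atoms))
  for (geom in c("helix", "strand", "coil")) {
    s <- make_toy_pdb(10, geom, seed = 3)
    ca <- as.matrix(s$atoms[s$atoms$name == "CA", c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(abs(steps - 3.8) < 0.3), info = geom)
  }
  expect_error(make_toy_pdb(1, "helix"), "n_residues")
  expect_error(make_toy_pdb(3, "helix", "AA"), "length")
})
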