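# Constructed-geometry fixtures with hand-placed atoms; counts are verified
# against the independent brute-force oracles in helper-oracles.R.

make_atoms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], x = r[[2]], y = r[[3]], z = r[[4]],
               resno = r[[5]], resname = r[[6]], chain = "A")))
}

test_that("a constructed donor-acceptor pair yields exactly one hydrogen bond", {
  # residue 1 contributes a backbone carbonyl O at the origin; residue 10's
  # amide N sits 2.9 A away with its CA antecedent at 150 degrees
  ca10 <- c(2.9, 0, 0) + 1.45 * c(cos(pi / 6), sin(pi / 6), 0)
  s <- protein_structure(make_atoms(
    list("N", -3.4, 1.2, 0, 1, "ALA"), list("CA", -2.5, 0.1, 0, 1, "ALA"),
    list("C", -1.23, 0.05, 0, 1, "ALA"), list("O", 0, 0, 0, 1, "ALA"),
    list("N", 2.9, 0, 0, 10, "ALA"), list("CA", ca10[1], ca10[2], ca10[3], 10, "ALA"),
    list("C", ca10[1] + 1.3, ca10[2] + 0.6, 0, 10, "ALA"),
    list("O", ca10[1] + 1.5, ca10[2] + 1.8, 0, 10, "ALA")))
  hb <- detect_hbonds(s)
  expect_equal(nrow(hb), oracle_hbond_count(s))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O")
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$angle, 150, tolerance = 1e-6)

  # pull the acceptor 10 A away: nothing left
  far <- s
  far$atoms$x[far$atoms$resno == 1] <- far$atoms$x[far$atoms$resno == 1] - 10
  expect_equal(nrow(detect_hbonds(far)), 0)
})

test_that("hydrogen bonds are invariant under rigid-body motion", {
  s <- make_toy_pdb(15, "helix", seed = 4)
  hb0 <- detect_hbonds(s)
  r <- random_rotation(seed = 11)
  s2 <- transform_structure(s, r, c(5, -3, 12))
  hb1 <- detect_hbonds(s2)
  expect_equal(hb1$donor_res, hb0$donor_res)
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-6)
  expect_equal(hb1$angle, hb0$angle, tolerance = 1e-6)
})

test_that("a constructed Val-Leu pair has exactly three hydrophobic contacts", {
  s <- protein_structure(make_atoms(
    list("N", -2.2, 1.2, 0, 1, "VAL"), list("CA", -1.5, 0, 0, 1, "VAL"),
    list("C", -2.2, -1.2, 0, 1, "VAL"), list("O", -3.4, -1.2, 0, 1, "VAL"),
    list("CB", 0, 0, 0, 1, "VAL"), list("CG1", 1.5, 0, 0, 1, "VAL"),
    list("CG2", 0, 1.5, 0, 1, "VAL"),
    list("N", 4.4, 1.7, 0, 5, "LEU"), list("CA", 4.0, 1.5, 0, 5, "LEU"),
    list("C", 4.4, 2.9, 0, 5, "LEU"), list("O", 5.6, 3.1, 0, 5, "LEU"),
    list("CB", 4.0, 0, 0, 5, "LEU"), list("CG", 8.0, 0, 0, 5, "LEU"),
    list("CD1", 9.0, 1.0, 0, 5, "LEU"), list("CD2", 9.0, -1.0, 0, 5, "LEU")))
  # within 5 A: VAL CB-LEU CB (4.0), VAL CG1-LEU CB (2.5), VAL CG2-LEU CB (4.27)
  expect_equal(count_hydrophobic_contacts(s), 3L)
  expect_equal(count_hydrophobic_contacts(s), oracle_hydrophobic_count(s))

  # all-Gly: no side-chain carbons at all
  g <- make_toy_pdb(6, "helix", "GGGGGG", seed = 0)
  expect_equal(count_hydrophobic_contacts(g), 0L)

  # two Leu far apart
  far <- s
  far$atoms[far$atoms$resno == 5, c("x", "y", "z")] <-
    far$atoms[far$atoms$resno == 5, c("x", "y", "z")] + 100
  expect_equal(count_hydrophobic_contacts(far), 0L)
})

test_that("geometric counters match the brute-force oracle on random structures", {
  for (seed in 1:5) {
    geom <- c("helix", "strand", "coil")[(seed %% 3) + 1]
    s <- make_toy_pdb(8 + seed * 3, geom, seed = seed)
    expect_equal(nrow(detect_hbonds(s)), oracle_hbond_count(s), info = seed)
    expect_equal(count_hydrophobic_contacts(s), oracle_hydrophobic_count(s),
                 info = seed)
  }
})

test_that("entropy flag marks Gly/Pro involvement on either side", {
  expect_equal(entropy_flag("A10P"), 1L)
  expect_equal(entropy_flag("G10A"), 1L)
  expect_equal(entropy_flag("P10G"), 1L)
  expect_equal(entropy_flag("S10E"), 0L)
  expect_equal(entropy_flag(mutation("L", 3, "W")), 0L)
})

test_that("feature deltas are local, oracle-consistent and antisymmetric", {
  s <- make_toy_pdb(18, "helix", seed = 9)
  seqs <- strsplit(get_sequence(s), "")[[1]]
  pos <- 8
  mut <- mutation(seqs[pos], pos, if (seqs[pos] == "N") "Q" else "N")
  mu_struct <- build_mutant(s, mut)
  fv <- compute_features(s, mut, delta_tm = 2.0)
  # recount both structures with the oracle over the same local scopes
  key <- paste("A", pos, "", sep = "|")
  scope_wt <- stabmut:::environment_scope(s, key, 8)
  scope_mu <- stabmut:::environment_scope(mu_struct, key, 8)
  oracle_d <- nrow(detect_hbonds(mu_struct, residue_scope = scope_mu)) -
    nrow(detect_hbonds(s, residue_scope = scope_wt))
  expect_equal(fv$hbond, oracle_d)
  # CA coordinates come from the wild type, exactly
  expect_equal(c(fv$ca_x, fv$ca_y, fv$ca_z), stabmut:::atom_xyz(s, key, "CA"))

  # antisymmetry: swapping wild type and mutant negates both deltas
  rev_mut <- mutation(mut$mut_aa, pos, mut$wt_aa)
  fv_rev <- compute_features(mu_struct, rev_mut, delta_tm = -2.0, mutant = s)
  expect_equal(fv_rev$hbond, -fv$hbond)
  expect_equal(fv_rev$hydrophobic, -fv$hydrophobic)

  # mutating to Gly can only remove side-chain carbons
  for (p in c(3, 9, 14)) {
    if (seqs[p] == "G") next
    fg <- compute_features(s, mutation(seqs[p], p, "G"), delta_tm = 1)
    expect_lte(fg$hydrophobic, 0)
  }
})

test_that("feature tables keep the canonical column order and reject duplicates", {
  s <- make_toy_pdb(10, "helix", seed = 5)
  seqs <- strsplit(get_sequence(s), "")[[1]]
  pick <- function(pos, want, alt) paste0(seqs[pos], pos,
                                          if (seqs[pos] == want) alt else want)
  entries <- data.frame(
    mutation = c(pick(3, "W", "F"), pick(6, "E", "K"), pick(9, "G", "A")),
    delta_tm = c(4, 2.5, 1.6))
  tab <- feature_table(entries, s)
  expect_equal(names(tab), c("mutation", "position", "delta_tm", "hbond",
                             "hydrophobic", "entropy", "ca_x", "ca_y", "ca_z"))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$position, c(3, 6, 9))
  for (i in 1:3)
    expect_equal(unlist(tab[i, c("ca_x", "ca_y", "ca_z")], use.names = FALSE),
                 stabmut:::atom_xyz(s, paste("A", tab$position[i], "", sep = "|"), "CA"))
  expect_equal(nrow(feature_table(entries[0, ], s)), 0)
  expect_error(feature_table(rbind(entries, entries[1, ]), s), "duplicate")
})

test_that("mutation tables load from CSV and plain text", {
  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutation,delta_tm", "S121E,3.2", "A17G,1.6"), fc)
  tc <- read_mutation_table(fc)
  expect_equal(tc$mutation, c("S121E", "A17G"))
  expect_equal(tc$delta_tm, c(3.2, 1.6))
  ft <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("S121E 3.2", "A17G 1.6"), ft)
  expect_equal(read_mutation_table(ft), tc)
})
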