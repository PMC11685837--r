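# Independent brute-force oracles and fixture builders used across the suite.
# The oracles deliberately re-derive geometry with plain scalar loops so they
# share no scan logic with the package implementations they cross-check.

oracle_angle <- function(a, b, c) {
  u <- (a - b) / sqrt(sum((a - b)^2))
  v <- (c - b) / sqrt(sum((c - b)^2))
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# O(n^2) donor x acceptor scan using the package's chemistry tables but an
# independent pairwise loop (peptide-unit exclusion and unordered dedup
# re-derived here).
oracle_hbond_count <- function(structure, cutoff = 3.5, min_angle = 90) {
  hp <- stabmut:::hbond_partners(structure)
  a <- structure$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  seen <- character(0)
  count <- 0L
  for (d in seq_len(nrow(hp$donors))) {
    di <- hp$donors[d, 1]; anti <- hp$donors[d, 2]
    for (ai in hp$acceptors) {
      if (a$reskey[di] == a$reskey[ai]) next
      if (a$name[di] == "N" && a$name[ai] == "O" &&
          a$chain[di] == a$chain[ai] &&
          a$resno[di] - a$resno[ai] >= 0 && a$resno[di] - a$resno[ai] <= 1) next
      dist <- sqrt(sum((xyz[di, ] - xyz[ai, ])^2))
      if (dist > cutoff) next
      if (oracle_angle(xyz[anti, ], xyz[di, ], xyz[ai, ]) < min_angle) next
      key <- paste(min(di, ai), max(di, ai))
      if (key %in% seen) next
      seen <- c(seen, key)
      count <- count + 1L
    }
  }
  count
}

# O(n^2) scan over side-chain carbons of hydrophobic residues.
oracle_hydrophobic_count <- function(structure, cutoff = 5.0, min_sep = 2) {
  a <- structure$atoms
  hydro3 <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO", "TYR")
  idx <- which(a$element == "C" & !a$is_backbone & a$resname %in% hydro3)
  count <- 0L
  if (length(idx) < 2) return(count)
  for (i in seq_len(length(idx) - 1)) {
    for (j in (i + 1):length(idx)) {
      ii <- idx[i]; jj <- idx[j]
      if (a$reskey[ii] == a$reskey[jj]) next
      if (a$chain[ii] == a$chain[jj] &&
          abs(a$resno[ii] - a$resno[jj]) < min_sep) next
      dd <- sqrt((a$x[ii] - a$x[jj])^2 + (a$y[ii] - a$y[jj])^2 + (a$z[ii] - a$z[jj])^2)
      if (dd <= cutoff) count <- count + 1L
    }
  }
  count
}

# Mean silhouette width computed from first principles (no cluster pkg).
oracle_silhouette <- function(labels, x) {
  d <- as.matrix(stats::dist(x))
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a_i <- mean(d[i, own])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(l)
      mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Two structures' chains glued into one two-chain structure.
two_chain_fixture <- function(seed = 0) {
  a <- make_toy_pdb(5, "helix", seed = seed, chain = "A")
  b <- make_toy_pdb(4, "helix", seed = seed + 1, chain = "B")
  b$atoms[, c("x", "y", "z")] <- b$atoms[, c("x", "y", "z")] + 30
  cols <- c("name", "element", "x", "y", "z", "resno", "insert", "resname", "chain")
  protein_structure(rbind(a$atoms[, cols], b$atoms[, cols]))
}

# Feature table with two planted blobs separated by `separation` spreads in
# delta_tm and CA space; returns the table and the planted labels.
planted_blob_table <- function(n_per = 6, separation = 6, seed = 0) {
  stabmut:::with_seed(seed, {
    jit <- function(n, sd = 1) stats::rnorm(n, 0, sd)
    shift <- c(rep(0, n_per), rep(separation, n_per))
    tab <- data.frame(
      mutation = paste0("A", seq_len(2 * n_per), "G"),
      position = seq_len(2 * n_per),
      delta_tm = 2 + shift + jit(2 * n_per),
      hbond = 0L, hydrophobic = 0L, entropy = 0L,
      ca_x = shift + jit(2 * n_per),
      ca_y = shift + jit(2 * n_per),
      ca_z = shift + jit(2 * n_per))
    list(table = tab, labels = rep(c(0L, 1L), each = n_per))
  })
}

# Same partition iff the label pairing is a bijection.
partitions_equal <- function(l1, l2) {
  length(unique(paste(l1, l2))) == length(unique(l1)) &&
    length(unique(l1)) == length(unique(l2))
}
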