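# Deterministic toy-structure generator: ideal-geometry backbones (helix,
# strand, or a smooth seeded coil) decorated with template side chains.
# These structures exercise every geometric code path (H-bond detection,
# contact counting, mutant building) without any external structure files.

#' Generate a toy protein structure
#'
#' Builds an ideal-geometry single-chain backbone and adds template side
#' chains. Helix geometry uses a rise of 1.5 Angstrom and 100 degrees of turn
#' per residue about the axis (radius 2.28 Angstrom), giving consecutive
#' CA-CA distances near 3.8 Angstrom; strands use 3.3 Angstrom rise and 180
#' degrees per residue; coils follow a smooth seeded random curve with 3.8
#' Angstrom CA steps.
#'
#' @param n_residues number of residues (>= 2).
#' @param geometry `"helix"` (default), `"strand"`, or `"coil"`.
#' @param sequence 1-letter sequence of length `n_residues`, or `NULL` for a
#'   random sequence drawn under `seed`.
#' @param seed integer seed controlling the random sequence and coil path.
#' @param chain chain identifier (default `"A"`).
#' @return a validated [protein_structure()]; serialize with [write_pdb()].
#' @examples
#' s <- make_toy_pdb(5, "helix", "AAAAA", seed = 0)
#' get_sequence(s)
#' @export
make_toy_pdb <- function(n_residues, geometry = c("helix", "strand", "coil"),
                         sequence = NULL, seed = 0, chain = "A") {
  geometry <- match.arg(geometry)
  if (!is_count(n_residues) || n_residues < 2)
    stopf("n_residues must be an integer >= 2")
  if (is.null(sequence)) {
    sequence <- with_seed(seed, paste(sample(AA1, n_residues, replace = TRUE),
                                      collapse = ""))
  }
  aa <- strsplit(sequence, "")[[1]]
  if (length(aa) != n_residues)
    stopf("sequence length (%d) does not match n_residues (%d)",
          length(aa), n_residues)
  if (!all(aa %in% AA1))
    stopf("sequence contains non-standard residue letter(s)")

  ca <- switch(geometry,
    helix = {
      i <- seq_len(n_residues) - 1
      theta <- i * 100 * pi / 180
      cbind(2.28 * cos(theta), 2.28 * sin(theta), 1.5 * i)
    },
    strand = {
      i <- seq_len(n_residues) - 1
      theta <- i * pi
      cbind(0.95 * cos(theta), 0.95 * sin(theta), 3.3 * i)
    },
    coil = with_seed(seed + 1L, {
      pos <- matrix(0, n_residues, 3)
      dir <- c(1, 0, 0)
      for (i in 2:n_residues) {
        bend <- unitv(dir + stats::rnorm(3, sd = 0.35))
        dir <- bend
        pos[i, ] <- pos[i - 1, ] + 3.8 * dir
      }
      pos
    })
  )

  atoms <- NULL
  for (i in seq_len(n_residues)) {
    prev_ca <- if (i > 1) ca[i - 1, ] else 2 * ca[i, ] - ca[i + 1, ]
    next_ca <- if (i < n_residues) ca[i + 1, ] else 2 * ca[i, ] - ca[i - 1, ]
    e1 <- unitv(next_ca - prev_ca)
    curv <- prev_ca + next_ca - 2 * ca[i, ]
    curv <- curv - sum(curv * e1) * e1
    e2 <- if (vnorm(curv) > 1e-6) unitv(curv) else {
      ref <- if (abs(e1[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      unitv(ref - sum(ref * e1) * e1)
    }
    # N and C flank CA symmetrically in the (e1, e2) plane at a 111 deg angle
    n_xyz <- ca[i, ] + 1.45 * (-cos(34.5 * pi / 180) * e1 + sin(34.5 * pi / 180) * e2)
    c_xyz <- ca[i, ] + 1.52 * (cos(34.5 * pi / 180) * e1 + sin(34.5 * pi / 180) * e2)
    o_xyz <- place_atom(n_xyz, ca[i, ], c_xyz, 1.23, 120.5, -35)
    res <- data.frame(name = c("N", "CA", "C", "O"),
                      x = c(n_xyz[1], ca[i, 1], c_xyz[1], o_xyz[1]),
                      y = c(n_xyz[2], ca[i, 2], c_xyz[2], o_xyz[2]),
                      z = c(n_xyz[3], ca[i, 3], c_xyz[3], o_xyz[3]))
    sc <- template_side_chain(n_xyz, ca[i, ], c_xyz, AA3[[aa[i]]])
    if (!is.null(sc)) res <- rbind(res, sc[, c("name", "x", "y", "z")])
    res$resno <- i
    res$resname <- AA3[[aa[i]]]
    res$chain <- chain
    atoms <- rbind(atoms, res)
  }
  protein_structure(atoms)
}
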