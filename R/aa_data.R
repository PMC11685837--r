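# Amino-acid chemistry tables used by mutant building and feature extraction.
# Side-chain templates are internal-coordinate ("Z-matrix") definitions of the
# most common rotamer; each atom is placed by torsion geometry from three
# previously placed atoms (reference frame ref1-ref2-ref3, with ref3 the
# bonded parent).

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")

AA321 <- stats::setNames(names(AA3), AA3)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Hydrophobic residue set for contact counting.
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "M", "F", "W", "P", "Y")

rt <- function(atom, ref1, ref2, ref3, bond, angle, torsion) {
  data.frame(atom = atom, ref1 = ref1, ref2 = ref2, ref3 = ref3,
             bond = bond, angle = angle, torsion = torsion,
             stringsAsFactors = FALSE)
}

# Per-residue side-chain rows beyond CB; CB itself is placed identically for
# every non-Gly residue (improper N-C-CA-CB at -122.6 deg).
SIDECHAIN_TOPOLOGY <- list(
  GLY = NULL,
  ALA = NULL,
  SER = rt("OG", "N", "CA", "CB", 1.42, 110.8, -65),
  CYS = rt("SG", "N", "CA", "CB", 1.81, 113.8, -65),
  THR = rbind(rt("OG1", "N", "CA", "CB", 1.43, 109.6, -60),
              rt("CG2", "N", "CA", "CB", 1.52, 110.5, 60)),
  VAL = rbind(rt("CG1", "N", "CA", "CB", 1.52, 110.5, 175),
              rt("CG2", "N", "CA", "CB", 1.52, 110.5, 55)),
  ILE = rbind(rt("CG1", "N", "CA", "CB", 1.53, 110.4, -65),
              rt("CG2", "N", "CA", "CB", 1.53, 110.5, 55),
              rt("CD1", "CA", "CB", "CG1", 1.51, 113.9, 170)),
  LEU = rbind(rt("CG", "N", "CA", "CB", 1.53, 116.3, -65),
              rt("CD1", "CA", "CB", "CG", 1.52, 110.5, 175),
              rt("CD2", "CA", "CB", "CG", 1.52, 110.5, 55)),
  MET = rbind(rt("CG", "N", "CA", "CB", 1.52, 114.1, -65),
              rt("SD", "CA", "CB", "CG", 1.81, 112.7, -65),
              rt("CE", "CB", "CG", "SD", 1.79, 100.8, -70)),
  PHE = rbind(rt("CG", "N", "CA", "CB", 1.50, 113.8, -65),
              rt("CD1", "CA", "CB", "CG", 1.39, 120.8, -85),
              rt("CD2", "CA", "CB", "CG", 1.39, 120.8, 95),
              rt("CE1", "CB", "CG", "CD1", 1.39, 120.8, 180),
              rt("CE2", "CB", "CG", "CD2", 1.39, 120.8, 180),
              rt("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = rbind(rt("CG", "N", "CA", "CB", 1.51, 113.8, -65),
              rt("CD1", "CA", "CB", "CG", 1.39, 120.8, -85),
              rt("CD2", "CA", "CB", "CG", 1.39, 120.8, 95),
              rt("CE1", "CB", "CG", "CD1", 1.39, 120.8, 180),
              rt("CE2", "CB", "CG", "CD2", 1.39, 120.8, 180),
              rt("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0),
              rt("OH", "CD1", "CE1", "CZ", 1.38, 119.9, 180)),
  TRP = rbind(rt("CG", "N", "CA", "CB", 1.50, 113.6, -65),
              rt("CD1", "CA", "CB", "CG", 1.37, 127.0, -90),
              rt("CD2", "CA", "CB", "CG", 1.43, 126.6, 90),
              rt("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180),
              rt("CE2", "CB", "CG", "CD2", 1.41, 107.2, 180),
              rt("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
              rt("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180),
              rt("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 180),
              rt("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0)),
  ASP = rbind(rt("CG", "N", "CA", "CB", 1.52, 113.1, -65),
              rt("OD1", "CA", "CB", "CG", 1.25, 119.2, -15),
              rt("OD2", "CA", "CB", "CG", 1.25, 118.2, 165)),
  ASN = rbind(rt("CG", "N", "CA", "CB", 1.52, 112.7, -65),
              rt("OD1", "CA", "CB", "CG", 1.23, 120.8, -65),
              rt("ND2", "CA", "CB", "CG", 1.33, 116.5, 115)),
  GLU = rbind(rt("CG", "N", "CA", "CB", 1.52, 114.1, -65),
              rt("CD", "CA", "CB", "CG", 1.52, 114.2, 180),
              rt("OE1", "CB", "CG", "CD", 1.25, 119.0, -10),
              rt("OE2", "CB", "CG", "CD", 1.25, 118.2, 170)),
  GLN = rbind(rt("CG", "N", "CA", "CB", 1.52, 114.1, -65),
              rt("CD", "CA", "CB", "CG", 1.52, 112.7, 180),
              rt("OE1", "CB", "CG", "CD", 1.23, 120.8, -60),
              rt("NE2", "CB", "CG", "CD", 1.33, 116.5, 120)),
  LYS = rbind(rt("CG", "N", "CA", "CB", 1.52, 114.1, -65),
              rt("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
              rt("CE", "CB", "CG", "CD", 1.52, 111.3, 180),
              rt("NZ", "CG", "CD", "CE", 1.49, 111.9, 180)),
  ARG = rbind(rt("CG", "N", "CA", "CB", 1.52, 114.1, -65),
              rt("CD", "CA", "CB", "CG", 1.52, 111.3, 180),
              rt("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
              rt("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
              rt("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
              rt("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = rbind(rt("CG", "N", "CA", "CB", 1.49, 113.8, -65),
              rt("ND1", "CA", "CB", "CG", 1.38, 122.7, -75),
              rt("CD2", "CA", "CB", "CG", 1.35, 131.0, 105),
              rt("CE1", "CB", "CG", "ND1", 1.32, 109.0, 180),
              rt("NE2", "CB", "CG", "CD2", 1.37, 107.0, 180)),
  PRO = rbind(rt("CG", "N", "CA", "CB", 1.50, 104.5, -26),
              rt("CD", "CA", "CB", "CG", 1.50, 106.1, 35))
)

# Hydrogen-bond chemistry: heavy-atom N/O donors with their bonded antecedent
# (used for the hydrogen-free angle criterion) and N/O acceptors. Backbone N
# is a donor for every residue except proline; backbone O always accepts.
SIDECHAIN_DONORS <- list(
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"), LYS = c(NZ = "CE"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CE1"), TRP = c(NE1 = "CE2")
)

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

element_of <- function(atom_name) substr(atom_name, 1, 1)
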