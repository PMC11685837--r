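# The protein_structure container: a validated heavy-atom model of one or
# more protein chains, stored as an atom table (one row per atom) in file
# order. Residue identity is (chain, author residue number, insertion code).

#' Construct a protein structure from an atom table
#'
#' The canonical container for all geometry in the package. Atoms are stored
#' in a data frame, one row per heavy atom, grouped contiguously by residue in
#' chain order; residue identity is the triplet (chain, author residue number,
#' insertion code) so that mutation names match the numbering users see in
#' their PDB files.
#'
#' @param atoms data frame with columns `name` (PDB atom name), `x`, `y`, `z`
#'   (Angstrom), `resno` (author numbering), `resname` (3-letter code),
#'   `chain`; optional `insert` (defaults to `""`) and `element` (derived from
#'   the atom name when absent).
#' @param validate if `TRUE` (default) enforce the structural invariants:
#'   standard residues only, exactly one CA per residue, strictly increasing
#'   residue numbers within each chain.
#' @return an object of class `protein_structure` with element `atoms` (the
#'   completed atom table, including derived `element`, `is_backbone`, and
#'   `reskey` columns).
#' @seealso [read_pdb()], [make_toy_pdb()], [get_sequence()]
#' @export
protein_structure <- function(atoms, validate = TRUE) {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "x", "y", "z", "resno", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0)
    stopf("atom table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (!"element" %in% names(atoms)) atoms$element <- element_of(atoms$name)
  atoms$is_backbone <- atoms$name %in% BACKBONE_ATOMS
  atoms$reskey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  atoms <- atoms[, c("name", "element", "x", "y", "z", "resno", "insert",
                     "resname", "chain", "is_backbone", "reskey")]
  rownames(atoms) <- NULL
  obj <- structure(list(atoms = atoms), class = "protein_structure")
  if (validate) validate_structure(obj)
  obj
}

#' @export
is_protein_structure <- function(x) inherits(x, "protein_structure")

validate_structure <- function(structure) {
  atoms <- structure$atoms
  if (nrow(atoms) == 0) stopf("structure contains no atoms")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stopf("non-finite atom coordinates")
  bad_res <- setdiff(unique(atoms$resname), names(AA321))
  if (length(bad_res) > 0)
    stopf("non-standard residue name(s): %s", paste(bad_res, collapse = ", "))
  rt <- residue_table(structure)
  n_ca <- vapply(split(atoms$name, factor(atoms$reskey, levels = rt$reskey)),
                 function(nm) sum(nm == "CA"), integer(1))
  if (any(n_ca != 1)) {
    bad <- rt$reskey[n_ca != 1][1]
    row <- rt[rt$reskey == bad, ]
    stopf("residue %s:%s%s (%s) has %d CA atoms (expected exactly 1)",
          row$chain, row$resno, row$insert, row$resname, n_ca[[bad]])
  }
  for (ch in unique(rt$chain)) {
    sub <- rt[rt$chain == ch, ]
    # insertion codes sort after the bare number at the same resno ("" < "A")
    ord <- order(sub$resno, sub$insert)
    if (is.unsorted(ord, strictly = TRUE) ||
        anyDuplicated(paste(sub$resno, sub$insert)))
      stopf("residue numbering in chain %s is not strictly increasing", ch)
  }
  invisible(structure)
}

#' Residue-level summary of a structure
#'
#' @param structure a [protein_structure()].
#' @return data frame with one row per residue in structure order: `chain`,
#'   `resno`, `insert`, `resname`, `aa` (1-letter), and `reskey`.
#' @export
residue_table <- function(structure) {
  atoms <- structure$atoms
  first <- !duplicated(atoms$reskey)
  out <- atoms[first, c("chain", "resno", "insert", "resname", "reskey")]
  out$aa <- unname(AA321[out$resname])
  rownames(out) <- NULL
  out
}

#' Chain identifiers present in a structure
#' @param structure a [protein_structure()].
#' @return character vector of chain IDs in order of appearance.
#' @export
chain_ids <- function(structure) unique(structure$atoms$chain)

#' One-letter sequence of a chain
#'
#' @param structure a [protein_structure()].
#' @param chain chain identifier; defaults to the first chain.
#' @return single string of 1-letter residue codes in residue order.
#' @export
get_sequence <- function(structure, chain = chain_ids(structure)[1]) {
  rt <- residue_table(structure)
  paste(rt$aa[rt$chain == chain], collapse = "")
}

#' Restrict a structure to one chain
#'
#' Keeps only the atoms of the requested chain; residue numbering is left
#' untouched so downstream mutation names remain in the author numbering.
#'
#' @param structure a [protein_structure()].
#' @param chain_id single chain identifier.
#' @return a [protein_structure()] containing only that chain.
#' @export
select_chain <- function(structure, chain_id) {
  stopifnot(is_protein_structure(structure))
  avail <- chain_ids(structure)
  if (!chain_id %in% avail)
    stopf("chain \"%s\" not present; available chains: %s",
          chain_id, paste(avail, collapse = ", "))
  protein_structure(structure$atoms[structure$atoms$chain == chain_id,
                                    setdiff(names(structure$atoms),
                                            c("is_backbone", "reskey"))])
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat(sprintf("<protein_structure> %d atoms, %d residues, chain(s) %s\n",
              nrow(x$atoms), nrow(rt), paste(chain_ids(x), collapse = ",")))
  for (ch in chain_ids(x))
    cat(sprintf("  %s: %s\n", ch, get_sequence(x, ch)))
  invisible(x)
}

# Coordinates of one named atom of one residue (or NULL when absent).
atom_xyz <- function(structure, reskey, name) {
  a <- structure$atoms
  i <- which(a$reskey == reskey & a$name == name)
  if (length(i) == 0) return(NULL)
  as.numeric(a[i[1], c("x", "y", "z")])
}
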