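# Single-point mutations: parsing/formatting of canonical names (e.g. S121E),
# saturation enumeration, and naive template-based mutant model building.

#' Define a single-point mutation
#'
#' @param wt_aa wild-type residue, 1-letter code.
#' @param position author residue number (as in the PDB file).
#' @param mut_aa mutant residue, 1-letter code; must differ from `wt_aa`.
#' @param chain chain identifier (default `"A"`).
#' @param insert insertion code (default `""`).
#' @return an object of class `mutation`. Its canonical name renders as
#'   `<wt><position><mut>`, e.g. `"S121E"`.
#' @export
mutation <- function(wt_aa, position, mut_aa, chain = "A", insert = "") {
  wt_aa <- toupper(wt_aa); mut_aa <- toupper(mut_aa)
  if (!wt_aa %in% AA1) stopf("unknown wild-type residue \"%s\"", wt_aa)
  if (!mut_aa %in% AA1) stopf("unknown mutant residue \"%s\"", mut_aa)
  if (wt_aa == mut_aa)
    stopf("mutation must change the residue (got %s -> %s at %s)",
          wt_aa, mut_aa, position)
  structure(list(chain = chain, wt_aa = wt_aa, position = as.integer(position),
                 insert = insert, mut_aa = mut_aa),
            class = "mutation")
}

#' Parse a canonical mutation name
#'
#' @param name string like `"S121E"` or `"S121AE"` (trailing letter after the
#'   number block is the mutant; an insertion code letter may follow the
#'   number, e.g. `"S121aE"` uses lowercase for the insertion code).
#' @param chain chain identifier to attach (default `"A"`).
#' @return a [mutation()].
#' @export
parse_mutation <- function(name, chain = "A") {
  m <- regmatches(name, regexec("^([A-Z])([0-9]+)([a-z]?)([A-Z])$", name))[[1]]
  if (length(m) == 0) stopf("cannot parse mutation name \"%s\"", name)
  mutation(m[2], as.integer(m[3]), m[5], chain = chain, insert = toupper(m[4]))
}

#' @export
format.mutation <- function(x, ...) {
  paste0(x$wt_aa, x$position, tolower(x$insert), x$mut_aa)
}

#' @export
print.mutation <- function(x, ...) {
  cat(sprintf("<mutation> %s (chain %s)\n", format(x), x$chain))
  invisible(x)
}

#' Enumerate all candidate single-point mutations of a chain
#'
#' Saturation scan: every residue of the chain is substituted by each of the
#' other 19 amino acids, ordered by position and then alphabetically by mutant
#' residue.
#'
#' @param structure a [protein_structure()].
#' @param chain_id chain to scan (default: first chain).
#' @param exclude_positions residue numbers to skip (e.g. catalytic residues).
#' @return list of [mutation()] objects, `19 * (n_residues - n_excluded)` long.
#' @export
enumerate_candidate_mutations <- function(structure,
                                          chain_id = chain_ids(structure)[1],
                                          exclude_positions = integer(0)) {
  if (!chain_id %in% chain_ids(structure))
    stopf("chain \"%s\" not present; available chains: %s",
          chain_id, paste(chain_ids(structure), collapse = ", "))
  rt <- residue_table(structure)
  rt <- rt[rt$chain == chain_id & !(rt$resno %in% exclude_positions), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rt))) {
    wt <- rt$aa[i]
    for (mut in sort(setdiff(AA1, wt)))
      out[[length(out) + 1]] <- mutation(wt, rt$resno[i], mut,
                                         chain = chain_id, insert = rt$insert[i])
  }
  out
}

# Build side-chain atoms for a residue from its backbone N/CA/C and the
# internal-coordinate template of the target residue type.
template_side_chain <- function(n, ca, c_at, resname) {
  if (resname == "GLY") return(NULL)
  coords <- list(N = n, CA = ca, C = c_at)
  rows <- rt("CB", "N", "C", "CA", 1.53, 110.6, -122.6)
  extra <- SIDECHAIN_TOPOLOGY[[resname]]
  if (!is.null(extra)) rows <- rbind(rows, extra)
  out <- data.frame(name = rows$atom, x = NA_real_, y = NA_real_, z = NA_real_)
  for (i in seq_len(nrow(rows))) {
    p <- place_atom(coords[[rows$ref1[i]]], coords[[rows$ref2[i]]],
                    coords[[rows$ref3[i]]],
                    rows$bond[i], rows$angle[i], rows$torsion[i])
    coords[[rows$atom[i]]] <- p
    out[i, c("x", "y", "z")] <- p
  }
  out$element <- element_of(out$name)
  out
}

#' Build a naive mutant model
#'
#' Replaces the side chain of the mutated residue by an idealized template of
#' the mutant residue (most common rotamer, constructed by internal
#' coordinates off the actual N-CA-C backbone frame). Backbone atoms of the
#' mutated residue and all other residues are untouched; no repacking or
#' minimization is done. The result is a deterministic, testable stand-in for
#' an external mutant-model builder.
#'
#' @param structure wild-type [protein_structure()].
#' @param mut a [mutation()]; its `wt_aa` must match the structure.
#' @return the mutant [protein_structure()].
#' @export
build_mutant <- function(structure, mut) {
  stopifnot(is_protein_structure(structure), inherits(mut, "mutation"))
  rt_ <- residue_table(structure)
  key <- paste(mut$chain, mut$position, mut$insert, sep = "|")
  row <- rt_[rt_$reskey == key, , drop = FALSE]
  if (nrow(row) == 0)
    stopf("no residue at %s%s in chain %s", mut$position, mut$insert, mut$chain)
  if (row$aa != mut$wt_aa)
    stopf("wild-type mismatch at %s: expected %s, found %s",
          mut$position, mut$wt_aa, row$aa)
  atoms <- structure$atoms
  res_idx <- which(atoms$reskey == key)
  bb <- atoms[res_idx, ][atoms$name[res_idx] %in% BACKBONE_ATOMS, , drop = FALSE]
  need <- c("N", "CA", "C")
  if (!all(need %in% bb$name))
    stopf("residue %s lacks backbone atoms needed for mutant building", key)
  get_bb <- function(nm) as.numeric(bb[bb$name == nm, c("x", "y", "z")][1, ])
  sc <- template_side_chain(get_bb("N"), get_bb("CA"), get_bb("C"),
                            AA3[[mut$mut_aa]])
  new_res <- bb[, c("name", "element", "x", "y", "z", "resno", "insert",
                    "resname", "chain")]
  if (!is.null(sc)) {
    sc$resno <- mut$position; sc$insert <- mut$insert
    sc$resname <- AA3[[mut$mut_aa]]; sc$chain <- mut$chain
    new_res <- rbind(new_res, sc[, names(new_res)])
  }
  new_res$resname <- AA3[[mut$mut_aa]]
  before <- atoms[seq_len(min(res_idx) - 1),
                  c("name", "element", "x", "y", "z", "resno", "insert",
                    "resname", "chain"), drop = FALSE]
  after_idx <- seq_len(nrow(atoms)) > max(res_idx)
  after <- atoms[after_idx, c("name", "element", "x", "y", "z", "resno",
                              "insert", "resname", "chain"), drop = FALSE]
  protein_structure(rbind(before, new_res, after))
}
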