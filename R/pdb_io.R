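# PDB reading/writing, delegating the format itself to bio3d.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records into a validated [protein_structure()]. The model is
#' reduced to what the geometric features are defined on: heavy atoms of
#' standard amino acids. HETATM records (waters, ligands), hydrogens and
#' deuteriums, and non-primary alternate locations are dropped; residues with
#' non-standard names are dropped with a warning; insertion codes are kept as
#' part of residue identity. Multi-model (NMR) files use the first model.
#'
#' @param path path to a PDB file.
#' @param model_policy `"first"` (default) silently takes the first MODEL of a
#'   multi-model file; `"error"` refuses multi-model input.
#' @return a validated [protein_structure()].
#' @export
read_pdb <- function(path, model_policy = c("first", "error")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  if (model_policy == "error") {
    n_models <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
    if (n_models > 1) stopf("multi-model PDB refused (model_policy = \"error\"): %s", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                          verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stopf("no parsable ATOM records in %s", path)
  elem <- at$elesy
  no_elem <- is.na(elem) | trimws(elem) == ""
  elem[no_elem] <- element_of(sub("^[0-9]*", "", at$elety[no_elem]))
  elem <- trimws(elem)
  keep <- !(toupper(elem) %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  nonstd <- !(at$resid %in% names(AA321))
  if (any(nonstd)) {
    warning(sprintf("dropping %d atom(s) in non-standard residue(s): %s",
                    sum(nonstd),
                    paste(unique(at$resid[nonstd]), collapse = ", ")),
            call. = FALSE)
    at <- at[!nonstd, , drop = FALSE]
    elem <- elem[!nonstd]
  }
  if (nrow(at) == 0) stopf("no standard amino-acid residues in %s", path)
  ins <- at$insert
  ins[is.na(ins)] <- ""
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  protein_structure(data.frame(
    name = at$elety, element = elem,
    x = at$x, y = at$y, z = at$z,
    resno = at$resno, insert = ins, resname = at$resid, chain = chain,
    stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#'
#' Emits ATOM records only, at standard PDB coordinate precision (3 decimals),
#' so that [read_pdb()] round-trips the structure.
#'
#' @param structure a [protein_structure()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(is_protein_structure(structure))
  a <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   eleno = seq_len(nrow(a)), elety = a$name, elesy = a$element,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(path)
}
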