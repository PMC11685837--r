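# Structure-based features of stabilizing mutations: hydrogen-bond and
# hydrophobic-contact changes relative to wild type, a backbone-entropy flag,
# and the wild-type CA coordinates of the mutated residue. Together with the
# measured melting-temperature improvement these form the clustering feature
# vector.

# Donor atoms (with bonded antecedent) and acceptor atoms of a structure.
hbond_partners <- function(structure) {
  a <- structure$atoms
  don <- list(); acc <- integer(0)
  for (key in unique(a$reskey)) {
    idx <- which(a$reskey == key)
    nm <- a$name[idx]
    resname <- a$resname[idx[1]]
    # backbone amide N donates except in proline (no amide hydrogen)
    if (resname != "PRO" && all(c("N", "CA") %in% nm))
      don[[length(don) + 1]] <- c(idx[match("N", nm)], idx[match("CA", nm)])
    sd <- SIDECHAIN_DONORS[[resname]]
    if (!is.null(sd)) {
      for (j in seq_along(sd)) {
        d_i <- match(names(sd)[j], nm); ant_i <- match(sd[[j]], nm)
        if (!is.na(d_i) && !is.na(ant_i))
          don[[length(don) + 1]] <- c(idx[d_i], idx[ant_i])
      }
    }
    acc_names <- c(intersect(c("O", "OXT"), nm), intersect(SIDECHAIN_ACCEPTORS[[resname]], nm))
    acc <- c(acc, idx[match(acc_names, nm)])
  }
  list(donors = if (length(don)) do.call(rbind, don) else matrix(integer(0), 0, 2),
       acceptors = acc)
}

#' Detect hydrogen bonds by heavy-atom geometry
#'
#' A hydrogen-free geometric criterion: a bond is reported for every
#' donor/acceptor heavy-atom pair (N/O donors with their bonded antecedent,
#' N/O acceptors, by residue chemistry) at distance at most `distance_cutoff`
#' whose antecedent-donor-acceptor angle is at least `min_angle`. Pairs within
#' one residue are excluded, as is the backbone amide N with the carbonyl O of
#' the immediately preceding residue (the two belong to the same covalent
#' peptide unit), and each unordered atom pair is reported once.
#'
#' @param structure a validated [protein_structure()] (heavy atoms).
#' @param residue_scope optional character vector of residue keys
#'   (`"chain|resno|insert"`); when given, both partners must belong to it.
#' @param distance_cutoff donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param min_angle minimum antecedent-donor-acceptor angle in degrees
#'   (default 90).
#' @return data frame with one row per bond: donor/acceptor residue keys and
#'   atom names, distance (Angstrom) and angle (degrees).
#' @export
detect_hbonds <- function(structure, residue_scope = NULL,
                          distance_cutoff = 3.5, min_angle = 90) {
  stopifnot(is_protein_structure(structure))
  a <- structure$atoms
  hp <- hbond_partners(structure)
  empty <- data.frame(donor_res = character(0), donor_atom = character(0),
                      acceptor_res = character(0), acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0))
  if (nrow(hp$donors) == 0 || length(hp$acceptors) == 0) return(empty)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  di <- hp$donors[, 1]; ai <- hp$acceptors
  # all donor x acceptor combinations
  grid <- expand.grid(d = seq_along(di), a = seq_along(ai))
  d_at <- di[grid$d]; a_at <- ai[grid$a]; ant_at <- hp$donors[grid$d, 2]
  keep <- a$reskey[d_at] != a$reskey[a_at]
  # same peptide unit: donor backbone N with the preceding residue's carbonyl
  # O (author numbering; insertion-coded residues are conservatively treated
  # as adjacent when their numbers differ by at most one)
  peptide <- a$name[d_at] == "N" & a$name[a_at] == "O" &
    a$chain[d_at] == a$chain[a_at] &
    a$resno[d_at] - a$resno[a_at] <= 1 & a$resno[d_at] - a$resno[a_at] >= 0 &
    a$reskey[d_at] != a$reskey[a_at]
  keep <- keep & !peptide
  if (!is.null(residue_scope))
    keep <- keep & a$reskey[d_at] %in% residue_scope & a$reskey[a_at] %in% residue_scope
  d_at <- d_at[keep]; a_at <- a_at[keep]; ant_at <- ant_at[keep]
  if (length(d_at) == 0) return(empty)
  dv <- xyz[a_at, , drop = FALSE] - xyz[d_at, , drop = FALSE]
  dist <- sqrt(rowSums(dv^2))
  ok <- dist <= distance_cutoff
  d_at <- d_at[ok]; a_at <- a_at[ok]; ant_at <- ant_at[ok]; dist <- dist[ok]
  if (length(d_at) == 0) return(empty)
  u <- xyz[ant_at, , drop = FALSE] - xyz[d_at, , drop = FALSE]
  v <- xyz[a_at, , drop = FALSE] - xyz[d_at, , drop = FALSE]
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ok <- ang >= min_angle
  d_at <- d_at[ok]; a_at <- a_at[ok]; dist <- dist[ok]; ang <- ang[ok]
  if (length(d_at) == 0) return(empty)
  pair_id <- paste(pmin(d_at, a_at), pmax(d_at, a_at))
  first <- !duplicated(pair_id)
  d_at <- d_at[first]; a_at <- a_at[first]; dist <- dist[first]; ang <- ang[first]
  data.frame(donor_res = a$reskey[d_at], donor_atom = a$name[d_at],
             acceptor_res = a$reskey[a_at], acceptor_atom = a$name[a_at],
             distance = dist, angle = ang)
}

#' Count hydrophobic side-chain contacts
#'
#' Counts side-chain carbon atom pairs at most `distance_cutoff` apart between
#' residues of the hydrophobic set (A, V, L, I, M, F, W, P, Y) separated by at
#' least `min_separation` positions in sequence (inter-chain pairs always
#' qualify). Each atom pair is counted once.
#'
#' @inheritParams detect_hbonds
#' @param distance_cutoff carbon-carbon distance cutoff in Angstrom
#'   (default 5.0).
#' @param min_separation minimum sequence separation between the two residues
#'   (default 2).
#' @return integer contact count.
#' @export
count_hydrophobic_contacts <- function(structure, residue_scope = NULL,
                                       distance_cutoff = 5.0,
                                       min_separation = 2) {
  stopifnot(is_protein_structure(structure))
  a <- structure$atoms
  idx <- which(a$element == "C" & !a$is_backbone &
                 a$resname %in% unname(AA3[HYDROPHOBIC_SET]))
  if (!is.null(residue_scope)) idx <- idx[a$reskey[idx] %in% residue_scope]
  if (length(idx) < 2) return(0L)
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  key <- a$reskey[idx]
  ch <- a$chain[idx]
  pos <- a$resno[idx]
  n <- length(idx)
  count <- 0L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    sep_ok <- ch[j] != ch[i] | abs(pos[j] - pos[i]) >= min_separation
    count <- count + sum(dmat[i, j] <= distance_cutoff & key[j] != key[i] & sep_ok)
  }
  as.integer(count)
}

#' Backbone-entropy flag of a substitution
#'
#' Returns 1 when the substitution involves glycine or proline on either side
#' (the canonical backbone-conformational-entropy effects in stabilization
#' engineering: removing/introducing the flexible Gly or the rigid Pro), else
#' 0.
#'
#' @param mut a [mutation()] or canonical mutation name string.
#' @return integer 0 or 1.
#' @export
entropy_flag <- function(mut) {
  if (is.character(mut)) mut <- parse_mutation(mut)
  as.integer(mut$wt_aa %in% c("G", "P") || mut$mut_aa %in% c("G", "P"))
}

# Residue keys with any atom within `radius` of any atom of residue `reskey`.
environment_scope <- function(structure, reskey, radius = 8.0) {
  a <- structure$atoms
  ref <- as.matrix(a[a$reskey == reskey, c("x", "y", "z")])
  if (nrow(ref) == 0) stopf("no residue with key %s", reskey)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  near <- rep(FALSE, nrow(xyz))
  for (r in seq_len(nrow(ref)))
    near <- near | rowSums(sweep(xyz, 2, ref[r, ])^2) <= radius^2
  unique(a$reskey[near])
}

#' Compute the feature vector of one stabilizing mutation
#'
#' Hydrogen-bond and hydrophobic-contact changes are computed as mutant count
#' minus wild-type count, restricted to the local environment of the mutated
#' residue (every residue with an atom within `env_radius` of it), so distant
#' structural noise cannot contaminate the local feature. The CA coordinates
#' are taken from the wild-type structure.
#'
#' @param wt wild-type [protein_structure()].
#' @param mut a [mutation()] or canonical name string.
#' @param delta_tm measured melting-temperature improvement (degrees C).
#' @param mutant optional mutant [protein_structure()]; built with
#'   [build_mutant()] when omitted.
#' @param env_radius local-environment radius in Angstrom (default 8.0).
#' @param hbond_cutoff,hbond_min_angle,hydrophobic_cutoff geometric criteria
#'   passed to [detect_hbonds()] and [count_hydrophobic_contacts()].
#' @return one-row data frame with columns `mutation`, `position`, `delta_tm`,
#'   `hbond`, `hydrophobic`, `entropy`, `ca_x`, `ca_y`, `ca_z`.
#' @export
compute_features <- function(wt, mut, delta_tm, mutant = NULL,
                             env_radius = 8.0, hbond_cutoff = 3.5,
                             hbond_min_angle = 90, hydrophobic_cutoff = 5.0) {
  if (is.character(mut)) mut <- parse_mutation(mut, chain = chain_ids(wt)[1])
  stopifnot(is.numeric(delta_tm), length(delta_tm) == 1)
  key <- paste(mut$chain, mut$position, mut$insert, sep = "|")
  ca <- atom_xyz(wt, key, "CA")
  if (is.null(ca)) stopf("no residue at position %s in chain %s", mut$position, mut$chain)
  if (is.null(mutant)) mutant <- build_mutant(wt, mut)
  local_counts <- function(s) {
    scope <- environment_scope(s, key, env_radius)
    c(hb = nrow(detect_hbonds(s, residue_scope = scope,
                              distance_cutoff = hbond_cutoff,
                              min_angle = hbond_min_angle)),
      ph = count_hydrophobic_contacts(s, residue_scope = scope,
                                      distance_cutoff = hydrophobic_cutoff))
  }
  wt_c <- local_counts(wt)
  mu_c <- local_counts(mutant)
  data.frame(mutation = format(mut), position = mut$position,
             delta_tm = delta_tm,
             hbond = as.integer(mu_c["hb"] - wt_c["hb"]),
             hydrophobic = as.integer(mu_c["ph"] - wt_c["ph"]),
             entropy = entropy_flag(mut),
             ca_x = ca[1], ca_y = ca[2], ca_z = ca[3])
}

#' Feature table for a set of validated stabilizing mutations
#'
#' One row per mutation, in the nine-column layout consumed by the clustering
#' stage: mutation name, residue index, melting-temperature improvement,
#' hydrogen-bond change, hydrophobic-contact change, entropy flag, and the
#' wild-type CA coordinates.
#'
#' @param entries data frame with columns `mutation` (canonical names) and
#'   `delta_tm` (degrees C), e.g. from [read_mutation_table()].
#' @param wt wild-type [protein_structure()].
#' @param ... further arguments passed to [compute_features()].
#' @return data frame with columns `mutation`, `position`, `delta_tm`,
#'   `hbond`, `hydrophobic`, `entropy`, `ca_x`, `ca_y`, `ca_z`.
#' @export
feature_table <- function(entries, wt, ...) {
  stopifnot(is.data.frame(entries), all(c("mutation", "delta_tm") %in% names(entries)))
  if (anyDuplicated(entries$mutation))
    stopf("duplicate mutation name(s): %s",
          paste(unique(entries$mutation[duplicated(entries$mutation)]), collapse = ", "))
  if (nrow(entries) == 0)
    return(data.frame(mutation = character(0), position = integer(0),
                      delta_tm = numeric(0), hbond = integer(0),
                      hydrophobic = integer(0), entropy = integer(0),
                      ca_x = numeric(0), ca_y = numeric(0), ca_z = numeric(0)))
  rows <- lapply(seq_len(nrow(entries)), function(i)
    compute_features(wt, entries$mutation[i], entries$delta_tm[i], ...))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a mutation/delta-Tm table
#'
#' Accepts either CSV with a header containing `mutation` (and optionally
#' `delta_tm`), or plain whitespace-separated text with one mutation per line
#' (optionally followed by its delta-Tm value).
#'
#' @param path path to a `.csv` or `.txt` file.
#' @return data frame with columns `mutation` and (when present) `delta_tm`.
#' @export
read_mutation_table <- function(path) {
  if (!file.exists(path)) stopf("mutation table not found: %s", path)
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl(",", first)) {
    out <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"mutation" %in% names(out))
      stopf("CSV mutation table needs a 'mutation' column: %s", path)
  } else {
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    names(raw)[1] <- "mutation"
    if (ncol(raw) >= 2) names(raw)[2] <- "delta_tm"
    out <- raw
  }
  out
}
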