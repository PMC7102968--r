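# Nucleic-acid geometry annotation: backbone torsions, glycosidic
# syn/anti classes, base-pair detection with Leontis-Westhof
# edge/orientation classification, stacking runs with flipped-out base
# flags, and categorical helix-form calls from mean rise/twist.

.PURINES <- c("A", "G", "DA", "DG")

.glyc_atoms <- function(resid) {
  if (resid %in% .PURINES) c("N9", "C4") else c("N1", "C2")
}

# Ordered nucleotide list of one chain (author numbering).
.chain_nucleotides <- function(model, chain) {
  at <- model$atoms
  at <- at[at$chain == chain & at$kind == "nucleotide", , drop = FALSE]
  if (nrow(at) == 0) stop("chain ", chain, " contains no nucleotides")
  res <- unique(at[, c("chain", "resno", "insert", "resid")])
  res[order(res$resno, res$insert), , drop = FALSE]
}

#' Backbone and glycosidic torsions of a nucleic-acid chain
#'
#' Standard signed dihedrals: alpha O3'(i-1)-P-O5'-C5', beta
#' P-O5'-C5'-C4', gamma O5'-C5'-C4'-C3', delta C5'-C4'-C3'-O3',
#' epsilon C4'-C3'-O3'-P(i+1), zeta C3'-O3'-P(i+1)-O5'(i+1), chi
#' O4'-C1'-N9-C4 (purines) / O4'-C1'-N1-C2 (pyrimidines).  A torsion
#' needing atoms of a neighboring nucleotide is `NA` (undefined) when
#' that neighbor is not modeled at the sequential residue number.
#'
#' @param model A `structure_model`.
#' @param chain Nucleic-acid chain identifier.
#' @return Data frame, one row per nucleotide: `resno`, `resid`,
#'   `alpha` ... `zeta`, `chi`, `glycosidic` (`"anti"`/`"syn"`;
#'   boundary at chi = +/-90 deg, syn inside).
#' @export
backbone_torsions <- function(model, chain) {
  res <- .chain_nucleotides(model, chain)
  n <- nrow(res)
  ra <- lapply(seq_len(n), function(i)
    residue_atoms(model, res$chain[i], res$resno[i], res$insert[i]))
  tor <- function(points) {
    if (any(vapply(points, is.null, logical(1)))) return(NA_real_)
    dihedral_angle(points[[1]], points[[2]], points[[3]], points[[4]])
  }
  out <- res[, c("resno", "resid")]
  out$alpha <- out$beta <- out$gamma <- out$delta <- out$epsilon <-
    out$zeta <- out$chi <- NA_real_
  for (i in seq_len(n)) {
    prev <- if (i > 1 && res$resno[i - 1] == res$resno[i] - 1) ra[[i - 1]]
    nxt <- if (i < n && res$resno[i + 1] == res$resno[i] + 1) ra[[i + 1]]
    cur <- ra[[i]]
    P <- atom_xyz(cur, "P"); O5 <- atom_xyz(cur, "O5'")
    C5 <- atom_xyz(cur, "C5'"); C4 <- atom_xyz(cur, "C4'")
    C3 <- atom_xyz(cur, "C3'"); O3 <- atom_xyz(cur, "O3'")
    if (!is.null(prev))
      out$alpha[i] <- tor(list(atom_xyz(prev, "O3'"), P, O5, C5))
    out$beta[i] <- tor(list(P, O5, C5, C4))
    out$gamma[i] <- tor(list(O5, C5, C4, C3))
    out$delta[i] <- tor(list(C5, C4, C3, O3))
    if (!is.null(nxt)) {
      Pn <- atom_xyz(nxt, "P"); O5n <- atom_xyz(nxt, "O5'")
      out$epsilon[i] <- tor(list(C4, C3, O3, Pn))
      out$zeta[i] <- tor(list(C3, O3, Pn, O5n))
    }
    g <- .glyc_atoms(res$resid[i])
    out$chi[i] <- tor(list(atom_xyz(cur, "O4'"), atom_xyz(cur, "C1'"),
                           atom_xyz(cur, g[1]), atom_xyz(cur, g[2])))
  }
  out$glycosidic <- ifelse(is.na(out$chi), NA_character_,
                           ifelse(abs(out$chi) <= 90, "syn", "anti"))
  rownames(out) <- NULL
  out
}

#' Glycosidic conformation classes of a chain
#'
#' @inheritParams backbone_torsions
#' @return Character vector (`"anti"`, `"syn"` or `NA`) named by
#'   residue number.
#' @export
glycosidic_classification <- function(model, chain) {
  t <- backbone_torsions(model, chain)
  stats::setNames(t$glycosidic, t$resno)
}

# Leontis-Westhof edge membership per base atom.  Atoms bordering two
# edges (e.g. purine N6/O6 between Watson-Crick and Hoogsteen) vote
# for both; the pair-level call takes the majority with ties resolved
# WC > Hoogsteen > Sugar.
.EDGES <- list(
  A = list(WatsonCrick = c("N1", "C2", "N6"),
           Hoogsteen = c("N6", "N7", "C8"),
           SugarEdge = c("C2", "N3", "O2'", "O4'")),
  G = list(WatsonCrick = c("N1", "N2", "O6"),
           Hoogsteen = c("O6", "N7", "C8"),
           SugarEdge = c("N2", "N3", "O2'", "O4'")),
  C = list(WatsonCrick = c("N3", "N4", "O2"),
           Hoogsteen = c("N4", "C5", "C6"),
           SugarEdge = c("O2", "O2'", "O4'")),
  U = list(WatsonCrick = c("N3", "O4", "O2"),
           Hoogsteen = c("O4", "C5", "C6"),
           SugarEdge = c("O2", "O2'", "O4'")))
.EDGES$DA <- .EDGES$A; .EDGES$DG <- .EDGES$G
.EDGES$DC <- .EDGES$C; .EDGES$DT <- .EDGES$U

.edge_votes <- function(resid, atoms) {
  ed <- .EDGES[[resid]]
  if (is.null(ed)) return(c(WatsonCrick = 0, Hoogsteen = 0, SugarEdge = 0))
  vapply(ed, function(a) sum(atoms %in% a), numeric(1))
}

.majority_edge <- function(votes) {
  pri <- c("WatsonCrick", "Hoogsteen", "SugarEdge")
  votes <- votes[pri]
  pri[which.max(votes)]   # which.max takes the first maximum: WC > H > S
}

.COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G",
                 DA = "DT", DT = "DA", DG = "DC", DC = "DG")

# Single-residue atom selection helper.
.res_selection <- function(model, chain, resno, insert = "",
                           atom_names = NULL) {
  at <- model$atoms
  keep <- which(at$chain == chain & at$resno == resno & at$insert == insert)
  if (!is.null(atom_names)) keep <- keep[at$elety[keep] %in% atom_names]
  m <- at[keep, c("chain", "resno", "insert", "resid", "kind", "elety")]
  m$idx <- keep
  structure(list(members = m, skipped = 0L, model_id = model$identifier),
            class = "atom_selection")
}

# Base (+ sugar O2'/O4') atom names eligible for inter-base H-bonds.
.base_edge_atoms <- function(resid) {
  unique(unlist(.EDGES[[resid]]))
}

#' Detect and classify base pairs
#'
#' Candidate pairs have at least two inter-base hydrogen bonds (the
#' heavy-atom criteria of [detect_hydrogen_bonds()], restricted to
#' edge atoms) and a base interplanar angle of at most 45 degrees.
#' Each pair side is labeled with its interacting edge (Watson-Crick /
#' Hoogsteen / sugar) by majority vote of the hydrogen-bonded atoms;
#' the glycosidic-bond orientation is `cis` when the two glycosidic
#' bonds point to the same side of the C1'-C1' axis in the pair plane,
#' `trans` otherwise.
#'
#' @param model A `structure_model`.
#' @param chains Nucleic-acid chains to consider (default: all).
#' @param hbond_dist,hbond_angle Hydrogen-bond gates.
#' @param max_plane_angle Maximum base interplanar angle (45 deg).
#' @param max_plane_offset Maximum distance of either base centroid
#'   from the partner's base plane (2.0 A): separates in-plane
#'   pairing from stacking, which also has parallel normals.
#' @return Data frame, one row per pair (lower (chain, resno) first):
#'   residue identities, `edge_i`, `edge_j`, `orientation`,
#'   `canonical` (cis WC/WC A:U, G:C), `wobble` (cis WC/WC G:U),
#'   `n_hbonds`.
#' @export
detect_base_pairs <- function(model, chains = NULL, hbond_dist = 3.5,
                              hbond_angle = 90, max_plane_angle = 45,
                              max_plane_offset = 2.0) {
  at <- model$atoms
  if (is.null(chains)) chains <- unique(at$chain[at$kind == "nucleotide"])
  res <- do.call(rbind, lapply(chains, function(ch)
    .chain_nucleotides(model, ch)))
  n <- nrow(res)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    rdef <- .RINGS[[res$resid[i]]]
    ra <- residue_atoms(model, res$chain[i], res$resno[i], res$insert[i])
    xyz <- t(vapply(rdef[[1]], function(nm) {
      p <- atom_xyz(ra, nm); if (is.null(p)) rep(NA_real_, 3) else p
    }, numeric(3)))
    if (!anyNA(xyz)) frames[[i]] <- plane_fit(xyz)
  }
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (is.null(frames[[i]]) || is.null(frames[[j]])) next
    if (vec_norm(frames[[i]]$centroid - frames[[j]]$centroid) > 12) next
    plane_ang <- acute_angle(frames[[i]]$normal, frames[[j]]$normal)
    if (plane_ang > max_plane_angle) next
    sep <- frames[[j]]$centroid - frames[[i]]$centroid
    if (abs(sum(sep * frames[[i]]$normal)) > max_plane_offset ||
        abs(sum(sep * frames[[j]]$normal)) > max_plane_offset) next
    si <- .res_selection(model, res$chain[i], res$resno[i], res$insert[i],
                         .base_edge_atoms(res$resid[i]))
    sj <- .res_selection(model, res$chain[j], res$resno[j], res$insert[j],
                         .base_edge_atoms(res$resid[j]))
    if (nrow(si$members) == 0 || nrow(sj$members) == 0) next
    hb <- detect_hydrogen_bonds(model, si, sj, hbond_dist, hbond_angle)
    if (nrow(hb) < 2) next
    atoms_i <- ifelse(hb$direction == "AB", hb$donor_atom, hb$acceptor_atom)
    atoms_j <- ifelse(hb$direction == "AB", hb$acceptor_atom, hb$donor_atom)
    sugar <- c("O2'", "O4'")
    if (!any(!atoms_i %in% sugar) || !any(!atoms_j %in% sugar)) next
    edge_i <- .majority_edge(.edge_votes(res$resid[i], atoms_i))
    edge_j <- .majority_edge(.edge_votes(res$resid[j], atoms_j))
    ori <- .pair_orientation(model, res[i, ], res[j, ])
    if (is.na(ori)) next
    comp <- identical(.COMPLEMENT[[res$resid[i]]], res$resid[j])
    gu <- paste(sort(c(res$resid[i], res$resid[j])), collapse = "") %in%
      c("GU", "DGDT")
    canonical <- edge_i == "WatsonCrick" && edge_j == "WatsonCrick" &&
      ori == "cis" && comp
    wobble <- edge_i == "WatsonCrick" && edge_j == "WatsonCrick" &&
      ori == "cis" && gu
    out <- rbind(out, data.frame(
      chain_i = res$chain[i], resno_i = res$resno[i], resid_i = res$resid[i],
      chain_j = res$chain[j], resno_j = res$resno[j], resid_j = res$resid[j],
      edge_i = edge_i, edge_j = edge_j, orientation = ori,
      canonical = canonical, wobble = wobble, n_hbonds = nrow(hb),
      interplanar_angle = plane_ang, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(chain_i = character(0), resno_i = integer(0),
                      resid_i = character(0), chain_j = character(0),
                      resno_j = integer(0), resid_j = character(0),
                      edge_i = character(0), edge_j = character(0),
                      orientation = character(0), canonical = logical(0),
                      wobble = logical(0), n_hbonds = integer(0),
                      interplanar_angle = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# cis/trans from glycosidic-bond direction vectors: remove the
# component along the C1'-C1' axis; same-side projections = cis.
.pair_orientation <- function(model, ri, rj) {
  ai <- residue_atoms(model, ri$chain, ri$resno, ri$insert)
  aj <- residue_atoms(model, rj$chain, rj$resno, rj$insert)
  c1i <- atom_xyz(ai, "C1'"); c1j <- atom_xyz(aj, "C1'")
  ni <- atom_xyz(ai, .glyc_atoms(ri$resid)[1])
  nj <- atom_xyz(aj, .glyc_atoms(rj$resid)[1])
  if (is.null(c1i) || is.null(c1j) || is.null(ni) || is.null(nj))
    return(NA_character_)
  u <- unit_vec(c1j - c1i)
  vi <- (ni - c1i) - sum((ni - c1i) * u) * u
  vj <- (nj - c1j) - sum((nj - c1j) * u) * u
  if (vec_norm(vi) < 1e-6 || vec_norm(vj) < 1e-6) return(NA_character_)
  if (sum(vi * vj) > 0) "cis" else "trans"
}

# TRUE if the bases of two nucleotides stack (any ring-ring pair
# passing the centroid-distance + interplanar-angle gate).
.bases_stack <- function(model, ra, rb, stack_dist = 4.5, stack_angle = 30) {
  fa <- .base_ring_frames(model, ra)
  fb <- .base_ring_frames(model, rb)
  for (x in fa) for (y in fb) {
    if (vec_norm(x$centroid - y$centroid) <= stack_dist &&
        acute_angle(x$normal, y$normal) <= stack_angle) return(TRUE)
  }
  FALSE
}

.base_ring_frames <- function(model, r) {
  rdef <- .RINGS[[r$resid]]
  ra <- residue_atoms(model, r$chain, r$resno, r$insert)
  out <- list()
  for (ring in rdef) {
    xyz <- t(vapply(ring, function(nm) {
      p <- atom_xyz(ra, nm); if (is.null(p)) rep(NA_real_, 3) else p
    }, numeric(3)))
    if (!anyNA(xyz)) out[[length(out) + 1]] <- plane_fit(xyz)
  }
  out
}

#' Stacking runs and flipped-out bases along a chain
#'
#' Runs are maximal sequences of sequential nucleotides whose bases
#' mutually stack (gates as in [detect_ring_interactions()]).  A
#' nucleotide is flagged flipped-out when it stacks with neither
#' sequential neighbor although both neighbors are modeled.
#'
#' @param model A `structure_model`.
#' @param chain Nucleic-acid chain identifier.
#' @param stack_dist,stack_angle Stacking gates.
#' @return List with `runs` (list of residue-number vectors, length
#'   >= 2) and `flipped` (data frame `resno`, `resid`,
#'   `flipped_out`).
#' @export
stacking_runs_and_flips <- function(model, chain, stack_dist = 4.5,
                                    stack_angle = 30) {
  res <- .chain_nucleotides(model, chain)
  n <- nrow(res)
  seq_stack <- rep(FALSE, max(n - 1, 0))
  for (i in seq_len(n - 1)) {
    if (res$resno[i + 1] != res$resno[i] + 1) next
    seq_stack[i] <- .bases_stack(model, res[i, ], res[i + 1, ],
                                 stack_dist, stack_angle)
  }
  runs <- list()
  i <- 1
  while (i <= n - 1) {
    if (seq_stack[i]) {
      j <- i
      while (j <= n - 1 && seq_stack[j]) j <- j + 1
      runs[[length(runs) + 1]] <- res$resno[i:j]
      i <- j
    } else i <- i + 1
  }
  flipped <- rep(FALSE, n)
  for (i in seq_len(n)) {
    has_prev <- i > 1 && res$resno[i - 1] == res$resno[i] - 1
    has_next <- i < n && res$resno[i + 1] == res$resno[i] + 1
    if (has_prev && has_next)
      flipped[i] <- !seq_stack[i - 1] && !seq_stack[i]
  }
  list(runs = runs,
       flipped = data.frame(resno = res$resno, resid = res$resid,
                            flipped_out = flipped,
                            stringsAsFactors = FALSE))
}

#' Helix-form call from mean rise and twist
#'
#' Builds a frame per base pair (origin: C1'-C1' midpoint; x: C1'->
#' C1' direction; z: mean base normal, oriented along the helix) and
#' derives the mean helical rise (origin step along the mean normal)
#' and twist (rotation of the x axis about it).  Categorical call: A
#' if rise in [2.3, 3.1] A and twist in [30, 34] deg; B if rise in
#' (3.1, 3.6] A and twist in (34, 38] deg; otherwise irregular.
#'
#' @param model A `structure_model`.
#' @param pairs Base-pair table ([detect_base_pairs()] rows) of at
#'   least 3 consecutive pairs of one helical segment, in strand
#'   order.
#' @return List with `form` (`"A"`, `"B"` or `"irregular"`),
#'   `mean_rise` (Angstroms) and `mean_twist` (degrees).
#' @export
helix_form <- function(model, pairs) {
  if (nrow(pairs) < 3) stop("need at least 3 consecutive base pairs")
  n <- nrow(pairs)
  origin <- matrix(0, n, 3); xaxis <- matrix(0, n, 3); zaxis <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    ri <- residue_atoms(model, pairs$chain_i[k], pairs$resno_i[k])
    rj <- residue_atoms(model, pairs$chain_j[k], pairs$resno_j[k])
    c1i <- atom_xyz(ri, "C1'"); c1j <- atom_xyz(rj, "C1'")
    fi <- .base_ring_frames(model, data.frame(chain = pairs$chain_i[k],
                                              resno = pairs$resno_i[k],
                                              insert = "",
                                              resid = pairs$resid_i[k]))
    fj <- .base_ring_frames(model, data.frame(chain = pairs$chain_j[k],
                                              resno = pairs$resno_j[k],
                                              insert = "",
                                              resid = pairs$resid_j[k]))
    if (is.null(c1i) || is.null(c1j) || !length(fi) || !length(fj))
      stop("pair ", k, ": missing C1' or base ring atoms")
    origin[k, ] <- (c1i + c1j) / 2
    xaxis[k, ] <- unit_vec(c1j - c1i)
    nz <- fi[[1]]$normal
    if (sum(nz * fj[[1]]$normal) < 0) nz <- nz - fj[[1]]$normal else
      nz <- nz + fj[[1]]$normal
    zaxis[k, ] <- unit_vec(nz)
  }
  # orient normals consistently along the origin progression
  prog <- origin[n, ] - origin[1, ]
  for (k in seq_len(n)) if (sum(zaxis[k, ] * prog) < 0)
    zaxis[k, ] <- -zaxis[k, ]
  rises <- numeric(n - 1); twists <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    zm <- unit_vec(zaxis[k, ] + zaxis[k + 1, ])
    rises[k] <- abs(sum((origin[k + 1, ] - origin[k, ]) * zm))
    x1 <- xaxis[k, ] - sum(xaxis[k, ] * zm) * zm
    x2 <- xaxis[k + 1, ] - sum(xaxis[k + 1, ] * zm) * zm
    ang <- atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2))
    twists[k] <- abs(deg(ang))
  }
  rise <- mean(rises); twist <- mean(twists)
  form <- if (rise >= 2.3 && rise <= 3.1 && twist >= 30 && twist <= 34) "A"
  else if (rise > 3.1 && rise <= 3.6 && twist > 34 && twist <= 38) "B"
  else "irregular"
  list(form = form, mean_rise = rise, mean_twist = twist)
}
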