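# Protein-nucleic-acid interface census: distance-cutoff contact
# residues, Shrake-Rupley solvent-accessible surface area with a
# buried-area decomposition per protein domain, and typed interactions
# (hydrogen bonds on heavy-atom criteria, pi-pi stacking, cation-pi).
#
# The hydrogen-bond, stacking and cation-pi gates are permissive
# literature values chosen for structures deposited without hydrogens;
# every geometric parameter is reported per hit so results can be
# re-gated.

# Bondi van der Waals radii (Angstroms); single fixed source.
.VDW <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80)

vdw_radii <- function(elements) {
  r <- .VDW[elements]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  as.numeric(r)
}

#' Default interface-analysis thresholds
#'
#' @return Named list: `contact_cutoff` (3.7 A), `hbond_dist` (3.5 A),
#'   `hbond_angle` (90 deg minimum antecedent-donor-acceptor angle),
#'   `stack_dist` (4.5 A ring-centroid), `stack_angle` (30 deg max
#'   interplanar), `cation_pi_dist` (6.0 A), `cation_pi_angle` (45 deg
#'   max off-normal), `sasa_probe` (1.4 A), `sasa_points` (960).
#' @export
interface_thresholds <- function() {
  list(contact_cutoff = 3.7, hbond_dist = 3.5, hbond_angle = 90,
       stack_dist = 4.5, stack_angle = 30,
       cation_pi_dist = 6.0, cation_pi_angle = 45,
       sasa_probe = 1.4, sasa_points = 960)
}

.sel_table <- function(model, selection) {
  at <- model$atoms[selection$members$idx, , drop = FALSE]
  at$idx <- selection$members$idx
  at
}

#' Contact residue census at a distance cutoff
#'
#' A protein residue is counted as a contact residue if any of its
#' atoms lies within `cutoff` of any nucleic-acid atom.
#'
#' @param model A `structure_model`.
#' @param protein_sel,nucleic_sel `atom_selection`s for the two
#'   components (heavy atoms unless hydrogens are deliberately
#'   included in the selections).
#' @param cutoff Distance cutoff in Angstroms (default 3.7).
#' @return List with `contacts` (data frame of atom pairs within the
#'   cutoff and their distances), `residues` (unique contact residues,
#'   per chain), and `per_chain_counts`.
#' @export
find_contact_residues <- function(model, protein_sel, nucleic_sel,
                                  cutoff = 3.7) {
  if (cutoff <= 0) stop("cutoff must be positive")
  pa <- .sel_table(model, protein_sel)
  na <- .sel_table(model, nucleic_sel)
  D <- cross_distances(as.matrix(pa[, c("x", "y", "z")]),
                       as.matrix(na[, c("x", "y", "z")]))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0) hit <- matrix(integer(0), 0, 2)
  contacts <- data.frame(
    stringsAsFactors = FALSE,
    protein_chain = pa$chain[hit[, 1]], protein_resno = pa$resno[hit[, 1]],
    protein_resid = pa$resid[hit[, 1]], protein_atom = pa$elety[hit[, 1]],
    nucleic_chain = na$chain[hit[, 2]], nucleic_resno = na$resno[hit[, 2]],
    nucleic_resid = na$resid[hit[, 2]], nucleic_atom = na$elety[hit[, 2]],
    distance = D[hit], type = rep("generic", nrow(hit)))
  contacts <- contacts[order(contacts$protein_chain, contacts$protein_resno,
                             contacts$distance), , drop = FALSE]
  rownames(contacts) <- NULL
  res <- unique(contacts[, c("protein_chain", "protein_resno",
                             "protein_resid")])
  res <- res[order(res$protein_chain, res$protein_resno), , drop = FALSE]
  rownames(res) <- NULL
  list(contacts = contacts, residues = res,
       per_chain_counts = if (nrow(res)) table(res$protein_chain)
                          else table(character(0)),
       n_residues = nrow(res), cutoff = cutoff)
}

# Deterministic near-uniform points on the unit sphere (golden-section
# spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA over a deterministic spiral point lattice.  The
#' environment is the full atom set; areas are reported per atom.
#'
#' @param xyz n x 3 coordinate matrix.
#' @param elements Element symbol per atom (H, C, N, O, P, S).
#' @param probe Probe radius in Angstroms (default 1.4).
#' @param n_points Lattice points per atom sphere (default 960).
#' @return Numeric vector of per-atom accessible areas (Angstroms^2).
#' @export
solvent_accessible_area <- function(xyz, elements, probe = 1.4,
                                    n_points = 960) {
  xyz <- as.matrix(xyz)
  r <- vdw_radii(elements) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  area <- numeric(n)
  D <- cross_distances(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(D[i, ] < r[i] + r & seq_len(n) != i)
    full <- 4 * pi * r[i]^2
    if (length(nb) == 0) { area[i] <- full; next }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
            (p[, 3] - xyz[j, 3])^2
      buried <- buried | d2 < r[j]^2
      if (all(buried)) break
    }
    area[i] <- full * sum(!buried) / n_points
  }
  area
}

# SASA for the atoms of a selection evaluated in the context of a
# model subset given by `context_idx` (row indices into model$atoms).
.sasa_of <- function(model, target_idx, context_idx, probe, n_points) {
  at <- model$atoms[context_idx, , drop = FALSE]
  a <- solvent_accessible_area(as.matrix(at[, c("x", "y", "z")]),
                               at$elesy, probe, n_points)
  sum(a[match(target_idx, context_idx)])
}

#' Buried-surface-area decomposition by protein domain
#'
#' The area a protein domain buries on complex formation:
#' SASA(protein alone, domain atoms) - SASA(complex, domain atoms).
#' The total over domains is the protein-side binding epitope.
#'
#' @param model A `structure_model`.
#' @param protein_sel,nucleic_sel `atom_selection`s for the two
#'   components.
#' @param domains Named list of `atom_selection`s partitioning the
#'   protein atoms of interest (e.g. one per NBD); they must not
#'   overlap.
#' @param probe,n_points SASA parameters (see
#'   [solvent_accessible_area()]).
#' @return List with `per_domain` (named numeric, Angstroms^2) and
#'   `total`.
#' @export
buried_area_decomposition <- function(model, protein_sel, nucleic_sel,
                                      domains, probe = 1.4, n_points = 960) {
  dom_idx <- lapply(domains, function(d) d$members$idx)
  if (anyDuplicated(unlist(dom_idx)) > 0)
    stop("domain definitions overlap")
  prot_idx <- protein_sel$members$idx
  comp_idx <- sort(c(prot_idx, nucleic_sel$members$idx))
  per <- vapply(dom_idx, function(idx) {
    free <- .sasa_of(model, idx, sort(prot_idx), probe, n_points)
    bound <- .sasa_of(model, idx, comp_idx, probe, n_points)
    free - bound
  }, numeric(1))
  list(per_domain = per, total = sum(per))
}

# Hydrogen-bond chemistry: heavy-atom donors/acceptors and donor
# antecedents, amino acids and nucleotides.  Sulfur omitted.
.HB <- local({
  don <- list(
    backbone_aa = c("N"),
    ARG = c("NE", "NH1", "NH2"), LYS = c("NZ"), HIS = c("ND1", "NE2"),
    TRP = c("NE1"), ASN = c("ND2"), GLN = c("NE2"), SER = c("OG"),
    THR = c("OG1"), TYR = c("OH"),
    A = c("N6", "O2'"), G = c("N1", "N2", "O2'"),
    C = c("N4", "O2'"), U = c("N3", "O2'"),
    DA = c("N6"), DG = c("N1", "N2"), DC = c("N4"), DT = c("N3"))
  acc <- list(
    backbone_aa = c("O", "OXT"),
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = c("OD1"),
    GLN = c("OE1"), HIS = c("ND1", "NE2"), SER = c("OG"), THR = c("OG1"),
    TYR = c("OH"),
    nuc_backbone = c("OP1", "OP2", "O5'", "O3'", "O4'", "O2'"),
    A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
    C = c("O2", "N3"), U = c("O2", "O4"),
    DA = c("N1", "N3", "N7"), DG = c("O6", "N3", "N7"),
    DC = c("O2", "N3"), DT = c("O2", "O4"))
  ante <- c(N = "CA", NE = "CD", NH1 = "CZ", NH2 = "CZ", NZ = "CE",
            ND1 = "CG", NE2 = "CD2", NE1 = "CD1", ND2 = "CG",
            OG = "CB", OG1 = "CB", OH = "CZ",
            N6 = "C6", N1 = "C2", N2 = "C2", N4 = "C4", N3 = "C2",
            "O2'" = "C2'")
  list(don = don, acc = acc, ante = ante)
})

.hb_roles <- function(at) {
  donor <- logical(nrow(at)); accep <- logical(nrow(at))
  for (i in seq_len(nrow(at))) {
    res <- at$resid[i]; nm <- at$elety[i]
    if (at$kind[i] == "amino_acid") {
      donor[i] <- nm %in% .HB$don$backbone_aa ||
        nm %in% .HB$don[[res]]
      accep[i] <- nm %in% .HB$acc$backbone_aa ||
        nm %in% .HB$acc[[res]]
    } else if (at$kind[i] == "nucleotide") {
      donor[i] <- nm %in% .HB$don[[res]]
      accep[i] <- nm %in% .HB$acc$nuc_backbone || nm %in% .HB$acc[[res]]
    }
  }
  list(donor = donor, acceptor = accep)
}

# Antecedent-donor-acceptor angle (degrees); NA when no antecedent atom.
.ante_angle <- function(model, don_row, acc_xyz) {
  ante_name <- .HB$ante[don_row$elety]
  if (is.na(ante_name)) return(NA_real_)
  res_at <- residue_atoms(model, don_row$chain, don_row$resno, don_row$insert)
  axyz <- atom_xyz(res_at, ante_name)
  if (is.null(axyz)) return(NA_real_)
  d <- as.numeric(don_row[c("x", "y", "z")])
  v1 <- axyz - d; v2 <- acc_xyz - d
  deg(acos(max(-1, min(1, sum(unit_vec(v1) * unit_vec(v2))))))
}

#' Detect hydrogen bonds between two atom groups
#'
#' Heavy-atom criteria for structures without hydrogens: a
#' donor-acceptor pair is reported when the N/O--N/O distance is at
#' most `dist_cutoff` and, where the donor's antecedent atom is
#' modeled, the antecedent-donor-acceptor angle is at least
#' `angle_min` degrees.  Donor/acceptor classes come from a fixed
#' chemistry table.
#'
#' @param model A `structure_model`.
#' @param selA,selB `atom_selection`s for the two groups.
#' @param dist_cutoff Donor-acceptor distance gate (default 3.5 A).
#' @param angle_min Antecedent angle gate (default 90 deg).
#' @return Data frame of hydrogen bonds (donor/acceptor identity,
#'   distance, antecedent angle, direction A->B or B->A), plus a
#'   `bidentate` attribute: residue pairs joined by >= 2 bonds.
#' @export
detect_hydrogen_bonds <- function(model, selA, selB, dist_cutoff = 3.5,
                                  angle_min = 90) {
  ta <- .sel_table(model, selA); tb <- .sel_table(model, selB)
  ra <- .hb_roles(ta); rb <- .hb_roles(tb)
  out <- NULL
  D <- cross_distances(as.matrix(ta[, c("x", "y", "z")]),
                       as.matrix(tb[, c("x", "y", "z")]))
  add_bonds <- function(dt, at, di, ai, dirn) {
    res <- NULL
    for (k in seq_along(di)) {
      i <- di[k]; j <- ai[k]
      dist <- if (dirn == "AB") D[i, j] else D[j, i]
      if (dist > dist_cutoff || dist < 0.5) next
      ang <- .ante_angle(model, dt[i, ], as.numeric(at[j, c("x", "y", "z")]))
      if (!is.na(ang) && ang < angle_min) next
      res <- rbind(res, data.frame(
        donor_chain = dt$chain[i], donor_resno = dt$resno[i],
        donor_resid = dt$resid[i], donor_atom = dt$elety[i],
        acceptor_chain = at$chain[j], acceptor_resno = at$resno[j],
        acceptor_resid = at$resid[j], acceptor_atom = at$elety[j],
        distance = dist, antecedent_angle = ang, direction = dirn,
        stringsAsFactors = FALSE))
    }
    res
  }
  # donors in A vs acceptors in B
  hits <- which(outer(ra$donor, rb$acceptor, "&") & D <= dist_cutoff,
                arr.ind = TRUE)
  if (nrow(hits)) out <- rbind(out, add_bonds(ta, tb, hits[, 1], hits[, 2], "AB"))
  hits <- which(outer(rb$donor, ra$acceptor, "&") & t(D) <= dist_cutoff,
                arr.ind = TRUE)
  if (nrow(hits)) out <- rbind(out, add_bonds(tb, ta, hits[, 1], hits[, 2], "BA"))
  if (is.null(out))
    out <- data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_resno = integer(0),
                      acceptor_resid = character(0), acceptor_atom = character(0),
                      distance = numeric(0), antecedent_angle = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  pair_key <- paste(out$donor_chain, out$donor_resno, "|",
                    out$acceptor_chain, out$acceptor_resno)
  counts <- table(pair_key)
  attr(out, "bidentate") <- names(counts)[counts >= 2]
  out
}

# Aromatic ring definitions: amino-acid side chains and nucleobases
# (purines contribute their 6- and 5-membered rings separately).
.RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  A = list(c("N1", "C2", "N3", "C4", "C5", "C6"),
           c("C4", "C5", "N7", "C8", "N9")),
  G = list(c("N1", "C2", "N3", "C4", "C5", "C6"),
           c("C4", "C5", "N7", "C8", "N9")),
  C = list(c("N1", "C2", "N3", "C4", "C5", "C6")),
  U = list(c("N1", "C2", "N3", "C4", "C5", "C6")))
.RINGS$DA <- .RINGS$A; .RINGS$DG <- .RINGS$G
.RINGS$DC <- .RINGS$C; .RINGS$DT <- .RINGS$U

# Cationic side-chain groups: atoms whose centroid carries the charge.
.CATIONS <- list(ARG = c("CZ", "NE", "NH1", "NH2"), LYS = c("NZ"))

# Ring centroids + normals for all residues of a selection.
.ring_frames <- function(model, sel) {
  mem <- unique(sel$members[, c("chain", "resno", "insert", "resid")])
  out <- list()
  for (i in seq_len(nrow(mem))) {
    rdef <- .RINGS[[mem$resid[i]]]
    if (is.null(rdef)) next
    res_at <- residue_atoms(model, mem$chain[i], mem$resno[i], mem$insert[i])
    for (k in seq_along(rdef)) {
      xyz <- t(vapply(rdef[[k]], function(nm) {
        p <- atom_xyz(res_at, nm)
        if (is.null(p)) rep(NA_real_, 3) else p
      }, numeric(3)))
      if (anyNA(xyz)) next
      pf <- plane_fit(xyz)
      out[[length(out) + 1]] <- list(chain = mem$chain[i],
                                     resno = mem$resno[i],
                                     resid = mem$resid[i], ring = k,
                                     centroid = pf$centroid,
                                     normal = pf$normal)
    }
  }
  out
}

.cation_centroids <- function(model, sel) {
  mem <- unique(sel$members[, c("chain", "resno", "insert", "resid")])
  out <- list()
  for (i in seq_len(nrow(mem))) {
    cdef <- .CATIONS[[mem$resid[i]]]
    if (is.null(cdef)) next
    res_at <- residue_atoms(model, mem$chain[i], mem$resno[i], mem$insert[i])
    xyz <- t(vapply(cdef, function(nm) {
      p <- atom_xyz(res_at, nm)
      if (is.null(p)) rep(NA_real_, 3) else p
    }, numeric(3)))
    if (anyNA(xyz)) next
    out[[length(out) + 1]] <- list(chain = mem$chain[i], resno = mem$resno[i],
                                   resid = mem$resid[i],
                                   centroid = colMeans(xyz))
  }
  out
}

#' Detect pi-pi stacking and cation-pi interactions
#'
#' Stacking: ring-centroid distance <= `stack_dist` and interplanar
#' angle <= `stack_angle`.  Cation-pi: cationic-group centroid (Arg
#' guanidinium, Lys ammonium) within `cation_dist` of a ring centroid
#' and within `cation_angle` of the ring normal.
#'
#' @param model A `structure_model`.
#' @param selA,selB `atom_selection`s for the two groups.
#' @param stack_dist,stack_angle,cation_dist,cation_angle Gates (see
#'   [interface_thresholds()]).
#' @return Data frame with one row per hit: `type` (`stacking` or
#'   `cation_pi`), partner identities, centroid distance, interplanar
#'   or off-normal angle.
#' @export
detect_ring_interactions <- function(model, selA, selB, stack_dist = 4.5,
                                     stack_angle = 30, cation_dist = 6.0,
                                     cation_angle = 45) {
  fa <- .ring_frames(model, selA); fb <- .ring_frames(model, selB)
  ca <- .cation_centroids(model, selA); cb <- .cation_centroids(model, selB)
  out <- NULL
  rec <- function(type, a, b, dist, ang) data.frame(
    type = type, chain_a = a$chain, resno_a = a$resno, resid_a = a$resid,
    chain_b = b$chain, resno_b = b$resno, resid_b = b$resid,
    centroid_distance = dist, angle = ang, stringsAsFactors = FALSE)
  for (ra in fa) for (rb in fb) {
    same <- ra$chain == rb$chain && ra$resno == rb$resno
    if (same) next
    dist <- vec_norm(ra$centroid - rb$centroid)
    if (dist > stack_dist) next
    ang <- acute_angle(ra$normal, rb$normal)
    if (ang <= stack_angle)
      out <- rbind(out, rec("stacking", ra, rb, dist, ang))
  }
  cat_vs_rings <- function(cats, rings) {
    res <- NULL
    for (cc in cats) for (rr in rings) {
      v <- cc$centroid - rr$centroid
      dist <- vec_norm(v)
      if (dist > cation_dist || dist < 1e-6) next
      off <- acute_angle(v, rr$normal)
      if (off <= cation_angle)
        res <- rbind(res, rec("cation_pi", cc, rr, dist, off))
    }
    res
  }
  out <- rbind(out, cat_vs_rings(ca, fb), cat_vs_rings(cb, fa))
  if (is.null(out))
    out <- data.frame(type = character(0), chain_a = character(0),
                      resno_a = integer(0), resid_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      resid_b = character(0), centroid_distance = numeric(0),
                      angle = numeric(0), stringsAsFactors = FALSE)
  # de-duplicate multiple ring-ring hits of the same residue pair: keep
  # the closest
  if (nrow(out) > 1) {
    key <- paste(out$type, out$chain_a, out$resno_a, out$chain_b, out$resno_b)
    out <- out[order(key, out$centroid_distance), , drop = FALSE]
    out <- out[!duplicated(paste(out$type, out$chain_a, out$resno_a,
                                 out$chain_b, out$resno_b)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Full interface summary of a protein-nucleic-acid complex
#'
#' Runs the contact census, buried-area decomposition and typed
#' interaction detection with one set of thresholds.
#'
#' @param model A `structure_model`.
#' @param protein_sel,nucleic_sel Component `atom_selection`s.
#' @param domains Named list of domain `atom_selection`s for the
#'   buried-area decomposition (default: one domain per protein chain).
#' @param thresholds See [interface_thresholds()].
#' @return An `interface_summary` list: `census`, `buried_area`,
#'   `hydrogen_bonds`, `ring_interactions`, `thresholds`.
#' @export
interface_summary <- function(model, protein_sel, nucleic_sel,
                              domains = NULL,
                              thresholds = interface_thresholds()) {
  if (is.null(domains)) {
    chains <- unique(protein_sel$members$chain)
    domains <- lapply(chains, function(ch) {
      sub <- protein_sel
      keep <- sub$members$chain == ch
      sub$members <- sub$members[keep, , drop = FALSE]
      sub
    })
    names(domains) <- chains
  }
  census <- find_contact_residues(model, protein_sel, nucleic_sel,
                                  thresholds$contact_cutoff)
  buried <- buried_area_decomposition(model, protein_sel, nucleic_sel,
                                      domains, thresholds$sasa_probe,
                                      thresholds$sasa_points)
  hb <- detect_hydrogen_bonds(model, protein_sel, nucleic_sel,
                              thresholds$hbond_dist, thresholds$hbond_angle)
  rings <- detect_ring_interactions(model, protein_sel, nucleic_sel,
                                    thresholds$stack_dist,
                                    thresholds$stack_angle,
                                    thresholds$cation_pi_dist,
                                    thresholds$cation_pi_angle)
  structure(list(census = census, buried_area = buried,
                 hydrogen_bonds = hb, ring_interactions = rings,
                 thresholds = thresholds),
            class = "interface_summary")
}
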