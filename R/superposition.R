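# Rigid-body superposition and the domain-anchored r.m.s.d. protocol
# used to compare inter-domain orientations across dimer structures:
# superpose on a conformationally invariant anchor domain (pooled over
# both protomers), then measure the probe-domain r.m.s.d. under that
# transform without refitting.

#' Define a residue-segment domain
#'
#' @param name Domain label, e.g. `"EBD"` or `"NBD"`.
#' @param segments Inclusive residue ranges (see [select_atoms()]),
#'   applied identically to each protomer.
#' @return A `domain_definition` object.
#' @export
domain_definition <- function(name, segments) {
  segs <- parse_segments(segments)
  lo <- vapply(segs, `[`, integer(1), 1)
  if (is.unsorted(lo)) stop("segments must be ascending")
  for (i in seq_along(segs)[-1])
    if (segs[[i]][1] <= segs[[i - 1]][2]) stop("segments must not overlap")
  structure(list(name = name, segments = segs), class = "domain_definition")
}

#' Anchor segments of the effector-binding domain
#'
#' The conformationally invariant residue set used to anchor dimer
#' superpositions: 48-66, 73-103, 108-129, 131-137, 139-151, 166-173,
#' 179-180, 183-202 (present once per protomer).
#' @return A `domain_definition`.
#' @export
ebd_domain <- function() {
  domain_definition("EBD", "48-66,73-103,108-129,131-137,139-151,166-173,179-180,183-202")
}

#' Probe segments of the nucleotide-binding domain
#'
#' The DNA-reading head (helices alpha-1 to alpha-3), taken as residues
#' 2-47 per protomer: everything N-terminal of the first anchor segment.
#' @return A `domain_definition`.
#' @export
nbd_domain <- function() domain_definition("NBD", "2-47")

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the
#' r.m.s. deviation between `moving %*% t(R) + t` and `fixed`.
#'
#' @param moving,fixed n x 3 coordinate matrices, n >= 3, paired row
#'   by row.
#' @return A `superposition_result`: list with `rotation` (3x3,
#'   det = +1), `translation`, `rmsd` (Angstroms, post-fit),
#'   `n_pairs`, and `per_pair_distances`.
#' @export
kabsch_superpose <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (!all(dim(moving) == dim(fixed)))
    stop("coordinate sets differ in size: ", nrow(moving), " vs ",
         nrow(fixed), " points")
  if (nrow(moving) < 3) stop("need at least 3 points to superpose")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  X <- sweep(moving, 2, cm); Y <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(X, Y))          # H = X^T Y
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate point set (collinear or coincident): superposition ill-defined")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  moved <- apply_rigid(moving, R, t)
  dists <- sqrt(rowSums((moved - fixed)^2))
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(dists^2)), n_pairs = nrow(moving),
                 per_pair_distances = dists),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.3f A over %d pairs\n", x$rmsd, x$n_pairs))
  invisible(x)
}

# Residues of `dom` modeled (with the given atom) in both chains; returns
# paired coordinate matrices in matched residue order.
.paired_domain_coords <- function(modelA, chainsA, modelB, chainsB,
                                  dom, atom = "CA") {
  stopifnot(length(chainsA) == length(chainsB))
  xa <- NULL; xb <- NULL; n_res <- 0L
  for (k in seq_along(chainsA)) {
    sa <- select_atoms(modelA, chains = chainsA[k], atoms = atom,
                       segments = dom$segments)
    sb <- select_atoms(modelB, chains = chainsB[k], atoms = atom,
                       segments = dom$segments)
    common <- intersect(sa$members$resno, sb$members$resno)
    ma <- sa$members[match(common, sa$members$resno), ]
    mb <- sb$members[match(common, sb$members$resno), ]
    xa <- rbind(xa, as.matrix(modelA$atoms[ma$idx, c("x", "y", "z")]))
    xb <- rbind(xb, as.matrix(modelB$atoms[mb$idx, c("x", "y", "z")]))
    n_res <- n_res + length(common)
  }
  list(a = xa, b = xb, n = n_res)
}

#' Domain-anchored r.m.s.d. between two dimer structures
#'
#' Superposes `modelA` onto `modelB` using only the Cα atoms of the
#' anchor domain, pooled over both protomers, then evaluates the probe
#' domain r.m.s.d. under that same transform with no refit.  Because
#' crystallographic chain labels are arbitrary, both chain pairings
#' (A-A/B-B and A-B/B-A) are tried and the one minimizing the anchor
#' r.m.s.d. is kept.
#'
#' @param modelA,modelB `structure_model`s sharing author numbering.
#' @param chainsA,chainsB Length-2 character vectors naming the two
#'   protomer chains of each dimer.
#' @param anchor,probe `domain_definition`s (defaults: [ebd_domain()],
#'   [nbd_domain()]).
#' @param atom Atom name used for pairing (default `"CA"`).
#' @return List with `anchor_rmsd`, `probe_rmsd`, `n_anchor_pairs`,
#'   `n_probe_pairs`, `transform` (the anchor superposition), and
#'   `chain_pairing`.
#' @export
anchored_domain_rmsd <- function(modelA, modelB, chainsA, chainsB,
                                 anchor = ebd_domain(), probe = nbd_domain(),
                                 atom = "CA") {
  pairings <- list(cbind(chainsA, chainsB),
                   cbind(chainsA, rev(chainsB)))
  best <- NULL
  for (p in pairings) {
    pc <- .paired_domain_coords(modelA, p[, 1], modelB, p[, 2], anchor, atom)
    if (pc$n < 3) next
    fit <- kabsch_superpose(pc$a, pc$b)
    if (is.null(best) || fit$rmsd < best$fit$rmsd)
      best <- list(fit = fit, pairing = p, n_anchor = pc$n)
  }
  if (is.null(best)) stop("fewer than 3 anchor residue pairs in common")
  pp <- .paired_domain_coords(modelA, best$pairing[, 1],
                              modelB, best$pairing[, 2], probe, atom)
  if (is.null(pp$a) || nrow(pp$a) == 0) stop("probe selection is empty")
  moved <- apply_rigid(pp$a, best$fit$rotation, best$fit$translation)
  probe_rmsd <- sqrt(mean(rowSums((moved - pp$b)^2)))
  list(anchor_rmsd = best$fit$rmsd, probe_rmsd = probe_rmsd,
       n_anchor_pairs = best$n_anchor, n_probe_pairs = nrow(pp$a),
       transform = best$fit,
       chain_pairing = stats::setNames(best$pairing[, 2], best$pairing[, 1]))
}

#' Averaged inter-residue distance under a fixed transform
#'
#' Distance between the positions of the same residue (same author
#' number, one atom) in two superposed dimers, averaged over the two
#' protomer copies.
#'
#' @param modelA,modelB `structure_model`s.
#' @param chainsA,chainsB Protomer chains, already in corresponding
#'   order (use `chain_pairing` from [anchored_domain_rmsd()]).
#' @param transform A `superposition_result` applied to `modelA`
#'   coordinates (identity if `NULL`).
#' @param resno Author residue number.
#' @param atom Atom name (default `"CA"`).
#' @return Mean distance in Angstroms over the protomer copies.
#' @export
inter_residue_distance <- function(modelA, modelB, chainsA, chainsB,
                                   resno, transform = NULL, atom = "CA") {
  d <- numeric(0)
  for (k in seq_along(chainsA)) {
    ra <- residue_atoms(modelA, chainsA[k], resno)
    rb <- residue_atoms(modelB, chainsB[k], resno)
    pa <- atom_xyz(ra, atom); pb <- atom_xyz(rb, atom)
    if (is.null(pa))
      stop("residue ", resno, " (", atom, ") missing in model A chain ",
           chainsA[k])
    if (is.null(pb))
      stop("residue ", resno, " (", atom, ") missing in model B chain ",
           chainsB[k])
    if (!is.null(transform))
      pa <- as.numeric(transform$rotation %*% pa) + transform$translation
    d <- c(d, vec_norm(pa - pb))
  }
  mean(d)
}

#' Protomer-vs-protomer r.m.s.d. within one dimer
#'
#' Full Kabsch superposition of the residues modeled (with the chosen
#' atom) in both chains.
#'
#' @param model A `structure_model`.
#' @param chainA,chainB The two protomer chain identifiers.
#' @param atom Atom name (default `"CA"`).
#' @return A `superposition_result` (see [kabsch_superpose()]).
#' @export
protomer_rmsd <- function(model, chainA, chainB, atom = "CA") {
  sa <- select_atoms(model, chains = chainA, atoms = atom)
  sb <- select_atoms(model, chains = chainB, atoms = atom)
  common <- intersect(sa$members$resno, sb$members$resno)
  if (length(common) < 3)
    stop("chains ", chainA, " and ", chainB, " share fewer than 3 residues")
  ia <- sa$members$idx[match(common, sa$members$resno)]
  ib <- sb$members$idx[match(common, sb$members$resno)]
  kabsch_superpose(as.matrix(model$atoms[ia, c("x", "y", "z")]),
                   as.matrix(model$atoms[ib, c("x", "y", "z")]))
}
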