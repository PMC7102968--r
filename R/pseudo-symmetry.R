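# Dyad pseudo-symmetry analysis: derive the two-fold axis relating the
# protomers of a homodimer, rotate the nucleic-acid component 180
# degrees about it, and quantify how well the ligand maps onto itself
# via phosphorus-phosphorus correspondences.

#' Two-fold (dyad) axis of a homodimer
#'
#' Extracted by axis-angle decomposition of the rotation that best
#' superposes chain A onto chain B.  Real dimers are never exactly C2,
#' so the screw component (residual translation along the axis) is
#' reported rather than silently absorbed.
#'
#' @param model A `structure_model`.
#' @param chainA,chainB Protomer chain identifiers.
#' @param atom Atom used for the superposition (default `"CA"`).
#' @return A `symmetry_axis` list: `point` (a point on the axis),
#'   `direction` (unit 3-vector), `angle` (degrees, ~180 for a true
#'   dyad), `screw` (translation along the axis, Angstroms) and
#'   `fit` (the underlying superposition).
#' @export
dimer_dyad_axis <- function(model, chainA, chainB, atom = "CA") {
  fit <- protomer_rmsd(model, chainA, chainB, atom)
  aa <- rotation_axis_angle(fit$rotation)
  if (aa$angle < 90)
    stop("chains not related by an approximate dyad (rotation angle ",
         round(aa$angle, 1), " deg < 90)")
  a <- aa$axis
  t <- fit$translation
  screw <- sum(t * a)
  t_perp <- t - screw * a
  # point on the rotation axis: p = t_perp/2 + (a x t_perp)/(2 tan(theta/2))
  half <- rad(aa$angle) / 2
  p <- t_perp / 2 + cross3(a, t_perp) / (2 * tan(half))
  structure(list(point = p, direction = a, angle = aa$angle,
                 screw = screw, fit = fit),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf("dyad axis: angle %.2f deg, direction (%.3f, %.3f, %.3f), screw %.2f A\n",
              x$angle, x$direction[1], x$direction[2], x$direction[3],
              x$screw))
  invisible(x)
}

#' Self-correspondence of the nucleic component under the dimer dyad
#'
#' Rotates all phosphorus atoms of the nucleic-acid chain(s) by
#' exactly 180 degrees about the dyad axis and maps each rotated
#' phosphorus to its nearest original phosphorus, keeping mutual
#' nearest neighbors only.  For a ligand bound symmetrically (e.g. a
#' palindromic duplex) all distances are small; for an asymmetric
#' monomeric ligand the match is poor and degrades towards the chain
#' termini.
#'
#' @param model A `structure_model`.
#' @param chains Nucleic-acid chain identifier(s).
#' @param axis A `symmetry_axis` from [dimer_dyad_axis()].
#' @return List with `table` (per-nucleotide rows sorted by residue
#'   number: nucleotide, mapped counterpart, P-P distance in
#'   Angstroms, `mutual` flag) and `rmsd` (over mutual pairs).
#' @export
rna_self_correspondence <- function(model, chains, axis) {
  if (abs(axis$angle - 180) > 15)
    stop("axis angle ", round(axis$angle, 1),
         " deg is not close to 180: not a dyad")
  sel <- select_atoms(model, chains = chains, atoms = "P",
                      kinds = "nucleotide")
  P <- selection_coords(model, sel)
  if (nrow(P) == 0) stop("no phosphorus atoms in chains ",
                         paste(chains, collapse = ","))
  R <- rotation_about_axis(axis$direction, 180)
  rotated <- sweep(sweep(P, 2, axis$point) %*% t(R), 2, -axis$point)
  D <- cross_distances(rotated, P)
  nn <- apply(D, 1, which.min)
  nn_back <- apply(D, 2, which.min)
  mutual <- nn_back[nn] == seq_along(nn)
  dists <- D[cbind(seq_along(nn), nn)]
  mem <- sel$members
  tab <- data.frame(chain = mem$chain, resno = mem$resno,
                    resid = mem$resid,
                    counterpart_resno = mem$resno[nn],
                    counterpart_resid = mem$resid[nn],
                    pp_distance = dists, mutual = mutual,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$chain, tab$resno), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab,
       rmsd = if (any(mutual)) sqrt(mean(dists[mutual]^2)) else NA_real_)
}
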