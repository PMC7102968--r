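# Shared fixtures and independent oracles.  All randomness is seeded
# inside the helpers so tests are deterministic.

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

random_rotation <- function() quat_to_rot(rnorm(4))

# Any unit vector perpendicular to v.
perp_vector <- function(v) {
  ref <- if (abs(v[3]) < 0.9 * sqrt(sum(v^2))) c(0, 0, 1) else c(1, 0, 0)
  w <- c(v[2] * ref[3] - v[3] * ref[2],
         v[3] * ref[1] - v[1] * ref[3],
         v[1] * ref[2] - v[2] * ref[1])
  w / sqrt(sum(w^2))
}

# Brute-force superposition oracle: search rotation space directly
# (random quaternion starts + derivative-free refinement), translation
# handled by centering.  Independent of the SVD route.
oracle_rmsd <- function(moving, fixed, n_starts = 12) {
  X <- sweep(moving, 2, colMeans(moving))
  Y <- sweep(fixed, 2, colMeans(fixed))
  f <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    q0 <- rnorm(4)
    o <- optim(q0, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    o <- optim(o$par, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    if (o$value < best) best <- o$value
  }
  best
}

# O(n^2) double-loop contact census oracle.
oracle_contact_count <- function(pxyz, pres, nxyz, cutoff) {
  hit_res <- character(0)
  for (i in seq_len(nrow(pxyz))) {
    for (j in seq_len(nrow(nxyz))) {
      if (sqrt(sum((pxyz[i, ] - nxyz[j, ])^2)) <= cutoff) {
        hit_res <- union(hit_res, pres[i])
        break
      }
    }
  }
  length(hit_res)
}

# Random toy protein/nucleic "complex" as a structure_model: atom
# clouds with residue structure (n_res residues x atoms each).
random_toy_complex <- function(n_prot_res = 20, n_nuc_res = 10,
                               atoms_per_res = 5, spread = 12) {
  mk <- function(chain, n_res, resid, kind) {
    n <- n_res * atoms_per_res
    data.frame(chain = chain,
               resno = rep(seq_len(n_res), each = atoms_per_res),
               insert = "", resid = resid,
               elety = paste0("X", rep(seq_len(atoms_per_res), n_res)),
               elesy = sample(c("C", "N", "O"), n, replace = TRUE),
               x = runif(n, 0, spread), y = runif(n, 0, spread),
               z = runif(n, 0, spread), o = 1, b = 0, kind = kind,
               stringsAsFactors = FALSE)
  }
  at <- rbind(mk("P", n_prot_res, "ALA", "amino_acid"),
              mk("N", n_nuc_res, "A", "nucleotide"))
  structure(list(identifier = "toy", source_format = "synthetic",
                 atoms = at), class = "structure_model")
}

# Minimal model from an atom table fragment.
model_from_atoms <- function(atoms, id = "frag") {
  if (is.null(atoms$kind)) atoms$kind <- aptcomplex:::residue_kind(atoms$resid)
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  structure(list(identifier = id, source_format = "synthetic",
                 atoms = atoms), class = "structure_model")
}

atom_row <- function(chain, resno, resid, elety, elesy, x, y, z) {
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z,
             o = 1, b = 0, stringsAsFactors = FALSE)
}

# Rotate all chain-D atoms of a one-pair duplex 180 deg about the
# C1'-C1' axis, then re-optimize the in-plane placement onto the
# reverse-Watson-Crick bond set so the flipped base forms a genuine
# trans pair (bonds N1...N3 and N6...O2 for A:U).
build_trans_au_pair <- function() {
  h <- build_helix(helix_spec("A", form = "A"))
  at <- h$atoms
  iD <- which(at$chain == "D")
  c1i <- as.numeric(at[at$chain == "C" & at$elety == "C1'",
                       c("x", "y", "z")])
  c1j <- as.numeric(at[at$chain == "D" & at$elety == "C1'",
                       c("x", "y", "z")])
  R <- rotation_about_axis(c1j - c1i, 180)
  xyz <- as.matrix(at[iD, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, c1i) %*% t(R), 2, -c1i)
  # in-plane refinement: rigid motion of the flipped base minimizing
  # deviation of the reverse-WC bonds from 2.9 A
  A <- at[at$chain == "C", ]
  Axyz <- as.matrix(A[, c("x", "y", "z")])
  target <- function(par) {
    Rz <- rotation_about_axis(c(0, 0, 1), par[3])
    p <- sweep(sweep(xyz, 2, colMeans(xyz)) %*% t(Rz), 2,
               -(colMeans(xyz) + c(par[1], par[2], 0)))
    nm <- at$elety[iD]
    d1 <- sqrt(sum((as.numeric(A[A$elety == "N1", c("x", "y", "z")]) -
                    p[nm == "N3", ])^2))
    d2 <- sqrt(sum((as.numeric(A[A$elety == "N6", c("x", "y", "z")]) -
                    p[nm == "O2", ])^2))
    D <- aptcomplex:::cross_distances(Axyz, p)
    clash <- sum(pmax(0, 2.6 - D)^2)
    (d1 - 2.9)^2 + (d2 - 2.9)^2 + clash
  }
  o <- NULL
  for (th0 in c(0, -30, 30, -60, 60)) {
    cand <- optim(c(0, 0, th0), target,
                  control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(o) || cand$value < o$value) o <- cand
  }
  Rz <- rotation_about_axis(c(0, 0, 1), o$par[3])
  xyz <- sweep(sweep(xyz, 2, colMeans(xyz)) %*% t(Rz), 2,
               -(colMeans(xyz) + c(o$par[1], o$par[2], 0)))
  at[iD, c("x", "y", "z")] <- xyz
  h$atoms <- at
  h
}

# Path where a locally provided crystallographic deposition would be
# found (the package bundles none; real-structure checks require the
# user to place the files here).
deposited_structure_path <- function(accession) {
  file.path("depositions", paste0(accession, ".cif"))
}
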