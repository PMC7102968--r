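# Synthetic structure generators.  Every downstream module is testable
# without external depositions: ideal A-/B-form nucleic-acid helices
# built from bundled idealized nucleotide templates, C2-symmetric toy
# protein dimers with symmetrically or asymmetrically placed nucleic
# components, and seeded Gaussian coordinate perturbation.
#
# The helix builder targets base geometry (Watson-Crick pairing,
# stacking, helical rise/twist); the sugar-phosphate backbone follows
# each base rigidly and is not torsion-idealized.

.pkg_cache <- new.env(parent = emptyenv())

# Idealized heavy-atom nucleotide templates (standard chemical
# component geometry bundled as plain text).
nucleotide_templates <- function() {
  if (!is.null(.pkg_cache$templates)) return(.pkg_cache$templates)
  path <- system.file("extdata", "nucleotide_templates.tsv",
                      package = "aptcomplex")
  if (path == "") path <- "inst/extdata/nucleotide_templates.tsv"
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  .pkg_cache$templates <- split(tab, tab$res)
  .pkg_cache$templates
}

# Orient a template: base 6-ring in the z = 0 plane (normal +z),
# glycosidic N at the origin, C1' in the z <= 0 ... fixed in-plane
# convention (glycosidic-N -> ring-centroid along +y).
.oriented_template <- function(resid) {
  tpl <- nucleotide_templates()[[resid]]
  if (is.null(tpl)) stop("unknown base: ", resid)
  xyz <- as.matrix(tpl[, c("x", "y", "z")])
  ring <- .RINGS[[resid]][[1]]
  ring_xyz <- xyz[match(ring, tpl$atom), , drop = FALSE]
  pf <- plane_fit(ring_xyz)
  # rotation taking the ring normal to +z
  z <- pf$normal
  ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x1 <- unit_vec(cross3(ref, z))
  y1 <- cross3(z, x1)
  R1 <- rbind(x1, y1, z)              # rows = new basis
  xyz <- xyz %*% t(R1)
  glyc <- .glyc_atoms(resid)[1]
  g <- xyz[match(glyc, tpl$atom), ]
  xyz <- sweep(xyz, 2, g)
  ctr <- colMeans(xyz[match(ring, tpl$atom), , drop = FALSE])
  ang <- atan2(ctr[1], ctr[2])        # rotate so centroid along +y
  Rz <- rotation_about_axis(c(0, 0, 1), deg(ang))
  xyz <- xyz %*% t(Rz)
  list(atom = tpl$atom, element = tpl$element, xyz = xyz, resid = resid)
}

# Watson-Crick hydrogen-bond atom pairs (strand-1 base first).
.WC_BONDS <- list(
  "G|C" = list(c("O6", "N4"), c("N1", "N3"), c("N2", "O2")),
  "A|U" = list(c("N6", "O4"), c("N1", "N3")),
  "A|T" = list(c("N6", "O4"), c("N1", "N3")))
.WC_BONDS[["C|G"]] <- lapply(.WC_BONDS[["G|C"]], rev)
.WC_BONDS[["U|A"]] <- lapply(.WC_BONDS[["A|U"]], rev)
.WC_BONDS[["T|A"]] <- lapply(.WC_BONDS[["A|T"]], rev)

.base_letter <- function(resid) sub("^D", "", resid)

# Geometry of one idealized Watson-Crick pair, in the standard pair
# frame: C1'-C1' midpoint at the origin, C1'(i) -> C1'(j) along +x,
# bases in the z = 0 plane.  Placement of the second base is found by
# deterministic least squares on the canonical hydrogen-bond lengths
# (2.9 A) and the C1'-C1' distance (10.4 A).
.pair_geometry <- function(res_i, res_j) {
  key <- paste(res_i, res_j, sep = "|")
  if (!is.null(.pkg_cache$pairs[[key]])) return(.pkg_cache$pairs[[key]])
  bonds <- .WC_BONDS[[paste(.base_letter(res_i), .base_letter(res_j),
                            sep = "|")]]
  if (is.null(bonds)) stop("no Watson-Crick pairing for ", res_i, ":", res_j)
  t1 <- .oriented_template(res_i)
  t2 <- .oriented_template(res_j)
  # flip base j so the strands are antiparallel (normal -> -z)
  t2$xyz <- t2$xyz %*% t(rotation_about_axis(c(1, 0, 0), 180))
  i1 <- match(vapply(bonds, `[`, character(1), 1), t1$atom)
  i2 <- match(vapply(bonds, `[`, character(1), 2), t2$atom)
  c1_1 <- t1$xyz[match("C1'", t1$atom), ]
  g1 <- t1$xyz[match(.glyc_atoms(res_i)[1], t1$atom), ]
  ang_at <- function(apex, toward, other) {
    deg(acos(max(-1, min(1, sum(unit_vec(toward - apex) *
                                unit_vec(other - apex))))))
  }
  # two in-plane branches satisfy the bond distances; the glycosidic
  # lambda angles (~54.5 deg between each glycosidic bond and the
  # C1'-C1' line) select the Watson-Crick branch
  obj <- function(par) {
    R <- rotation_about_axis(c(0, 0, 1), par[3])
    p2 <- t2$xyz %*% t(R)
    p2[, 1] <- p2[, 1] + par[1]; p2[, 2] <- p2[, 2] + par[2]
    d <- sqrt(rowSums((t1$xyz[i1, , drop = FALSE] -
                       p2[i2, , drop = FALSE])^2))
    c1_2p <- p2[match("C1'", t2$atom), ]
    g2p <- p2[match(.glyc_atoms(res_j)[1], t2$atom), ]
    cc <- sqrt(sum((c1_1 - c1_2p)^2))
    lam1 <- ang_at(c1_1, g1, c1_2p)
    lam2 <- ang_at(c1_2p, g2p, c1_1)
    sum((d - 2.9)^2) + 0.25 * (cc - 10.4)^2 +
      0.02 * ((lam1 - 54.5)^2 + (lam2 - 54.5)^2)
  }
  best <- NULL
  for (th in c(0, 60, 120, 180, 240, 300)) {
    o <- stats::optim(c(6, -3, th), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || o$value < best$value) best <- o
  }
  R <- rotation_about_axis(c(0, 0, 1), best$par[3])
  xyz2 <- t2$xyz %*% t(R)
  xyz2[, 1] <- xyz2[, 1] + best$par[1]
  xyz2[, 2] <- xyz2[, 2] + best$par[2]
  # standard pair frame
  a <- c1_1
  b <- xyz2[match("C1'", t2$atom), ]
  mid <- (a + b) / 2
  xax <- unit_vec(b - a)
  zax <- c(0, 0, 1)
  xax <- unit_vec(xax - sum(xax * zax) * zax)
  yax <- cross3(zax, xax)
  M <- rbind(xax, yax, zax)
  g1 <- list(atom = t1$atom, element = t1$element,
             xyz = sweep(t1$xyz, 2, mid) %*% t(M), resid = res_i)
  g2 <- list(atom = t2$atom, element = t2$element,
             xyz = sweep(xyz2, 2, mid) %*% t(M), resid = res_j)
  out <- list(base_i = g1, base_j = g2, objective = best$value)
  if (is.null(.pkg_cache$pairs)) .pkg_cache$pairs <- list()
  .pkg_cache$pairs[[key]] <- out
  out
}

.complement_base <- function(resid) {
  comp <- .COMPLEMENT[[resid]]
  if (is.null(comp)) stop("unknown base letter: ", resid)
  comp
}

.seq_to_resids <- function(sequence, dna = FALSE) {
  letters <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(letters, c("A", "C", "G", "U", "T"))
  if (length(bad) > 0)
    stop("unknown base letter(s): ", paste(unique(bad), collapse = ", "))
  if (dna || any(letters == "T")) paste0("D", sub("U", "T", letters))
  else letters
}

#' Specification for an ideal nucleic-acid helix
#'
#' Default fiber parameters: rise 2.81 A / twist 32.7 deg for A-form,
#' rise 3.38 A / twist 36.0 deg for B-form.
#'
#' @param sequence Strand-1 sequence, 5' to 3' (letters ACGU, or ACGT
#'   for DNA).
#' @param form `"A"` or `"B"`.
#' @param duplex Build the Watson-Crick complementary strand too?
#' @param dna Force DNA residue types (implied by `T` in the
#'   sequence; B-form defaults to DNA).
#' @param rise,twist Override the form defaults (Angstroms / degrees
#'   per step).
#' @return A `helix_spec` list.
#' @export
helix_spec <- function(sequence, form = c("A", "B"), duplex = TRUE,
                       dna = NULL, rise = NULL, twist = NULL) {
  form <- match.arg(form)
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  if (is.null(dna)) dna <- form == "B" || grepl("T", toupper(sequence))
  if (is.null(rise)) rise <- if (form == "A") 2.81 else 3.38
  if (is.null(twist)) twist <- if (form == "A") 32.7 else 36.0
  structure(list(sequence = toupper(sequence), form = form,
                 duplex = duplex, dna = dna, rise = rise, twist = twist),
            class = "helix_spec")
}

#' Build an idealized helical nucleic acid
#'
#' Places idealized Watson-Crick base pairs (or single nucleotides)
#' along a straight helix axis (+z) with the requested rise and
#' twist.  Strand 1 is chain `"C"` (residues 1..n, 5' to 3'); the
#' complementary strand, if built, is chain `"D"` with reversed
#' numbering so that base i pairs with base n - i + 1.
#'
#' @param spec A [helix_spec()].
#' @return A `structure_model`.
#' @export
build_helix <- function(spec) {
  resids <- .seq_to_resids(spec$sequence, spec$dna)
  n <- length(resids)
  rows <- list()
  add_res <- function(g, chain, resno, xyz) {
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = g$resid,
      elety = g$atom, elesy = g$element,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    comp <- .complement_base(resids[k])
    pg <- .pair_geometry(resids[k], comp)
    Rz <- rotation_about_axis(c(0, 0, 1), (k - 1) * spec$twist)
    shift <- c(0, 0, (k - 1) * spec$rise)
    x1 <- sweep(pg$base_i$xyz %*% t(Rz), 2, -shift)
    add_res(pg$base_i, "C", k, x1)
    if (spec$duplex) {
      x2 <- sweep(pg$base_j$xyz %*% t(Rz), 2, -shift)
      add_res(pg$base_j, "D", n - k + 1, x2)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(match(atoms$chain, c("C", "D")), atoms$resno), ]
  rownames(atoms) <- NULL
  atoms$kind <- residue_kind(atoms$resid)
  structure(list(identifier = paste0("helix_", spec$form, "_",
                                     spec$sequence),
                 source_format = "synthetic", atoms = atoms),
            class = "structure_model")
}

# CA-only three-helix mini-domain protomer (36 residues, poly-Ala);
# synthetic stand-in for a small nucleic-acid-binding domain.
.protomer_atoms <- function(chain = "A") {
  ca_helix <- function(nres, origin, direction) {
    ax <- unit_vec(direction)
    ref <- if (abs(ax[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- unit_vec(cross3(ax, ref)); v <- cross3(ax, u)
    t(vapply(seq_len(nres) - 1, function(i)
      origin + 1.5 * i * ax + 2.3 * (cos(rad(100 * i)) * u +
                                     sin(rad(100 * i)) * v),
      numeric(3)))
  }
  xyz <- rbind(ca_helix(12, c(0, 0, 0), c(0, 0, 1)),
               ca_helix(12, c(9, 0, 16.5), c(0, 0, -1)),
               ca_helix(12, c(4.5, 7, 0), c(0, 0.15, 1)))
  data.frame(chain = chain, resno = 1:36, insert = "", resid = "ALA",
             elety = "CA", elesy = "C",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             kind = "amino_acid", stringsAsFactors = FALSE)
}

# Rigid transform applied to an atom data frame.
.df_transform <- function(at, R, t = c(0, 0, 0)) {
  xyz <- apply_rigid(as.matrix(at[, c("x", "y", "z")]), R, t)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  at
}

# Internal dyad of an ideal duplex: superpose strand-1 P atoms onto
# reversed strand-2 P atoms and decompose the rotation.
.duplex_dyad <- function(duplex) {
  p1 <- selection_coords(duplex, select_atoms(duplex, "C", atoms = "P"))
  p2 <- selection_coords(duplex, select_atoms(duplex, "D", atoms = "P"))
  fit <- kabsch_superpose(p1, p2)
  aa <- rotation_axis_angle(fit$rotation)
  t <- fit$translation
  screw <- sum(t * aa$axis)
  t_perp <- t - screw * aa$axis
  point <- t_perp / 2 + cross3(aa$axis, t_perp) / (2 * tan(rad(aa$angle) / 2))
  list(axis = aa$axis, angle = aa$angle, point = point)
}

#' Specification for a C2 toy complex
#'
#' @param nucleic_sequence Sequence of the nucleic component (strand 1
#'   of a duplex in `symmetric`/`offset` modes; the full single
#'   strand in `monomeric_L` mode).  Symmetric mode requires a
#'   self-complementary (palindromic) duplex for residue-identity
#'   symmetry; geometric P-atom symmetry holds for any sequence.
#' @param mode `"symmetric"`, `"offset"` or `"monomeric_L"`.
#' @param form Helix form of the nucleic component.
#' @param offset Lateral displacement (Angstroms) applied in `offset`
#'   mode.
#' @return A `toy_complex_spec` list.
#' @export
toy_complex_spec <- function(nucleic_sequence = "GGAUCC",
                             mode = c("symmetric", "offset", "monomeric_L"),
                             form = "A", offset = 3) {
  mode <- match.arg(mode)
  structure(list(nucleic_sequence = nucleic_sequence, mode = mode,
                 form = form, offset = offset),
            class = "toy_complex_spec")
}

#' Build a C2-symmetric toy dimer-nucleic-acid complex
#'
#' Two copies of a synthetic three-helix protomer exactly related by a
#' 180-degree rotation about the z axis (the dyad), plus a nucleic
#' component: a duplex whose internal pseudo-dyad is aligned with the
#' protein dyad (`symmetric`), the same duplex displaced off the dyad
#' (`offset`), or a bent single-stranded L-shaped chain that breaks
#' the symmetry (`monomeric_L`).
#'
#' @param spec A [toy_complex_spec()].
#' @return A `structure_model` with protein chains `"A"`/`"B"` and
#'   nucleic chains `"C"` (and `"D"` for duplexes).
#' @export
build_c2_complex <- function(spec) {
  protA <- .protomer_atoms("A")
  protA <- .df_transform(protA, diag(3), c(12, 16, -10))
  protB <- .df_transform(protA, rotation_about_axis(c(0, 0, 1), 180))
  protB$chain <- "B"
  if (spec$mode %in% c("symmetric", "offset")) {
    duplex <- build_helix(helix_spec(spec$nucleic_sequence,
                                     form = spec$form))
    dy <- .duplex_dyad(duplex)
    # move the duplex's internal dyad onto the z axis
    z <- unit_vec(dy$axis)
    ref <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u <- unit_vec(cross3(ref, z)); v <- cross3(z, u)
    M <- rbind(u, v, z)               # rotation: dyad axis -> +z
    nuc <- duplex$atoms
    xyz <- sweep(as.matrix(nuc[, c("x", "y", "z")]), 2, dy$point) %*% t(M)
    nuc$x <- xyz[, 1]; nuc$y <- xyz[, 2]; nuc$z <- xyz[, 3]
    if (spec$mode == "offset") nuc$x <- nuc$x + spec$offset
  } else {
    n <- nchar(spec$nucleic_sequence)
    n1 <- ceiling(n / 2)
    arm1 <- build_helix(helix_spec(substr(spec$nucleic_sequence, 1, n1),
                                   form = spec$form, duplex = FALSE))
    arm2 <- build_helix(helix_spec(substr(spec$nucleic_sequence, n1 + 1, n),
                                   form = spec$form, duplex = FALSE))
    a1 <- arm1$atoms
    a2 <- .df_transform(arm2$atoms, rotation_about_axis(c(0, 1, 0), 90),
                        c(6, 3, (n1 - 1) * 2.81 + 3))
    a2$resno <- a2$resno + n1
    nuc <- rbind(a1, a2)
    nuc$chain <- "C"
  }
  atoms <- rbind(protA, protB, nuc)
  rownames(atoms) <- NULL
  model <- structure(list(identifier = paste0("c2_complex_", spec$mode),
                          source_format = "synthetic", atoms = atoms),
                     class = "structure_model")
  assert_no_clash(model)
  model
}

# Error if any protein atom lies within 1.5 A of any nucleic atom.
assert_no_clash <- function(model, min_dist = 1.5) {
  at <- model$atoms
  prot_xyz <- as.matrix(at[at$kind == "amino_acid", c("x", "y", "z")])
  nuc_xyz <- as.matrix(at[at$kind == "nucleotide", c("x", "y", "z")])
  if (nrow(prot_xyz) && nrow(nuc_xyz) &&
      min(cross_distances(prot_xyz, nuc_xyz)) < min_dist)
    stop("clashing placement: interatomic distance < ", min_dist,
         " A between components")
  invisible(model)
}

#' Perturb a structure with isotropic Gaussian noise
#'
#' @param model A `structure_model`.
#' @param sigma Per-coordinate displacement s.d. (Angstroms); 0 is the
#'   identity.
#' @param seed Integer seed (deterministic output).
#' @param chains Restrict the perturbation to these chains.
#' @return The perturbed `structure_model`.
#' @export
perturb_structure <- function(model, sigma, seed = 1, chains = NULL) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(model)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  rows <- if (is.null(chains)) seq_len(nrow(model$atoms))
  else which(model$atoms$chain %in% chains)
  noise <- matrix(stats::rnorm(3 * length(rows), 0, sigma),
                  ncol = 3)
  model$atoms$x[rows] <- model$atoms$x[rows] + noise[, 1]
  model$atoms$y[rows] <- model$atoms$y[rows] + noise[, 2]
  model$atoms$z[rows] <- model$atoms$z[rows] + noise[, 3]
  model
}
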