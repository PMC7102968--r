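two_atom_complex <- function(d) {
  at <- rbind(atom_row("P", 1, "ALA", "CB", "C", 0, 0, 0),
              atom_row("N", 1, "A", "C2", "C", d, 0, 0))
  model_from_atoms(at)
}

test_that("contact census respects the cutoff boundary", {
  m <- two_atom_complex(3.6)
  ps <- select_atoms(m, "P"); ns <- select_atoms(m, "N")
  expect_equal(find_contact_residues(m, ps, ns, 3.7)$n_residues, 1)
  expect_equal(find_contact_residues(m, ps, ns, 3.5)$n_residues, 0)
  expect_error(find_contact_residues(m, ps, ns, -1), "positive")
})

test_that("census equals the all-pairs brute-force oracle on random toys", {
  set.seed(101)
  for (case in 1:50) {
    m <- random_toy_complex()
    ps <- select_atoms(m, "P"); ns <- select_atoms(m, "N")
    fast <- find_contact_residues(m, ps, ns, 3.7)$n_residues
    pa <- aptcomplex:::.sel_table(m, ps)
    na <- aptcomplex:::.sel_table(m, ns)
    slow <- oracle_contact_count(as.matrix(pa[, c("x", "y", "z")]),
                                 paste(pa$chain, pa$resno),
                                 as.matrix(na[, c("x", "y", "z")]), 3.7)
    expect_equal(fast, slow)
  }
})

test_that("SASA matches closed forms for isolated and overlapping spheres", {
  # isolated atom: exact sphere
  a <- solvent_accessible_area(matrix(0, 1, 3), "C")
  expect_equal(a, 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)
  # two distant atoms: additivity
  a2 <- solvent_accessible_area(rbind(c(0, 0, 0), c(50, 0, 0)),
                                c("C", "N"))
  expect_equal(a2[1], 4 * pi * (1.70 + 1.4)^2, tolerance = 0.005)
  expect_equal(a2[2], 4 * pi * (1.55 + 1.4)^2, tolerance = 0.005)
  # two overlapping equal spheres: spherical-cap closed form
  R <- 1.70 + 1.4
  for (d in c(1.5, 2.5, 4.0)) {
    a3 <- solvent_accessible_area(rbind(c(0, 0, 0), c(d, 0, 0)),
                                  c("C", "C"))
    exact <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
    expect_equal(a3[1], exact, tolerance = 0.005)
    expect_equal(a3[2], exact, tolerance = 0.005)
  }
  expect_error(solvent_accessible_area(matrix(0, 1, 3), "Xx"), "radius")
})

test_that("doubling SASA sphere points changes areas by < 1%", {
  m <- build_helix(helix_spec("GAUC", form = "A"))
  xyz <- selection_coords(m)
  el <- m$atoms$elesy
  a1 <- sum(solvent_accessible_area(xyz, el, n_points = 960))
  a2 <- sum(solvent_accessible_area(xyz, el, n_points = 1920))
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("buried area is zero for separated components and symmetric for C2", {
  m <- build_c2_complex(toy_complex_spec("GGAUCC"))
  ps <- select_atoms(m, c("A", "B")); ns <- select_atoms(m, c("C", "D"))
  doms <- list(A = select_atoms(m, "A"), B = select_atoms(m, "B"))
  b <- buried_area_decomposition(m, ps, ns, doms)
  expect_equal(unname(b$per_domain), c(0, 0), tolerance = 1e-9)
  # move the nucleic component into contact, symmetrically on the dyad
  m2 <- m
  idx <- m2$atoms$chain %in% c("C", "D")
  # nucleic sits on the z axis; protein protomers at +/- (x, y): shift
  # the protein chains towards the axis until the surfaces touch
  for (ch in c("A", "B")) {
    rows <- m2$atoms$chain == ch
    ctr <- colMeans(as.matrix(m2$atoms[rows, c("x", "y", "z")]))
    pull <- -0.72 * ctr * c(1, 1, 0)
    m2$atoms[rows, c("x", "y", "z")] <-
      sweep(as.matrix(m2$atoms[rows, c("x", "y", "z")]), 2, -pull)
  }
  ps2 <- select_atoms(m2, c("A", "B")); ns2 <- select_atoms(m2, c("C", "D"))
  doms2 <- list(A = select_atoms(m2, "A"), B = select_atoms(m2, "B"))
  b2 <- buried_area_decomposition(m2, ps2, ns2, doms2)
  expect_gt(b2$total, 10)
  expect_equal(b2$per_domain[["A"]], b2$per_domain[["B"]],
               tolerance = 0.01 * max(b2$per_domain))
  expect_equal(b2$total, sum(b2$per_domain), tolerance = 0.5)
  # monotone non-increasing when pulled apart
  m3 <- m2
  rows3 <- m3$atoms$chain %in% c("C", "D")
  m3$atoms[rows3, "z"] <- m3$atoms[rows3, "z"] + 25
  b3 <- buried_area_decomposition(m3, select_atoms(m3, c("A", "B")),
                                  select_atoms(m3, c("C", "D")),
                                  list(A = select_atoms(m3, "A"),
                                       B = select_atoms(m3, "B")))
  expect_lte(b3$total, b2$total + 1e-6)
  expect_error(buried_area_decomposition(m2, ps2, ns2,
                                         list(A = ps2, B = doms2$B)),
               "overlap")
})

test_that("census and buried areas are invariant under rigid motion", {
  m <- build_c2_complex(toy_complex_spec("GGAUCC"))
  for (ch in c("A", "B")) {
    rows <- m$atoms$chain == ch
    ctr <- colMeans(as.matrix(m$atoms[rows, c("x", "y", "z")]))
    m$atoms[rows, c("x", "y", "z")] <-
      sweep(as.matrix(m$atoms[rows, c("x", "y", "z")]), 2, 0.72 * ctr * c(1, 1, 0))
  }
  mR <- aptcomplex:::transform_model(m, rotation_about_axis(c(1, 2, 3), 77),
                                     c(5, -8, 2))
  census <- function(mod) {
    find_contact_residues(mod, select_atoms(mod, c("A", "B")),
                          select_atoms(mod, c("C", "D")), 3.7)$n_residues
  }
  area <- function(mod) {
    buried_area_decomposition(mod, select_atoms(mod, c("A", "B")),
                              select_atoms(mod, c("C", "D")),
                              list(A = select_atoms(mod, "A"),
                                   B = select_atoms(mod, "B")))$total
  }
  expect_equal(census(m), census(mR))
  expect_equal(area(m), area(mR), tolerance = 0.01 * max(area(m), 1))
})

test_that("hydrogen bonds pass and fail the distance/angle gates", {
  # idealized N-H...O=C: backbone N donor with CA antecedent at 160 deg
  mk <- function(d, ang_deg) {
    # place the acceptor so that angle(CA, N, O) = ang_deg, with CA on +x
    acc <- c(d * cos(rad(ang_deg)), d * sin(rad(ang_deg)), 0)
    at <- rbind(atom_row("P", 1, "GLY", "N", "N", 0, 0, 0),
                atom_row("P", 1, "GLY", "CA", "C", 1.46, 0, 0),
                atom_row("N", 5, "A", "OP1", "O",
                         acc[1], acc[2], acc[3]))
    model_from_atoms(at)
  }
  rad <- function(x) x * pi / 180
  m <- mk(2.9, 160)
  hb <- detect_hydrogen_bonds(m, select_atoms(m, "P"), select_atoms(m, "N"))
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_gt(hb$antecedent_angle, 150)
  # too long
  expect_equal(nrow(detect_hydrogen_bonds(mk(4.0, 160),
                                          select_atoms(mk(4.0, 160), "P"),
                                          select_atoms(mk(4.0, 160), "N"))), 0)
  # bad antecedent angle
  m3 <- mk(2.9, 45)
  expect_equal(nrow(detect_hydrogen_bonds(m3, select_atoms(m3, "P"),
                                          select_atoms(m3, "N"))), 0)
})

test_that("bidentate donor pairs are grouped per residue pair", {
  # arginine guanidinium donating to a guanine Hoogsteen edge (O6, N7)
  at <- rbind(atom_row("P", 28, "ARG", "CZ", "C", 0, 0, 0),
              atom_row("P", 28, "ARG", "NH1", "N", 1.33 * cos(pi / 6),
                       1.33 * sin(pi / 6), 0),
              atom_row("P", 28, "ARG", "NH2", "N", 1.33 * cos(-pi / 6),
                       1.33 * sin(-pi / 6), 0),
              atom_row("N", 31, "G", "O6", "O", 1.33 * cos(pi / 6) + 2.9,
                       1.33 * sin(pi / 6) + 0.4, 0),
              atom_row("N", 31, "G", "N7", "N", 1.33 * cos(-pi / 6) + 2.9,
                       1.33 * sin(-pi / 6) - 0.4, 0))
  m <- model_from_atoms(at)
  hb <- detect_hydrogen_bonds(m, select_atoms(m, "P"), select_atoms(m, "N"))
  expect_gte(nrow(hb), 2)
  expect_true(any(grepl("28", attr(hb, "bidentate"))))
})

test_that("ring stacking requires near-parallel planes at short range", {
  ring6 <- function(chain, resno, resid, z, names, tilt = 0) {
    th <- seq(0, 300, by = 60) * pi / 180
    xyz <- cbind(1.39 * cos(th), 1.39 * sin(th), z)
    if (tilt != 0) {
      R <- rotation_about_axis(c(1, 0, 0), tilt)
      xyz <- sweep(xyz, 2, c(0, 0, z)) %*% t(R)
      xyz <- sweep(xyz, 2, -c(0, 0, z))
    }
    do.call(rbind, lapply(seq_along(names), function(i)
      atom_row(chain, resno, resid, names[i],
               substr(names[i], 1, 1), xyz[i, 1], xyz[i, 2], xyz[i, 3])))
  }
  tyr <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ura <- c("N1", "C2", "N3", "C4", "C5", "C6")
  m <- model_from_atoms(rbind(ring6("P", 42, "TYR", 0, tyr),
                              ring6("N", 16, "U", 3.5, ura)))
  hits <- detect_ring_interactions(m, select_atoms(m, "P"),
                                   select_atoms(m, "N"))
  expect_equal(nrow(hits[hits$type == "stacking", ]), 1)
  expect_lt(hits$angle[1], 1)
  # perpendicular rings: no stacking
  m2 <- model_from_atoms(rbind(ring6("P", 42, "TYR", 0, tyr),
                               ring6("N", 16, "U", 3.5, ura, tilt = 90)))
  hits2 <- detect_ring_interactions(m2, select_atoms(m2, "P"),
                                    select_atoms(m2, "N"))
  expect_equal(nrow(hits2[hits2$type == "stacking", ]), 0)
})

test_that("cation-pi detection respects distance and off-normal angle", {
  ade <- function(z, dx = 0) {
    th <- seq(0, 300, by = 60) * pi / 180
    names <- c("N1", "C2", "N3", "C4", "C5", "C6")
    do.call(rbind, lapply(seq_along(names), function(i)
      atom_row("N", 15, "A", names[i], substr(names[i], 1, 1),
               1.39 * cos(th[i]) + dx, 1.39 * sin(th[i]), z)))
  }
  lys_nz <- function(x, y, z) atom_row("P", 10, "LYS", "NZ", "N", x, y, z)
  # on-axis at 4 A: hit
  m <- model_from_atoms(rbind(lys_nz(0, 0, 4), ade(0)))
  h <- detect_ring_interactions(m, select_atoms(m, "P"), select_atoms(m, "N"))
  expect_equal(nrow(h[h$type == "cation_pi", ]), 1)
  # in-plane at 4 A: off-normal angle 90 deg, no hit
  m2 <- model_from_atoms(rbind(lys_nz(4, 0, 0), ade(0)))
  h2 <- detect_ring_interactions(m2, select_atoms(m2, "P"),
                                 select_atoms(m2, "N"))
  expect_equal(nrow(h2[h2$type == "cation_pi", ]), 0)
  # on-axis but 7 A away: no hit
  m3 <- model_from_atoms(rbind(lys_nz(0, 0, 7), ade(0)))
  h3 <- detect_ring_interactions(m3, select_atoms(m3, "P"),
                                 select_atoms(m3, "N"))
  expect_equal(nrow(h3[h3$type == "cation_pi", ]), 0)
})
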