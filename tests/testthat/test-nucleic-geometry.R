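test_that("dihedral angle handles trans, sign and mirror symmetry", {
  p1 <- c(1, 1, 0); p2 <- c(1, 0, 0); p3 <- c(2, 0, 0); p4 <- c(2, -1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, p4), 180)
  p4b <- c(2, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, p4b), 0)
  set.seed(5)
  for (i in 1:20) {
    pts <- lapply(1:4, function(...) rnorm(3))
    a <- do.call(dihedral_angle, pts)
    mirr <- lapply(pts, function(p) p * c(1, 1, -1))
    b <- do.call(dihedral_angle, mirr)
    expect_equal(b, -a, tolerance = 1e-9)
  }
})

test_that("backbone torsions are rigid-motion invariant and mirror-negated", {
  h <- build_helix(helix_spec("GAUCG", form = "A", duplex = FALSE))
  t1 <- backbone_torsions(h, "C")
  hR <- aptcomplex:::transform_model(h, rotation_about_axis(c(2, 1, 5), 63),
                                     c(3, 3, -9))
  t2 <- backbone_torsions(hR, "C")
  cols <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "chi")
  for (cn in cols)
    expect_equal(t2[[cn]], t1[[cn]], tolerance = 1e-6)
  hM <- h
  hM$atoms$z <- -hM$atoms$z
  t3 <- backbone_torsions(hM, "C")
  for (cn in cols)
    expect_equal(t3[[cn]], -t1[[cn]], tolerance = 1e-6)
})

test_that("torsions needing unmodeled neighbors are undefined, not zero", {
  h <- build_helix(helix_spec("GAUCG", form = "A", duplex = FALSE))
  # remove residue 3: residues 2 and 4 lose their inter-residue torsions
  h$atoms <- h$atoms[h$atoms$resno != 3, ]
  t <- backbone_torsions(h, "C")
  expect_true(is.na(t$epsilon[t$resno == 2]))
  expect_true(is.na(t$zeta[t$resno == 2]))
  expect_true(is.na(t$alpha[t$resno == 4]))
  expect_false(is.na(t$chi[t$resno == 4]))
})

test_that("glycosidic classification splits at chi = +/-90", {
  h <- build_helix(helix_spec("G", form = "A", duplex = FALSE))
  t <- backbone_torsions(h, "C")
  expect_equal(t$glycosidic, "anti")   # idealized nucleotides are anti
  # rotate the base about the glycosidic bond to force syn
  at <- h$atoms
  base_atoms <- c("N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2",
                  "N3", "C4")
  c1 <- as.numeric(at[at$elety == "C1'", c("x", "y", "z")])
  n9 <- as.numeric(at[at$elety == "N9", c("x", "y", "z")])
  R <- rotation_about_axis(n9 - c1, 180)
  rows <- at$elety %in% base_atoms
  xyz <- as.matrix(at[rows, c("x", "y", "z")])
  at[rows, c("x", "y", "z")] <- sweep(sweep(xyz, 2, c1) %*% t(R), 2, -c1)
  hs <- h; hs$atoms <- at
  ts <- backbone_torsions(hs, "C")
  expect_equal(ts$glycosidic, "syn")
  expect_lte(abs(ts$chi), 90)
})

test_that("ideal duplexes give canonical cis WC/WC pairs for all bases", {
  h <- build_helix(helix_spec("GAUCGAUC", form = "A"))
  bp <- detect_base_pairs(h)
  expect_equal(nrow(bp), 8)
  expect_true(all(bp$canonical))
  expect_true(all(bp$orientation == "cis"))
  expect_true(all(bp$edge_i == "WatsonCrick" & bp$edge_j == "WatsonCrick"))
  # reported once with lower (chain, resno) first
  expect_true(all(bp$chain_i <= bp$chain_j))
  hB <- build_helix(helix_spec("GCATGCAT", form = "B"))
  bpB <- detect_base_pairs(hB)
  expect_equal(sum(bpB$canonical), 8)
})

test_that("a constructed 180-degree flipped base classifies as trans", {
  h <- build_trans_au_pair()
  bp <- detect_base_pairs(h)
  expect_equal(nrow(bp), 1)
  expect_equal(bp$orientation, "trans")
  expect_false(bp$canonical)
})

test_that("pair orientation flips when one glycosidic bond is mirrored", {
  h <- build_helix(helix_spec("G", form = "A"))
  res <- data.frame(chain = c("C", "D"), resno = c(1, 1), insert = "",
                    resid = c("G", "C"), stringsAsFactors = FALSE)
  expect_equal(aptcomplex:::.pair_orientation(h, res[1, ], res[2, ]), "cis")
  # rotate the whole D nucleotide 180 deg about the C1'-C1' axis
  at <- h$atoms
  iD <- which(at$chain == "D")
  c1i <- as.numeric(at[at$chain == "C" & at$elety == "C1'", c("x", "y", "z")])
  c1j <- as.numeric(at[at$chain == "D" & at$elety == "C1'", c("x", "y", "z")])
  R <- rotation_about_axis(c1j - c1i, 180)
  xyz <- as.matrix(at[iD, c("x", "y", "z")])
  at[iD, c("x", "y", "z")] <- sweep(sweep(xyz, 2, c1i) %*% t(R), 2, -c1i)
  hf <- h; hf$atoms <- at
  expect_equal(aptcomplex:::.pair_orientation(hf, res[1, ], res[2, ]),
               "trans")
})

test_that("stacking runs cover ideal strands and flag constructed flips", {
  h <- build_helix(helix_spec("AAAAAAAA", form = "A", duplex = FALSE))
  s <- stacking_runs_and_flips(h, "C")
  expect_equal(s$runs, list(1:8))
  expect_false(any(s$flipped$flipped_out))
  # rotate base 4 away about its backbone: runs split, base 4 flipped
  at <- h$atoms
  base_atoms <- c("N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4")
  rows <- at$resno == 4 & at$elety %in% base_atoms
  c1 <- as.numeric(at[at$resno == 4 & at$elety == "C1'", c("x", "y", "z")])
  n9 <- as.numeric(at[at$resno == 4 & at$elety == "N9", c("x", "y", "z")])
  R <- rotation_about_axis(perp_vector(n9 - c1), 120)
  xyz <- as.matrix(at[rows, c("x", "y", "z")])
  at[rows, c("x", "y", "z")] <- sweep(sweep(xyz, 2, c1) %*% t(R), 2, -c1)
  h2 <- h; h2$atoms <- at
  s2 <- stacking_runs_and_flips(h2, "C")
  expect_equal(s2$runs, list(1:3, 5:8))
  expect_equal(s2$flipped$resno[s2$flipped$flipped_out], 4)
})

test_that("helix form calls match the builder parameters", {
  hA <- build_helix(helix_spec("GGGGGGGG", form = "A"))
  bpA <- detect_base_pairs(hA)
  fA <- helix_form(hA, bpA[order(bpA$resno_i), ])
  expect_equal(fA$form, "A")
  expect_equal(fA$mean_rise, 2.81, tolerance = 0.02)
  expect_equal(fA$mean_twist, 32.7, tolerance = 0.2)
  hB <- build_helix(helix_spec("GCGCGCGC", form = "B"))
  bpB <- detect_base_pairs(hB)
  fB <- helix_form(hB, bpB[order(bpB$resno_i), ])
  expect_equal(fB$form, "B")
  expect_equal(fB$mean_rise, 3.38, tolerance = 0.02)
  expect_equal(fB$mean_twist, 36.0, tolerance = 0.2)
  # distorted geometry is neither A nor B
  hI <- build_helix(helix_spec("GGGGGGGG", form = "A", rise = 4.2,
                               twist = 20))
  bpI <- detect_base_pairs(hI)
  expect_equal(helix_form(hI, bpI[order(bpI$resno_i), ])$form, "irregular")
  expect_error(helix_form(hA, bpA[1:2, ]), "at least 3")
})
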