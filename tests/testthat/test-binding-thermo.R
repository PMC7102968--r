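# Tabulated calorimetric rows (dissociation constant in nM, dH kJ/mol,
# dS J/mol/K) with the published derived columns (-TdS and dG, kJ/mol)
# used as fixed reference values.
thermo_rows <- data.frame(
  id = c("rna_wt", "rna_q38a", "rna_y42a", "dna_wt", "dna_q38a"),
  K_d = c(5.6, 26.2, 13.9e3, 51.1, 432.7),
  n = c(0.96, 1.10, 1, 1.17, 1.11),
  dH = c(-156.0, -152.8, -74.6, 57.7, 53.4),
  dS = c(-365.2, -367.2, -157.1, 336.4, 300.9),
  minus_TdS_printed = c(108.8, 109.4, 46.8, -100.2, -89.7),
  dG_printed = c(-47.2, -43.4, -27.8, -42.5, -36.3),
  stringsAsFactors = FALSE)

test_that("dG from K_d vanishes at K_d = 1 M and is monotone", {
  expect_equal(derive_thermo(binding_parameters(1, dH = 0, dS = 0))$dG_from_Kd, 0)
  kds <- 10^seq(-12, -3, by = 1)
  dgs <- vapply(kds, function(k)
    derive_thermo(binding_parameters(k, dH = 0, dS = 0))$dG_from_Kd,
    numeric(1))
  expect_true(all(diff(dgs) > 0))
  expect_error(derive_thermo(binding_parameters(1e-9, dH = 1, dS = 1,
                                                T_K = -1)), "positive")
  expect_error(binding_parameters(-1e-9), "positive")
})

test_that("derived -TdS and dG reproduce every tabulated row at 298 K", {
  for (i in seq_len(nrow(thermo_rows))) {
    r <- thermo_rows[i, ]
    d <- derive_thermo(binding_parameters(r$K_d * 1e-9, r$n, r$dH, r$dS))
    expect_lt(abs(d$minus_TdS - r$minus_TdS_printed), 0.15)
    expect_lt(abs(d$dG - r$dG_printed), 0.15)
  }
  # spot values for the wild-type rows
  d_rna <- derive_thermo(binding_parameters(5.6e-9, 0.96, -156.0, -365.2))
  expect_equal(d_rna$TdS, -108.8, tolerance = 0.001)
  expect_equal(d_rna$dG, -47.2, tolerance = 0.002)
  d_dna <- derive_thermo(binding_parameters(51.1e-9, 1.17, 57.7, 336.4))
  expect_equal(d_dna$minus_TdS, -100.2, tolerance = 0.001)
  expect_equal(d_dna$dG, -42.5, tolerance = 0.002)
  # the two dG routes may disagree by K_d rounding; the residual is
  # reported, not hidden
  expect_true(is.finite(d_dna$residual))
})

test_that("fold changes reproduce two-significant-figure presentation", {
  f1 <- fold_change(432.7, 51.1)
  expect_equal(f1$ratio, 8.468, tolerance = 1e-3)
  expect_equal(f1$presentation, "8.5-fold")
  f2 <- fold_change(13900, 5.6)
  expect_equal(f2$ratio, 2482, tolerance = 0.5)
  expect_equal(f2$presentation, "2500-fold")
  expect_equal(fold_change(7, 7)$ratio, 1)
  expect_error(fold_change(-1, 2), "positive")
})

test_that("simulated heats vanish at dH = 0 and obey the tight-binding limit", {
  p0 <- binding_parameters(1e-9, 1, dH = 0, dS = 0)
  expect_true(all(simulate_itc(p0)$heats == 0))
  # titrant limiting, K_d -> 0: total heat = dH x injected titrant moles
  prot <- itc_protocol(cell_conc = 1e-3, syringe_conc = 15e-6)
  p <- binding_parameters(1e-13, 1, dH = -100, dS = 0)
  sim <- simulate_itc(p, prot)
  injected_mol <- 15e-6 * sum(prot$injection_volumes_uL) * 1e-6
  expect_equal(sum(sim$heats), -100e3 * injected_mol * 1e6,
               tolerance = 1e-3 * abs(-100e3 * injected_mol * 1e6))
})

test_that("the standard protocol yields a sigmoid with equivalence near 1", {
  p <- binding_parameters(5.6e-9, 1, dH = -156.0, dS = -365.2)
  sim <- simulate_itc(p)
  q <- sim$heats[-1]
  ratio <- sim$molar_ratio[-1]
  # large early heats, small late heats
  expect_gt(abs(q[1]), 10 * abs(q[length(q)]))
  # steepest drop close to molar ratio 1
  eq <- ratio[which.max(abs(diff(q)))]
  expect_gt(eq, 0.8); expect_lt(eq, 1.2)
  expect_false(sim$saturation_warning)
  # under-filled syringe triggers the saturation warning
  weak <- simulate_itc(p, itc_protocol(syringe_conc = 10e-6))
  expect_true(weak$saturation_warning)
})

test_that("simulate -> fit is the identity at zero noise", {
  p <- binding_parameters(5.6e-9, 0.96, dH = -156.0, dS = -365.2)
  fit <- fit_itc(simulate_itc(p))
  expect_equal(fit$K_d, 5.6e-9, tolerance = 0.001 * 5.6e-9)
  expect_equal(fit$dH, -156.0, tolerance = 0.001 * 156)
  expect_equal(fit$n, 0.96, tolerance = 0.001)
  # derived dS is consistent with the generating value
  expect_equal(fit$dS, -365.2, tolerance = 0.5)
})

test_that("sub-unity stoichiometry is recovered", {
  p <- binding_parameters(5.6e-9, 0.96, dH = -156.0, dS = -365.2)
  sim <- simulate_itc(p, noise_sd = 0.5, seed = 17)
  fit <- fit_itc(sim)
  expect_equal(fit$n, 0.96, tolerance = 0.02)
})

test_that("median fitted K_d stays within 15% of truth at 2% noise", {
  p <- binding_parameters(5.6e-9, 0.96, dH = -156.0, dS = -365.2)
  clean <- simulate_itc(p)
  sd2 <- 0.02 * max(abs(clean$heats))
  kds <- vapply(1:100, function(seed) {
    fit_itc(simulate_itc(p, noise_sd = sd2, seed = seed))$K_d
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 5.6e-9) / 5.6e-9, 0.15)
})

test_that("fit_itc enforces usable-injection and convergence contracts", {
  p <- binding_parameters(5.6e-9, 1, dH = -156.0, dS = -365.2)
  short <- simulate_itc(p, itc_protocol(
    injection_volumes_uL = c(2, rep(5, 7))))
  expect_error(fit_itc(short), "at least 10")
})

test_that("fraction-bound fitting recovers the generating constant", {
  conc <- c(5, 20, 50, 80, 200, 800) * 1e-9
  f_exact <- conc / (80e-9 + conc)
  fit <- fit_fraction_bound(conc, f_exact)
  expect_equal(fit$K_d, 80e-9, tolerance = 1e-6 * 80e-9)
  # midpoint identity: f = 0.5 at [P] = K_d
  expect_equal(80e-9 / (fit$K_d + 80e-9), 0.5, tolerance = 1e-6)
  # noisy titration
  set.seed(8)
  f_noisy <- pmin(1, pmax(0, f_exact + rnorm(6, 0, 0.05)))
  fit2 <- fit_fraction_bound(conc, f_noisy)
  expect_lt(abs(fit2$K_d - 80e-9) / 80e-9, 0.25)
  expect_error(fit_fraction_bound(conc[1:3], f_exact[1:3]), "at least 4")
  expect_error(fit_fraction_bound(conc, rep(0.999, 6)), "transition")
})

test_that("thermo_table derives tabulated columns and fold changes", {
  tab <- thermo_table(thermo_rows[, c("id", "K_d", "n", "dH", "dS")],
                      reference = "rna_wt")
  expect_equal(tab$minus_TdS, thermo_rows$minus_TdS_printed,
               tolerance = 0.05)
  expect_equal(tab$dG, thermo_rows$dG_printed, tolerance = 0.05)
  expect_equal(tab$fold_change[tab$id == "rna_wt"], 1)
  expect_equal(tab$fold_change[tab$id == "rna_y42a"], 2482, tolerance = 1)
  # unit normalization: K_d in uM gives identical derived energies
  rows_um <- thermo_rows[, c("id", "K_d", "n", "dH", "dS")]
  rows_um$K_d <- rows_um$K_d / 1000
  tab_um <- thermo_table(rows_um, kd_unit = "uM")
  expect_equal(tab_um$dG_from_Kd, tab$dG_from_Kd, tolerance = 1e-9)
  expect_error(thermo_table(thermo_rows, reference = "nope"), "not found")
  # the bundled parameter table gives the same derivations
  path <- system.file("extdata", "binding_parameters.tsv",
                      package = "aptcomplex")
  tab_file <- thermo_table(path, reference = "rna_wt")
  expect_equal(tab_file$dG, tab$dG, tolerance = 1e-9)
})
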