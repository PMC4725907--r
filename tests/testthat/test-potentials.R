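test_that("step potentials are zero beyond their cutoff", {
  for (key in sample(names(the_table$potentials), 25)) {
    pot <- the_table$potentials[[key]]
    cut <- step_cutoff(pot)
    expect_identical(step_energy(pot, cut + c(1e-9, 1, 100)), c(0, 0, 0))
    if (length(pot$shell_radii) > 0) {
      expect_true(all(is.finite(pot$shell_energies)))
      expect_true(all(diff(c(pot$hardcore, pot$shell_radii)) > 0))
    }
  }
})

test_that("discretize reproduces flat and square-well potentials exactly", {
  flat <- discretize(function(r) rep(1.7, length(r)), 2, 6, n_shells = 5)
  expect_equal(flat$shell_energies, rep(1.7, 5))
  # one shell over a square well recovers the well exactly
  sq <- function(r) ifelse(r < 5, -2, 0)
  one <- discretize(sq, 3, 5, n_shells = 1)
  expect_equal(one$shell_energies, -2)
  expect_equal(one$shell_radii, 5)
  expect_error(suppressWarnings(
    discretize(function(r) sqrt(r - 3), 2.5, 4, 4)), "divergent")
})

test_that("discretized Lennard-Jones captures the well depth", {
  eps <- 1; sigma <- 3.5
  lj <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  pot <- discretize(lj, 3.3, 7.3, n_shells = 8)
  rmin <- sigma * 2^(1 / 6)
  shell <- findInterval(rmin, c(pot$hardcore, pot$shell_radii))
  got <- pot$shell_energies[shell]
  # independent averaging oracle for the same shell
  lo <- c(pot$hardcore, pot$shell_radii)[shell]
  hi <- pot$shell_radii[shell]
  oracle <- stats::integrate(lj, lo, hi)$value / (hi - lo)
  expect_equal(got, oracle, tolerance = 1e-3)
  expect_lt(abs(got - (-eps)), 0.1 * eps)
})

test_that("discretize preserves monotonicity of monotone potentials", {
  for (f in list(function(r) exp(-r), function(r) r^2)) {
    pot <- discretize(f, 1, 8, n_shells = 6)
    expect_true(all(diff(pot$shell_energies) < 0) ||
                  all(diff(pot$shell_energies) > 0))
  }
})

test_that("Debye length matches the electrolyte formula", {
  lam <- debye_length(100, 300)
  expect_gt(lam, 9.4)
  expect_lt(lam, 9.8)
  expect_equal(round(lam), 10)
  # inverse square-root scaling in ionic strength
  expect_equal(debye_length(400, 300), lam / 2, tolerance = 1e-12)
  expect_equal(debye_length(25, 300), lam * 2, tolerance = 1e-12)
  expect_error(debye_length(-1, 300))
})

test_that("screened Coulomb follows the Debye-Hueckel form", {
  p <- electrostatics_params()
  expect_equal(screened_coulomb(0, 1, c(1, 5, 20), p), c(0, 0, 0))
  # at r = lambda the value is e^-1 of the unscreened value there
  lam <- p$screening_length
  expect_equal(screened_coulomb(1, 1, lam, p),
               exp(-1) * p$prefactor / lam)
  expect_equal(screened_coulomb(1, 1, 5, p),
               p$prefactor * exp(-0.5) / 5)
  expect_gt(screened_coulomb(1, 1, 5, p), 0)
  expect_lt(screened_coulomb(-1, 1, 5, p), 0)
  expect_error(screened_coulomb(1, 1, 0, p))
})

test_that("pair lookups are symmetric and reject unknown classes", {
  pairs <- list(c("backbone", "sidechain_polar"),
                c("ligand_aromatic:curcumin", "sidechain_aromatic"),
                c("sidechain_charged", "backbone+"))
  for (pr in pairs) {
    a <- pair_potential(pr[1], pr[2], the_table)
    b <- pair_potential(pr[2], pr[1], the_table)
    expect_identical(a$shell_energies, b$shell_energies)
  }
  expect_error(pair_potential("backbone", "unobtainium", the_table),
               "unknown bead class")
})

test_that("hydrophobicity ordering shapes the pair table", {
  depth <- function(a, b) min(pair_potential(a, b, the_table)$shell_energies)
  # polar-polar attraction is weaker than hydrophobic-hydrophobic
  expect_gt(depth("sidechain_polar", "sidechain_polar"),
            depth("sidechain_hydrophobic", "sidechain_hydrophobic"))
  # mixed polar-hydrophobic pairs are near zero (solvation penalty)
  expect_gt(depth("sidechain_polar", "sidechain_hydrophobic"), -0.12)
  # aromatic stacking surrogate present
  expect_lt(depth("sidechain_aromatic", "sidechain_aromatic"),
            depth("sidechain_hydrophobic", "sidechain_hydrophobic"))
  # curcumin sits at the deepest rung of the ladder
  d_asp <- depth("ligand_aromatic:aspirin", "ligand_aromatic:aspirin")
  d_res <- depth("ligand_aromatic:resveratrol",
                 "ligand_aromatic:resveratrol")
  d_cur <- depth("ligand_aromatic:curcumin", "ligand_aromatic:curcumin")
  expect_lt(d_cur, d_res)
  expect_lt(d_cur, d_asp)
})

test_that("molecule-level virial sums order the three ligands", {
  # a molecule's stickiness combines per-bead depth with its bead count;
  # less attractive = larger summed B2: aspirin > resveratrol > curcumin
  b2 <- vapply(c("aspirin", "resveratrol", "curcumin"), function(sp) {
    species_pair_virial(sp, sp, the_table)
  }, numeric(1))
  expect_gt(b2[["aspirin"]], b2[["resveratrol"]])
  expect_gt(b2[["resveratrol"]], b2[["curcumin"]])
})

test_that("hydrogen-bond rule validates its geometry", {
  hb <- hbond_rule()
  expect_lt(hb$d_min, hb$d_max)
  expect_lt(hb$bond_energy, 0)
  expect_error(hbond_rule(d_min = 5, d_max = 4))
  expect_error(hbond_rule(bond_energy = 1))
})
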