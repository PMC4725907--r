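test_that("box edge preserves peptide density", {
  expect_equal(box_edge(1, 63.7), 63.7)
  expect_equal(box_edge(8, 63.65), 127.3, tolerance = 1e-4)
  expect_equal(box_edge(27, 10), 30)  # cube scaling
  expect_error(box_edge(0, 63.7))
  expect_error(box_edge(1, -1))
  # density invariance across all simulated sizes
  for (n in c(1, 2, 4, 6, 8)) {
    expect_equal(peptide_concentration(n, box_edge(n, 63.7)),
                 peptide_concentration(1, 63.7), tolerance = 1e-12)
  }
  # the two printed box edges imply the same density within 0.5%
  expect_equal(peptide_concentration(1, 63.7),
               peptide_concentration(8, 127.3), tolerance = 5e-3)
})

test_that("peptide concentration matches the direct arithmetic", {
  expect_equal(peptide_concentration(8, 127.3), 6.44, tolerance = 1e-2)
  expect_equal(peptide_concentration(1, 63.7), 6.43, tolerance = 1e-2)
  expect_equal(peptide_concentration(0, 50), 0)
  expect_error(peptide_concentration(1, 0))
})

test_that("DLS mixture arithmetic reproduces the sample sheet", {
  expect_equal(dls_mixture_concentration(64, 6, 20), 19.2)
  expect_equal(dls_mixture_concentration(87, 9, 20), 39.15)
  expect_equal(dls_mixture_concentration(50, 5, 5), 50)  # no dilution
  expect_error(dls_mixture_concentration(64, 25, 20), "exceed")
  expect_error(dls_mixture_concentration(64, -1, 20))
  # molar ratios of the mixture series: 1:2, 1:2.7, 1:3.1
  iapp <- dls_mixture_concentration(64, 6, 20)
  ratios <- dls_mixture_concentration(87, c(9, 12, 14), 20) / iapp
  expect_equal(round(ratios, 1), c(2.0, 2.7, 3.1), tolerance = 0.051)
})

test_that("assembly produces the expected bead counts and is seeded", {
  cfg <- system_config(8, "curcumin", seed = 1, event_budget = 1)
  sys <- assemble_system(cfg)
  expect_equal(nrow(sys$beads), 8 * 72 + 16 * 5)  # 656
  expect_equal(sys$box_edge, box_edge(8, 63.7))
  sys2 <- assemble_system(cfg)
  expect_identical(sys$beads, sys2$beads)  # bit-identical given the seed
})

test_that("assembly never violates minimum-image hardcore distances", {
  for (seed in 1:3) {
    cfg <- system_config(2, "resveratrol", seed = seed, event_budget = 1)
    sys <- assemble_system(cfg)
    b <- sys$beads
    xyz <- cbind(b$x, b$y, b$z)
    d2 <- oligodmd:::.min_image_cross_dist2(xyz, xyz, sys$box_edge)
    lim2 <- outer(b$hardcore_radius, b$hardcore_radius, "+")^2
    inter <- outer(b$mol, b$mol, "!=")
    expect_false(any(d2[inter & upper.tri(d2)] <
                       lim2[inter & upper.tri(d2)] - 1e-9))
    expect_true(all(b$x >= 0 & b$x < sys$box_edge))
  }
})

test_that("velocity assignment is Maxwell-Boltzmann with zero momentum", {
  cfg <- system_config(1, NULL, seed = 2, event_budget = 1)
  sys <- assemble_system(cfg)
  b <- sys$beads
  # mean kinetic energy per degree of freedom ~ kT/2 within 5% at 216 dof
  ke <- 0.5 * sum(b$mass * (b$vx^2 + b$vy^2 + b$vz^2))
  expect_equal(ke / (3 * nrow(b)), kT(300) / 2, tolerance = 0.05)
  expect_equal(sum(b$mass * b$vx), 0, tolerance = 1e-9)
  expect_equal(sum(b$mass * b$vy), 0, tolerance = 1e-9)
  expect_equal(sum(b$mass * b$vz), 0, tolerance = 1e-9)
})

test_that("velocity moments converge over many seeds", {
  # per-component mean -> 0 and variance -> kT/m within 3 standard errors
  vels <- numeric(0)
  scaled <- numeric(0)
  for (seed in 1:100) {
    cfg <- system_config(1, NULL, seed = seed, event_budget = 1)
    b <- assemble_system(cfg)$beads
    scaled <- c(scaled, b$vx * sqrt(b$mass / kT(300)))
  }
  n <- length(scaled)
  expect_lt(abs(mean(scaled)), 3 / sqrt(n))
  expect_lt(abs(stats::var(scaled) - 1), 3 * sqrt(2 / (n - 1)))
})

test_that("invalid configurations are rejected", {
  expect_error(system_config(-1), "invalid")
  expect_error(system_config(0, n_ligands = 4), "ligand_species")
  expect_error(system_config(0, "aspirin", n_ligands = 16),
               "explicit `edge`")
  # a box far too small for its contents reports placement failure
  cfg <- system_config(4, NULL, base_edge = 18, seed = 1)
  expect_error(assemble_system(cfg, max_tries = 50), "too dense")
})
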