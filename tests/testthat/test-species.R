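test_that("IAPP topology has the canonical bead bookkeeping", {
  top <- build_species("IAPP")
  expect_equal(nrow(top$beads), 72)  # 37 backbone + 35 sidechain beads
  expect_equal(max(top$residue_map), 37)
  expect_equal(sum(top$beads$klass == "backbone"), 37)
  # glycines 24 and 33 carry no sidechain bead
  sc_res <- top$beads$residue[top$beads$klass != "backbone"]
  expect_false(any(c(24, 33) %in% sc_res))
  # exactly one crosslink, joining the Cys2 and Cys7 sidechains
  xl <- dplyr::filter(top$bonds, kind == "crosslink")
  expect_equal(nrow(xl), 1)
  xl_res <- top$beads$residue[c(xl$i, xl$j)]
  expect_setequal(xl_res, c(2, 7))
  # aromatic flags on Phe15, His18, Phe23, Tyr37
  aro_res <- top$beads$residue[top$beads$klass == "sidechain_aromatic"]
  expect_setequal(aro_res, c(15, 18, 23, 37))
  # charges: Lys1 sidechain, Arg11 sidechain, free N-terminus
  charged <- top$beads[top$beads$charge != 0, ]
  expect_equal(sum(charged$charge), 3)
  expect_setequal(unique(charged$residue), c(1, 11))
})

test_that("bead invariants hold for every species", {
  for (sp in species_names) {
    top <- build_species(sp)
    expect_true(all(top$beads$mass > 0), info = sp)
    expect_true(all(top$beads$hardcore_radius > 0), info = sp)
    expect_true(all(top$beads$hbond_donors >= 0 &
                      top$beads$hbond_donors <= 4), info = sp)
    expect_true(all(top$beads$hbond_acceptors >= 0 &
                      top$beads$hbond_acceptors <= 4), info = sp)
    expect_true(all(top$bonds$d_min < top$bonds$d_max), info = sp)
  }
})

test_that("ligand bead graphs carry the expected interaction features", {
  cur <- build_species("curcumin")
  expect_equal(nrow(cur$beads), 5)
  expect_equal(sum(cur$beads$klass == "ligand_aromatic"), 2)
  expect_equal(sum(cur$beads$hbond_donors), 2)   # one hydroxyl per ring
  expect_equal(sum(cur$beads$hbond_acceptors), 3)
  res <- build_species("resveratrol")
  expect_equal(nrow(res$beads), 4)
  expect_equal(sum(res$beads$hbond_donors), 3)
  expect_equal(sum(res$beads$hbond_acceptors), 3)
  asp <- build_species("aspirin")
  expect_equal(nrow(asp$beads), 2)
  o_bead <- asp$beads[asp$beads$klass == "ligand_polar_O", ]
  expect_equal(o_bead$hbond_donors, 1L)
  expect_equal(o_bead$hbond_acceptors, 2L)
})

test_that("unknown species are rejected", {
  expect_error(build_species("EGCG"), "unknown species")
  expect_error(build_species(c("IAPP", "aspirin")), "unknown")
})

test_that("reference conformations satisfy their own topology", {
  for (sp in species_names) {
    top <- build_species(sp)
    ref <- top$ref_coords
    d <- sqrt(rowSums((ref[top$bonds$i, , drop = FALSE] -
                         ref[top$bonds$j, , drop = FALSE])^2))
    expect_true(all(d >= top$bonds$d_min & d <= top$bonds$d_max),
                info = sp)
    # no non-bonded pair inside the hardcore
    n <- nrow(ref)
    if (n > 1) {
      excl <- matrix(FALSE, n, n)
      excl[cbind(top$bonds$i, top$bonds$j)] <- TRUE
      excl[cbind(top$bonds$j, top$bonds$i)] <- TRUE
      dm <- as.matrix(dist(ref))
      lim <- outer(top$beads$hardcore_radius, top$beads$hardcore_radius,
                   "+")
      bad <- dm < lim & !excl & upper.tri(dm)
      expect_false(any(bad), info = sp)
    }
  }
})

test_that("the species library round-trips through its JSON schema", {
  path <- withr::local_tempfile(fileext = ".json")
  lib <- species_library()
  write_species_library(lib, path)
  back <- read_species_library(path)
  expect_setequal(names(back$topologies), species_names)
  for (sp in species_names) {
    expect_equal(back$topologies[[sp]]$beads, lib$topologies[[sp]]$beads)
    expect_equal(back$topologies[[sp]]$bonds, lib$topologies[[sp]]$bonds)
    expect_equal(back$topologies[[sp]]$ref_coords,
                 lib$topologies[[sp]]$ref_coords, tolerance = 1e-12)
  }
  # the rebuilt pair table reproduces every potential
  k <- "backbone|sidechain_hydrophobic"
  expect_equal(back$pair_table$potentials[[k]]$shell_energies,
               lib$pair_table$potentials[[k]]$shell_energies)
  expect_equal(back$hbond$bond_energy, lib$hbond$bond_energy)
})
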