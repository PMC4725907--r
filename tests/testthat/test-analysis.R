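make_pair_frame <- function(d, edge = 40) {
  dplyr::bind_rows(
    bead_row(1, 1, "IAPP", 10, 10, 10),
    bead_row(2, 2, "curcumin", 10 + d, 10, 10)
  )
}

test_that("the contact rule is strict at the cutoff", {
  fr <- make_pair_frame(5.4)
  expect_equal(nrow(contacts(fr, box_edge = 40)), 1)
  fr <- make_pair_frame(5.5)
  expect_equal(nrow(contacts(fr, box_edge = 40)), 0)
  # intra-molecular pairs are never contacts
  fr <- dplyr::bind_rows(bead_row(1, 1, "IAPP", 0, 0, 0),
                         bead_row(2, 1, "IAPP", 2, 0, 0))
  expect_equal(nrow(contacts(fr, box_edge = 40)), 0)
  expect_error(contacts(make_pair_frame(3), cutoff = -1, box_edge = 40))
})

test_that("cell-list contacts equal the brute-force double loop", {
  set.seed(7)
  for (rep in 1:6) {
    n <- 100
    edge <- stats::runif(1, 18, 60)
    fr <- bead_row(1:n, sample(1:30, n, replace = TRUE), "IAPP",
                   stats::runif(n, 0, edge), stats::runif(n, 0, edge),
                   stats::runif(n, 0, edge))
    a <- contacts(fr, box_edge = edge, method = "cell")
    b <- contacts(fr, box_edge = edge, method = "brute")
    key <- function(cm) sort(paste(cm$i, cm$j))
    expect_identical(key(a), key(b))
  }
})

test_that("clustering is transitive through shared contacts", {
  fr <- dplyr::bind_rows(
    bead_row(1, 1, "IAPP", 10, 10, 10),
    bead_row(2, 2, "IAPP", 14, 10, 10),
    bead_row(3, 3, "IAPP", 18, 10, 10),   # touches 2 but not 1
    bead_row(4, 4, "IAPP", 30, 30, 30)    # isolated
  )
  ca <- cluster_frame(contacts(fr, box_edge = 50))
  expect_equal(ca$cluster[1], ca$cluster[2])
  expect_equal(ca$cluster[2], ca$cluster[3])
  expect_false(ca$cluster[4] == ca$cluster[1])
  expect_equal(length(unique(ca$cluster)), 2)
})

test_that("clustering equals the union-find oracle on random graphs", {
  set.seed(11)
  for (rep in 1:200) {
    n_mol <- sample(4:25, 1)
    n_edges <- sample(0:(2 * n_mol), 1)
    ei <- sample(n_mol, n_edges, replace = TRUE)
    ej <- sample(n_mol, n_edges, replace = TRUE)
    keep <- ei != ej
    cmap <- tibble::tibble(i = ei[keep], j = ej[keep],
                           mol_i = ei[keep], mol_j = ej[keep],
                           dist = 5)
    attr(cmap, "molecules") <- tibble::tibble(
      mol = seq_len(n_mol), species = "IAPP", n_beads = 1)
    got <- cluster_frame(cmap)$cluster
    want <- uf_components(n_mol, ei[keep], ej[keep])
    # same partition (labels may differ)
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster statistics recover forced fixture values", {
  spec <- cluster_spec(tibble::tibble(n_peptides = c(3, 3, 2),
                                      n_ligands = c(6, 6, 4)),
                       separation = 45, n_frames = 3, seed = 7)
  fx <- make_clustered_trajectory(spec)
  st <- cluster_stats(fx$trajectory, window = 1:3)
  expect_equal(st$count_hist$n_clusters, 3)
  expect_equal(st$count_hist$probability, 1)
  p <- st$size_hist
  expect_equal(p$probability[p$s == 3], 0.75)
  expect_equal(p$probability[p$s == 2], 0.25)
  expect_setequal(
    paste(st$composition$n_peptides, st$composition$n_ligands),
    c("3 6", "2 4"))
  expect_equal(cluster_ligand_peptide_ratio(st), 2)
})

test_that("a lone octamer gives P(8) = 1", {
  spec <- cluster_spec(tibble::tibble(n_peptides = 8, n_ligands = 0),
                       separation = 60, n_frames = 2, seed = 3)
  fx <- make_clustered_trajectory(spec)
  st <- cluster_stats(fx$trajectory, window = 1:2)
  expect_equal(st$size_hist$s, 8)
  expect_equal(st$size_hist$probability, 1)
  expect_equal(st$count_hist$n_clusters, 1)
})

test_that("mass-weighted histograms are normalized and conserve chains", {
  set.seed(5)
  for (rep in 1:5) {
    k <- sample(2:4, 1)
    npep <- sample(1:4, k, replace = TRUE)
    spec <- cluster_spec(tibble::tibble(n_peptides = npep,
                                        n_ligands = sample(0:3, k, TRUE)),
                         separation = 50, n_frames = 2, seed = rep)
    fx <- make_clustered_trajectory(spec)
    st <- cluster_stats(fx$trajectory, window = 1:2)
    expect_equal(sum(st$size_hist$probability), 1, tolerance = 1e-12)
    # every frame's cluster sizes sum to the total chain count
    for (ca in oligodmd:::.window_clusters(fx$trajectory, 1:2)) {
      cl <- attr(ca, "clusters")
      expect_equal(sum(cl$n_peptides), sum(npep))
    }
  }
})

test_that("radial profiles separate a built core from its corona", {
  # ligand beads at radius 3, peptide beads at radius 8 around a centre
  set.seed(2)
  centre <- c(20, 20, 20)
  pts_in <- matrix(stats::rnorm(3 * 30), ncol = 3)
  pts_in <- 3 * pts_in / sqrt(rowSums(pts_in^2))
  pts_out <- matrix(stats::rnorm(3 * 30), ncol = 3)
  pts_out <- 8 * pts_out / sqrt(rowSums(pts_out^2))
  # chain them into two molecules close enough to form one cluster
  beads <- dplyr::bind_rows(
    bead_row(1:30, 1, "curcumin", centre[1] + pts_in[, 1],
             centre[2] + pts_in[, 2], centre[3] + pts_in[, 3],
             klass = "ligand_aromatic"),
    bead_row(31:60, 2, "IAPP", centre[1] + pts_out[, 1],
             centre[2] + pts_out[, 2], centre[3] + pts_out[, 3])
  )
  traj <- manual_trajectory(beads, list(cbind(beads$x, beads$y, beads$z)),
                            box_edge = 40)
  prof <- radial_profile(traj, window = 1, n_pep = 1, bin_width = 1)
  peak <- function(sel) {
    p <- dplyr::filter(prof, selector == sel)
    p$bin_lo[which.max(p$frequency)]
  }
  expect_lt(peak("ligand"), peak("peptide"))
  # translation across the periodic boundary leaves the profile unchanged
  shift <- c(19, -7, 33)
  beads2 <- dplyr::mutate(beads, x = (x + shift[1]) %% 40,
                          y = (y + shift[2]) %% 40,
                          z = (z + shift[3]) %% 40)
  traj2 <- manual_trajectory(beads2,
                             list(cbind(beads2$x, beads2$y, beads2$z)), 40)
  prof2 <- radial_profile(traj2, window = 1, n_pep = 1, bin_width = 1)
  expect_equal(prof$frequency, prof2$frequency, tolerance = 1e-12)
  # a single bead "cluster" has all mass in the first bin
  lone <- bead_row(1, 1, "IAPP", 5, 5, 5)
  traj3 <- manual_trajectory(lone, list(cbind(5, 5, 5)), 40)
  prof3 <- radial_profile(traj3, window = 1, n_pep = 1)
  pep3 <- dplyr::filter(prof3, selector == "peptide")
  expect_equal(pep3$frequency[pep3$bin_lo == 0], 1)
  expect_error(radial_profile(traj3, window = 1, n_pep = 5), "no cluster")
})

test_that("secondary-structure templates are labelled as built", {
  ssh <- secondary_structure(make_ss_template("helix", 20))
  expect_true(all(ssh$ss[3:18] == "H"))
  sse <- secondary_structure(make_ss_template("extended", 20))
  expect_true(all(sse$ss[3:18] == "E"))
  # chains shorter than 4 residues are all coil
  tiny <- secondary_structure(make_ss_template("helix", 5)[1:3, ])
  expect_equal(as.character(tiny$ss), c("C", "C", "C"))
  expect_error(make_ss_template("helix", 3), "at least 4")
})

test_that("secondary-structure content partitions every chain", {
  cfg <- system_config(1, NULL, seed = 8, event_budget = 5e3)
  tr <- run_dmd(assemble_system(cfg), emit_every = 1e3)
  for (k in seq_len(n_frames(tr))) {
    counts <- dplyr::count(secondary_structure(traj_frame(tr, k)),
                           mol, name = "n")
    expect_true(all(counts$n == 37))
  }
  cont <- ss_content(tr, window = seq_len(n_frames(tr)))
  expect_equal(sum(cont$mean_residues), 37, tolerance = 1e-12)
  expect_setequal(as.character(cont$ss), c("H", "E", "T", "C"))
})

test_that("residue-ligand contact frequency counts windowed fractions", {
  pep <- function(xoff) dplyr::bind_rows(
    bead_row(1, 1, "IAPP", 10, 10, 10, residue = 1L),
    bead_row(2, 1, "IAPP", 18, 10, 10, residue = 2L),
    bead_row(3, 1, "IAPP", 26, 10, 10, residue = 3L)
  )
  lig_at <- function(x) bead_row(4, 2, "curcumin", x, 10, 10)
  frames <- list(
    {b <- dplyr::bind_rows(pep(), lig_at(28)); cbind(b$x, b$y, b$z)},
    {b <- dplyr::bind_rows(pep(), lig_at(12)); cbind(b$x, b$y, b$z)},
    {b <- dplyr::bind_rows(pep(), lig_at(40)); cbind(b$x, b$y, b$z)}
  )
  # frame 1: ligand at 28 -> contacts residue 3 (d=2); frame 2: at 12 ->
  # residue 1 (d=2); frame 3: far from everything
  beads <- dplyr::bind_rows(pep(), lig_at(28))
  traj <- manual_trajectory(beads, frames, box_edge = 60)
  freq <- residue_ligand_contact_frequency(traj, window = 1:3)
  expect_equal(freq$frequency[freq$residue == 1], 1 / 3)
  expect_equal(freq$frequency[freq$residue == 2], 0)
  expect_equal(freq$frequency[freq$residue == 3], 1 / 3)
  # a ligand-free trajectory is all zeros
  traj0 <- manual_trajectory(pep(), list(
    {b <- pep(); cbind(b$x, b$y, b$z)}), 60)
  expect_true(all(residue_ligand_contact_frequency(traj0, 1)$frequency == 0))
})

test_that("binding fractions distinguish per-ligand and any-ligand modes", {
  pep <- bead_row(1, 1, "IAPP", 10, 10, 10)
  l1 <- function(x) bead_row(2, 2, "curcumin", x, 10, 10)
  l2 <- function(x) bead_row(3, 3, "curcumin", 10, x, 10)
  mk <- function(x1, x2) {
    b <- dplyr::bind_rows(pep, l1(x1), l2(x2))
    cbind(b$x, b$y, b$z)
  }
  beads <- dplyr::bind_rows(pep, l1(13), l2(13))
  # ligand 1 bound in both frames, ligand 2 in one of two
  traj <- manual_trajectory(beads, list(mk(13, 13), mk(13, 40)), 60)
  expect_equal(binding_fraction(traj, window = 1:2, "per_ligand"), 0.75)
  expect_equal(binding_fraction(traj, window = 1:2, "any_ligand"), 1.0)
  # never bound
  traj0 <- manual_trajectory(beads, list(mk(40, 40), mk(40, 40)), 60)
  expect_equal(binding_fraction(traj0, window = 1:2, "per_ligand"), 0)
  expect_equal(binding_fraction(traj0, window = 1:2, "any_ligand"), 0)
})

test_that("inter-chain contacts honour the region restriction", {
  spec <- cluster_spec(tibble::tibble(n_peptides = 2, n_ligands = 0),
                       separation = 50, n_frames = 2, seed = 13)
  fx <- make_clustered_trajectory(spec)
  full <- interchain_contacts(fx$trajectory, window = 1:2)
  expect_true(all(full$contacts > 0))  # chained molecules touch
  reg <- interchain_contacts(fx$trajectory, window = 1:2, region = c(1, 2))
  expect_true(all(reg$contacts <= full$contacts))
  expect_error(interchain_contacts(fx$trajectory, 1:2, region = c(0, 99)))
  # a monomer has no inter-chain contacts
  spec1 <- cluster_spec(tibble::tibble(n_peptides = 1, n_ligands = 0),
                        separation = 50, n_frames = 1, seed = 1)
  fx1 <- make_clustered_trajectory(spec1)
  expect_true(all(interchain_contacts(fx1$trajectory, 1)$contacts == 0))
})

test_that("steady-state windows take the last half of frames", {
  mk <- function(nf) {
    b <- bead_row(1, 1, "IAPP", 1, 1, 1)
    manual_trajectory(b, rep(list(cbind(1, 1, 1)), nf), 20)
  }
  expect_equal(range(steady_state_window(mk(100))), c(51, 100))
  expect_equal(as.integer(steady_state_window(mk(2))), 2L)
  expect_equal(range(steady_state_window(mk(101))), c(51, 101))
  expect_error(steady_state_window(mk(1)), "at least 2")
})

test_that("the census counts hydrogen bonds and stacking contacts", {
  # two reacted donor-acceptor pairs handed in as a registry
  fr <- dplyr::bind_rows(
    bead_row(1, 1, "IAPP", 10, 10, 10, donors = 1L),
    bead_row(2, 2, "curcumin", 14, 10, 10, acceptors = 1L),
    bead_row(3, 3, "IAPP", 10, 20, 10, donors = 1L),
    bead_row(4, 4, "IAPP", 14, 20, 10, acceptors = 1L)
  )
  reg <- rbind(c(1L, 2L), c(3L, 4L))
  cen <- hbond_stack_census(fr, hb_registry = reg, box_edge = 40)
  expect_equal(cen$peptide_ligand_hbonds, 1)
  expect_equal(cen$peptide_peptide_hbonds, 1)
  # no aromatic beads anywhere -> no stacking
  fr2 <- dplyr::mutate(fr, klass = "backbone", iclass = "backbone")
  cen2 <- hbond_stack_census(fr2, hb_registry = reg, box_edge = 40)
  expect_equal(cen2$stacking_contacts, 0)
})

test_that("the census never exceeds donor capacity", {
  set.seed(3)
  for (rep in 1:10) {
    n <- 25
    fr <- bead_row(1:n, 1:n, "IAPP",
                   stats::runif(n, 0, 25), stats::runif(n, 0, 25),
                   stats::runif(n, 0, 25),
                   donors = sample(0:2, n, TRUE),
                   acceptors = sample(0:2, n, TRUE))
    reg <- oligodmd:::.greedy_hbonds(fr, 25, hbond_rule())
    if (nrow(reg) > 0) {
      expect_true(all(table(reg[, 1]) <= fr$hbond_donors[as.integer(
        names(table(reg[, 1])))]))
      expect_true(all(table(reg[, 2]) <= fr$hbond_acceptors[as.integer(
        names(table(reg[, 2])))]))
    }
  }
})
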