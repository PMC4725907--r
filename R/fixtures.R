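# Synthetic-data generators and closed-form oracles: trajectories with
# known cluster structure, idealised chain geometries, non-interacting
# gases, and the two-body square-well configurational integral. These make
# every analysis stage testable without running production simulations.

#' Specification of a synthetic clustered trajectory
#'
#' @param clusters Data frame with one row per cluster: `n_peptides`,
#'   `n_ligands`, and optionally `spread` (molecule-to-molecule link step,
#'   Angstrom; default 4).
#' @param separation Distance between cluster centres (Angstrom); must
#'   exceed twice the largest cluster extent plus the contact cutoff.
#' @param n_frames Number of frames.
#' @param jitter Per-frame uniform whole-molecule displacement amplitude
#'   (Angstrom; keep below 0.4 so links never open past the cutoff).
#' @param seed Integer seed.
#' @param box_edge Box edge; default large enough to hold the cluster grid.
#' @param ligand_species Species label given to ligand molecules.
#' @return A `cluster_spec` list.
#' @export
cluster_spec <- function(clusters, separation = 40, n_frames = 3,
                         jitter = 0.3, seed = 1L, box_edge = NULL,
                         ligand_species = "curcumin") {
  clusters <- as_tibble(clusters)
  if (!all(c("n_peptides", "n_ligands") %in% names(clusters))) {
    stop("clusters needs n_peptides and n_ligands columns", call. = FALSE)
  }
  if (!"spread" %in% names(clusters)) clusters$spread <- 4.0
  if (jitter < 0 || jitter > 0.4) {
    stop("jitter must lie in [0, 0.4] to keep links closed", call. = FALSE)
  }
  structure(
    list(clusters = clusters, separation = separation, n_frames = n_frames,
         jitter = jitter, seed = as.integer(seed), box_edge = box_edge,
         ligand_species = ligand_species),
    class = "cluster_spec"
  )
}

# synthetic molecules: a 3-bead chain for a peptide, 1 bead for a ligand
.synth_molecule <- function(species, anchor, mol_id, bead0, ligand_species) {
  if (species == "IAPP") {
    offs <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
    tibble(
      bead = bead0 + seq_len(3), mol = mol_id, species = "IAPP",
      klass = "backbone", iclass = "backbone",
      residue = 1:3, mass = 100, hardcore_radius = 2.0, charge = 0,
      hbond_donors = 0L, hbond_acceptors = 0L,
      x = anchor[1] + offs[, 1], y = anchor[2] + offs[, 2],
      z = anchor[3] + offs[, 3]
    )
  } else {
    tibble(
      bead = bead0 + 1L, mol = mol_id, species = species,
      klass = "ligand_aromatic",
      iclass = paste0("ligand_aromatic:", species),
      residue = NA_integer_, mass = 100, hardcore_radius = 2.0, charge = 0,
      hbond_donors = 0L, hbond_acceptors = 0L,
      x = anchor[1], y = anchor[2], z = anchor[3]
    )
  }
}

#' Generate a trajectory with prescribed cluster structure
#'
#' Cluster centres sit on a cubic grid `separation` apart; within a
#' cluster, molecules are chained anchor-to-anchor with steps of length
#' `spread` (so the cluster is connected under the 5.5 Angstrom rule by
#' construction), peptides first, then ligands. Each frame displaces whole
#' molecules by a uniform jitter. The generator verifies, frame by frame,
#' that ground-truth clusters are internally connected and mutually farther
#' apart than the cutoff, and errors otherwise, so the emitted labels are
#' provably the unique connected-component solution.
#'
#' @param spec A [cluster_spec()].
#' @param cutoff Contact cutoff the ground truth must respect (Angstrom).
#' @return A list: `trajectory` (a `dmd_trajectory`-compatible object) and
#'   `truth`, a tibble (`mol`, `species`, `cluster`).
#' @export
make_clustered_trajectory <- function(spec, cutoff = 5.5) {
  stopifnot(inherits(spec, "cluster_spec"))
  set.seed(spec$seed)
  k <- nrow(spec$clusters)
  n_side <- ceiling(k^(1 / 3))
  edge <- spec$box_edge
  if (is.null(edge)) edge <- n_side * spec$separation
  grid <- expand.grid(gx = seq_len(n_side), gy = seq_len(n_side),
                      gz = seq_len(n_side))[seq_len(k), ]
  centres <- as.matrix(grid - 0.5) * spec$separation
  if (any(centres > edge)) {
    stop("cluster grid does not fit inside the box", call. = FALSE)
  }

  beads <- list()
  truth <- list()
  mol_id <- 0L
  bead0 <- 0L
  for (c_idx in seq_len(k)) {
    row <- spec$clusters[c_idx, ]
    n_mol <- row$n_peptides + row$n_ligands
    anchor <- centres[c_idx, ]
    for (m in seq_len(n_mol)) {
      species <- if (m <= row$n_peptides) "IAPP" else spec$ligand_species
      mol_id <- mol_id + 1L
      mb <- .synth_molecule(species, anchor, mol_id, bead0,
                            spec$ligand_species)
      bead0 <- bead0 + nrow(mb)
      beads[[length(beads) + 1L]] <- mb
      truth[[length(truth) + 1L]] <- tibble(
        mol = mol_id, species = species, cluster = c_idx)
      u <- stats::rnorm(3)
      anchor <- anchor + row$spread * u / sqrt(sum(u^2))
    }
  }
  beads <- bind_rows(beads)
  truth <- bind_rows(truth)

  # extent / separation invariant
  ext <- purrr::map_dbl(seq_len(k), function(cc) {
    idx <- beads$mol %in% truth$mol[truth$cluster == cc]
    xyz <- cbind(beads$x, beads$y, beads$z)[idx, , drop = FALSE]
    ctr <- colMeans(xyz)
    2 * sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  })
  if (spec$separation <= 2 * max(ext) / 2 + cutoff + 2 * spec$jitter) {
    # extent here is a diameter; centres must clear half-extents + cutoff
    if (spec$separation <= max(ext) + cutoff + 2 * spec$jitter) {
      stop("separation too small for the requested cluster extents",
           call. = FALSE)
    }
  }

  n <- nrow(beads)
  nf <- spec$n_frames
  coords <- array(NA_real_, c(nf, n, 3))
  for (f in seq_len(nf)) {
    fb <- beads
    for (m in seq_len(mol_id)) {
      dj <- stats::runif(3, -spec$jitter, spec$jitter)
      idx <- fb$mol == m
      fb$x[idx] <- fb$x[idx] + dj[1]
      fb$y[idx] <- fb$y[idx] + dj[2]
      fb$z[idx] <- fb$z[idx] + dj[3]
    }
    coords[f, , ] <- cbind(fb$x, fb$y, fb$z) %% edge
  }

  traj <- structure(
    list(
      frames = tibble(frame = seq_len(nf), time = as.numeric(seq_len(nf)),
                      kinetic = NA_real_, potential = NA_real_,
                      temperature = NA_real_),
      coords = coords,
      velocities = NULL,
      beads = beads[, c("bead", "mol", "species", "klass", "iclass",
                        "residue", "mass", "hardcore_radius", "charge",
                        "hbond_donors", "hbond_acceptors")],
      box_edge = edge,
      config = list(generator = "make_clustered_trajectory",
                    seed = spec$seed, jitter = spec$jitter,
                    spread = spec$clusters$spread,
                    distribution = "chained anchors, uniform jitter"),
      seed = spec$seed
    ),
    class = "dmd_trajectory"
  )

  # verify the ground truth is the unique contact-clustering solution
  for (f in seq_len(nf)) {
    ca <- cluster_frame(contacts(traj_frame(traj, f)))
    joined <- dplyr::inner_join(ca, truth, by = c("mol", "species"))
    tab <- table(joined$cluster.x, joined$cluster.y)
    if (any(rowSums(tab > 0) != 1) || any(colSums(tab > 0) != 1)) {
      stop("generated frame ", f, " does not realize the requested ",
           "cluster structure", call. = FALSE)
    }
  }
  list(trajectory = traj, truth = truth)
}

#' Two-body square-well specification
#'
#' @param sigma Hardcore distance (Angstrom).
#' @param lambda Well width ratio (> 1); the well spans
#'   `[sigma, lambda * sigma]`.
#' @param epsilon Well depth in kcal/mol (> 0).
#' @param box_edge Cubic box edge (Angstrom).
#' @param temperature Temperature (K).
#' @export
two_body_spec <- function(sigma = 4, lambda = 1.5, epsilon = 2,
                          box_edge = 40, temperature = 300) {
  stopifnot(lambda > 1, epsilon > 0, sigma > 0, box_edge > 0)
  structure(list(sigma = sigma, lambda = lambda, epsilon = epsilon,
                 box_edge = box_edge, temperature = temperature),
            class = "two_body_spec")
}

#' Equilibrium bound probability of an isolated square-well pair
#'
#' Configurational integral: `P = Z_in / (Z_in + Z_out)` with
#' `Z_in = Integral_sigma^(lambda sigma) 4 pi r^2 exp(eps/kT) dr` and
#' `Z_out = V - 4/3 pi (lambda sigma)^3`, evaluated by quadrature. The
#' independent oracle for the engine's time-averaged bound fraction.
#'
#' @param spec A [two_body_spec()].
#' @return Bound probability in `(0, 1)`.
#' @export
bound_fraction_oracle <- function(spec) {
  stopifnot(inherits(spec, "two_body_spec"))
  beta <- 1 / kT(spec$temperature)
  z_in <- stats::integrate(
    function(r) 4 * pi * r^2 * exp(beta * spec$epsilon),
    lower = spec$sigma, upper = spec$lambda * spec$sigma
  )$value
  z_out <- spec$box_edge^3 - 4 / 3 * pi * (spec$lambda * spec$sigma)^3
  z_in / (z_in + z_out)
}

#' Square-well step potential of a two-body spec
#'
#' @param spec A [two_body_spec()].
#' @return A [step_potential()] with a single well.
#' @export
two_body_potential <- function(spec) {
  step_potential(spec$sigma, spec$lambda * spec$sigma, -spec$epsilon)
}

#' Idealised backbone templates for the secondary-structure rule
#'
#' Chains built at the centres of the assignment windows: the helix
#' template uses a pseudo-angle of 95 degrees and pseudo-dihedral of 50
#' degrees; the extended template 127.5 and 180 degrees.
#'
#' @param kind `"helix"` or `"extended"`.
#' @param n_residues Chain length (>= 4).
#' @param bond Backbone bead spacing (Angstrom).
#' @return Matrix of backbone coordinates (`n_residues` x 3).
#' @export
make_ss_template <- function(kind = c("helix", "extended"), n_residues,
                             bond = 3.8) {
  kind <- match.arg(kind)
  if (n_residues < 4) stop("need at least 4 residues", call. = FALSE)
  if (kind == "helix") {
    .chain_trace(n_residues, bond, 95, 50)
  } else {
    .chain_trace(n_residues, bond, 127.5, 180)
  }
}

#' Non-interacting reference gas
#'
#' Beads of the `ideal` class carry no potentials at all: free flight
#' between thermostat events, for kinematics and thermostat validation.
#'
#' @param n Number of beads.
#' @param box_edge Cubic box edge (Angstrom).
#' @param temperature Temperature (K) for the initial velocities.
#' @param seed Integer seed.
#' @param mass Bead mass (amu).
#' @return A `system_state` runnable by [run_dmd()].
#' @export
make_ideal_gas <- function(n, box_edge = 50, temperature = 300, seed = 1L,
                           mass = 20) {
  stopifnot(n >= 1)
  set.seed(seed)
  sd_v <- sqrt(kT(temperature) / mass)
  v <- matrix(stats::rnorm(3 * n, sd = sd_v), n, 3)
  v <- sweep(v, 2, colMeans(v))
  beads <- tibble(
    bead = seq_len(n), mol = seq_len(n), species = "ideal",
    klass = "ideal", iclass = "ideal", residue = NA_integer_,
    mass = mass, hardcore_radius = 0, charge = 0,
    hbond_donors = 0L, hbond_acceptors = 0L,
    x = stats::runif(n, 0, box_edge),
    y = stats::runif(n, 0, box_edge),
    z = stats::runif(n, 0, box_edge),
    vx = v[, 1], vy = v[, 2], vz = v[, 3]
  )
  structure(
    list(
      beads = beads,
      bonds = tibble(i = integer(0), j = integer(0),
                     d_min = numeric(0), d_max = numeric(0),
                     kind = character(0)),
      box_edge = box_edge, time = 0,
      config = structure(list(seed = as.integer(seed),
                              temperature = temperature),
                         class = "system_config"),
      species_count = c(ideal = n)
    ),
    class = "system_state"
  )
}

#' Assemble a bespoke two-bead square-well system
#'
#' @param spec A [two_body_spec()].
#' @param seed Integer seed for velocities.
#' @param mass Bead mass (amu).
#' @return A `system_state` whose two beads interact through the single
#'   square well; run it with `pair_table = two_body_table(spec)`.
#' @export
make_two_body_system <- function(spec, seed = 1L, mass = 40) {
  set.seed(seed)
  sd_v <- sqrt(kT(spec$temperature) / mass)
  v <- matrix(stats::rnorm(6, sd = sd_v), 2, 3)
  v <- sweep(v, 2, colMeans(v))
  start <- spec$sigma * (1 + spec$lambda) / 2
  beads <- tibble(
    bead = 1:2, mol = 1:2, species = "ideal", klass = "ideal",
    iclass = c("twobody", "twobody"), residue = NA_integer_,
    mass = mass, hardcore_radius = spec$sigma / 2, charge = 0,
    hbond_donors = 0L, hbond_acceptors = 0L,
    x = c(spec$box_edge / 2, spec$box_edge / 2 + start),
    y = spec$box_edge / 2, z = spec$box_edge / 2,
    vx = v[, 1], vy = v[, 2], vz = v[, 3]
  )
  structure(
    list(beads = beads,
         bonds = tibble(i = integer(0), j = integer(0),
                        d_min = numeric(0), d_max = numeric(0),
                        kind = character(0)),
         box_edge = spec$box_edge, time = 0,
         config = structure(list(seed = as.integer(seed),
                                 temperature = spec$temperature),
                            class = "system_config"),
         species_count = c(twobody = 2)),
    class = "system_state"
  )
}

#' Pair table containing only the two-body square well
#'
#' @param spec A [two_body_spec()].
#' @return A `pair_table` with the single class `"twobody"`.
#' @export
two_body_table <- function(spec) {
  pot <- two_body_potential(spec)
  attr(pot, "dispersion_tail") <- FALSE
  structure(
    list(classes = "twobody",
         potentials = stats::setNames(list(pot),
                                      .pair_key("twobody", "twobody")),
         params = list()),
    class = "pair_table"
  )
}
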