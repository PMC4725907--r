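# Shared fixtures: built once per test run.

the_table <- default_pair_table()

# small assembled system reused by engine tests: 1 peptide + 2 curcumin
small_system <- local({
  cfg <- system_config(1, "curcumin", seed = 11, event_budget = 2e4)
  assemble_system(cfg)
})

# a short NVE trajectory on the small system
small_nve <- run_dmd(small_system, pair_table = the_table,
                     event_budget = 2e4, thermostat_rate = 0,
                     emit_every = 2000)

# hand-rolled union-find: the independent clustering oracle
uf_components <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (k in seq_along(edges_i)) {
    ra <- find(edges_i[k]); rb <- find(edges_j[k])
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force scan oracle for the first boundary crossing of |r + v t| = d
scan_first_crossing <- function(r, v, boundaries, t_max = 50, dt = 1e-4) {
  boundaries <- sort(boundaries)
  t <- seq(0, t_max, by = dt)
  dist <- sqrt(colSums((outer(r, rep(1, length(t))) +
                          outer(v, t))^2))
  side0 <- findInterval(dist[1], boundaries)
  sides <- findInterval(dist, boundaries)
  hit <- which(sides != side0)[1]
  if (is.na(hit)) return(NULL)
  crossed <- if (sides[hit] < side0) boundaries[side0] else
    boundaries[side0 + 1L]
  list(time = t[hit], boundary = crossed)
}

# build a dmd_trajectory-shaped object from an explicit bead tibble and a
# list of coordinate matrices (one per frame)
manual_trajectory <- function(beads, frames_xyz, box_edge) {
  nf <- length(frames_xyz)
  n <- nrow(beads)
  coords <- array(NA_real_, c(nf, n, 3))
  for (k in seq_len(nf)) coords[k, , ] <- frames_xyz[[k]]
  structure(
    list(
      frames = tibble::tibble(frame = seq_len(nf),
                              time = as.numeric(seq_len(nf)),
                              kinetic = NA_real_, potential = NA_real_,
                              temperature = NA_real_),
      coords = coords, velocities = NULL,
      beads = beads, box_edge = box_edge,
      config = list(), seed = 0L
    ),
    class = "dmd_trajectory"
  )
}

# minimal bead row constructor for manual fixtures
bead_row <- function(bead, mol, species, x, y, z,
                     klass = if (species == "IAPP") "backbone"
                             else "ligand_aromatic",
                     residue = NA_integer_, donors = 0L, acceptors = 0L) {
  tibble::tibble(
    bead = bead, mol = mol, species = species, klass = klass,
    iclass = klass, residue = residue, mass = 100,
    hardcore_radius = 2, charge = 0,
    hbond_donors = donors, hbond_acceptors = acceptors,
    x = x, y = y, z = z
  )
}
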