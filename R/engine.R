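# R surface of the event-driven dynamics engine.

#' @useDynLib oligodmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# convert a pair_table to the flat representation the C++ core uses
.table_for_engine <- function(table) {
  classes <- table$classes
  nc <- length(classes)
  pots <- list()
  tail <- integer(0)
  pt_index <- matrix(-1L, nc, nc)
  for (ia in seq_len(nc)) {
    for (ib in ia:nc) {
      pot <- pair_potential(classes[ia], classes[ib], table)
      if (length(pot$shell_radii) == 0) next
      pots[[length(pots) + 1L]] <- list(
        radii = c(pot$hardcore, pot$shell_radii),
        energies = pot$shell_energies
      )
      tail <- c(tail, as.integer(isTRUE(attr(pot, "dispersion_tail"))))
      pt_index[ia, ib] <- pt_index[ib, ia] <- length(pots) - 1L
    }
  }
  list(classes = classes, pots = pots, tail = tail, pt_index = pt_index)
}

.bead_class_index <- function(iclass, classes) {
  idx <- match(iclass, classes)
  if (anyNA(idx)) {
    stop("bead classes not covered by the pair table: ",
         paste(unique(iclass[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx - 1L
}

#' Run event-driven dynamics from an assembled system
#'
#' Executes two-body events (hardcore bounces, shell crossings, bond walls,
#' hydrogen-bond reactions) in causal order, interleaved with Anderson
#' thermostat reassignments, and emits frames either every `emit_every`
#' two-body events or every `emit_dt` reduced time units. Deterministic
#' given the seed.
#'
#' @param system A `system_state` from [assemble_system()].
#' @param pair_table Pair potentials, see [default_pair_table()].
#' @param hbond Hydrogen-bond rule, see [hbond_rule()]; `NULL` disables
#'   hydrogen bonding.
#' @param event_budget Two-body events to execute (default from the config).
#' @param max_time Stop time in reduced units.
#' @param emit_every Frame every this many two-body events (0 disables).
#' @param emit_dt Frame every this much reduced time (`Inf` disables).
#' @param thermostat_rate Anderson rate per bead per reduced time
#'   (0 gives NVE dynamics).
#' @param temperature Target temperature (K).
#' @param seed Engine RNG seed (default derived from the config).
#' @param delta Neighbour-search travel bound (Angstrom).
#' @param horizon Upper bound on a bead's refresh interval (reduced time).
#' @return A `dmd_trajectory`: frame metadata tibble (`time`, `kinetic`,
#'   `potential`, `temperature`, hydrogen-bond counts), coordinate and
#'   velocity arrays, the static bead table, the final state and the final
#'   hydrogen-bond registry.
#' @export
run_dmd <- function(system,
                    pair_table = default_pair_table(),
                    hbond = hbond_rule(),
                    event_budget = NULL,
                    max_time = NULL,
                    emit_every = NULL,
                    emit_dt = Inf,
                    thermostat_rate = NULL,
                    temperature = NULL,
                    seed = NULL,
                    delta = 1.0,
                    horizon = 25) {
  stopifnot(inherits(system, "system_state"))
  cfg <- system$config
  grab <- function(x, dflt) if (!is.null(x)) x else dflt
  event_budget <- grab(event_budget, grab(cfg$event_budget, 2e5))
  max_time <- grab(max_time, grab(cfg$max_time, Inf))
  emit_every <- grab(emit_every, grab(cfg$emit_every, 1000))
  thermostat_rate <- grab(thermostat_rate, grab(cfg$thermostat_rate, 0.002))
  temperature <- grab(temperature, grab(cfg$temperature, 300))
  seed <- grab(seed, grab(cfg$seed, 1L))
  if (!is.finite(max_time) && !is.finite(event_budget)) {
    stop("need a finite event_budget or max_time", call. = FALSE)
  }

  b <- system$beads
  eng <- .table_for_engine(pair_table)
  iclass <- .bead_class_index(b$iclass, eng$classes)
  hb_on <- !is.null(hbond)
  if (!hb_on) hbond <- hbond_rule()  # placeholder values, disabled below

  bonds <- system$bonds
  # validate bond ranges at entry so wall reflections are well defined
  d0 <- sqrt((.min_image(b$x[bonds$i] - b$x[bonds$j], system$box_edge))^2 +
             (.min_image(b$y[bonds$i] - b$y[bonds$j], system$box_edge))^2 +
             (.min_image(b$z[bonds$i] - b$z[bonds$j], system$box_edge))^2)
  bad <- which(d0 < bonds$d_min - 1e-9 | d0 > bonds$d_max + 1e-9)
  if (length(bad) > 0) {
    stop("initial state violates ", length(bad), " bond range(s)",
         call. = FALSE)
  }

  res <- cpp_run_dmd(
    x0 = cbind(b$x, b$y, b$z),
    v0 = cbind(b$vx, b$vy, b$vz),
    mass = b$mass,
    iclass = iclass,
    mol = b$mol - 1L,
    don_cap = as.integer(b$hbond_donors),
    acc_cap = as.integer(b$hbond_acceptors),
    is_pep = as.integer(b$species == "IAPP"),
    box_edge = system$box_edge,
    pots_in = eng$pots,
    pots_tail = eng$tail,
    pt_index_in = eng$pt_index,
    hb_dmin = hbond$d_min, hb_dmax = hbond$d_max,
    hb_eps = hbond$bond_energy, hb_on = hb_on,
    bond_i = bonds$i - 1L, bond_j = bonds$j - 1L,
    bond_dmin = bonds$d_min, bond_dmax = bonds$d_max,
    kT_target = kT(temperature),
    thermo_rate = thermostat_rate,
    event_budget = event_budget, max_time = max_time,
    emit_every = emit_every, emit_dt = emit_dt,
    seed = seed, delta = delta, horizon = horizon,
    t0 = system$time
  )

  n <- nrow(b)
  nf <- res$n_frames
  coords <- aperm(array(res$frame_x, dim = c(3, n, nf)), c(3, 2, 1))
  vels <- aperm(array(res$frame_v, dim = c(3, n, nf)), c(3, 2, 1))
  ndof <- 3 * n
  frames <- tibble(
    frame = seq_len(nf),
    time = res$frame_time,
    kinetic = res$frame_ke,
    potential = res$frame_pe,
    temperature = 2 * res$frame_ke / (ndof * .kB_kcal),
    hb_peptide_peptide = res$frame_hb_pp,
    hb_peptide_ligand = res$frame_hb_pl,
    events = res$frame_events
  )

  final <- system
  final$beads$x <- res$x_final[, 1]
  final$beads$y <- res$x_final[, 2]
  final$beads$z <- res$x_final[, 3]
  final$beads$vx <- res$v_final[, 1]
  final$beads$vy <- res$v_final[, 2]
  final$beads$vz <- res$v_final[, 3]
  final$time <- res$time_final

  structure(
    list(
      frames = frames,
      coords = coords,
      velocities = vels,
      beads = b[, setdiff(names(b), c("x", "y", "z", "vx", "vy", "vz"))],
      box_edge = system$box_edge,
      config = cfg,
      seed = seed,
      final_state = final,
      hb_registry = res$hb_registry,
      event_counts = res$counts,
      n_pair_events = res$n_pair_events
    ),
    class = "dmd_trajectory"
  )
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat("<dmd_trajectory> ", nrow(x$frames), " frames, ",
      nrow(x$beads), " beads, t in [",
      format(min(x$frames$time), digits = 4), ", ",
      format(max(x$frames$time), digits = 4), "] (",
      format(x$n_pair_events, big.mark = ","), " two-body events)\n",
      sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `dmd_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$frames)

#' Extract one frame as a bead tibble
#'
#' @param traj A `dmd_trajectory`.
#' @param k Frame index (1-based).
#' @param velocities Include velocity columns?
#' @return The static bead table with `x`, `y`, `z` (and optionally
#'   `vx`, `vy`, `vz`) for that frame, plus `time` and `box_edge` attributes.
#' @export
traj_frame <- function(traj, k, velocities = FALSE) {
  stopifnot(k >= 1, k <= n_frames(traj))
  out <- traj$beads
  out$x <- traj$coords[k, , 1]
  out$y <- traj$coords[k, , 2]
  out$z <- traj$coords[k, , 3]
  if (velocities) {
    out$vx <- traj$velocities[k, , 1]
    out$vy <- traj$velocities[k, , 2]
    out$vz <- traj$velocities[k, , 3]
  }
  attr(out, "time") <- traj$frames$time[k]
  attr(out, "box_edge") <- traj$box_edge
  out
}

#' Total kinetic and potential energy of a state
#'
#' Direct O(N^2) shell lookup over all non-bonded pairs plus the
#' hydrogen-bond registry; the reference implementation against which the
#' engine's incremental bookkeeping is validated.
#'
#' @param state A `system_state` (or a frame tibble with a `box_edge`
#'   attribute).
#' @param pair_table Pair potentials.
#' @param hbond Hydrogen-bond rule (`NULL` to ignore hydrogen bonds).
#' @param hb_registry Optional two-column matrix of reacted (donor,
#'   acceptor) bead indices; if `NULL` and `hbond` is given, a greedy
#'   distance-based registry is built (ties broken by bead index).
#' @return Named list with `kinetic` and `potential` (kcal/mol).
#' @export
total_energy <- function(state, pair_table = default_pair_table(),
                         hbond = hbond_rule(), hb_registry = NULL) {
  if (inherits(state, "system_state")) {
    b <- state$beads
    edge <- state$box_edge
  } else {
    b <- state
    edge <- attr(state, "box_edge")
    if (is.null(edge)) stop("frame tibble lacks a box_edge attribute",
                            call. = FALSE)
  }
  eng <- .table_for_engine(pair_table)
  iclass <- .bead_class_index(b$iclass, eng$classes)
  if (is.null(hb_registry)) {
    hb_registry <- if (is.null(hbond)) {
      matrix(integer(0), 0, 2)
    } else {
      .greedy_hbonds(b, edge, hbond)
    }
  }
  vx <- if ("vx" %in% names(b)) b$vx else rep(0, nrow(b))
  vy <- if ("vy" %in% names(b)) b$vy else rep(0, nrow(b))
  vz <- if ("vz" %in% names(b)) b$vz else rep(0, nrow(b))
  bonds <- if (inherits(state, "system_state")) state$bonds else
    attr(state, "bonds")
  if (is.null(bonds)) bonds <- tibble(i = integer(0), j = integer(0))
  res <- cpp_total_energy(
    x = cbind(b$x, b$y, b$z), v = cbind(vx, vy, vz), mass = b$mass,
    iclass = iclass, mol = b$mol - 1L, box_edge = edge,
    pots_in = eng$pots, pots_tail = eng$tail, pt_index_in = eng$pt_index,
    bond_i = bonds$i - 1L, bond_j = bonds$j - 1L,
    hb_registry = hb_registry,
    hb_eps = if (is.null(hbond)) 0 else hbond$bond_energy
  )
  list(kinetic = res$kinetic, potential = res$potential)
}

# greedy distance-based hydrogen-bond registry (capacity-limited, ties by
# bead index); used when no engine registry is available
.greedy_hbonds <- function(beads, edge, rule) {
  don <- as.integer(beads$hbond_donors)
  acc <- as.integer(beads$hbond_acceptors)
  cand <- which(don > 0 | acc > 0)
  if (length(cand) < 2) return(matrix(integer(0), 0, 2))
  xyz <- cbind(beads$x, beads$y, beads$z)[cand, , drop = FALSE]
  d2 <- .min_image_cross_dist2(xyz, xyz, edge)
  hits <- which(upper.tri(d2) & d2 < rule$d_max^2 & d2 > rule$d_min^2,
                arr.ind = TRUE)
  if (nrow(hits) == 0) return(matrix(integer(0), 0, 2))
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  reg <- matrix(integer(0), 0, 2)
  for (k in seq_len(nrow(hits))) {
    i <- cand[hits[k, 1]]; j <- cand[hits[k, 2]]
    if (don[i] > 0 && acc[j] > 0) {
      don[i] <- don[i] - 1L; acc[j] <- acc[j] - 1L
      reg <- rbind(reg, c(i, j))
    } else if (don[j] > 0 && acc[i] > 0) {
      don[j] <- don[j] - 1L; acc[i] <- acc[i] - 1L
      reg <- rbind(reg, c(j, i))
    }
  }
  reg
}

#' Predict the next boundary crossing of a free-flying pair
#'
#' Smallest positive root of `|r + v t| = d` over the supplied boundary
#' radii: the first potential step the pair will encounter, or `NULL` if the
#' pair separates past all boundaries.
#'
#' @param r Relative position (3-vector, Angstrom), optionally reduced to
#'   its minimum image when `box_edge` is given.
#' @param v Relative velocity (3-vector).
#' @param boundaries Boundary radii (any order).
#' @param box_edge Optional periodic box edge.
#' @return `NULL`, or a list with `time` and `boundary`.
#' @export
predict_pair_event <- function(r, v, boundaries, box_edge = NULL) {
  if (any(!is.finite(r)) || any(!is.finite(v))) {
    stop("NaN/Inf in pair kinematics", call. = FALSE)
  }
  if (!is.null(box_edge)) r <- .min_image(r, box_edge)
  boundaries <- sort(boundaries)
  rr2 <- sum(r^2); rr <- sqrt(rr2)
  b <- sum(r * v); v2 <- sum(v^2)
  if (v2 <= 0) return(NULL)
  tol <- 1e-9
  inner <- boundaries[boundaries < rr - tol]
  outer <- boundaries[boundaries > rr + tol]
  if (b < 0 && length(inner) > 0) {
    din <- max(inner)
    disc <- b^2 - v2 * (rr2 - din^2)
    if (disc > 0) {
      return(list(time = (-b - sqrt(disc)) / v2, boundary = din))
    }
  }
  if (length(outer) == 0) return(NULL)
  dout <- min(outer)
  disc <- max(b^2 - v2 * (rr2 - dout^2), 0)
  list(time = (-b + sqrt(disc)) / v2, boundary = dout)
}

#' Resolve a two-body collision at a potential step
#'
#' Applies an impulse along the line of centres: the pair crosses the step
#' if the radial kinetic energy exceeds the step height `dU` (new radial
#' speed `sqrt(vr^2 - 2 dU / mu)`), otherwise it reflects elastically.
#' `dU = Inf` encodes a hard wall. Linear momentum is conserved exactly and
#' only the radial velocity component changes.
#'
#' @param m1,m2 Masses (amu).
#' @param r12 Vector from bead 1 to bead 2 at the boundary.
#' @param v1,v2 Velocities.
#' @param dU Step height crossed in the direction of motion (kcal/mol).
#' @return List with new velocities `v1`, `v2`, whether the step was
#'   `crossed`, and the potential-energy change `dU_applied`.
#' @export
resolve_collision <- function(m1, m2, r12, v1, v2, dU) {
  nvec <- r12 / sqrt(sum(r12^2))
  vr <- sum((v2 - v1) * nvec)
  mu <- m1 * m2 / (m1 + m2)
  crossed <- is.finite(dU) && 0.5 * mu * vr^2 > dU
  vrp <- if (crossed) sign(vr) * sqrt(vr^2 - 2 * dU / mu) else -vr
  dvr <- vrp - vr
  list(
    v1 = v1 - mu * dvr / m1 * nvec,
    v2 = v2 + mu * dvr / m2 * nvec,
    crossed = crossed,
    dU_applied = if (crossed) dU else 0
  )
}

#' Annealed aggregation run: hot assembly stage, then a 300 K quench
#'
#' Self-assembly at the study's peptide density is encounter-limited: with
#' physical bead masses, cluster-cluster collisions are rare once most
#' chains are bound. This protocol runs a weakly coupled hot stage (the
#' binding energy released by association is allowed to accelerate
#' transport) followed by a strongly coupled quench to the target
#' temperature; statistics are taken from the quenched trajectory's
#' steady-state window, where the kinetic temperature has relaxed to
#' ~300 K.
#'
#' @param system A `system_state` from [assemble_system()].
#' @param hot_events Two-body events for the assembly stage.
#' @param cold_events Two-body events for the quench stage.
#' @param hot_rate Anderson rate during assembly (weak coupling).
#' @param cold_rate Anderson rate during the quench (strong coupling).
#' @param ... Passed to both [run_dmd()] calls.
#' @return The quenched `dmd_trajectory`; the assembly-stage trajectory is
#'   attached as the `hot_stage` attribute.
#' @export
run_dmd_annealed <- function(system, hot_events = 1.2e7, cold_events = 2e6,
                             hot_rate = 3e-4, cold_rate = 0.01, ...) {
  seed <- system$config$seed
  if (is.null(seed)) seed <- 1L
  hot <- run_dmd(system, thermostat_rate = hot_rate,
                 event_budget = hot_events,
                 emit_every = max(1, floor(hot_events / 20)), ...)
  cold <- run_dmd(hot$final_state, thermostat_rate = cold_rate,
                  event_budget = cold_events,
                  emit_every = max(1, floor(cold_events / 40)),
                  seed = seed + 7919L, ...)
  attr(cold, "hot_stage") <- hot
  cold
}

#' Assemble-then-quench protocol with an adaptive hot stage
#'
#' Runs the weakly coupled hot stage in chunks and stops as soon as the
#' peptides form the target number of contact clusters (or the chunk budget
#' is exhausted), then quenches to the target temperature. Self-assembly at
#' the study density is encounter-limited with a heavy-tailed time to the
#' final cluster merge, so fast seeds stop early and stragglers get the
#' remaining budget.
#'
#' @param system A `system_state` with at least one peptide.
#' @param chunk_events Two-body events per hot chunk.
#' @param max_chunks Hot-stage budget cap, in chunks.
#' @param target_clusters Stop when the peptide-containing cluster count
#'   reaches this value (default 1).
#' @param cold_events,hot_rate,cold_rate See [run_dmd_annealed()].
#' @param ... Passed to [run_dmd()].
#' @return The quenched `dmd_trajectory`, with attributes `hot_chunks`
#'   (chunks used) and `assembled` (whether the target was reached).
#' @export
run_until_assembled <- function(system, chunk_events = 4e6, max_chunks = 4,
                                target_clusters = 1, cold_events = 2e6,
                                hot_rate = 3e-4, cold_rate = 0.01, ...) {
  seed <- system$config$seed
  if (is.null(seed)) seed <- 1L
  state <- system
  assembled <- FALSE
  used <- 0L
  for (chunk in seq_len(max_chunks)) {
    tr <- run_dmd(state, thermostat_rate = hot_rate,
                  event_budget = chunk_events, emit_every = chunk_events,
                  seed = seed + 131L * chunk, ...)
    state <- tr$final_state
    used <- chunk
    fr <- traj_frame(tr, n_frames(tr))
    cl <- attr(cluster_frame(contacts(fr)), "clusters")
    n_pep_cl <- sum(cl$n_peptides > 0)
    if (n_pep_cl <= target_clusters) {
      assembled <- TRUE
      break
    }
  }
  cold <- run_dmd(state, thermostat_rate = cold_rate,
                  event_budget = cold_events,
                  emit_every = max(1, floor(cold_events / 40)),
                  seed = seed + 7919L, ...)
  attr(cold, "hot_chunks") <- used
  attr(cold, "assembled") <- assembled
  cold
}
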