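# Assembly of simulation boxes: constant peptide density across system
# sizes, 1:2 peptide:ligand stoichiometry, randomized overlap-free placement
# and Maxwell-Boltzmann velocities.

#' Cubic box edge preserving peptide density
#'
#' The box grows as the cube root of the chain count so the peptide number
#' density is identical for every system size.
#'
#' @param n_peptides Number of peptide chains (>= 1).
#' @param base_edge Edge (Angstrom) of the one-peptide box; default 63.7.
#' @return Edge length in Angstrom.
#' @examples
#' box_edge(8, 63.65)  # ~127.3, the eight-chain box
#' @export
box_edge <- function(n_peptides, base_edge = 63.7) {
  if (any(n_peptides < 1) || any(base_edge <= 0)) {
    stop("n_peptides must be >= 1 and base_edge > 0", call. = FALSE)
  }
  base_edge * n_peptides^(1 / 3)
}

#' Peptide molar concentration in a cubic box
#'
#' @param n_peptides Number of chains (>= 0).
#' @param edge Box edge in Angstrom.
#' @return Concentration in mM.
#' @examples
#' peptide_concentration(8, 127.3)  # ~6.4 mM
#' @export
peptide_concentration <- function(n_peptides, edge) {
  if (any(edge <= 0)) stop("edge must be positive", call. = FALSE)
  if (any(n_peptides < 0)) stop("n_peptides must be >= 0", call. = FALSE)
  litres <- edge^3 * 1e-27
  n_peptides / (.N_avogadro * litres) * 1e3
}

#' Dilution arithmetic for a DLS sample well
#'
#' @param stock_conc Stock concentration (micromolar).
#' @param stock_volume Stock volume pipetted (microlitre).
#' @param final_volume Final well volume (microlitre).
#' @return Final concentration in micromolar.
#' @examples
#' dls_mixture_concentration(64, 6, 20)  # 19.2 uM working IAPP concentration
#' dls_mixture_concentration(87, 9, 20)  # 39.15 uM resveratrol control
#' @export
dls_mixture_concentration <- function(stock_conc, stock_volume, final_volume) {
  if (any(stock_volume <= 0) || any(final_volume <= 0)) {
    stop("volumes must be positive", call. = FALSE)
  }
  if (any(stock_volume > final_volume)) {
    stop("stock volume cannot exceed the final volume", call. = FALSE)
  }
  stock_conc * stock_volume / final_volume
}

#' Simulation configuration
#'
#' @param n_peptides Number of IAPP chains (0 for pure-ligand systems).
#' @param ligand_species Optional ligand species name.
#' @param ligands_per_peptide Ligands per peptide chain (default 2).
#' @param n_ligands Explicit ligand count; overrides `ligands_per_peptide`
#'   (required when `n_peptides = 0`).
#' @param base_edge Edge of the one-peptide box (Angstrom).
#' @param edge Explicit box edge; overrides the density rule.
#' @param temperature Target temperature (K).
#' @param seed Integer seed; every random choice derives from it.
#' @param event_budget Number of two-body events to execute.
#' @param max_time Optional stop time (reduced units).
#' @param thermostat_rate Anderson reassignment rate per bead per reduced
#'   time.
#' @param emit_every Emit a frame every this many two-body events.
#' @return A `system_config` list.
#' @export
system_config <- function(n_peptides,
                          ligand_species = NULL,
                          ligands_per_peptide = 2,
                          n_ligands = NULL,
                          base_edge = 63.7,
                          edge = NULL,
                          temperature = 300,
                          seed = 1L,
                          event_budget = 2e5,
                          max_time = Inf,
                          thermostat_rate = 0.002,
                          emit_every = 1000) {
  if (n_peptides < 0 || ligands_per_peptide < 0 || base_edge <= 0) {
    stop("invalid configuration", call. = FALSE)
  }
  if (is.null(n_ligands)) {
    n_ligands <- if (is.null(ligand_species)) 0L else
      as.integer(n_peptides * ligands_per_peptide)
  }
  if (n_ligands > 0 && is.null(ligand_species)) {
    stop("ligand_species required when ligands are requested", call. = FALSE)
  }
  if (is.null(edge)) {
    if (n_peptides < 1) {
      stop("an explicit `edge` is required for peptide-free systems",
           call. = FALSE)
    }
    edge <- box_edge(n_peptides, base_edge)
  }
  structure(
    list(n_peptides = as.integer(n_peptides),
         ligand_species = ligand_species,
         n_ligands = as.integer(n_ligands),
         base_edge = base_edge, edge = edge,
         temperature = temperature, seed = as.integer(seed),
         event_budget = event_budget, max_time = max_time,
         thermostat_rate = thermostat_rate, emit_every = emit_every),
    class = "system_config"
  )
}

# species-qualified interaction class of each bead
.bead_iclass <- function(klass, species, charge, residue = NA_integer_) {
  ifelse(
    startsWith(klass, "ligand"), paste0(klass, ":", species),
    ifelse(klass == "backbone" & charge != 0, "backbone+", klass)
  )
}

.min_image <- function(d, edge) d - edge * round(d / edge)

# minimum-image distances between one point set and another (matrices n x 3)
.min_image_cross_dist2 <- function(a, b, edge) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- .min_image(dx, edge)
  dy <- outer(a[, 2], b[, 2], "-"); dy <- .min_image(dy, edge)
  dz <- outer(a[, 3], b[, 3], "-"); dz <- .min_image(dz, edge)
  dx^2 + dy^2 + dz^2
}

.random_rotation <- function() {
  # uniform rotation from a random quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Assemble a randomized simulation box
#'
#' Molecules are placed with random positions and orientations and
#' rejection-sampled until no minimum-image hardcore overlap remains (the
#' event-driven dynamics has no gradients, so overlap-free placement plays
#' the role a steepest-descent minimization plays in force-field codes).
#' Per-bead velocities are drawn from the Maxwell-Boltzmann distribution at
#' the target temperature and shifted to zero total momentum. Deterministic
#' given `config$seed`.
#'
#' @param config A [system_config()].
#' @param max_tries Placement attempts per molecule before giving up.
#' @return A `system_state`: a list with a `beads` tibble (identity, class,
#'   mass, radius, charge, hydrogen-bond capacities, position, velocity),
#'   `box_edge`, `time` and the originating config.
#' @export
assemble_system <- function(config, max_tries = 5000) {
  stopifnot(inherits(config, "system_config"))
  set.seed(config$seed)
  specs <- character(0)
  if (config$n_peptides > 0) {
    specs <- c(specs, rep("IAPP", config$n_peptides))
  }
  if (config$n_ligands > 0) {
    specs <- c(specs, rep(config$ligand_species, config$n_ligands))
  }
  if (length(specs) == 0) stop("empty system", call. = FALSE)
  tops <- lapply(unique(specs), build_species)
  names(tops) <- unique(specs)

  edge <- config$edge
  placed <- list()
  placed_xyz <- NULL
  placed_radii <- numeric(0)
  for (m in seq_along(specs)) {
    top <- tops[[specs[m]]]
    ref <- top$ref_coords
    ref <- sweep(ref, 2, colMeans(ref))
    radii <- top$beads$hardcore_radius
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      xyz <- ref %*% t(.random_rotation())
      xyz <- sweep(xyz, 2, stats::runif(3, 0, edge), "+")
      if (is.null(placed_xyz)) {
        ok <- TRUE
      } else {
        d2 <- .min_image_cross_dist2(xyz, placed_xyz, edge)
        lim <- outer(radii, placed_radii, "+")
        ok <- all(d2 >= lim^2)
      }
      if (ok) break
    }
    if (!ok) {
      stop("could not place molecule ", m, " of ", length(specs),
           " without hardcore overlap after ", max_tries,
           " attempts; the box is too dense", call. = FALSE)
    }
    placed[[m]] <- xyz
    placed_xyz <- rbind(placed_xyz, xyz)
    placed_radii <- c(placed_radii, radii)
  }

  bead_tabs <- lapply(seq_along(specs), function(m) {
    top <- tops[[specs[m]]]
    b <- top$beads
    tibble(
      mol = m, species = specs[m],
      klass = b$klass,
      residue = if (!is.null(top$residue_map)) top$residue_map else
        NA_integer_,
      mass = b$mass, hardcore_radius = b$hardcore_radius,
      charge = b$charge,
      hbond_donors = b$hbond_donors, hbond_acceptors = b$hbond_acceptors,
      x = placed[[m]][, 1] %% edge,
      y = placed[[m]][, 2] %% edge,
      z = placed[[m]][, 3] %% edge
    )
  })
  beads <- bind_rows(bead_tabs)
  beads$bead <- seq_len(nrow(beads))
  beads$iclass <- .bead_iclass(beads$klass, beads$species, beads$charge)

  n <- nrow(beads)
  sd_v <- sqrt(kT(config$temperature) / beads$mass)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd_v
  ptot <- colSums(v * beads$mass)
  v <- sweep(v, 2, ptot / sum(beads$mass))
  beads$vx <- v[, 1]; beads$vy <- v[, 2]; beads$vz <- v[, 3]

  beads <- beads[, c("bead", "mol", "species", "klass", "iclass", "residue",
                     "mass", "hardcore_radius", "charge", "hbond_donors",
                     "hbond_acceptors", "x", "y", "z", "vx", "vy", "vz")]

  bonds <- bind_rows(lapply(seq_along(specs), function(m) {
    top <- tops[[specs[m]]]
    off <- min(beads$bead[beads$mol == m]) - 1L
    mutate(top$bonds, i = .data$i + off, j = .data$j + off)
  }))

  structure(
    list(beads = as_tibble(beads), bonds = bonds, box_edge = edge,
         time = 0, config = config,
         species_count = table(specs)),
    class = "system_state"
  )
}

#' @export
print.system_state <- function(x, ...) {
  cat("<system_state> ", nrow(x$beads), " beads / ",
      length(unique(x$beads$mol)), " molecules in a ",
      format(x$box_edge, digits = 5), " A box, t = ",
      format(x$time, digits = 5), "\n", sep = "")
  invisible(x)
}
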