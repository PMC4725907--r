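# Discrete (multi-step) pair potentials.
#
# Interactions are class-pair square-well ladders obtained by discretizing a
# Lennard-Jones-style attractive profile whose depth is the product of
# per-class hydrophobicity weights; charged classes additionally carry a
# discretized Debye-Hueckel tail. Hydrogen bonds are handled by a separate
# reaction rule (distance-triggered, capacity-limited) in the engine.

# class hardcore radii (A); bead radii in the species library equal these so
# the class-pair hardcore distance is exactly the sum of bead radii
.class_radius <- c(
  backbone = 2.0, `backbone+` = 2.0,
  sidechain_hydrophobic = 2.1, sidechain_polar = 2.0,
  sidechain_charged = 2.2, sidechain_aromatic = 2.3,
  ligand_aromatic = 2.3, ligand_aliphatic = 2.0, ligand_polar_O = 1.8,
  ideal = 0
)

.class_charge <- c(
  backbone = 0, `backbone+` = 1,
  sidechain_hydrophobic = 0, sidechain_polar = 0,
  sidechain_charged = 1, sidechain_aromatic = 0,
  ligand_aromatic = 0, ligand_aliphatic = 0, ligand_polar_O = 0,
  ideal = 0
)

.polar_like <- c("sidechain_polar", "sidechain_charged", "ligand_polar_O")
.hydrophobic_like <- c("sidechain_hydrophobic", "sidechain_aromatic",
                       "ligand_aromatic", "ligand_aliphatic")
.aromatic_like <- c("sidechain_aromatic", "ligand_aromatic")

#' Default ligand hydrophobicity multipliers
#'
#' The three small molecules share bead classes; their differing association
#' propensity (solubility ladder: aspirin most soluble, curcumin least) is
#' carried by a per-species multiplier on the ligand-bead hydrophobicity
#' weights. Values were calibrated with `scripts/calibrate_ladder.R` so that
#' pure-ligand self-assembly reproduces the monomer-probability ordering
#' aspirin > resveratrol > curcumin.
#' @return Named numeric vector.
#' @export
default_ligand_scales <- function() {
  c(aspirin = 0.60, resveratrol = 0.55, curcumin = 1.22)
}

# base hydrophobicity weights per class (unscaled)
.class_hydro <- c(
  backbone = 0.62, `backbone+` = 0.62,
  sidechain_hydrophobic = 1.00, sidechain_polar = 0.38,
  sidechain_charged = 0.25, sidechain_aromatic = 1.12,
  ligand_aromatic = 1.05, ligand_aliphatic = 0.85, ligand_polar_O = 0.35,
  ideal = 0
)

# ---- step potentials -------------------------------------------------------

#' Construct a step (square-well ladder) potential
#'
#' @param hardcore Hardcore distance in Angstrom (infinite wall below).
#' @param shell_radii Strictly increasing radii ending at the cutoff.
#' @param shell_energies Energy (kcal/mol) inside each shell, i.e. between
#'   consecutive radii starting at the hardcore; zero beyond the cutoff.
#' @return A `step_potential` object.
#' @export
step_potential <- function(hardcore, shell_radii, shell_energies) {
  shell_radii <- as.numeric(shell_radii)
  shell_energies <- as.numeric(shell_energies)
  if (length(shell_radii) != length(shell_energies)) {
    stop("need one energy per shell", call. = FALSE)
  }
  if (length(shell_radii) > 0) {
    if (any(diff(c(hardcore, shell_radii)) <= 0)) {
      stop("shell radii must be strictly increasing and exceed the hardcore",
           call. = FALSE)
    }
    if (any(!is.finite(shell_energies))) {
      stop("shell energies must be finite", call. = FALSE)
    }
  }
  structure(
    list(hardcore = hardcore, shell_radii = shell_radii,
         shell_energies = shell_energies),
    class = "step_potential"
  )
}

#' @export
print.step_potential <- function(x, ...) {
  cat("<step_potential> hardcore ", format(x$hardcore), " A, ",
      length(x$shell_radii), " shell(s), cutoff ",
      format(step_cutoff(x)), " A\n", sep = "")
  invisible(x)
}

#' Cutoff radius of a step potential
#' @param pot A `step_potential`.
#' @export
step_cutoff <- function(pot) {
  if (length(pot$shell_radii) == 0) pot$hardcore else max(pot$shell_radii)
}

#' Evaluate a step potential at distances `r`
#'
#' @param pot A `step_potential`.
#' @param r Distances (Angstrom); vectorised.
#' @return Energies in kcal/mol (`Inf` inside the hardcore, 0 beyond cutoff).
#' @export
step_energy <- function(pot, r) {
  edges <- c(pot$hardcore, pot$shell_radii)
  vals <- c(Inf, pot$shell_energies, 0)
  idx <- findInterval(r, edges, left.open = FALSE) + 1L
  out <- vals[idx]
  out[r <= pot$hardcore] <- Inf
  out
}

# sum two step potentials over the union of their breakpoints
.combine_steps <- function(p1, p2) {
  hc <- max(p1$hardcore, p2$hardcore)
  radii <- sort(unique(c(p1$shell_radii, p2$shell_radii)))
  radii <- radii[radii > hc]
  if (length(radii) == 0) return(step_potential(hc, numeric(0), numeric(0)))
  mids <- (c(hc, utils::head(radii, -1)) + radii) / 2
  e <- step_energy(p1, mids) + step_energy(p2, mids)
  keep_trailing_zero_trim <- function(radii, e) {
    while (length(e) > 0 && e[length(e)] == 0) {
      e <- e[-length(e)]
      radii <- radii[-length(radii)]
    }
    list(radii = radii, e = e)
  }
  tz <- keep_trailing_zero_trim(radii, e)
  step_potential(hc, tz$radii, tz$e)
}

#' Discretize a continuous pair potential into equal-width shells
#'
#' Shell radii are uniformly spaced between the hardcore and the cutoff; each
#' shell energy is the mean of `U` over the shell (midpoint-sampled). The
#' energy beyond the last shell is exactly zero.
#'
#' @param U Function of distance (Angstrom) returning kcal/mol.
#' @param hardcore Hardcore distance.
#' @param cutoff Cutoff distance (> hardcore).
#' @param n_shells Number of shells (>= 1).
#' @param n_sample Midpoint samples per shell for the average.
#' @return A [step_potential()].
#' @export
discretize <- function(U, hardcore, cutoff, n_shells, n_sample = 32) {
  stopifnot(cutoff > hardcore, n_shells >= 1)
  radii <- hardcore + (cutoff - hardcore) * seq_len(n_shells) / n_shells
  lo <- c(hardcore, utils::head(radii, -1))
  energies <- vapply(seq_len(n_shells), function(k) {
    w <- radii[k] - lo[k]
    pts <- lo[k] + w * (seq_len(n_sample) - 0.5) / n_sample
    u <- U(pts)
    if (any(!is.finite(u))) {
      stop("potential is divergent inside the discretization range",
           call. = FALSE)
    }
    mean(u)
  }, numeric(1))
  step_potential(hardcore, radii, energies)
}

# ---- electrostatics --------------------------------------------------------

#' Electrostatics parameters
#'
#' @param screening_length Debye screening length in Angstrom (default 10,
#'   the 100 mM NaCl value).
#' @param prefactor Dielectric-lumped Coulomb prefactor in
#'   kcal mol^-1 Angstrom per unit charge pair (default `332.0637 / 78.4`).
#' @export
electrostatics_params <- function(screening_length = 10,
                                  prefactor = .coulomb_kcal / .eps_water) {
  stopifnot(screening_length > 0)
  list(screening_length = screening_length, prefactor = prefactor)
}

#' Debye screening length of a 1:1 electrolyte
#'
#' `1/kappa = 1 / sqrt(8 pi l_B N_A I)` with the Bjerrum length
#' `l_B = e^2 / (4 pi eps0 eps_r kB T)` evaluated at `eps_r = 78.4`.
#'
#' @param ionic_strength Ionic strength in mM.
#' @param temperature Temperature in K.
#' @return Screening length in Angstrom.
#' @examples
#' debye_length(100, 300)  # ~9.6 A, the "10 A at 100 mM NaCl" value
#' @export
debye_length <- function(ionic_strength, temperature = 300) {
  if (any(ionic_strength <= 0) || any(temperature <= 0)) {
    stop("ionic strength and temperature must be positive", call. = FALSE)
  }
  l_bjerrum <- .coulomb_kcal / (.eps_water * .kB_kcal * temperature)
  n <- ionic_strength * 1e-3 * .N_avogadro * 1e-27  # ions per A^3 per species
  1 / sqrt(8 * pi * l_bjerrum * n)
}

#' Screened Coulomb (Debye-Hueckel) interaction energy
#'
#' @param q1,q2 Charges in elementary charge units.
#' @param r Distance in Angstrom (> 0).
#' @param params An [electrostatics_params()] list.
#' @return Energy in kcal/mol.
#' @export
screened_coulomb <- function(q1, q2, r, params = electrostatics_params()) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  params$prefactor * q1 * q2 * exp(-r / params$screening_length) / r
}

# ---- hydrogen-bond rule ----------------------------------------------------

#' Hydrogen-bond reaction rule
#'
#' A donor-acceptor bead pair reacts (forms a bond) when it crosses `d_max`
#' inward with spare capacity on both beads; the reacted pair gains
#' `bond_energy` inside `[d_min, d_max]` and must pay it back to escape.
#' Capacities are enforced greedily; ties are broken by bead index.
#'
#' @param d_min,d_max Bond distance range in Angstrom.
#' @param bond_energy Well depth in kcal/mol (negative).
#' @return An `hbond_rule` list.
#' @export
hbond_rule <- function(d_min = 3.0, d_max = 5.0, bond_energy = -1.5) {
  stopifnot(d_min < d_max, bond_energy < 0)
  structure(
    list(
      d_min = d_min, d_max = d_max, bond_energy = bond_energy,
      donor_classes = c("backbone", "backbone+", "sidechain_polar",
                        "sidechain_charged", "sidechain_aromatic",
                        "ligand_aromatic", "ligand_polar_O"),
      acceptor_classes = c("backbone", "backbone+", "sidechain_polar",
                           "sidechain_aromatic", "ligand_aromatic",
                           "ligand_polar_O")
    ),
    class = "hbond_rule"
  )
}

# ---- pair table ------------------------------------------------------------

.pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")

.qualified_classes <- function() {
  lig <- c("ligand_aromatic", "ligand_aliphatic", "ligand_polar_O")
  qual <- as.vector(outer(lig, names(default_ligand_scales()),
                          function(k, s) paste0(k, ":", s)))
  c("backbone", "backbone+", "sidechain_hydrophobic", "sidechain_polar",
    "sidechain_charged", "sidechain_aromatic", lig, qual, "ideal")
}

.base_class <- function(klass) sub(":.*$", "", klass)

.class_species <- function(klass) {
  ifelse(grepl(":", klass), sub("^.*:", "", klass), NA_character_)
}

#' Build the default pair-potential table
#'
#' Every bead-class pair maps to a discretized attractive well whose depth is
#' `eps0 * h_a * h_b` with per-class hydrophobicity weights `h`; aromatic-
#' aromatic pairs get a stacking bonus, mixed polar-hydrophobic pairs are
#' reduced to near zero (the implicit-solvation penalty), and charged pairs
#' carry a discretized screened-Coulomb tail. Ligand classes may be
#' species-qualified (`"ligand_aromatic:curcumin"`) so the three molecules can
#' sit at different rungs of the hydrophobicity ladder.
#'
#' @param eps0 Depth scale in kcal/mol.
#' @param ligand_scales Named per-species multipliers, see
#'   [default_ligand_scales()].
#' @param well_reach Range of the finely resolved attractive well beyond the
#'   hardcore (Angstrom).
#' @param tail_reach End of the single wide dispersion-tail shell
#'   (Angstrom beyond the hardcore); the weak long tail gives slow, heavy
#'   aggregates a realistic mutual capture cross-section.
#' @param n_shells Shells for the van-der-Waals-like term.
#' @param n_shells_elec Shells for the electrostatic tail.
#' @param elec_cutoff Electrostatics cutoff (Angstrom).
#' @param stacking_bonus Multiplier on aromatic-aromatic depths.
#' @param electrostatics An [electrostatics_params()] list.
#' @return A `pair_table` object.
#' @export
default_pair_table <- function(eps0 = 1.50,
                               ligand_scales = default_ligand_scales(),
                               well_reach = 3.2,
                               tail_reach = 6.0,
                               n_shells = 4,
                               n_shells_elec = 6,
                               elec_cutoff = 12,
                               stacking_bonus = 1.25,
                               electrostatics = electrostatics_params()) {
  classes <- .qualified_classes()
  pots <- list()
  for (ia in seq_along(classes)) {
    for (ib in ia:length(classes)) {
      a <- classes[ia]; b <- classes[ib]
      key <- .pair_key(a, b)
      pots[[key]] <- .build_class_pair(a, b, eps0, ligand_scales, well_reach,
                                       tail_reach, n_shells, n_shells_elec,
                                       elec_cutoff, stacking_bonus,
                                       electrostatics)
    }
  }
  structure(
    list(classes = classes, potentials = pots,
         params = list(eps0 = eps0, ligand_scales = ligand_scales,
                       well_reach = well_reach, tail_reach = tail_reach,
                       n_shells = n_shells,
                       n_shells_elec = n_shells_elec,
                       elec_cutoff = elec_cutoff,
                       stacking_bonus = stacking_bonus,
                       electrostatics = electrostatics)),
    class = "pair_table"
  )
}

.build_class_pair <- function(a, b, eps0, ligand_scales, well_reach,
                              tail_reach, n_shells, n_shells_elec,
                              elec_cutoff, stacking_bonus, electrostatics) {
  ba <- .base_class(a); bb <- .base_class(b)
  if (ba == "ideal" || bb == "ideal") {
    return(step_potential(0, numeric(0), numeric(0)))
  }
  hc <- .class_radius[[ba]] + .class_radius[[bb]]
  ha <- .class_hydro[[ba]]
  hb <- .class_hydro[[bb]]
  sa <- .class_species(a); sb <- .class_species(b)
  if (!is.na(sa) && startsWith(ba, "ligand")) ha <- ha * ligand_scales[[sa]]
  if (!is.na(sb) && startsWith(bb, "ligand")) hb <- hb * ligand_scales[[sb]]
  eps <- eps0 * ha * hb
  if (ba %in% .aromatic_like && bb %in% .aromatic_like) {
    eps <- eps * stacking_bonus
  }
  mixed <- (ba %in% .polar_like && bb %in% .hydrophobic_like) ||
    (bb %in% .polar_like && ba %in% .hydrophobic_like)
  if (mixed) eps <- 0.05 * eps
  lj <- function(r) 4 * eps * ((hc / r)^12 - (hc / r)^6)
  pot <- discretize(lj, hc, hc + well_reach, n_shells)
  has_tail <- FALSE
  if (tail_reach > well_reach && eps > 0) {
    # one wide outer shell standing in for the dispersion tail. Its depth
    # (a tenth of the contact depth) exceeds the relative kinetic energy of
    # slow, heavy aggregates, giving them the mutual capture funnel that the
    # full many-bead dispersion sum would provide; dropped when negligible
    # so weak pairs keep a short event horizon.
    e_tail <- -0.12 * eps
    if (abs(e_tail) >= 0.01) {
      pot <- step_potential(hc, c(pot$shell_radii, hc + tail_reach),
                            c(pot$shell_energies, e_tail))
      has_tail <- TRUE
    }
  }
  qa <- .class_charge[[ba]]; qb <- .class_charge[[bb]]
  if (qa * qb != 0) {
    elec <- discretize(function(r) screened_coulomb(qa, qb, r, electrostatics),
                       hc, elec_cutoff, n_shells_elec)
    pot <- .combine_steps(pot, elec)
    has_tail <- FALSE  # electrostatic tail applies intra-molecularly too
  }
  attr(pot, "dispersion_tail") <- has_tail
  pot
}

#' Look up the step potential for a class pair
#'
#' The lookup is symmetric in its arguments. Species-qualified ligand classes
#' (e.g. `"ligand_aromatic:curcumin"`) resolve to that species' rung of the
#' hydrophobicity ladder; unqualified ligand classes use the resveratrol
#' (middle) rung.
#'
#' @param a,b Bead class names.
#' @param table A `pair_table` from [default_pair_table()].
#' @return A [step_potential()].
#' @export
pair_potential <- function(a, b, table = default_pair_table()) {
  resolve <- function(k) {
    if (k %in% table$classes) return(k)
    stop("unknown bead class: ", k, call. = FALSE)
  }
  a <- resolve(a); b <- resolve(b)
  key <- .pair_key(a, b)
  pot <- table$potentials[[key]]
  if (is.null(pot)) stop("unresolvable class pair: ", key, call. = FALSE)
  pot
}

#' Second virial coefficient of a step potential
#'
#' `B2 = -2 pi Integral (exp(-U/kT) - 1) r^2 dr`, evaluated in closed form
#' over the shells (the integrand is piecewise constant in `exp(-U/kT)`).
#' Less attractive pairs have larger (more positive) `B2`.
#'
#' @param pot A [step_potential()].
#' @param temperature Temperature in K.
#' @return B2 in Angstrom^3.
#' @export
second_virial <- function(pot, temperature = 300) {
  beta <- 1 / kT(temperature)
  edges <- c(0, pot$hardcore, pot$shell_radii)
  mayer <- c(-1, exp(-beta * pot$shell_energies) - 1)  # core, then shells
  seg <- diff(edges^3) / 3
  -2 * pi * sum(mayer * seg)
}

#' Molecule-level pairwise virial sum for two species
#'
#' Sum of bead-pair second virial coefficients over all cross combinations
#' of the two species' beads. A species with more interaction-capable beads
#' is stickier at equal per-bead depth, so this is the molecule-level
#' analogue of the pair B2: larger values mean less mutual attraction.
#'
#' @param species_a,species_b Species names.
#' @param table A `pair_table`.
#' @param temperature Temperature in K.
#' @return Summed B2 in Angstrom^3.
#' @export
species_pair_virial <- function(species_a, species_b,
                                table = default_pair_table(),
                                temperature = 300) {
  qual <- function(sp) {
    b <- build_species(sp)$beads
    cl <- b$klass
    ifelse(startsWith(cl, "ligand"), paste0(cl, ":", sp), cl)
  }
  ca <- qual(species_a)
  cb <- qual(species_b)
  tot <- 0
  for (a in ca) {
    for (b in cb) {
      tot <- tot + second_virial(pair_potential(a, b, table), temperature)
    }
  }
  tot
}
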