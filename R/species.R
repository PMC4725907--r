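#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows bind_cols n row_number across all_of if_else count
#'   rename distinct pull first last lag lead
#' @importFrom rlang .data
NULL

#' Bead classes understood by the pair-potential table
#' @export
bead_classes <- c(
  "backbone", "sidechain_hydrophobic", "sidechain_polar",
  "sidechain_charged", "sidechain_aromatic",
  "ligand_aromatic", "ligand_aliphatic", "ligand_polar_O"
)

#' Supported molecular species
#' @export
species_names <- c("IAPP", "aspirin", "curcumin", "resveratrol")

# Human IAPP (amylin), 37 residues, C-terminally amidated, disulfide 2-7.
iapp_sequence <- "KCNTATCATQRLANFLVHSSNNFGAILSSTNVGSNTY"

# average residue masses (amu); backbone bead carries the peptide unit (~56 amu)
.aa_mass <- c(
  G = 57.05, A = 71.08, S = 87.08, C = 103.14, T = 101.10, V = 99.13,
  L = 113.16, I = 113.16, N = 114.10, Q = 128.13, K = 128.17, R = 156.19,
  H = 137.14, F = 147.18, Y = 163.18
)
.bb_mass <- 56.04

# per-residue hydrogen-bond capacities of the sidechain bead
.sc_donors <- c(
  S = 1, T = 1, Y = 1, N = 1, Q = 1, K = 1, R = 2, H = 1, C = 0, G = 0,
  A = 0, V = 0, L = 0, I = 0, F = 0
)
.sc_acceptors <- c(
  S = 1, T = 1, Y = 1, N = 1, Q = 1, K = 0, R = 0, H = 1, C = 0, G = 0,
  A = 0, V = 0, L = 0, I = 0, F = 0
)

.small_sidechains <- c("A", "S", "T", "C", "V", "G")

.residue_class <- function(aa, idx) {
  if (idx %in% c(15L, 18L, 23L, 37L)) return("sidechain_aromatic")
  if (aa %in% c("K", "R")) return("sidechain_charged")
  if (aa %in% c("L", "F", "I", "V", "A")) return("sidechain_hydrophobic")
  "sidechain_polar"
}

new_molecule_topology <- function(species_name, beads, bonds, ref_coords,
                                  residue_map = NULL,
                                  amyloidogenic_range = NULL) {
  structure(
    list(
      species_name = species_name,
      beads = beads,
      bonds = bonds,
      ref_coords = ref_coords,
      residue_map = residue_map,
      amyloidogenic_range = amyloidogenic_range
    ),
    class = "molecule_topology"
  )
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat("<molecule_topology> ", x$species_name, ": ",
      nrow(x$beads), " beads, ", nrow(x$bonds), " bonds/constraints",
      sep = "")
  if (!is.null(x$residue_map)) {
    cat(", ", max(x$residue_map), " residues", sep = "")
  }
  cat("\n")
  invisible(x)
}

# ---- internal-coordinate chain building ------------------------------------

# place point d from a, b, c with |c-d| = bond, angle(b,c,d) = theta and
# torsion(a,b,c,d) = tau (degrees)
.place_next <- function(a, b, c, bond, theta, tau) {
  th <- theta * pi / 180
  ta <- -tau * pi / 180  # match the analyzer dihedral sign convention
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  )
  n <- n / sqrt(sum(n^2))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  d2 <- bond * c(-cos(th), sin(th) * cos(ta), sin(th) * sin(ta))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# backbone trace with per-position bend angles theta[i] (at bead i, for
# i = 2..n-1) and torsions tau[i] (for bead i+.. defined from bead 4 on)
.chain_trace <- function(n, bond, theta, tau) {
  theta <- rep_len(theta, n)
  tau <- rep_len(tau, n)
  xyz <- matrix(0, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  if (n >= 2) xyz[2, ] <- c(bond, 0, 0)
  if (n >= 3) {
    th <- theta[2] * pi / 180
    xyz[3, ] <- xyz[2, ] + bond * c(-cos(th), sin(th), 0)
  }
  if (n >= 4) {
    for (i in 4:n) {
      xyz[i, ] <- .place_next(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                              bond, theta[i - 1], tau[i])
    }
  }
  xyz
}

# sidechain centroid placement: radially away from the local backbone midpoint
.sidechain_point <- function(bb, i, dist = 3.2) {
  n <- nrow(bb)
  j1 <- max(1L, i - 1L)
  j2 <- min(n, i + 1L)
  if (j1 == i) j1 <- min(n, i + 2L)
  if (j2 == i) j2 <- max(1L, i - 2L)
  u <- bb[i, ] - (bb[j1, ] + bb[j2, ]) / 2
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) u <- c(0, 0, 1) else u <- u / nu
  bb[i, ] + dist * u
}

# ---- species builders ------------------------------------------------------

.build_iapp <- function() {
  seq_chars <- strsplit(iapp_sequence, "")[[1]]
  n_res <- length(seq_chars)
  stopifnot(n_res == 37L)

  has_sc <- seq_chars != "G"
  bead_rows <- list()
  bead_id <- 0L
  bb_idx <- integer(n_res)
  sc_idx <- rep(NA_integer_, n_res)
  for (i in seq_len(n_res)) {
    aa <- seq_chars[i]
    bead_id <- bead_id + 1L
    bb_idx[i] <- bead_id
    bead_rows[[length(bead_rows) + 1L]] <- tibble(
      bead_id = bead_id, klass = "backbone", mass = .bb_mass,
      hardcore_radius = 2.0,
      charge = if (i == 1L) 1 else 0,  # free N-terminal amine; C-term amidated
      hbond_donors = 1L, hbond_acceptors = 1L, residue = i
    )
    if (has_sc[i]) {
      bead_id <- bead_id + 1L
      sc_idx[i] <- bead_id
      kl <- .residue_class(aa, i)
      bead_rows[[length(bead_rows) + 1L]] <- tibble(
        bead_id = bead_id, klass = kl,
        mass = .aa_mass[[aa]] - .bb_mass,
        hardcore_radius = .class_radius[[kl]],
        charge = if (i %in% c(1L, 11L)) 1 else 0,  # Lys1, Arg11 at pH 7
        hbond_donors = .sc_donors[[aa]], hbond_acceptors = .sc_acceptors[[aa]],
        residue = i
      )
    }
  }
  beads <- bind_rows(bead_rows)

  sc_res <- which(has_sc)
  prev_ok <- sc_res[sc_res > 1L]
  next_ok <- sc_res[sc_res < n_res]
  bonds <- bind_rows(
    # backbone chain
    tibble(i = bb_idx[seq_len(n_res - 1L)], j = bb_idx[2:n_res],
           d_min = 3.45, d_max = 4.15, kind = "bond"),
    # backbone -> sidechain centroid
    tibble(i = bb_idx[sc_res], j = sc_idx[sc_res],
           d_min = 2.7, d_max = 3.7, kind = "bond"),
    # chain-stiffness window: covers both helical and extended geometry
    tibble(i = bb_idx[seq_len(n_res - 2L)], j = bb_idx[3:n_res],
           d_min = 4.5, d_max = 7.4, kind = "constraint"),
    # 1-3 exclusions keeping sidechains off the adjacent backbone beads
    tibble(i = sc_idx[prev_ok], j = bb_idx[prev_ok - 1L],
           d_min = 3.0, d_max = 8.5, kind = "constraint"),
    tibble(i = sc_idx[next_ok], j = bb_idx[next_ok + 1L],
           d_min = 3.0, d_max = 8.5, kind = "constraint"),
    # crowded disulfide-loop region: keep the tilted Cys sidechains off the
    # residue 3-6 beads
    tibble(i = rep(c(sc_idx[2L], sc_idx[7L]), each = 8L),
           j = rep(c(bb_idx[3:6], sc_idx[3:6]), 2L),
           d_min = 2.5, d_max = 9.5, kind = "constraint"),
    # disulfide bridge Cys2-Cys7, kept intact throughout
    tibble(i = sc_idx[2L], j = sc_idx[7L], d_min = 3.3, d_max = 5.3,
           kind = "crosslink")
  )

  ref <- .iapp_reference_coords(bb_idx, sc_idx, has_sc)

  new_molecule_topology(
    "IAPP", beads, bonds, ref,
    residue_map = beads$residue,
    amyloidogenic_range = c(22L, 29L)
  )
}

# Compact helix-like starting conformation (helical intermediates are the
# experimentally reported pre-aggregation state); the helix fits a 63.7 A
# box without approaching its own periodic image, and the Cys2/Cys7
# sidechains are tilted toward each other so the disulfide constraint is
# satisfied at t = 0.
.iapp_reference_coords <- function(bb_idx, sc_idx, has_sc) {
  n_res <- length(bb_idx)
  bb <- .chain_trace(n_res, 3.8, 90, 46)

  n_beads <- max(c(bb_idx, sc_idx), na.rm = TRUE)
  xyz <- matrix(NA_real_, n_beads, 3)
  xyz[bb_idx, ] <- bb
  for (i in seq_len(n_res)) {
    if (has_sc[i]) xyz[sc_idx[i], ] <- .sidechain_point(bb, i)
  }
  # tilt Cys2 / Cys7 sidechains toward each other for the disulfide
  w <- bb[7, ] - bb[2, ]
  w <- w / sqrt(sum(w^2))
  u2 <- xyz[sc_idx[2], ] - bb[2, ]; u2 <- u2 / sqrt(sum(u2^2))
  u7 <- xyz[sc_idx[7], ] - bb[7, ]; u7 <- u7 / sqrt(sum(u7^2))
  v2 <- 0.5 * u2 + 0.866 * w;  v2 <- v2 / sqrt(sum(v2^2))
  v7 <- 0.5 * u7 - 0.866 * w;  v7 <- v7 / sqrt(sum(v7^2))
  xyz[sc_idx[2], ] <- bb[2, ] + 3.2 * v2
  xyz[sc_idx[7], ] <- bb[7, ] + 3.2 * v7
  xyz
}

.build_ligand <- function(name) {
  if (name == "aspirin") {
    beads <- tibble(
      bead_id = 1:2,
      klass = c("ligand_aromatic", "ligand_polar_O"),
      mass = c(77.1, 103.1),
      hardcore_radius = c(2.3, 1.8),
      charge = 0,
      hbond_donors = c(0L, 1L),
      hbond_acceptors = c(0L, 2L)
    )
    bonds <- tibble(i = 1L, j = 2L, d_min = 2.6, d_max = 3.4, kind = "bond")
    ref <- matrix(c(0, 0, 0, 3.0, 0, 0), 2, 3, byrow = TRUE)
  } else if (name == "curcumin") {
    beads <- tibble(
      bead_id = 1:5,
      klass = c("ligand_aromatic", "ligand_aliphatic", "ligand_polar_O",
                "ligand_aliphatic", "ligand_aromatic"),
      mass = c(123, 40, 42, 40, 123),
      hardcore_radius = c(2.3, 2.0, 1.8, 2.0, 2.3),
      charge = 0,
      hbond_donors = c(1L, 0L, 0L, 0L, 1L),
      hbond_acceptors = c(1L, 0L, 1L, 0L, 1L)
    )
    bonds <- bind_rows(
      tibble(i = 1:4, j = 2:5, d_min = 2.9, d_max = 3.9, kind = "bond"),
      tibble(i = 1:3, j = 3:5, d_min = 4.0, d_max = 6.9, kind = "constraint")
    )
    ref <- .chain_trace(5, 3.4, 130, 180)
  } else if (name == "resveratrol") {
    beads <- tibble(
      bead_id = 1:4,
      klass = c("ligand_aromatic", "ligand_aliphatic", "ligand_aliphatic",
                "ligand_aromatic"),
      mass = c(110, 12, 12, 94),
      hardcore_radius = c(2.3, 2.0, 2.0, 2.3),
      charge = 0,
      hbond_donors = c(2L, 0L, 0L, 1L),
      hbond_acceptors = c(2L, 0L, 0L, 1L)
    )
    bonds <- bind_rows(
      tibble(i = 1:3, j = 2:4, d_min = 2.9, d_max = 3.9, kind = "bond"),
      tibble(i = 1:2, j = 3:4, d_min = 4.0, d_max = 6.9, kind = "constraint")
    )
    ref <- .chain_trace(4, 3.4, 130, 180)
  } else {
    stop("unknown species: ", name, call. = FALSE)
  }
  new_molecule_topology(name, beads, bonds, ref)
}

#' Build the coarse-grained topology of a supported species
#'
#' IAPP is represented with two beads per residue (backbone + sidechain
#' centroid; glycine has no sidechain bead), sidechain classes assigned from
#' residue identity, charges for the pH 7 protonation state (Lys1, Arg11 and
#' the free N-terminus; amidated C-terminus neutral), and the Cys2-Cys7
#' disulfide as a permanent crosslink. The three small molecules are 2-5-bead
#' graphs carrying the interaction features that drive their association:
#' aromatic rings, aliphatic linkers, hydroxyl/carboxyl hydrogen-bond
#' capacity.
#'
#' @param name One of `"IAPP"`, `"aspirin"`, `"curcumin"`, `"resveratrol"`.
#' @return A `molecule_topology`: a list with a `beads` tibble (`bead_id`,
#'   `klass`, `mass`, `hardcore_radius`, `charge`, `hbond_donors`,
#'   `hbond_acceptors`, and `residue` for peptides), a `bonds` tibble
#'   (`i`, `j`, `d_min`, `d_max`, `kind`), reference coordinates, and for
#'   peptides the residue map and the amyloidogenic interval (residues
#'   22-29).
#' @examples
#' top <- build_species("IAPP")
#' nrow(top$beads)  # 72: 37 backbone + 35 sidechain beads
#' @export
build_species <- function(name) {
  if (!is.character(name) || length(name) != 1 || !(name %in% species_names)) {
    stop("unknown species: ", paste(name, collapse = ", "),
         " (supported: ", paste(species_names, collapse = ", "), ")",
         call. = FALSE)
  }
  if (name == "IAPP") .build_iapp() else .build_ligand(name)
}

#' Species library with shipped default parameters
#'
#' @param ligand_scales Named hydrophobicity multipliers for the three
#'   ligands; the defaults encode the calibrated solubility ladder
#'   aspirin < resveratrol < curcumin.
#' @return A list of `molecule_topology` objects plus the default
#'   [pair_table()] and [hbond_rule()].
#' @export
species_library <- function(ligand_scales = default_ligand_scales()) {
  tops <- lapply(species_names, build_species)
  names(tops) <- species_names
  list(
    topologies = tops,
    pair_table = default_pair_table(ligand_scales = ligand_scales),
    hbond = hbond_rule()
  )
}

#' Write the species library to a JSON file
#'
#' Serializes every topology (beads, bonds, reference coordinates), the
#' pair-table construction parameters and the hydrogen-bond rule. The file
#' is a single JSON document with fields `format`, `topologies`,
#' `pair_table_params` and `hbond`; [read_species_library()] rebuilds the
#' library (including the full pair table) from it.
#'
#' @param library A [species_library()] list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_library <- function(library = species_library(), path) {
  doc <- list(
    format = "oligodmd-species-library",
    version = as.character(utils::packageVersion("oligodmd")),
    topologies = lapply(library$topologies, function(top) {
      list(
        species_name = top$species_name,
        beads = top$beads,
        bonds = top$bonds,
        ref_coords = top$ref_coords,
        residue_map = top$residue_map,
        amyloidogenic_range = top$amyloidogenic_range
      )
    }),
    pair_table_params = local({
      p <- library$pair_table$params
      p$ligand_scales <- as.list(p$ligand_scales)  # keep species names
      p
    }),
    hbond = library$hbond[c("d_min", "d_max", "bond_energy")]
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a species library written by [write_species_library()]
#'
#' @param path Path to the JSON document.
#' @return A list with `topologies`, `pair_table` (rebuilt from the stored
#'   parameters) and `hbond`.
#' @export
read_species_library <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "oligodmd-species-library")) {
    stop("not a species-library document: ", path, call. = FALSE)
  }
  tops <- lapply(doc$topologies, function(tp) {
    new_molecule_topology(
      tp$species_name,
      as_tibble(tp$beads),
      as_tibble(tp$bonds),
      as.matrix(tp$ref_coords),
      residue_map = tp$residue_map,
      amyloidogenic_range = tp$amyloidogenic_range
    )
  })
  p <- doc$pair_table_params
  table <- default_pair_table(
    eps0 = p$eps0,
    ligand_scales = unlist(p$ligand_scales),
    well_reach = p$well_reach,
    tail_reach = p$tail_reach,
    n_shells = p$n_shells,
    n_shells_elec = p$n_shells_elec,
    elec_cutoff = p$elec_cutoff,
    stacking_bonus = p$stacking_bonus,
    electrostatics = electrostatics_params(
      screening_length = p$electrostatics$screening_length,
      prefactor = p$electrostatics$prefactor
    )
  )
  hb <- hbond_rule(d_min = doc$hbond$d_min, d_max = doc$hbond$d_max,
                   bond_energy = doc$hbond$bond_energy)
  list(topologies = tops, pair_table = table, hbond = hb)
}
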