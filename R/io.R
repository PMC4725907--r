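# Trajectory formats and replicate orchestration: extended-XYZ plus a JSON
# sidecar for lossless round trips, PDB snapshots for visualization, and
# the ten-replicate protocol with last-half aggregation.

# one visualization element symbol per bead class (the sidecar carries the
# real classes; these only make the XYZ renderable)
.klass_element <- c(
  backbone = "C", sidechain_hydrophobic = "S", sidechain_polar = "O",
  sidechain_charged = "N", sidechain_aromatic = "P",
  ligand_aromatic = "F", ligand_aliphatic = "B", ligand_polar_O = "K",
  ideal = "He"
)

#' Write a trajectory as extended-XYZ with a JSON sidecar
#'
#' Positions are written to 1e-6 Angstrom; the sidecar (`<path>.json`)
#' carries the box, seed, frame metadata (time, energies, hydrogen-bond
#' counts) and the full species map so the round trip is lossless for
#' analysis purposes.
#'
#' @param traj A `dmd_trajectory`.
#' @param path Output path for the XYZ file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  n <- nrow(traj$beads)
  nf <- n_frames(traj)
  el <- .klass_element[traj$beads$klass]
  el[is.na(el)] <- "X"
  con <- file(path, "w")
  on.exit(close(con))
  has_v <- !is.null(traj$velocities)
  for (k in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf(
      'Lattice="%.6f 0 0 0 %.6f 0 0 0 %.6f" Properties=species:S:1:pos:R:3%s time=%.9g kinetic=%.9g potential=%.9g',
      traj$box_edge, traj$box_edge, traj$box_edge,
      if (has_v) ":vel:R:3" else "",
      traj$frames$time[k],
      if (is.na(traj$frames$kinetic[k])) 0 else traj$frames$kinetic[k],
      if (is.na(traj$frames$potential[k])) 0 else traj$frames$potential[k]
    ), con)
    if (has_v) {
      writeLines(sprintf(
        "%s %.6f %.6f %.6f %.8f %.8f %.8f", el,
        traj$coords[k, , 1], traj$coords[k, , 2], traj$coords[k, , 3],
        traj$velocities[k, , 1], traj$velocities[k, , 2],
        traj$velocities[k, , 3]), con)
    } else {
      writeLines(sprintf(
        "%s %.6f %.6f %.6f", el,
        traj$coords[k, , 1], traj$coords[k, , 2], traj$coords[k, , 3]), con)
    }
  }
  sidecar <- list(
    format = "oligodmd-trajectory",
    version = as.character(utils::packageVersion("oligodmd")),
    box_edge = traj$box_edge,
    seed = traj$seed,
    n_beads = n,
    n_frames = nf,
    beads = traj$beads,
    frames = traj$frames,
    config = traj$config[!vapply(traj$config, is.null, logical(1))]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path Path to the XYZ file (the sidecar `<path>.json` must sit
#'   next to it).
#' @return A `dmd_trajectory`.
#' @export
read_trajectory <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop("missing sidecar file: ", sidecar_path, call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (!identical(sc$format, "oligodmd-trajectory")) {
    stop("not an oligodmd trajectory sidecar: ", sidecar_path, call. = FALSE)
  }
  beads <- as_tibble(sc$beads)
  n <- sc$n_beads
  nf <- sc$n_frames
  if (nrow(beads) != n) {
    stop("sidecar species map lists ", nrow(beads),
         " beads but declares n_beads = ", n, call. = FALSE)
  }
  lines <- readLines(path)
  per_frame <- n + 2L
  if (length(lines) < nf * per_frame) {
    stop("trajectory file truncated: expected ", nf * per_frame,
         " lines, found ", length(lines), " (near line ", length(lines),
         ")", call. = FALSE)
  }
  coords <- array(NA_real_, c(nf, n, 3))
  vels <- NULL
  for (k in seq_len(nf)) {
    off <- (k - 1L) * per_frame
    natoms <- suppressWarnings(as.integer(lines[off + 1L]))
    if (is.na(natoms) || natoms != n) {
      stop("bad atom count at line ", off + 1L, ": '", lines[off + 1L],
           "'", call. = FALSE)
    }
    block <- lines[(off + 3L):(off + 2L + n)]
    parts <- strsplit(block, " +")
    ncol_first <- length(parts[[1]])
    mat <- matrix(NA_real_, n, ncol_first - 1L)
    for (a in seq_len(n)) {
      p <- parts[[a]]
      if (length(p) != ncol_first) {
        stop("malformed atom record at line ", off + 2L + a, call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(p[-1]))
      if (anyNA(vals)) {
        stop("non-numeric coordinates at line ", off + 2L + a,
             call. = FALSE)
      }
      mat[a, ] <- vals
    }
    coords[k, , ] <- mat[, 1:3]
    if (ncol_first - 1L >= 6) {
      if (is.null(vels)) vels <- array(NA_real_, c(nf, n, 3))
      vels[k, , ] <- mat[, 4:6]
    }
  }
  frames <- as_tibble(sc$frames)
  structure(
    list(
      frames = frames,
      coords = coords,
      velocities = vels,
      beads = beads,
      box_edge = sc$box_edge,
      config = sc$config,
      seed = sc$seed
    ),
    class = "dmd_trajectory"
  )
}

#' Write one frame as a PDB snapshot
#'
#' One HETATM per bead; molecules map to chain identifiers so standard
#' viewers colour them separately.
#'
#' @param frame A bead tibble from [traj_frame()] (or a `system_state`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_snapshot <- function(frame, path) {
  if (inherits(frame, "system_state")) frame <- frame$beads
  chains <- c(LETTERS, letters, as.character(0:9))
  con <- file(path, "w")
  on.exit(close(con))
  el <- .klass_element[frame$klass]
  el[is.na(el)] <- "X"
  for (a in seq_len(nrow(frame))) {
    resseq <- if (!is.na(frame$residue[a])) frame$residue[a] else 1L
    writeLines(sprintf(
      "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      a %% 100000, substr(frame$klass[a], 1, 4),
      substr(frame$species[a], 1, 3),
      chains[(frame$mol[a] - 1L) %% length(chains) + 1L],
      resseq %% 10000,
      frame$x[a], frame$y[a], frame$z[a], el[a]), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Run independent replicate simulations and aggregate their statistics
#'
#' Mirrors the sampling protocol of the study design: `n_replicates`
#' simulations from seeds `base_seed .. base_seed + n - 1`, each analysed
#' over its last-half window, with means and standard deviations across
#' replicates. Failed replicates are recorded in the manifest and the
#' aggregation proceeds over the completed ones with a warning.
#'
#' @param config A [system_config()]; its seed is replaced per replicate.
#' @param n_replicates Number of independent runs (default 10).
#' @param base_seed First seed (default the config seed).
#' @param dir Optional directory; when given, each trajectory is written
#'   there and its MD5 recorded in the manifest.
#' @param ... Passed on to [run_dmd()].
#' @return A `replicate_set`: list with `manifest` (tibble), `stats`
#'   (per-replicate `cluster_stats`), `trajectories` (when `dir` is NULL,
#'   kept in memory), and `aggregate` (pooled histograms, replicate means
#'   and standard deviations; sd is `NA` for a single replicate).
#' @export
run_replicates <- function(config, n_replicates = 10,
                           base_seed = config$seed, dir = NULL, ...) {
  stopifnot(inherits(config, "system_config"), n_replicates >= 1)
  seeds <- base_seed + seq_len(n_replicates) - 1L
  rows <- list()
  stats <- list()
  trajs <- list()
  for (r in seq_along(seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    res <- tryCatch({
      sys <- assemble_system(cfg)
      tr <- run_dmd(sys, ...)
      st <- if (cfg$n_peptides > 0) cluster_stats(tr) else NULL
      path <- NA_character_
      md5 <- NA_character_
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        path <- file.path(dir, sprintf("replicate_%03d.xyz", seeds[r]))
        write_trajectory(tr, path)
        md5 <- unname(tools::md5sum(path))
      } else {
        trajs[[length(trajs) + 1L]] <- tr
      }
      stats[[length(stats) + 1L]] <- st
      tibble(seed = seeds[r], status = "ok", n_events = tr$n_pair_events,
             t_final = max(tr$frames$time), path = path, md5 = md5)
    }, error = function(e) {
      tibble(seed = seeds[r], status = paste("failed:", conditionMessage(e)),
             n_events = NA_real_, t_final = NA_real_,
             path = NA_character_, md5 = NA_character_)
    })
    rows[[r]] <- res
  }
  manifest <- bind_rows(rows)
  n_ok <- sum(manifest$status == "ok")
  if (n_ok < n_replicates) {
    warning(n_replicates - n_ok, " replicate(s) failed; aggregating over ",
            n_ok, call. = FALSE)
  }
  aggregate <- NULL
  stats <- Filter(Negate(is.null), stats)
  if (length(stats) > 0) {
    size_pooled <- purrr::map_dfr(stats, function(s) s$size_hist) %>%
      group_by(.data$s) %>%
      summarise(probability = sum(.data$probability) / length(stats),
                .groups = "drop")
    count_means <- purrr::map_dbl(stats, function(s) {
      sum(s$count_hist$n_clusters * s$count_hist$probability)
    })
    composition <- purrr::map_dfr(stats, function(s) s$composition) %>%
      group_by(.data$n_peptides, .data$n_ligands) %>%
      summarise(clusters = sum(.data$clusters), .groups = "drop")
    aggregate <- list(
      size_hist = size_pooled,
      composition = composition,
      mean_cluster_count = mean(count_means),
      sd_cluster_count = if (length(count_means) > 1) {
        stats::sd(count_means)
      } else {
        NA_real_  # undefined for a single replicate
      },
      ligand_peptide_ratio = if (any(composition$n_ligands > 0)) {
        cluster_ligand_peptide_ratio(stats)
      } else {
        NA_real_
      }
    )
  }
  structure(
    list(manifest = manifest, stats = stats,
         trajectories = if (is.null(dir)) trajs else NULL,
         aggregate = aggregate, config = config, seeds = seeds),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", nrow(x$manifest), " replicates (",
      sum(x$manifest$status == "ok"), " ok), seeds ",
      min(x$seeds), "..", max(x$seeds), "\n", sep = "")
  if (!is.null(x$aggregate)) {
    cat("  mean peptide-cluster count ",
        format(x$aggregate$mean_cluster_count, digits = 3), " +/- ",
        format(x$aggregate$sd_cluster_count, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
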