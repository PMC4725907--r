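# Aggregation statistics: contacts under the 5.5 A rule, contact-graph
# clustering, cluster histograms and compositions, radial core/corona
# profiles, backbone pseudo-dihedral secondary structure, steady-state
# windows.

.frame_box <- function(frame, box_edge) {
  if (!is.null(box_edge)) return(box_edge)
  be <- attr(frame, "box_edge")
  if (is.null(be)) stop("frame has no box_edge attribute; pass `box_edge`",
                        call. = FALSE)
  be
}

#' Inter-molecular bead contacts in one frame
#'
#' Two beads of different molecules are in contact when their minimum-image
#' distance is strictly smaller than `cutoff` (default 5.5 Angstrom). The
#' default method bins beads on a grid with cells at least one cutoff wide
#' and compares neighbouring cells only; `method = "brute"` is the plain
#' all-pairs double loop, retained as the reference implementation.
#'
#' @param frame A bead tibble (from [traj_frame()]) with `x`, `y`, `z`,
#'   `mol` columns.
#' @param cutoff Contact cutoff in Angstrom (> 0).
#' @param box_edge Periodic box edge; defaults to the frame attribute.
#' @param method `"cell"` (grid-accelerated) or `"brute"` (all pairs).
#' @return A tibble with one row per contact (`i`, `j` bead ids with
#'   `i < j`, `mol_i`, `mol_j`, `dist`), carrying the frame's molecule
#'   table, cutoff and box as attributes.
#' @export
contacts <- function(frame, cutoff = 5.5, box_edge = NULL,
                     method = c("cell", "brute")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  edge <- .frame_box(frame, box_edge)
  xyz <- cbind(frame$x, frame$y, frame$z) %% edge
  n <- nrow(xyz)
  ncell <- max(1L, floor(edge / cutoff))
  pairs <- if (method == "brute" || ncell < 3L) {
    .contact_pairs_brute(xyz, edge, cutoff)
  } else {
    .contact_pairs_cell(xyz, edge, cutoff, ncell)
  }
  keep <- pairs$dist < cutoff & frame$mol[pairs$i] != frame$mol[pairs$j]
  out <- tibble(
    i = pairs$i[keep], j = pairs$j[keep],
    mol_i = frame$mol[pairs$i[keep]], mol_j = frame$mol[pairs$j[keep]],
    dist = pairs$dist[keep]
  )
  mols <- frame %>%
    group_by(.data$mol, .data$species) %>%
    summarise(n_beads = n(), .groups = "drop")
  attr(out, "molecules") <- mols
  attr(out, "cutoff") <- cutoff
  attr(out, "box_edge") <- edge
  attr(out, "time") <- attr(frame, "time")
  out
}

.contact_pairs_brute <- function(xyz, edge, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(list(i = integer(0), j = integer(0), dist = numeric(0)))
  d2 <- .min_image_cross_dist2(xyz, xyz, edge)
  hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
  list(i = hit[, 1], j = hit[, 2], dist = sqrt(d2[hit]))
}

.contact_pairs_cell <- function(xyz, edge, cutoff, ncell) {
  cs <- edge / ncell
  ci <- floor(xyz / cs) %% ncell  # 0-based cell coords per axis
  cell_id <- ci[, 1] + ncell * (ci[, 2] + ncell * ci[, 3])
  by_cell <- split(seq_len(nrow(xyz)), cell_id)
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  # half-space of offsets (plus the zero offset) so each cell pair is
  # visited once
  offsets <- offsets[
    offsets$dx > 0 |
      (offsets$dx == 0 & (offsets$dy > 0 |
                            (offsets$dy == 0 & offsets$dz >= 0))), ]
  res_i <- list(); res_j <- list(); res_d <- list()
  keys <- as.integer(names(by_cell))
  kx <- keys %% ncell
  ky <- (keys %/% ncell) %% ncell
  kz <- keys %/% (ncell * ncell)
  lookup <- stats::setNames(seq_along(keys), keys)
  for (o in seq_len(nrow(offsets))) {
    ox <- (kx + offsets$dx[o]) %% ncell
    oy <- (ky + offsets$dy[o]) %% ncell
    oz <- (kz + offsets$dz[o]) %% ncell
    nbr_key <- ox + ncell * (oy + ncell * oz)
    nbr_pos <- lookup[as.character(nbr_key)]
    self <- offsets$dx[o] == 0 & offsets$dy[o] == 0 & offsets$dz[o] == 0
    for (k in seq_along(keys)) {
      p <- nbr_pos[k]
      if (is.na(p)) next
      a <- by_cell[[k]]; b <- by_cell[[p]]
      if (self) {
        if (length(a) < 2) next
        d2 <- .min_image_cross_dist2(xyz[a, , drop = FALSE],
                                     xyz[a, , drop = FALSE], edge)
        hit <- which(upper.tri(d2) & d2 < cutoff^2, arr.ind = TRUE)
        if (nrow(hit) == 0) next
        ii <- a[hit[, 1]]; jj <- a[hit[, 2]]
      } else {
        d2 <- .min_image_cross_dist2(xyz[a, , drop = FALSE],
                                     xyz[b, , drop = FALSE], edge)
        hit <- which(d2 < cutoff^2, arr.ind = TRUE)
        if (nrow(hit) == 0) next
        ii <- a[hit[, 1]]; jj <- b[hit[, 2]]
      }
      sw <- ii > jj
      tmp <- ii[sw]; ii[sw] <- jj[sw]; jj[sw] <- tmp
      res_i[[length(res_i) + 1]] <- ii
      res_j[[length(res_j) + 1]] <- jj
      res_d[[length(res_d) + 1]] <- sqrt(d2[hit])
    }
  }
  i <- unlist(res_i); j <- unlist(res_j); d <- unlist(res_d)
  if (is.null(i)) return(list(i = integer(0), j = integer(0),
                              dist = numeric(0)))
  dup <- duplicated(cbind(i, j))
  list(i = i[!dup], j = j[!dup], dist = d[!dup])
}

#' Cluster molecules by transitive contact
#'
#' Two molecules belong to the same cluster when they are connected through
#' a chain of pairwise contacts: the clusters are the connected components
#' of the molecule-level contact graph. Contact-free molecules form
#' singleton clusters.
#'
#' @param cmap A contact map from [contacts()].
#' @return A tibble with one row per molecule: `mol`, `species`, `cluster`
#'   (labels ordered by first molecule), plus `n_peptides`/`n_ligands` per
#'   cluster as attributes on the `clusters` summary attribute.
#' @export
cluster_frame <- function(cmap) {
  mols <- attr(cmap, "molecules")
  if (is.null(mols)) stop("contact map lacks its molecule table",
                          call. = FALSE)
  edges <- cmap %>%
    distinct(.data$mol_i, .data$mol_j)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$mol_i),
               to = as.character(edges$mol_j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(mols$mol))
  )
  memb <- igraph::components(g)$membership
  out <- mols %>%
    mutate(cluster = as.integer(memb[as.character(.data$mol)])) %>%
    select("mol", "species", "cluster")
  summary <- out %>%
    group_by(.data$cluster) %>%
    summarise(
      n_molecules = n(),
      n_peptides = sum(.data$species == "IAPP"),
      n_ligands = sum(.data$species != "IAPP"),
      .groups = "drop"
    )
  attr(out, "clusters") <- summary
  out
}

#' Steady-state analysis window
#'
#' By default the last half of the frames (floor split: the window holds
#' `ceiling(n/2)` frames). A linear-trend test on the potential energy over
#' the window is attached as the `plateau` attribute (slope, p-value) for
#' inspection; it never overrides the default window.
#'
#' @param traj A `dmd_trajectory`.
#' @return Integer vector of frame indices, with a `plateau` attribute.
#' @export
steady_state_window <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames", call. = FALSE)
  win <- (floor(nf / 2) + 1L):nf
  plateau <- tryCatch({
    fr <- traj$frames[win, ]
    fit <- stats::lm(potential ~ time, data = fr)
    co <- summary(fit)$coefficients
    list(slope = unname(co["time", "Estimate"]),
         p_value = unname(co["time", "Pr(>|t|)"]))
  }, error = function(e) list(slope = NA_real_, p_value = NA_real_))
  attr(win, "plateau") <- plateau
  win
}

# shared per-frame clustering loop
.window_clusters <- function(traj, window, cutoff = 5.5) {
  purrr::map(window, function(k) {
    cm <- contacts(traj_frame(traj, k), cutoff = cutoff)
    ca <- cluster_frame(cm)
    attr(ca, "frame") <- k
    ca
  })
}

#' Cluster statistics over an analysis window
#'
#' For each frame the molecules are clustered under the contact rule; the
#' result collects (i) the histogram of the number of peptide-containing
#' clusters, (ii) the mass-weighted cluster-size distribution
#' `P(s) = <s n_s> / N_peptides` (the probability that a randomly chosen
#' chain sits in a cluster of `s` peptides), and (iii) the cluster
#' composition heat map over (peptides, ligands). Ligand-only clusters are
#' excluded from the cluster count but retained in the composition map.
#'
#' @param traj A `dmd_trajectory` containing at least one peptide.
#' @param window Frame indices (default [steady_state_window()]).
#' @param cutoff Contact cutoff in Angstrom.
#' @return A `cluster_stats` object: list of tibbles `per_frame`,
#'   `count_hist`, `size_hist`, `composition` plus metadata.
#' @export
cluster_stats <- function(traj, window = steady_state_window(traj),
                          cutoff = 5.5) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  n_pep <- sum(traj$beads$species == "IAPP" & !duplicated(traj$beads$mol))
  if (n_pep == 0) stop("no peptides in the trajectory", call. = FALSE)
  cas <- .window_clusters(traj, window, cutoff)

  per_frame <- purrr::map_dfr(cas, function(ca) {
    cl <- attr(ca, "clusters")
    pep_cl <- filter(cl, .data$n_peptides > 0)
    tibble(
      frame = attr(ca, "frame"),
      n_clusters = nrow(pep_cl),
      largest = max(pep_cl$n_peptides),
      mean_size = sum(pep_cl$n_peptides^2) / sum(pep_cl$n_peptides)
    )
  })

  count_hist <- per_frame %>%
    count(.data$n_clusters, name = "frames") %>%
    mutate(probability = .data$frames / sum(.data$frames))

  # mass-weighted: every frame contributes s * n_s / N_pep at size s
  size_mass <- purrr::map_dfr(cas, function(ca) {
    cl <- filter(attr(ca, "clusters"), .data$n_peptides > 0)
    cl %>%
      count(s = .data$n_peptides, name = "n_s") %>%
      mutate(mass = .data$s * .data$n_s / n_pep)
  }) %>%
    group_by(.data$s) %>%
    summarise(mass = sum(.data$mass), .groups = "drop") %>%
    mutate(probability = .data$mass / length(cas)) %>%
    select("s", "probability")

  composition <- purrr::map_dfr(cas, function(ca) {
    attr(ca, "clusters") %>% select("n_peptides", "n_ligands")
  }) %>%
    count(.data$n_peptides, .data$n_ligands, name = "clusters")

  structure(
    list(
      per_frame = per_frame,
      count_hist = count_hist,
      size_hist = size_mass,
      composition = composition,
      n_peptides = n_pep,
      n_frames = length(window),
      cutoff = cutoff
    ),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  mode_s <- x$size_hist$s[which.max(x$size_hist$probability)]
  cat("<cluster_stats> ", x$n_frames, " frames, ", x$n_peptides,
      " peptides; modal mass-weighted size ", mode_s, "\n", sep = "")
  invisible(x)
}

#' Pooled ligand:peptide ratio over peptide-containing clusters
#'
#' Sums ligands and peptides across all peptide-containing clusters in the
#' window (optionally pooled over several trajectories' statistics) and
#' returns total ligands / total peptides.
#'
#' @param stats A `cluster_stats` object or a list of them.
#' @return The pooled ratio (numeric scalar).
#' @export
cluster_ligand_peptide_ratio <- function(stats) {
  if (inherits(stats, "cluster_stats")) stats <- list(stats)
  comp <- purrr::map_dfr(stats, function(s) s$composition)
  comp <- filter(comp, .data$n_peptides > 0)
  sum(comp$n_ligands * comp$clusters) / sum(comp$n_peptides * comp$clusters)
}

#' Per-residue ligand contact frequency
#'
#' Fraction of window frames in which each residue has at least one bead in
#' contact with any ligand bead.
#'
#' @param traj A `dmd_trajectory` with peptides and ligands.
#' @param window Frame indices.
#' @param cutoff Contact cutoff (Angstrom).
#' @return Tibble `residue`, `frequency`.
#' @export
residue_ligand_contact_frequency <- function(traj,
                                             window = steady_state_window(traj),
                                             cutoff = 5.5) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  b <- traj$beads
  if (!any(b$species != "IAPP")) {
    return(tibble(residue = sort(unique(b$residue[!is.na(b$residue)])),
                  frequency = 0))
  }
  is_lig <- b$species != "IAPP"
  res_of <- b$residue
  residues <- sort(unique(res_of[!is.na(res_of)]))
  hits <- matrix(0, length(window), length(residues))
  for (w in seq_along(window)) {
    cm <- contacts(traj_frame(traj, window[w]), cutoff = cutoff)
    lig_i <- is_lig[cm$i]; lig_j <- is_lig[cm$j]
    mixed <- xor(lig_i, lig_j)
    pep_bead <- ifelse(lig_i[mixed], cm$j[mixed], cm$i[mixed])
    rr <- unique(res_of[pep_bead])
    hits[w, match(rr, residues)] <- 1
  }
  tibble(residue = residues, frequency = colMeans(hits))
}

#' Ligand-peptide binding fraction
#'
#' `per_ligand`: the mean over ligands of the fraction of frames in which
#' that ligand touches any peptide. `any_ligand`: the fraction of frames in
#' which at least one ligand touches a peptide.
#'
#' @param traj A `dmd_trajectory` with ligands.
#' @param window Frame indices.
#' @param mode `"per_ligand"` (default) or `"any_ligand"`.
#' @param cutoff Contact cutoff (Angstrom).
#' @return Fraction in `[0, 1]`.
#' @export
binding_fraction <- function(traj, window = steady_state_window(traj),
                             mode = c("per_ligand", "any_ligand"),
                             cutoff = 5.5) {
  mode <- match.arg(mode)
  if (length(window) == 0) stop("empty window", call. = FALSE)
  b <- traj$beads
  lig_mols <- unique(b$mol[b$species != "IAPP"])
  if (length(lig_mols) == 0) stop("no ligands present", call. = FALSE)
  bound <- matrix(FALSE, length(window), length(lig_mols))
  for (w in seq_along(window)) {
    cm <- contacts(traj_frame(traj, window[w]), cutoff = cutoff)
    sp_i <- b$species[cm$i]; sp_j <- b$species[cm$j]
    mixed <- (sp_i == "IAPP") != (sp_j == "IAPP")
    lm_ <- ifelse(sp_i[mixed] == "IAPP", cm$mol_j[mixed], cm$mol_i[mixed])
    bound[w, match(unique(lm_), lig_mols)] <- TRUE
  }
  if (mode == "per_ligand") mean(colMeans(bound)) else mean(rowSums(bound) > 0)
}

#' Inter-peptide contact time series
#'
#' Per-frame count of inter-peptide bead-pair contacts, optionally
#' restricted to a residue interval on both chains (e.g. the amyloidogenic
#' region, residues 22-29).
#'
#' @param traj A `dmd_trajectory` with at least 2 peptides.
#' @param window Frame indices.
#' @param region Optional residue interval `c(lo, hi)` within 1..37.
#' @param cutoff Contact cutoff (Angstrom).
#' @return Tibble `frame`, `time`, `contacts`.
#' @export
interchain_contacts <- function(traj, window = steady_state_window(traj),
                                region = NULL, cutoff = 5.5) {
  b <- traj$beads
  n_pep <- length(unique(b$mol[b$species == "IAPP"]))
  if (n_pep < 2) {
    return(tibble(frame = window, time = traj$frames$time[window],
                  contacts = 0L))
  }
  if (!is.null(region)) {
    if (length(region) != 2 || region[1] > region[2] ||
        region[1] < 1 || region[2] > max(b$residue, na.rm = TRUE)) {
      stop("region must be an interval within the chain", call. = FALSE)
    }
  }
  counts <- purrr::map_int(window, function(k) {
    cm <- contacts(traj_frame(traj, k), cutoff = cutoff)
    pep <- b$species[cm$i] == "IAPP" & b$species[cm$j] == "IAPP"
    if (!is.null(region)) {
      ri <- b$residue[cm$i]; rj <- b$residue[cm$j]
      pep <- pep & ri >= region[1] & ri <= region[2] &
        rj >= region[1] & rj <= region[2]
    }
    sum(pep)
  })
  tibble(frame = window, time = traj$frames$time[window], contacts = counts)
}

# unwrap a cluster's beads across the periodic boundary: molecules are
# unwrapped internally about their first bead, then shifted molecule by
# molecule along a spanning tree of the contact graph
.unwrap_cluster <- function(frame, edge, members, cmap) {
  fb <- frame[frame$mol %in% members, ]
  xyz <- cbind(fb$x, fb$y, fb$z)
  mol_of <- fb$mol
  for (m in unique(mol_of)) {
    idx <- which(mol_of == m)
    anchor <- xyz[idx[1], ]
    d <- sweep(xyz[idx, , drop = FALSE], 2, anchor)
    xyz[idx, ] <- sweep(.min_image(d, edge), 2, anchor, "+")
  }
  if (length(members) > 1) {
    edges <- cmap %>%
      filter(.data$mol_i %in% members, .data$mol_j %in% members) %>%
      distinct(.data$mol_i, .data$mol_j, .keep_all = TRUE)
    shift <- stats::setNames(
      rep(list(NULL), length(members)), members)
    root <- members[1]
    shift[[as.character(root)]] <- c(0, 0, 0)
    queue <- root
    while (length(queue) > 0) {
      a <- queue[1]; queue <- queue[-1]
      nb <- edges %>%
        filter(.data$mol_i == a | .data$mol_j == a)
      for (r in seq_len(nrow(nb))) {
        bmol <- if (nb$mol_i[r] == a) nb$mol_j[r] else nb$mol_i[r]
        if (!is.null(shift[[as.character(bmol)]])) next
        bi <- if (nb$mol_i[r] == a) nb$i[r] else nb$j[r]
        bj <- if (nb$mol_i[r] == a) nb$j[r] else nb$i[r]
        pa <- xyz[which(fb$bead == bi), ] + shift[[as.character(a)]]
        pb <- xyz[which(fb$bead == bj), ]
        delta <- .min_image(pb - pa, edge)
        shift[[as.character(bmol)]] <- (pa + delta) - pb
        queue <- c(queue, bmol)
      }
    }
    for (m in members) {
      s <- shift[[as.character(m)]]
      if (is.null(s)) s <- c(0, 0, 0)  # unreachable: disconnected input
      idx <- which(mol_of == m)
      xyz[idx, ] <- sweep(xyz[idx, , drop = FALSE], 2, s, "+")
    }
  }
  fb$x <- xyz[, 1]; fb$y <- xyz[, 2]; fb$z <- xyz[, 3]
  fb
}

#' Radial core/corona profile of selected clusters
#'
#' Pools every cluster in the window whose composition matches the selector,
#' unwraps it across the periodic boundary, and histograms bead distances
#' from the cluster's mass-weighted centre of mass, separately for peptide
#' beads, ligand beads, ligand aliphatic carbons and ligand oxygens. Each
#' selector's frequencies sum to one.
#'
#' @param traj A `dmd_trajectory`.
#' @param window Frame indices.
#' @param n_pep Number of peptides the cluster must contain.
#' @param n_lig Optional exact ligand count.
#' @param bin_width Histogram bin width in Angstrom (default 1).
#' @param cutoff Contact cutoff (Angstrom).
#' @return A `radial_profile` tibble: `selector`, `bin_lo`, `bin_hi`,
#'   `frequency`.
#' @export
radial_profile <- function(traj, window = steady_state_window(traj),
                           n_pep, n_lig = NULL, bin_width = 1,
                           cutoff = 5.5) {
  sel_dist <- list(peptide = numeric(0), ligand = numeric(0),
                   ligand_aliphatic = numeric(0), ligand_O = numeric(0))
  found <- 0L
  for (k in window) {
    fr <- traj_frame(traj, k)
    cm <- contacts(fr, cutoff = cutoff)
    ca <- cluster_frame(cm)
    cl <- attr(ca, "clusters")
    ok <- cl$n_peptides == n_pep
    if (!is.null(n_lig)) ok <- ok & cl$n_ligands == n_lig
    match_cl <- cl$cluster[ok]
    for (cc in match_cl) {
      members <- ca$mol[ca$cluster == cc]
      fb <- .unwrap_cluster(fr, traj$box_edge, members, cm)
      com <- colSums(cbind(fb$x, fb$y, fb$z) * fb$mass) / sum(fb$mass)
      dist <- sqrt((fb$x - com[1])^2 + (fb$y - com[2])^2 +
                     (fb$z - com[3])^2)
      is_pep <- fb$species == "IAPP"
      sel_dist$peptide <- c(sel_dist$peptide, dist[is_pep])
      sel_dist$ligand <- c(sel_dist$ligand, dist[!is_pep])
      sel_dist$ligand_aliphatic <- c(
        sel_dist$ligand_aliphatic, dist[fb$klass == "ligand_aliphatic"])
      sel_dist$ligand_O <- c(
        sel_dist$ligand_O, dist[fb$klass == "ligand_polar_O"])
      found <- found + 1L
    }
  }
  if (found == 0L) {
    stop("no cluster in the window matches the selector", call. = FALSE)
  }
  rmax <- max(unlist(sel_dist), 0) + bin_width
  breaks <- seq(0, ceiling(rmax / bin_width) * bin_width, by = bin_width)
  out <- purrr::map_dfr(names(sel_dist), function(slc) {
    d <- sel_dist[[slc]]
    if (length(d) == 0) return(tibble())
    h <- hist(d, breaks = breaks, plot = FALSE)
    tibble(selector = slc, bin_lo = utils::head(breaks, -1),
           bin_hi = breaks[-1], frequency = h$counts / length(d))
  })
  attr(out, "n_clusters_pooled") <- found
  class(out) <- c("radial_profile", class(out))
  out
}

# interior angles (degrees) at each backbone bead and pseudo-dihedrals
.backbone_geometry <- function(bb) {
  nr <- nrow(bb)
  theta <- rep(NA_real_, nr)
  tau <- rep(NA_real_, nr)
  if (nr >= 3) {
    for (i in 2:(nr - 1)) {
      u <- bb[i - 1, ] - bb[i, ]
      w <- bb[i + 1, ] - bb[i, ]
      cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
      theta[i] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
  }
  if (nr >= 4) {
    for (i in 2:(nr - 2)) {
      b1 <- bb[i, ] - bb[i - 1, ]
      b2 <- bb[i + 1, ] - bb[i, ]
      b3 <- bb[i + 2, ] - bb[i + 1, ]
      n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
              b1[1] * b2[2] - b1[2] * b2[1])
      n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
              b2[1] * b3[2] - b2[2] * b3[1])
      m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
              n1[1] * b2[2] - n1[2] * b2[1])
      nb2 <- sqrt(sum(b2^2))
      tau[i] <- atan2(sum(m1 * n2) / nb2, sum(n1 * n2)) * 180 / pi
    }
  }
  list(theta = theta, tau = tau)
}

.runs_at_least <- function(flag, min_len) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  keep <- r$values & r$lengths >= min_len
  inverse.rle(list(lengths = r$lengths, values = keep))
}

#' Backbone secondary-structure assignment for one frame
#'
#' Coarse-grained analogue of a dictionary assignment: from the backbone
#' pseudo-angle `theta(i)` (beads i-1, i, i+1) and pseudo-dihedral `tau(i)`
#' (beads i-1..i+2), a residue is helical (H) when `tau` lies in
#' `[30, 70]` degrees and `theta` in `[85, 105]` for at least 3 consecutive
#' residues; extended (E) when `|tau| >= 150` and `theta` in `[110, 145]`
#' for at least 2 consecutive residues; turn (T) on 2-3 residue direction
#' reversals of the chain; otherwise coil (C). Chains shorter than 4
#' residues are all coil.
#'
#' @param frame A bead tibble with peptide backbone beads (or a plain
#'   numeric matrix of backbone coordinates for a single chain).
#' @return Tibble `mol`, `residue`, `ss` (factor H/E/T/C).
#' @export
secondary_structure <- function(frame) {
  if (is.matrix(frame)) {
    frame <- tibble(mol = 1L, species = "IAPP", klass = "backbone",
                    residue = seq_len(nrow(frame)),
                    x = frame[, 1], y = frame[, 2], z = frame[, 3])
  }
  bbs <- frame %>%
    filter(.data$species == "IAPP", .data$klass == "backbone") %>%
    arrange(.data$mol, .data$residue)
  purrr::map_dfr(unique(bbs$mol), function(m) {
    ch <- filter(bbs, .data$mol == m)
    nr <- nrow(ch)
    ss <- rep("C", nr)
    if (nr >= 4) {
      bb <- cbind(ch$x, ch$y, ch$z)
      geo <- .backbone_geometry(bb)
      h_ok <- geo$tau >= 30 & geo$tau <= 70 &
        geo$theta >= 85 & geo$theta <= 105
      e_ok <- abs(geo$tau) >= 150 & geo$theta >= 110 & geo$theta <= 145
      ss[.runs_at_least(h_ok, 3)] <- "H"
      ss[.runs_at_least(e_ok, 2) & ss == "C"] <- "E"
      # turns: short direction reversals of the local chain vectors
      rev_ok <- rep(FALSE, nr)
      for (i in 3:(nr - 2)) {
        v_in <- bb[i, ] - bb[i - 2, ]
        v_out <- bb[i + 2, ] - bb[i, ]
        rev_ok[i] <- sum(v_in * v_out) < 0
      }
      rev_ok <- rev_ok & ss == "C"
      r <- rle(rev_ok)
      keep <- r$values & r$lengths >= 2 & r$lengths <= 3
      ss[inverse.rle(list(lengths = r$lengths, values = keep))] <- "T"
    }
    tibble(mol = m, residue = ch$residue,
           ss = factor(ss, levels = c("H", "E", "T", "C")))
  })
}

#' Mean secondary-structure content per chain
#'
#' @param traj A `dmd_trajectory` with peptides.
#' @param window Frame indices.
#' @return Tibble `ss`, `mean_residues`: average number of residues per
#'   chain in each state over the window (they sum to the chain length).
#' @export
ss_content <- function(traj, window = steady_state_window(traj)) {
  if (length(window) == 0) stop("empty window", call. = FALSE)
  counts <- purrr::map_dfr(window, function(k) {
    secondary_structure(traj_frame(traj, k)) %>%
      count(.data$mol, .data$ss, .drop = FALSE, name = "residues")
  })
  counts %>%
    group_by(.data$ss) %>%
    summarise(mean_residues = sum(.data$residues) /
                (length(window) * length(unique(counts$mol))),
              .groups = "drop")
}

#' Hydrogen-bond and aromatic-stacking census of one frame
#'
#' Stacking contacts are inter-molecular aromatic-aromatic bead pairs
#' within the contact cutoff. Hydrogen-bond counts come from the engine's
#' reacted-pair registry when available, otherwise from a greedy
#' distance-based reconstruction (capacity-limited, ties broken by bead
#' index).
#'
#' @param frame A bead tibble.
#' @param hb_registry Optional engine registry (2-column matrix of donor,
#'   acceptor bead ids).
#' @param hbond Hydrogen-bond rule used for the distance-based fallback.
#' @param cutoff Stacking contact cutoff (Angstrom).
#' @param box_edge Periodic box edge (defaults to the frame attribute).
#' @return Tibble with `peptide_ligand_hbonds`, `peptide_peptide_hbonds`,
#'   `stacking_contacts` (all inter-molecular).
#' @export
hbond_stack_census <- function(frame, hb_registry = NULL,
                               hbond = hbond_rule(), cutoff = 5.5,
                               box_edge = NULL) {
  edge <- .frame_box(frame, box_edge)
  if (is.null(hb_registry)) {
    hb_registry <- .greedy_hbonds(frame, edge, hbond)
  }
  n_pl <- 0L; n_pp <- 0L
  if (nrow(hb_registry) > 0) {
    di <- hb_registry[, 1]; ai <- hb_registry[, 2]
    inter <- frame$mol[di] != frame$mol[ai]
    pep_d <- frame$species[di] == "IAPP"
    pep_a <- frame$species[ai] == "IAPP"
    n_pl <- sum(inter & xor(pep_d, pep_a))
    n_pp <- sum(inter & pep_d & pep_a)
  }
  aro <- frame$klass %in% c("sidechain_aromatic", "ligand_aromatic")
  n_stack <- 0L
  if (sum(aro) >= 2) {
    cm <- contacts(frame[aro, ], cutoff = cutoff, box_edge = edge)
    n_stack <- nrow(cm)
  }
  tibble(peptide_ligand_hbonds = n_pl,
         peptide_peptide_hbonds = n_pp,
         stacking_contacts = n_stack)
}
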