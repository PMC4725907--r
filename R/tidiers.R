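# broom-style tidiers for the result objects.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trajectory's frame table
#' @param x A `dmd_trajectory`.
#' @param ... Unused.
#' @return The frame metadata tibble.
#' @method tidy dmd_trajectory
#' @export
tidy.dmd_trajectory <- function(x, ...) x$frames

#' One-row summary of a trajectory
#'
#' @param x A `dmd_trajectory`.
#' @param ... Unused.
#' @return A tibble with frame/event counts, relative total-energy drift
#'   and the mean temperature over the last half.
#' @method glance dmd_trajectory
#' @export
glance.dmd_trajectory <- function(x, ...) {
  e_tot <- x$frames$kinetic + x$frames$potential
  win <- (floor(nrow(x$frames) / 2) + 1):nrow(x$frames)
  tibble(
    n_frames = nrow(x$frames),
    n_beads = nrow(x$beads),
    n_events = as.numeric(x$n_pair_events %||% NA),
    time_span = max(x$frames$time) - min(x$frames$time),
    energy_drift = if (all(is.finite(e_tot))) {
      (max(e_tot) - min(e_tot)) / abs(mean(e_tot))
    } else {
      NA_real_
    },
    mean_temperature_last_half = mean(x$frames$temperature[win])
  )
}

#' Tidy cluster statistics into the mass-weighted size distribution
#' @param x A `cluster_stats` object.
#' @param ... Unused.
#' @return Tibble `s`, `probability`.
#' @method tidy cluster_stats
#' @export
tidy.cluster_stats <- function(x, ...) x$size_hist

#' One-row summary of cluster statistics
#'
#' @param x A `cluster_stats` object.
#' @param ... Unused.
#' @return A tibble with the modal mass-weighted size, mean
#'   peptide-containing cluster count and pooled ligand:peptide ratio.
#' @method glance cluster_stats
#' @export
glance.cluster_stats <- function(x, ...) {
  tibble(
    n_frames = x$n_frames,
    n_peptides = x$n_peptides,
    modal_size = x$size_hist$s[which.max(x$size_hist$probability)],
    mean_cluster_count = sum(x$count_hist$n_clusters *
                               x$count_hist$probability),
    ligand_peptide_ratio = cluster_ligand_peptide_ratio(x)
  )
}

#' Tidy a replicate set's manifest
#' @param x A `replicate_set`.
#' @param ... Unused.
#' @return The manifest tibble.
#' @method tidy replicate_set
#' @export
tidy.replicate_set <- function(x, ...) x$manifest

#' One-row summary of a replicate set
#'
#' @param x A `replicate_set`.
#' @param ... Unused.
#' @return A tibble with replicate counts and aggregate cluster metrics.
#' @method glance replicate_set
#' @export
glance.replicate_set <- function(x, ...) {
  agg <- x$aggregate
  tibble(
    n_replicates = nrow(x$manifest),
    n_completed = sum(x$manifest$status == "ok"),
    mean_cluster_count = agg$mean_cluster_count %||% NA_real_,
    sd_cluster_count = agg$sd_cluster_count %||% NA_real_,
    modal_size = if (!is.null(agg)) {
      agg$size_hist$s[which.max(agg$size_hist$probability)]
    } else {
      NA_integer_
    },
    ligand_peptide_ratio = agg$ligand_peptide_ratio %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
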