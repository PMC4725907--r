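# ggplot2 views of the result objects.

#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_tile geom_point
#'   facet_wrap labs scale_fill_viridis_c theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Energy and temperature traces of a trajectory
#'
#' @param object A `dmd_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmd_trajectory
#' @export
autoplot.dmd_trajectory <- function(object, ...) {
  df <- object$frames %>%
    select("time", "kinetic", "potential", "temperature") %>%
    tidyr::pivot_longer(-"time", names_to = "quantity")
  ggplot(df, aes(x = .data$time, y = .data$value)) +
    geom_line(colour = "steelblue") +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = "time (reduced units)", y = NULL,
         title = "Trajectory energetics") +
    theme_minimal()
}

#' Mass-weighted cluster-size distribution
#'
#' @param object A `cluster_stats` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_stats
#' @export
autoplot.cluster_stats <- function(object, ...) {
  ggplot(object$size_hist, aes(x = factor(.data$s), y = .data$probability)) +
    geom_col(fill = "grey30") +
    labs(x = "peptides in cluster", y = "P(s) (mass-weighted)",
         title = "Cluster-size distribution") +
    theme_minimal()
}

#' Cluster composition heat map
#'
#' @param stats A `cluster_stats` object (or the aggregate of a
#'   `replicate_set`).
#' @return A ggplot of observed (peptides, ligands) cluster compositions.
#' @export
plot_composition <- function(stats) {
  comp <- if (inherits(stats, "cluster_stats")) stats$composition else
    stats$composition
  ggplot(comp, aes(x = .data$n_peptides, y = .data$n_ligands,
                   fill = .data$clusters)) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "peptides per cluster", y = "small molecules per cluster",
         fill = "clusters", title = "Cluster compositions") +
    theme_minimal()
}

#' Radial core/corona profile
#'
#' @param object A `radial_profile` tibble.
#' @param ... Unused.
#' @return A ggplot of normalized frequency vs distance from the cluster
#'   centre of mass, one line per selector.
#' @method autoplot radial_profile
#' @export
autoplot.radial_profile <- function(object, ...) {
  df <- mutate(object, r = (.data$bin_lo + .data$bin_hi) / 2)
  ggplot(df, aes(x = .data$r, y = .data$frequency,
                 colour = .data$selector)) +
    geom_line() +
    labs(x = "distance from cluster centre of mass (A)",
         y = "normalized frequency", colour = NULL,
         title = "Radial core/corona profile") +
    theme_minimal()
}

#' Per-residue ligand contact frequency
#'
#' @param freq Tibble from [residue_ligand_contact_frequency()].
#' @return A ggplot bar chart over residues.
#' @export
plot_contact_frequency <- function(freq) {
  ggplot(freq, aes(x = .data$residue, y = .data$frequency)) +
    geom_col(fill = "darkorange") +
    labs(x = "residue", y = "contact frequency",
         title = "Small-molecule contact frequency by residue") +
    theme_minimal()
}
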