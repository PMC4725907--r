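#!/usr/bin/env Rscript
# Calibration of the ligand hydrophobicity ladder.
#
# The three small molecules share bead classes; a per-species multiplier on
# the ligand hydrophobicity weights sets how strongly each self-associates.
# This script runs pure-ligand self-assembly (16 molecules in a 127.3 A
# box) over a seed panel for a grid of candidate multipliers and reports
# the steady-state monomer probability of each species. The shipped
# defaults (aspirin 0.60, resveratrol 0.55, curcumin 1.22) were chosen from
# this map as the roundest values that reproduce the solubility ordering
# of the monomer probability (aspirin > resveratrol > curcumin) with a
# clear margin, alongside aggregate formation by the two polyphenols.
#
# Usage: Rscript scripts/calibrate_ladder.R [n_seeds] [events]

suppressPackageStartupMessages(library(oligodmd))

args <- commandArgs(trailingOnly = TRUE)
n_seeds <- if (length(args) >= 1) as.integer(args[1]) else 4L
events <- if (length(args) >= 2) as.numeric(args[2]) else 1.5e6

monomer_probability <- function(species, scale, seeds, events) {
  scales <- default_ligand_scales()
  scales[species] <- scale
  tab <- default_pair_table(ligand_scales = scales)
  vals <- vapply(seeds, function(s) {
    cfg <- system_config(0, species, n_ligands = 16, edge = 127.3,
                         seed = s, event_budget = events,
                         emit_every = max(1, events / 20))
    tr <- run_dmd(assemble_system(cfg), pair_table = tab)
    win <- steady_state_window(tr)
    mono <- vapply(win, function(k) {
      ca <- cluster_frame(contacts(traj_frame(tr, k)))
      cl <- attr(ca, "clusters")
      sum(cl$n_molecules == 1) / 16
    }, numeric(1))
    mean(mono)
  }, numeric(1))
  mean(vals)
}

seeds <- seq_len(n_seeds)
grid <- list(
  aspirin = c(0.55, 0.60, 0.70),
  resveratrol = c(0.50, 0.55, 0.62),
  curcumin = c(1.10, 1.22, 1.35)
)
cat("species scale monomer_probability\n")
for (sp in names(grid)) {
  for (sc in grid[[sp]]) {
    p <- monomer_probability(sp, sc, seeds, events)
    cat(sprintf("%-11s %-5.2f %.3f\n", sp, sc, p))
  }
}
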