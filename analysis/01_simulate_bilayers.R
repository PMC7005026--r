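#!/usr/bin/env Rscript
# Step 1: simulate the three model bilayer compositions used throughout
# the analysis -- a cis-analog reference (all chains kinked), a saturated
# analog (all chains straight), and a PE analog (kinked chains, smaller
# headgroup, tighter lattice). Writes a summary of each trajectory.

suppressPackageStartupMessages(library(memprofiler))
dir.create("results", showWarnings = FALSE)

specs <- list(
  cis_analog = bilayer_gen_spec(49, fraction_kinked_chains = 1, seed = 101),
  saturated_analog = bilayer_gen_spec(49, fraction_kinked_chains = 0,
                                      seed = 102),
  pe_analog = bilayer_gen_spec(49, fraction_kinked_chains = 1,
                               headgroup_atom_count = 5,
                               area_per_lipid = 60, seed = 103)
)

summary <- do.call(rbind, lapply(names(specs), function(nm) {
  traj <- generate_bilayer(specs[[nm]], n_frames = 4, label = nm)
  data.frame(composition = nm,
             n_frames = traj$n_frames,
             n_atoms = nrow(traj$atoms),
             box_x_A = traj$box[1],
             box_z_A = traj$box[3],
             area_per_lipid_A2 = area_per_lipid(traj))
}))
write.csv(summary, "results/01_bilayer_summary.csv", row.names = FALSE)

cat("Simulated", nrow(summary), "compositions (4 frames each).\n")
cat("Realized areas per lipid match the requested lattice spacing:\n")
print(summary, row.names = FALSE)
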