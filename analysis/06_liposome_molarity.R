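#!/usr/bin/env Rscript
# Step 6: effective unsaturated acyl-chain molarity inside the membrane of
# a 200 nm liposome, for the sensor-activating (POPC) and sensor-silencing
# (1:1 DOPC:POPC) compositions.

suppressPackageStartupMessages(library(memprofiler))
dir.create("results", showWarnings = FALSE)

popc <- data.frame(species = "POPC", mol_fraction = 1, chains = 2,
                   unsat_chains = 1)
dopc_popc <- data.frame(species = c("DOPC", "POPC"),
                        mol_fraction = c(0.5, 0.5), chains = c(2, 2),
                        unsat_chains = c(2, 1))

rows <- lapply(list(ON = popc, OFF = dopc_popc), function(comp) {
  spec <- liposome_spec(diameter_nm = 200, thickness_nm = 4,
                        area_per_lipid_nm2 = 0.65, composition = comp)
  data.frame(lipid_count = lipid_count(spec),
             membrane_volume_l = membrane_volume(spec),
             unsaturated_chain_M = unsaturated_chain_molarity(spec))
})
out <- cbind(state = names(rows), do.call(rbind, rows))
write.csv(out, "results/06_liposome.csv", row.names = FALSE)

cat("Liposome membrane as a nanoscale solvent for unsaturated chains:\n")
print(out, row.names = FALSE)
cat("\nFinding: switching from pure POPC to 1:1 DOPC:POPC raises the local",
    "\nunsaturated-chain concentration from ~1.3 M to ~1.9 M at essentially",
    "\nconstant lipid count and membrane volume.\n")
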