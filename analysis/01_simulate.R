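#!/usr/bin/env Rscript
# Stage 1: generate the synthetic fixture set with known ground truth.
#
# Writes small, legal PDB files (plus JSON ground-truth sidecars) for each
# fixture family: a dissociative-type and an associative-type reaction
# center, a rigid-pair superposition harness, a slippage series, and the
# analytic surface-area / shape-complementarity systems. Every later stage
# can be validated against these records with no downloaded structure.

suppressPackageStartupMessages(library(tcsgeom))

out_dir <- "results/fixtures"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20161212

message("== simulating fixtures (seed ", seed, ") ==")

# a loose, Mg-asymmetric center (long transfer distance, ratio < 0.6) and a
# tight, near-symmetric one (short distance, ratio > 0.6)
rc_loose <- make_reaction_center(7.6, 3.0, 6.38, d_rxn = 5.8, seed = seed)
rc_tight <- make_reaction_center(5.1, 3.6, 4.4, d_rxn = 3.3, seed = seed)
write_fixture(rc_loose, file.path(out_dir, "rc_dissociative"))
write_fixture(rc_tight, file.path(out_dir, "rc_associative"))
message(sprintf("reaction centers: loose r_mg = %.2f (%s), tight r_mg = %.2f (%s)",
                rc_loose$truth$r_mg, rc_loose$truth$group,
                rc_tight$truth$r_mg, rc_tight$truth$group))

rp <- make_rigid_pair(50, angle = 147, axis = c(1, -1, 2),
                      translation = c(8, -3, 5), seed = seed)
write_fixture(list(structure = rp$a), file.path(out_dir, "rigid_pair_a"))
write_fixture(list(structure = rp$b,
                   truth = list(angle = 147, axis = c(1, -1, 2),
                                translation = c(8, -3, 5))),
              file.path(out_dir, "rigid_pair_b"))

ser <- make_slippage_series(4, seed = seed)
for (i in seq_along(ser$entries))
  write_fixture(list(structure = ser$entries[[i]]$structure),
                file.path(out_dir, sprintf("slip_entry_%d", i)))
utils::write.table(round(ser$M_dhp_true, 6),
                   file.path(out_dir, "slip_truth_M_dhp.tsv"),
                   sep = "\t", quote = FALSE)
message(sprintf("slippage series: %d entries, max imposed displacement %.2f A",
                length(ser$entries), max(ser$M_dhp_true)))

sys <- make_sphere_system(c(1.7, 1.9), rbind(c(0, 0, 0), c(3, 0, 0)))
write_fixture(sys, file.path(out_dir, "spheres_pair"))
walls <- make_sc_surfaces(gap = 0)
write_fixture(walls, file.path(out_dir, "sc_walls_gap0"))

message("fixtures written under ", out_dir)
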