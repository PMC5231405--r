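#!/usr/bin/env Rscript
# Stage 3: the two-regime "slippage" superposition matrix.
#
# First recovers the imposed receiver displacements of the synthetic series
# (DHp-fit regime equals the displacement, REC-fit regime equals zero),
# then summarises the published nine-pair benchmark matrix: the receiver
# slides along the kinase by up to ~2.4 A while its own conformation stays
# within ~0.3 A -- the signature of a slippery interface.

suppressPackageStartupMessages(library(tcsgeom))

dir.create("results", showWarnings = FALSE)

message("== synthetic series ==")
ser <- make_slippage_series(4, seed = 20161212)
m_syn <- superposition_matrix(ser$entries)
err <- max(abs(m_syn$M_dhp - ser$M_dhp_true), abs(m_syn$M_rec))
message(sprintf("ground-truth recovery: max |error| = %.2e A", err))
write_slippage_tsv(m_syn, "results/slippage_synthetic.tsv")

message("== published benchmark matrix ==")
m_ref <- reference_slippage_matrix()
sm <- slippage_summary(m_ref)
message(sprintf("DHp-fit regime:  max %.3f A, mean %.3f A", sm$max_dhp,
                sm$mean_dhp))
message(sprintf("REC-fit regime:  max %.3f A, mean %.3f A", sm$max_rec,
                sm$mean_rec))
message(sprintf("regime contrast (mean DHp - mean REC): %.3f A; cells where DHp < REC: %d",
                sm$contrast, sm$n_violations))
write_slippage_tsv(m_ref, "results/slippage_benchmark.tsv")
summary_df <- data.frame(stat = c("max_dhp", "mean_dhp", "max_rec",
                                  "mean_rec", "contrast"),
                         value = c(sm$max_dhp, sm$mean_dhp, sm$max_rec,
                                   sm$mean_rec, sm$contrast))
utils::write.table(summary_df, "results/slippage_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("matrices written under results/")
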