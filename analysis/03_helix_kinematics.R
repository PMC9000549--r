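#!/usr/bin/env Rscript
# Helix z-displacement relative to the four-helix center, plus the
# Arg204 sidechain track and the Phe146/Leu143 vs Asp108 gate gaps.
# Verdicts ("moved up/down") are the mean displacement over the final
# 20% of frames.

source("analysis/00_conditions.R")

conds <- build_conditions(seed = 1)
ch <- channel_definition()
rows <- list()
for (cond in conds) {
  hz <- helix_z_series(cond$trajectory, ch, rezero = FALSE)
  df <- data.frame(frame = hz[[1]]$frames)
  for (h in names(hz)) df[[paste0(h, "_z_A")]] <- sprintf("%.6f", hz[[h]]$z)
  write.csv(df, file.path(results_dir(),
                          paste0("helix_z_", cond$label, ".csv")),
            row.names = FALSE, quote = FALSE)
  arg <- sidechain_z_series(cond$trajectory, "204:ARG",
                            superpose_on = "108:ASP", rezero = TRUE)
  gapF <- gate_z_gap(cond$trajectory, "146:PHE", "108:ASP")
  gapL <- gate_z_gap(cond$trajectory, "143:LEU", "108:ASP")
  rows[[cond$label]] <- data.frame(
    condition = cond$label, potential_mV = cond$potential_mV,
    S1_final_A = final_displacement(hz$S1), S2_final_A = final_displacement(hz$S2),
    S3_final_A = final_displacement(hz$S3), S4_final_A = final_displacement(hz$S4),
    arg204_net_A = arg$z[length(arg$z)],
    phe146_gap_change_A = gapF$z[length(gapF$z)] - gapF$z[1],
    leu143_gap_change_A = gapL$z[length(gapL$z)] - gapL$z[1])
  message(sprintf(
    "%s: final rel. z  S2 %+0.2f A, S4 %+0.2f A; Phe146 gap change %+0.2f A",
    cond$label, rows[[cond$label]]$S2_final_A,
    rows[[cond$label]]$S4_final_A,
    rows[[cond$label]]$phe146_gap_change_A))
}
tab <- do.call(rbind, rows)
num <- vapply(tab, is.numeric, TRUE)
tab[num] <- lapply(tab[num], function(x) sprintf("%.6f", x))
write.csv(tab, file.path(results_dir(), "helix_displacement_summary.csv"),
          row.names = FALSE, quote = FALSE)
message("wrote results/helix_displacement_summary.csv")
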