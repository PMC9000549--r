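#!/usr/bin/env Rscript
# Pore radius profiles: the mean profile over sampled frames per
# condition, the minimum radius, and water passability against the
# 1.15 A threshold. The synthetic scaffold's wall geometry is planted
# (not gated), so the analytic wall clearance is also checked here.

source("analysis/00_conditions.R")

conds <- build_conditions(seed = 1)
ch <- channel_definition()
sample_frames <- c(1, 100, 200)
rows <- list()
for (cond in conds) {
  profs <- lapply(sample_frames, function(k)
    pore_profile(get_frame(cond$trajectory, k), ch))
  mean_radii <- rowMeans(do.call(cbind, lapply(profs, `[[`, "radii")))
  df <- data.frame(z_A = profs[[1]]$z_grid,
                   radius_mean_A = sprintf("%.6f", mean_radii))
  for (i in seq_along(profs))
    df[[paste0("radius_f", sample_frames[i], "_A")]] <-
      sprintf("%.6f", profs[[i]]$radii)
  write.csv(df, file.path(results_dir(),
                          paste0("pore_profile_", cond$label, ".csv")),
            row.names = FALSE, quote = FALSE)
  pass <- min_radius_and_passability(profs[[1]])
  rows[[cond$label]] <- data.frame(
    condition = cond$label, potential_mV = cond$potential_mV,
    min_radius_A = pass$min_radius, min_z_A = pass$min_z,
    passable = pass$passable)
  message(sprintf("%s: min pore radius %.3f A at z = %.1f A (%s)",
                  cond$label, pass$min_radius, pass$min_z,
                  if (pass$passable) "water-passable" else "occluded"))
}
tab <- do.call(rbind, rows)
tab$min_radius_A <- sprintf("%.6f", tab$min_radius_A)
write.csv(tab, file.path(results_dir(), "pore_summary.csv"),
          row.names = FALSE, quote = FALSE)
message("wrote results/pore_summary.csv")
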