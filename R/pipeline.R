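# Orchestration: run every analysis stage over one or more trajectory
# conditions (e.g. the four membrane potentials) and emit the analysis
# surfaces as CSV/JSON files with fixed formatting, so re-runs on
# identical inputs are byte-identical.

fmt_num <- function(x) sprintf("%.6f", x)

write_csv_fixed <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a multi-condition run configuration
#'
#' @param trajectories list of conditions, each
#'   `list(label =, path = or trajectory =, potential_mV =, format =)`.
#' @param channel a [channel_definition()].
#' @param wire_criteria a [water_wire_criteria()].
#' @param hbond a [hbond_criteria()].
#' @param hbond_pairs list of `c(basic, acidic)` residue-spec pairs for
#'   the salt-bridge analyses.
#' @param membrane_thickness_A membrane thickness for E = V/z.
#' @param equilibration `"auto"` (RMSD plateau) or a frame index.
#' @param output_dir where to write the report bundle.
#' @param pore_frames frame indices profiled (mean also reported).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(trajectories, channel = channel_definition(),
                       wire_criteria = water_wire_criteria(),
                       hbond = hbond_criteria(),
                       hbond_pairs = list(c("204:ARG", "108:ASP"),
                                          c("201:ARG", "108:ASP")),
                       membrane_thickness_A = 36,
                       equilibration = "auto",
                       output_dir = "hvgate_report",
                       pore_frames = 1) {
  labels <- vapply(trajectories, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("condition labels must be unique")
  structure(list(trajectories = trajectories, channel = channel,
                 wire_criteria = wire_criteria, hbond = hbond,
                 hbond_pairs = hbond_pairs,
                 membrane_thickness_A = membrane_thickness_A,
                 equilibration = equilibration, output_dir = output_dir,
                 pore_frames = pore_frames),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The YAML mirrors [run_config()]: a `trajectories` list (label, path,
#' potential_mV, format), optional `channel` overrides (membrane_z,
#' water_cylinder_radius, boundary_margin), criteria blocks `wire`
#' (oo_cutoff) and `hbond` (distance_cutoff, angle_cutoff), and
#' `output_dir`.
#'
#' @param path YAML file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  ch_args <- y$channel %||% list()
  ch <- do.call(channel_definition, ch_args)
  run_config(
    trajectories = y$trajectories,
    channel = ch,
    wire_criteria = do.call(water_wire_criteria, y$wire %||% list()),
    hbond = do.call(hbond_criteria, y$hbond %||% list()),
    hbond_pairs = y$hbond_pairs %||% list(c("204:ARG", "108:ASP"),
                                          c("201:ARG", "108:ASP")),
    membrane_thickness_A = y$membrane_thickness_A %||% 36,
    equilibration = y$equilibration %||% "auto",
    output_dir = y$output_dir %||% "hvgate_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Per condition: water-wire occupancy stripe and summary, helix
#' z-displacement series, Arg sidechain z series, hydrogen-bond count
#' series and salt-bridge partner table, gate z-gap series
#' (Phe146/Leu143 vs Asp108), pore profiles with the per-condition mean,
#' and the field magnitude E = V/z. A machine-readable JSON index lists
#' every artifact. All numeric CSV values use fixed 6-decimal formatting.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with per-condition summaries and the index.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- list()
  summaries <- list()
  for (cond in config$trajectories) {
    label <- cond$label
    message("[", label, "] loading trajectory")
    traj <- if (!is.null(cond$trajectory)) cond$trajectory else {
      if (is.null(cond$path) || !file.exists(cond$path %||% ""))
        stop("condition '", label, "': trajectory path unreadable: ",
             cond$path)
      read_trajectory(cond$path, cond$format %||% "pdb_multimodel")
    }
    cdir <- file.path(out_dir, label)
    dir.create(cdir, showWarnings = FALSE)
    files <- character(0)

    helix_res <- unlist(lapply(config$channel$helix_ranges,
                               function(r) r[1]:r[2]))
    rser <- rmsd_series(traj, 1, residues = helix_res, mode = "alpha_carbon")
    equil <- if (identical(config$equilibration, "auto")) {
      if (n_frames(traj) >= 20) detect_equilibration(rser) else 1L
    } else as.integer(config$equilibration)
    message("[", label, "] equilibration ends at frame ", equil)

    message("[", label, "] water-wire occupancy")
    occ <- occupancy_series(traj, config$channel, config$wire_criteria,
                            equil_start = equil)
    stripe <- data.frame(frame = occ$frames,
                         time_ns = fmt_num(traj$time[occ$frames]),
                         continuous = as.integer(occ$per_frame))
    f <- file.path(cdir, "water_wire_stripe.csv")
    utils::write.csv(stripe, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)

    message("[", label, "] helix kinematics")
    hz <- helix_z_series(traj, config$channel, equil_start = equil)
    hz_df <- data.frame(frame = hz[[1]]$frames,
                        time_ns = traj$time[hz[[1]]$frames])
    for (h in names(hz)) hz_df[[paste0(h, "_z_A")]] <- hz[[h]]$z
    f <- file.path(cdir, "helix_z_displacement.csv")
    write_csv_fixed(hz_df, f)
    files <- c(files, f)

    arg_res <- config$channel$gate_residues
    arg_res <- arg_res[arg_res$resname == "ARG", , drop = FALSE]
    arg_series <- list()
    for (i in seq_len(nrow(arg_res))) {
      spec_r <- paste0(arg_res$resnum[i], ":", arg_res$resname[i])
      s <- try(sidechain_z_series(traj, spec_r, superpose_on = "108:ASP",
                                  equil_start = equil), silent = TRUE)
      if (!inherits(s, "try-error")) arg_series[[spec_r]] <- s
    }
    if (length(arg_series)) {
      df <- data.frame(frame = arg_series[[1]]$frames)
      for (nm in names(arg_series)) df[[nm]] <- arg_series[[nm]]$z
      f <- file.path(cdir, "arg_sidechain_z.csv")
      write_csv_fixed(df, f)
      files <- c(files, f)
    }

    message("[", label, "] hydrogen bonds / salt bridges")
    hb_rows <- list()
    for (pair in config$hbond_pairs) {
      cs <- try(hbond_count_series(traj, pair[1], pair[2], config$hbond,
                                   equil_start = equil), silent = TRUE)
      if (inherits(cs, "try-error")) next
      hb_rows[[length(hb_rows) + 1]] <- data.frame(
        frame = cs$frames, pair = paste(cs$pair, collapse = "-"),
        count = cs$counts)
    }
    if (length(hb_rows)) {
      f <- file.path(cdir, "hbond_counts.csv")
      utils::write.csv(do.call(rbind, hb_rows), f, row.names = FALSE,
                       quote = FALSE)
      files <- c(files, f)
    }
    basic <- unique(vapply(config$hbond_pairs, `[`, "", 1))
    acidic <- unique(vapply(config$hbond_pairs, `[`, "", 2))
    ptab <- try(partner_occupancy_table(traj, basic, acidic, config$hbond,
                                        equil_start = equil), silent = TRUE)
    if (!inherits(ptab, "try-error")) {
      f <- file.path(cdir, "salt_bridge_occupancy.csv")
      write_csv_fixed(ptab$table, f)
      files <- c(files, f)
    }

    gate_gaps <- list()
    for (gr in c("146:PHE", "143:LEU")) {
      s <- try(gate_z_gap(traj, gr, "108:ASP", equil_start = equil),
               silent = TRUE)
      if (!inherits(s, "try-error")) gate_gaps[[gr]] <- s
    }
    if (length(gate_gaps)) {
      df <- data.frame(frame = gate_gaps[[1]]$frames)
      for (nm in names(gate_gaps)) df[[paste0(nm, "_gap_A")]] <-
          gate_gaps[[nm]]$z
      f <- file.path(cdir, "gate_z_gap.csv")
      write_csv_fixed(df, f)
      files <- c(files, f)
    }

    message("[", label, "] pore profile")
    profs <- lapply(config$pore_frames, function(k)
      pore_profile(get_frame(traj, k), config$channel))
    prof_df <- data.frame(z_A = profs[[1]]$z_grid)
    for (i in seq_along(profs))
      prof_df[[paste0("radius_frame", config$pore_frames[i], "_A")]] <-
        profs[[i]]$radii
    prof_df$radius_mean_A <- rowMeans(
      do.call(cbind, lapply(profs, `[[`, "radii")))
    f <- file.path(cdir, "pore_profile.csv")
    write_csv_fixed(prof_df, f)
    files <- c(files, f)

    field <- field_magnitude(cond$potential_mV %||% 0,
                             config$membrane_thickness_A)
    summary <- list(
      label = label,
      potential_mV = field$potential_mV,
      field_mV_per_A = field$magnitude_mV_per_A,
      equil_start_frame = equil,
      occupancy = occ$occupancy,
      longest_run = if (length(occ$run_lengths)) max(occ$run_lengths) else 0,
      helix_final_displacement_A =
        lapply(hz, function(s) final_displacement(s)),
      min_pore_radius_A = min(vapply(profs, `[[`, 0, "min_radius")))
    f <- file.path(cdir, "summary.json")
    jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    files <- c(files, f)
    summaries[[label]] <- summary
    # index paths relative to the output dir so re-runs are byte-identical
    index[[label]] <- list(files = as.list(substring(files,
                                                     nchar(out_dir) + 2)))
  }
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(summaries = summaries, index = index,
                 output_dir = out_dir))
}
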