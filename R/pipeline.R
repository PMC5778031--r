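# End-to-end orchestration: a single YAML config drives
# simulate -> dipoles -> spectra -> ATR, with one root seed feeding named
# substreams, stage logging and sidecar JSON manifests for provenance.

default_config <- function() {
  list(seed = 1L, output_dir = "anisoIR_out",
       geometry = "chain", width = "narrow", protonated = TRUE,
       n_waters = NULL, temperature = 300, dt = 0.5,
       equil_time = 15, segment_time = 5, n_segments = 2L, sample_every = 2L,
       charge_model = "nuclear_effective", wannier_jitter = 0.02,
       hopper = list(enabled = TRUE, hop_rate = 20,
                     transit_min = 5, transit_max = 20),
       spectral = list(sigma_nu = 50, nu_max = 4000, detrend = TRUE,
                       window = "none"),
       zundel = list(delta_threshold = 0.25),
       atr = list(alpha = 39, n1 = 3.42, n3 = 1.6, band = c(1700, 2200)))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

validate_config <- function(cfg) {
  bad <- character(0)
  if (!cfg$geometry %in% c("chain", "disc", "droplet"))
    bad <- c(bad, "geometry")
  if (!cfg$width %in% c("narrow", "wide")) bad <- c(bad, "width")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) bad <- c(bad, "seed")
  if (!cfg$charge_model %in% c("nuclear_effective", "wannier_full"))
    bad <- c(bad, "charge_model")
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) bad <- c(bad, "dt")
  if (!is.numeric(cfg$temperature) || cfg$temperature <= 0)
    bad <- c(bad, "temperature")
  if (cfg$hopper$hop_rate < 0) bad <- c(bad, "hopper.hop_rate")
  if (cfg$spectral$sigma_nu < 0) bad <- c(bad, "spectral.sigma_nu")
  if (length(bad))
    stop("invalid run configuration key(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Read (or build) a run configuration
#'
#' A single YAML file drives all pipeline stages; missing keys take package
#' defaults, and all randomness derives from the one root `seed` via named
#' substreams.
#'
#' @param path path to a YAML config, or `NULL` for the defaults.
#' @param overrides named list applied on top of the file (CLI-style
#'   overrides).
#' @return a validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg$seed <- as.integer(cfg$seed)
  structure(validate_config(cfg), class = "run_config")
}

#' Write a run configuration as YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(unclass(config)), tf)
  unname(tools::md5sum(tf))
}

stage_log <- function(stage, ...) {
  message(sprintf("[anisoIR %s] %s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

write_manifest <- function(path, config, files, extra = list()) {
  man <- c(list(package = "anisoIR",
                version = as.character(utils::packageVersion("anisoIR")),
                seed = config$seed, config_hash = config_hash(config),
                config = unclass(config),
                files = lapply(files, function(f)
                  list(path = basename(f), md5 = unname(tools::md5sum(f))))),
           extra)
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Stage 1: simulate cluster trajectories and write them to disk
#'
#' Builds the configured cluster, runs NVT equilibration plus NVE segments,
#' writes one multi-frame XYZ per segment (with inline synthetic Wannier
#' centers when the full charge model is configured) and a JSON manifest
#' carrying the seed, config hash, net charge and file checksums.
#'
#' @param config a `run_config`.
#' @return invisibly, list with `md` (the `toy_md` object), `files`,
#'   `manifest` path.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- confinement_spec(config$geometry, config$width)
  params <- sim_params(T = config$temperature, dt = config$dt,
                       n_waters = config$n_waters,
                       protonated = isTRUE(config$protonated),
                       equil_time = config$equil_time,
                       segment_time = config$segment_time,
                       n_segments = config$n_segments, seed = config$seed,
                       sample_every = config$sample_every)
  stage_log("simulate", sprintf("building %s (%s)", spec$label,
                                if (params$protonated) "protonated" else "neutral"))
  frame0 <- build_cluster(spec, params)
  md <- run_toy_md(frame0, spec, params)
  with_wannier <- config$charge_model == "wannier_full"
  files <- character(0)
  for (i in seq_along(md$segments)) {
    tr <- md$segments[[i]]
    if (with_wannier)
      tr <- synthesize_wannier_trajectory(tr, jitter_sd = config$wannier_jitter,
                                          seed = substream_seed(config$seed,
                                                                paste0("wann_seg", i)))
    f <- file.path(config$output_dir, paste0(tr$segment_id, ".xyz"))
    write_xyz_trajectory(tr, f)
    files <- c(files, f)
    md$segments[[i]] <- tr
  }
  nq <- total_charge(get_frame(md$segments[[1L]], 1L), charge_model("nuclear_effective"))
  manifest <- file.path(config$output_dir, "simulate_manifest.json")
  write_manifest(manifest, config, files,
                 extra = list(net_charge_e = nq,
                              mean_nvt_temperature_K = mean(md$nvt_temperature),
                              n_segments = length(md$segments)))
  stage_log("simulate", sprintf("done: %d segment(s), net charge %+g e, %.1f s",
                                length(files), nq,
                                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(md = md, files = files, manifest = manifest))
}

segment_spectrum <- function(series, scfg)
  spectrum_from_dipole(series, scfg)

#' Stage 2: direction-resolved spectra and decompositions
#'
#' From protonated segments produces the four-curve decomposition (full
#' nuclei+electrons, nuclear-effective, Zundel subgroup in both models) and,
#' when neutral segments are supplied, the protonated-minus-unprotonated
#' difference spectrum, all segment-averaged, Gaussian-smoothed and on one
#' wavenumber grid.  For a neutral input the subgroup outputs are skipped
#' with a logged reason.
#'
#' @param config a `run_config`.
#' @param trajectories list of `md_trajectory` segments, or paths to XYZ
#'   files written by [run_simulate].
#' @param neutral_trajectories optional matching neutral segments (or paths)
#'   for the difference spectrum.
#' @return invisibly, list of [ir_spectrum] objects (`nuclear`, `full`,
#'   `zundel_nuclear`, `zundel_full`, `difference` as available) plus
#'   `files`.
#' @export
run_spectra <- function(config, trajectories, neutral_trajectories = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  load_trajs <- function(x) {
    if (is.character(x))
      lapply(x, function(p) read_xyz_trajectory(p, dt = config$dt *
                                                  config$sample_every))
    else x
  }
  trajs <- load_trajs(trajectories)
  scfg <- spectral_config(dt = trajs[[1L]]$dt,
                          sigma_nu = config$spectral$sigma_nu,
                          nu_max = config$spectral$nu_max,
                          detrend = isTRUE(config$spectral$detrend),
                          window = config$spectral$window)
  protonated <- isTRUE(trajs[[1L]]$protonated) || isTRUE(config$protonated)
  has_w <- !is.null(trajs[[1L]]$wannier)
  if (config$charge_model == "wannier_full" && !has_w)
    stop("wannier_full charge model requested but trajectories carry no ",
         "Wannier centers")
  use_hopper <- protonated && isTRUE(config$hopper$enabled)
  hspec <- hopper_spec(hop_rate = config$hopper$hop_rate,
                       transit_range = c(config$hopper$transit_min,
                                         config$hopper$transit_max))
  nuc <- charge_model("nuclear_effective")
  ful <- if (has_w) charge_model("wannier_full")
  per_segment <- function(traj, i) {
    defect <- if (use_hopper)
      attach_proton_hopper(traj, hspec,
                           seed = substream_seed(config$seed, paste0("hop", i)))
    series_of <- function(model, subset = NULL) {
      s <- dipole_series(traj, model, subset = subset)
      if (!is.null(defect) && is.null(subset)) s <- add_dipole_series(s, defect)
      s
    }
    out <- list(nuclear = segment_spectrum(series_of(nuc), scfg))
    if (has_w) out$full <- segment_spectrum(series_of(ful), scfg)
    if (protonated) {
      zsub <- zundel_subset(traj, config$zundel$delta_threshold)
      out$zundel_nuclear <- segment_spectrum(
        dipole_series(traj, nuc, subset = zsub), scfg)
      if (has_w)
        out$zundel_full <- segment_spectrum(
          dipole_series(traj, ful, subset = zsub), scfg)
    }
    out
  }
  segs <- lapply(seq_along(trajs), function(i) per_segment(trajs[[i]], i))
  keys <- names(segs[[1L]])
  spectra <- lapply(keys, function(k)
    smooth_gaussian(average_segments(lapply(segs, `[[`, k)),
                    config$spectral$sigma_nu))
  names(spectra) <- keys
  if (!protonated)
    stage_log("spectrum", "neutral system: Zundel subgroup spectra skipped ",
              "(no excess-proton defect)")
  if (!is.null(neutral_trajectories)) {
    ntr <- load_trajs(neutral_trajectories)
    nsegs <- lapply(ntr, function(tr)
      segment_spectrum(dipole_series(tr, nuc), scfg))
    neutral_avg <- smooth_gaussian(average_segments(nsegs),
                                   config$spectral$sigma_nu)
    spectra$neutral <- neutral_avg
    spectra$difference <- difference_spectrum(spectra$nuclear, neutral_avg)
  }
  files <- character(0)
  for (k in names(spectra)) {
    f <- file.path(config$output_dir, paste0("spectrum_", k, ".csv"))
    write_spectrum_table(spectra[[k]], f)
    files <- c(files, f)
  }
  manifest <- file.path(config$output_dir, "spectrum_manifest.json")
  write_manifest(manifest, config, files,
                 extra = list(curves = names(spectra),
                              n_segments = length(trajs)))
  stage_log("spectrum", sprintf("done: %s (%.1f s)",
                                paste(names(spectra), collapse = ", "),
                                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  spectra$files <- files
  invisible(spectra)
}

#' Stage 3: resolve polarized ATR spectra and run the sensitivity scan
#'
#' Reads two-column CSVs (`wavenumber_cm-1`, absorbance) for the parallel
#' and perpendicular polarizations, resolves them into in-plane (xy) and
#' normal (z) components at the configured geometry, scans the alpha/n
#' uncertainty, and writes the resolved CSV plus a JSON report with the
#' scan table and the band-mean summary over the configured window.
#'
#' @param config a `run_config`.
#' @param a_par,a_perp paths to the polarized absorbance CSVs.
#' @return invisibly, list with `resolved` (a `dichroic_spectra`), `scan`,
#'   `band_summary`, `files`.
#' @export
run_atr <- function(config, a_par, a_perp) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  read2 <- function(p) {
    if (!file.exists(p)) stop("input file not found: ", p)
    d <- utils::read.csv(p, check.names = FALSE)
    if (ncol(d) < 2L) stop("expected two columns in ", p)
    d[, 1:2]
  }
  dp <- read2(a_par)
  ds <- read2(a_perp)
  if (nrow(dp) != nrow(ds) || any(abs(dp[[1L]] - ds[[1L]]) > 1e-6))
    stop("wavenumber grids of the two polarizations do not match")
  geom <- atr_geometry(config$atr$alpha, n1 = config$atr$n1,
                       n3 = config$atr$n3)
  res <- resolve_components(dp[[1L]], dp[[2L]], ds[[2L]], geom)
  scan <- sensitivity_scan(dp[[1L]], dp[[2L]], ds[[2L]], reference = geom)
  band <- config$atr$band
  sel <- res$nu >= band[1L] & res$nu <= band[2L]
  band_summary <- list(band_cm1 = band,
                       mean_A_xy = mean(res$A_xy[sel]),
                       mean_A_z = mean(res$A_z[sel]))
  fcsv <- file.path(config$output_dir, "atr_resolved.csv")
  utils::write.csv(as.data.frame(res), fcsv, row.names = FALSE)
  frep <- file.path(config$output_dir, "atr_report.json")
  jsonlite::write_json(list(geometry = list(alpha = geom$alpha, n1 = geom$n1,
                                            n3 = geom$n3),
                            band_summary = band_summary,
                            sensitivity = scan$scan,
                            seed = config$seed,
                            config_hash = config_hash(config)),
                       frep, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  stage_log("atr", sprintf("band %g-%g cm^-1: mean A_xy = %.4g, mean A_z = %.4g",
                           band[1L], band[2L], band_summary$mean_A_xy,
                           band_summary$mean_A_z))
  invisible(list(resolved = res, scan = scan$scan, band_summary = band_summary,
                 files = c(fcsv, frep)))
}
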