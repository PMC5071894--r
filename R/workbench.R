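# Scenario runner: configuration handling and the three canonical
# comparisons (controlled-measurement sweep, pattern comparison report,
# size-ratio sweep) on packaged fixtures.

#' Read and validate a run configuration
#'
#' Configurations are YAML (or equivalent R lists) validated against the
#' schema shipped at `inst/schema/runconfig-schema.json`. All angles are
#' degrees and all lengths meters; `unit_scale` applies to mesh files
#' only.
#'
#' @param config Path to a YAML file or a named list.
#' @return Validated config list (class `run_config`) with defaults
#'   filled in.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("io error: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: configuration must be a list")
  defaults <- list(
    scenario = "sweep",
    material = "bat_effective",
    frequency_hz = 10e9,
    plane_tilt_deg = 0,
    azimuth_step_deg = 10,
    tolerance = 1e-5,
    method = "auto",
    polarizability_model = "ldr",
    unit_scale = 1e-3,
    partial_voxels = FALSE,
    emulation = list(dynamic_range_limit = 8, median_halfwidth = 15,
                     mode = "shv"),
    output_dir = NULL,
    seed = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  geoms <- c("mesh_path", "ellipsoid_mm", "toy_organism")
  if (!any(geoms %in% names(cfg))) {
    stop("config error: need one of ", paste(geoms, collapse = ", "))
  }
  if (!is.null(cfg$ellipsoid_mm) && length(cfg$ellipsoid_mm) != 3L) {
    stop("config error: ellipsoid_mm must be the three FULL axis lengths (mm)")
  }
  if (!is.numeric(cfg$frequency_hz) || any(cfg$frequency_hz <= 0)) {
    stop("config error: frequency_hz must be positive")
  }
  if (abs(360 / cfg$azimuth_step_deg - round(360 / cfg$azimuth_step_deg)) > 1e-9) {
    stop("config error: azimuth_step_deg must divide 360")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

config_geometry <- function(cfg) {
  if (!is.null(cfg$mesh_path)) {
    read_mesh(cfg$mesh_path, unit_scale = cfg$unit_scale)
  } else if (!is.null(cfg$ellipsoid_mm)) {
    ax <- as.numeric(cfg$ellipsoid_mm) / 2 * 1e-3  # full axes mm -> semi m
    ellipsoid_spec(ax[1], ax[2], ax[3])
  } else {
    ts <- cfg$toy_organism
    if (isTRUE(ts) || is.null(ts) || length(ts) == 0L) {
      toy_organism_spec()
    } else {
      do.call(toy_organism_spec, ts)
    }
  }
}

config_spacing <- function(cfg, wavelength, material) {
  if (!is.null(cfg$spacing_m)) return(cfg$spacing_m)
  d <- wavelength / (10 * Mod(refractive_index(material)))
  if (!is.null(cfg$max_spacing_m)) d <- min(d, cfg$max_spacing_m)
  d
}

config_lattice <- function(cfg, wavelength) {
  mat <- as_material(cfg$material)
  d <- config_spacing(cfg, wavelength, mat)
  geom <- config_geometry(cfg)
  if (inherits(geom, "ellipsoid_spec")) {
    make_ellipsoid_lattice(geom, d, mat)
  } else {
    if (inherits(geom, "toy_organism_spec")) geom <- make_toy_organism(geom)
    voxelize_mesh(geom, d, material = mat,
                  partial = isTRUE(cfg$partial_voxels))
  }
}

#' Run an azimuth sweep scenario
#'
#' Builds the configured geometry and material, runs the sweep, and (if
#' `output_dir` is set) writes the pattern CSV, the resolved
#' configuration and a short run log next to each other.
#'
#' @param config Path or list, see [read_run_config()].
#' @return The `polar_pattern`, invisibly if written to disk.
#' @export
run_sweep <- function(config) {
  cfg <- read_run_config(config)
  lambda <- .c_mps / cfg$frequency_hz[1]
  t0 <- proc.time()[3]
  lattice <- config_lattice(cfg, lambda)
  pat <- azimuth_sweep(lattice, lambda, plane_tilt = cfg$plane_tilt_deg,
                       step = cfg$azimuth_step_deg,
                       tolerance = cfg$tolerance, method = cfg$method,
                       model = cfg$polarizability_model)
  elapsed <- proc.time()[3] - t0
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_pattern_csv(pat, file.path(cfg$output_dir, "pattern.csv"))
    resolved <- unclass(cfg)
    yaml::write_yaml(resolved, file.path(cfg$output_dir, "config.yaml"))
    writeLines(c(
      sprintf("scenario: %s", cfg$scenario),
      sprintf("sites: %d  spacing_m: %g", nrow(lattice$positions),
              lattice$spacing),
      sprintf("|m|kd: %.3f", max_mkd(lattice, 2 * pi / lambda)),
      sprintf("residual: %g", attr(pat, "residual")),
      sprintf("elapsed_s: %.1f", elapsed)
    ), file.path(cfg$output_dir, "run.log"))
    return(invisible(pat))
  }
  pat
}

#' Compare two patterns: sector report, correlation, RMSE, SHV series
#'
#' Produces the canonical model-vs-model (or model-vs-measurement)
#' report: per-sector means and medians in cm^2 and dBsm for both
#' patterns, full-circle means, Pearson r on linear RCS per channel,
#' RMSE, and the clipped + median-filtered SHV differential-RCS series
#' of each pattern.
#'
#' @param pattern_a,pattern_b `polar_pattern`s or CSV paths (matched
#'   azimuth grids).
#' @param emulation A `radar_emulation_config`.
#' @param output_dir Optional directory to write `report.json`.
#' @return List (class `pattern_comparison`) with elements
#'   `sectors_a`, `sectors_b`, `pearson`, `rmse_db`, `shv_a`, `shv_b`.
#' @export
run_compare <- function(pattern_a, pattern_b,
                        emulation = radar_emulation_config(),
                        output_dir = NULL) {
  if (is.character(pattern_a)) pattern_a <- read_pattern_csv(pattern_a)
  if (is.character(pattern_b)) pattern_b <- read_pattern_csv(pattern_b)
  stopifnot(inherits(pattern_a, "polar_pattern"),
            inherits(pattern_b, "polar_pattern"))
  chans <- c("vv", "hh")
  out <- list(
    sectors_a = sector_stats(pattern_a, chans),
    sectors_b = sector_stats(pattern_b, chans),
    pearson = vapply(chans, function(ch) {
      pearson_linear(pattern_a, pattern_b, ch)
    }, numeric(1)),
    rmse_db = vapply(chans, function(ch) {
      rmse_pattern(pattern_a, pattern_b, scale = "db", channel = ch)
    }, numeric(1)),
    shv_a = emulated_differential(pattern_a, emulation),
    shv_b = emulated_differential(pattern_b, emulation),
    emulation = emulation
  )
  class(out) <- c("pattern_comparison", "list")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(sectors_a = out$sectors_a, sectors_b = out$sectors_b,
           pearson = as.list(out$pearson), rmse_db = as.list(out$rmse_db),
           shv_a = out$shv_a, shv_b = out$shv_b),
      file.path(output_dir, "report.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  out
}

# clipped + circular-median-filtered differential series of a pattern
emulated_differential <- function(pattern, emulation) {
  raw <- if (emulation$mode == "shv" && !is.null(attr(pattern, "smatrix"))) {
    shv_differential_series(pattern)
  } else {
    differential_rcs(pmax(pattern$sigma_hh_m2, 1e-30),
                     pmax(pattern$sigma_vv_m2, 1e-30))
  }
  step <- if (nrow(pattern) > 1) pattern$azimuth_deg[2] - pattern$azimuth_deg[1] else 360
  filtered <- circular_median_filter(raw, emulation$median_halfwidth, step)
  clip_dynamic_range(filtered, emulation)
}

#' @export
print.pattern_comparison <- function(x, ...) {
  cat("Pattern comparison\n  Pearson r (linear RCS):",
      paste(sprintf("%s %.3f", toupper(names(x$pearson)), x$pearson),
            collapse = ", "),
      "\n  RMSE [dB]:",
      paste(sprintf("%s %.2f", toupper(names(x$rmse_db)), x$rmse_db),
            collapse = ", "), "\n")
  cat("  Sector table (pattern A):\n")
  print(x$sectors_a, ...)
  invisible(x)
}

#' Run the size-ratio scenario between two geometries
#'
#' Sweeps both geometries across the configured frequency list and
#' reports the size-ratio curve (ratio, Pearson r, RMSE) with the
#' operational equivalence threshold (first ratio with r >= 0.9
#' sustained).
#'
#' @param config Config (path or list) with `frequency_hz` a vector; the
#'   primary geometry keys name geometry A.
#' @param geometry_b Geometry for the comparison; defaults to
#'   [equivalent_ellipsoid()] of the configured toy organism.
#' @param body_length Body length for the ratio (default 0.05 m).
#' @return A `size_ratio_curve` with attribute `threshold`.
#' @export
run_size_ratio <- function(config, geometry_b = NULL, body_length = 0.05) {
  cfg <- read_run_config(config)
  freqs <- cfg$frequency_hz
  if (length(freqs) < 1L) stop("config error: need a frequency list")
  geom_a <- config_geometry(cfg)
  if (is.null(geometry_b)) {
    if (!inherits(geom_a, "toy_organism_spec")) {
      stop("give `geometry_b` explicitly for non-toy geometry A")
    }
    geometry_b <- equivalent_ellipsoid(geom_a)
  }
  mat <- as_material(cfg$material)
  sweep_one <- function(geom) {
    pats <- lapply(freqs, function(f) {
      lambda <- .c_mps / f
      d <- config_spacing(cfg, lambda, mat)
      g <- geom
      if (inherits(g, "toy_organism_spec")) g <- make_toy_organism(g)
      lat <- if (inherits(g, "ellipsoid_spec")) {
        make_ellipsoid_lattice(g, d, mat)
      } else {
        voxelize_mesh(g, d, material = mat,
                      partial = isTRUE(cfg$partial_voxels))
      }
      azimuth_sweep(lat, lambda, plane_tilt = cfg$plane_tilt_deg,
                    step = cfg$azimuth_step_deg, tolerance = cfg$tolerance,
                    method = cfg$method, model = cfg$polarizability_model)
    })
    attr(pats, "frequencies") <- freqs
    pats
  }
  pats_a <- sweep_one(geom_a)
  pats_b <- sweep_one(geometry_b)
  curve <- size_ratio_analysis(pats_a, pats_b, body_length)
  attr(curve, "threshold") <- equivalence_threshold(curve)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(curve),
                     file.path(cfg$output_dir, "size_ratio.csv"),
                     row.names = FALSE)
  }
  curve
}
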