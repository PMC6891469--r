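# Run configuration (YAML/JSON) and the simulate -> reconstruct -> evaluate
# pipeline behind the command-line interface.

.configDefaults <- function() {
  list(
    seed = 1L,
    optics = list(wavelength_um = 0.633, objective_na = 0.1, magnification = 2,
                  camera_pixel_um = 3.45, bit_depth = 10L,
                  dynamic_range_db = 50, sensor_shape = c(1536L, 2048L)),
    geometry = list(half_extent = 15L, pitch_mm = 2.5, standoff_mm = 93,
                    offset_mm = c(0, 0), roll_deg = 0),
    plan = list(ring_exposure_ms = defaultRingExposureMap(),
                max_ring = NA_integer_, duty_cycle = 1),
    camera = list(photon_budget = 700, read_noise_e = 50, bit_depth = 10L,
                  full_well = 1e5, shot_noise = TRUE, quantize = TRUE),
    sample = list(kind = "usaf", periods_um = c(6.6, 4.4, 2.19, 1.6),
                  n_bars = 3L, shape = 192L, pitch_um = NA_real_,
                  feature_scale_um = 10, max_phase_rad = 1,
                  factor_sigma = 0.2),
    recon = list(upsampling_factor = NA_integer_, max_sweeps = 10L,
                 rel_tol = 1e-3, update_order = "center_out_spiral"),
    sa = list(enabled = TRUE, t_initial = NA_real_, cooling = 0.9,
              proposals_per_visit = 3L, proposal_width = 0.1, t_floor = 1e-12),
    evaluation = list(min_contrast = 0.2, blank_margin_um = 5)
  )
}

mergeSection <- function(defaults, user, name) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown key(s) in config section '", name, "': ",
         paste(unknown, collapse = ", "))
  defaults[names(user)] <- user
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) file with sections `optics`, `geometry`, `plan`,
#' `camera`, `sample`, `recon`, `sa`, `evaluation` and a global `seed`, fills
#' defaults for everything omitted, rejects unknown keys and validates each
#' section by constructing its typed object. A round trip through
#' [saveRunConfig()] is the identity.
#'
#' @param path config file path
#' @return validated config list with all defaults filled
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  validateRunConfig(user)
}

#' Validate a run configuration list
#' @param user config list (possibly partial)
#' @return config list with defaults filled
#' @export
validateRunConfig <- function(user = list()) {
  d <- .configDefaults()
  unknown <- setdiff(names(user), names(d))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  cfg <- d
  cfg$seed <- if (!is.null(user$seed)) as.integer(user$seed) else d$seed
  for (s in setdiff(names(d), "seed"))
    cfg[[s]] <- mergeSection(d[[s]], user[[s]], s)
  # constructing the typed objects runs every validity method
  invisible(.configOptics(cfg)); invisible(.configGeometry(cfg))
  invisible(.configCamera(cfg))
  cfg
}

#' Save a run configuration as YAML
#' @param cfg config list from [validateRunConfig()]
#' @param path output path
#' @export
saveRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

.configOptics <- function(cfg) {
  o <- cfg$optics
  opticalSystem(o$wavelength_um, o$objective_na, o$magnification,
                o$camera_pixel_um, o$bit_depth, o$dynamic_range_db,
                o$sensor_shape)
}

.configGeometry <- function(cfg) {
  g <- cfg$geometry
  ledArrayGeometry(g$half_extent, g$pitch_mm, g$standoff_mm, g$offset_mm,
                   g$roll_deg)
}

.configCamera <- function(cfg) {
  cm <- cfg$camera
  cameraModel(cm$photon_budget, cm$read_noise_e, cm$bit_depth, cm$full_well,
              cm$shot_noise, cm$quantize)
}

.configPlan <- function(cfg, geom) {
  p <- cfg$plan
  maxRing <- if (is.na(p$max_ring)) geom@halfExtent else as.integer(p$max_ring)
  illuminationPlan(geom, p$ring_exposure_ms, maxRing, p$duty_cycle)
}

.configSample <- function(cfg, sys, geom) {
  s <- cfg$sample
  recon <- cfg$recon
  k <- if (is.na(recon$upsampling_factor)) {
    chooseUpsampling(sys, geom, s$shape, reconConfig())
  } else as.integer(recon$upsampling_factor)
  hrPitch <- if (is.na(s$pitch_um)) pixelPitchUm(sys) / k else s$pitch_um
  shape <- as.integer(s$shape)
  if (s$kind == "usaf") {
    defaultChart(s$periods_um, shape, hrPitch, nBars = s$n_bars)
  } else {
    phaseObject(s$feature_scale_um, s$max_phase_rad, shape, hrPitch,
                seed = cfg$seed)
  }
}

#' Default resolution chart layout
#'
#' Places one 3-bar vertical element per period at the quadrant centers of the
#' field (coarsest first), the layout used by the package's resolution
#' experiments.
#'
#' @param periodsUm element periods (um), at most 4
#' @param shape field side (pixels)
#' @param pitchUm pixel pitch (um)
#' @param nBars bars per element
#' @return a [ResolutionChart-class]
#' @export
defaultChart <- function(periodsUm, shape, pitchUm, nBars = 3L) {
  stopifnot(length(periodsUm) <= 4L)
  q <- shape * pitchUm / 4
  pos <- rbind(c(-q, -q), c(q, -q), c(-q, q), c(q, q))
  periodsUm <- sort(periodsUm, decreasing = TRUE)
  el <- data.frame(period_um = periodsUm, orientation = "vertical",
                   x_um = pos[seq_along(periodsUm), 1],
                   y_um = pos[seq_along(periodsUm), 2],
                   n_bars = as.integer(nBars))
  usafLikeTarget(el, shape, pitchUm)
}

#' Run the simulate / reconstruct / evaluate pipeline
#'
#' Executes the requested stages in order with one seeded random stream per
#' stage, writes every artifact under `outDir` and returns (and writes) a
#' machine-readable run report. Startup logs summarize the geometry-derived
#' quantities (illumination NA, overlap ratio, upsampling factor) so runs are
#' self-documenting.
#'
#' @param cfg config list from [loadRunConfig()] / [validateRunConfig()]
#' @param stages subset of c("simulate", "reconstruct", "evaluate")
#' @param outDir output directory (created if missing)
#' @return run report list, also written to `outDir/report.json`
#' @export
runPipeline <- function(cfg, stages = c("simulate", "reconstruct", "evaluate"),
                        outDir = "fpm-run") {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sys <- .configOptics(cfg)
  geom <- .configGeometry(cfg)
  cam <- .configCamera(cfg)
  plan <- .configPlan(cfg, geom)
  report <- list(config = cfg, stages = stages, timings_s = list(),
                 outputs = list(), metrics = list())
  message(sprintf(
    "geometry: illumination NA axial %.3f / radial %.3f, overlap ratio %.3f",
    illuminationNA(geom, "axial"), illuminationNA(geom, "radial"),
    overlapRatio(sys, geom)))

  chart <- NULL
  obj <- NULL
  if ("simulate" %in% stages || "evaluate" %in% stages) {
    obj <- .configSample(cfg, sys, geom)
    if (is(obj, "ResolutionChart")) chart <- obj
  }

  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    factors <- drawFactors(plan, cfg$sample$factor_sigma, seed = cfg$seed)
    stack <- simulateStack(obj, sys, geom, plan, factors, cam,
                           seed = cfg$seed + 1L)
    writeStack(stack, file.path(outDir, "stack"))
    writeComplexField(obj, file.path(outDir, "ground_truth"))
    if (!is.null(chart))
      utils::write.csv(chart@elements, file.path(outDir, "chart_elements.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(m = plan@entries$m, n = plan@entries$n,
                                factor = factors),
                     file.path(outDir, "factors_true.csv"), row.names = FALSE)
    report$timings_s$simulate <- unname(proc.time()[3] - t0)
    report$outputs$stack <- file.path(outDir, "stack.tiff")
  }

  res <- NULL
  if ("reconstruct" %in% stages) {
    t0 <- proc.time()[3]
    stackPath <- file.path(outDir, "stack")
    if (!file.exists(paste0(stackPath, ".tiff")))
      stop("reconstruct stage needs ", stackPath, ".tiff (run simulate first)")
    stack <- readStack(stackPath)
    stack <- normalizeStack(stack, cam)
    rc <- cfg$recon
    rcfg <- reconConfig(rc$upsampling_factor, rc$max_sweeps, rc$rel_tol,
                        rc$update_order, seed = cfg$seed + 2L)
    sa <- cfg$sa
    sac <- saConfig(sa$enabled, sa$t_initial, sa$cooling,
                    sa$proposals_per_visit, sa$proposal_width, sa$t_floor)
    res <- fpmReconstruct(stack, sys, geom, rcfg, sac)
    writeComplexField(hrField(res), file.path(outDir, "recon"))
    utils::write.csv(data.frame(m = stack@meta$m, n = stack@meta$n,
                                factor = reconFactors(res)),
                     file.path(outDir, "factors_recovered.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(sweep = seq_along(reconTrace(res)),
                                cost = reconTrace(res)),
                     file.path(outDir, "trace.csv"), row.names = FALSE)
    report$timings_s$reconstruct <- unname(proc.time()[3] - t0)
    report$metrics$sweeps <- res@sweeps
    report$metrics$final_cost <- unname(utils::tail(reconTrace(res), 1))
    report$outputs$recon <- file.path(outDir, "recon_amplitude.tiff")
  }

  if ("evaluate" %in% stages) {
    t0 <- proc.time()[3]
    reconPath <- file.path(outDir, "recon")
    if (!file.exists(paste0(reconPath, ".json")))
      stop("evaluate stage needs ", reconPath,
           "_amplitude.tiff (run reconstruct first)")
    rec <- readComplexField(reconPath)
    minC <- cfg$evaluation$min_contrast
    metrics <- list()
    if (!is.null(chart)) {
      metrics$smallest_resolved_period_um <-
        smallestResolvedPeriod(rec, chart@elements, minC)
      blank <- chartBlankRegion(chart, cfg$evaluation$blank_margin_um)
      metrics$background_ripple <- backgroundRipple(rec, blank)
      perElement <- chart@elements
      perElement$resolved <- vapply(seq_len(nrow(perElement)), function(i) {
        e <- perElement[i, ]
        prof <- elementProfile(intensity(rec), rec@pixelPitchUm, e)
        resolvable(prof, e$n_bars, minC,
                   if (isTRUE(e$dark)) "valleys" else "peaks")
      }, NA)
      utils::write.csv(perElement, file.path(outDir, "metrics_elements.csv"),
                       row.names = FALSE)
    }
    truthPath <- file.path(outDir, "ground_truth")
    if (file.exists(paste0(truthPath, ".json"))) {
      truth <- readComplexField(truthPath)
      if (all(dim(truth@data) == dim(rec@data)))
        metrics$rmse_complex <- rmseComplex(rec, truth)
    }
    report$metrics <- c(report$metrics, metrics)
    report$timings_s$evaluate <- unname(proc.time()[3] - t0)
    jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
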