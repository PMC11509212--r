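## Configuration validation and the end-to-end processing pipeline.

.config_schema <- list(
  input = c("frames_rds", "curve_csv"),
  simulate = c("preset", "n_steps", "total_stress_kpa", "snr_db", "n_x",
               "seed", "Em_kpa", "B_kpa", "vt", "Esil_kpa"),
  imaging = c("lambda0_nm", "pitch_axial_um", "pitch_lateral_um", "n"),
  processing = c("strain_method", "window_axial_px", "window_lateral_px",
                 "tissue_roi", "silicone_roi"),
  fitting = c("loss"),
  maps = c("sigma_std_kpa", "window_px", "tissue_rows", "tissue_cols"),
  top = c("input", "simulate", "imaging", "processing", "fitting", "maps",
          "output_dir", "seed", "log_level")
)

#' Validated run configuration
#'
#' Parses and validates a pipeline configuration (JSON file or list)
#' against the shipped key schema; any unknown key is rejected by name
#' before computation starts.
#'
#' @param config Path to a JSON configuration file, or a list.
#' @return Object of class `run_config` (the validated list).
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_schema$top)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), names(.config_schema))) {
    if (!is.list(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), .config_schema[[sec]])
    if (length(bad))
      stop(sprintf("unknown configuration key(s) in '%s': %s",
                   sec, paste(bad, collapse = ", ")))
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$output_dir)) config$output_dir <- "."
  meth <- config$processing$strain_method
  if (!is.null(meth) && !meth %in% c("vector", "leastsquares"))
    stop("processing$strain_method must be 'vector' or 'leastsquares'")
  structure(config, class = "run_config")
}

.stage <- function(name, expr, timings, quiet) {
  t0 <- proc.time()[["elapsed"]]
  res <- withCallingHandlers(
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)),
    warning = function(w) {
      if (!quiet) message(sprintf("[%s] warning: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  if (!quiet)
    message(sprintf("[%s] done in %.2f s", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

.roi_from_cfg <- function(x) list(rows = x$rows[1]:x$rows[2],
                                  cols = x$cols[1]:x$cols[2])

#' Run the full C-OCE processing pipeline
#'
#' Executes frames -> incremental strain -> cumulative strain ->
#' stress-strain curve -> constitutive fit (-> standardized-stress
#' modulus map, when configured) and writes every artifact plus a
#' manifest (input checksums, configuration, package version, seed)
#' under the configured output directory. Deterministic stages
#' reproduce byte-identically when rerun with the same manifest inputs.
#'
#' @param config A [run_config()], or anything accepted by it.
#' @param quiet Suppress per-stage log messages (default FALSE).
#' @return Invisibly, a list with the curve, fit, derived curves,
#'   optional map, and the manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  checksums <- list()

  frames <- truth <- NULL
  if (!is.null(cfg$input$frames_rds)) {
    path <- cfg$input$frames_rds
    if (!file.exists(path)) stop("input frames not found: ", path)
    checksums[[path]] <- unname(tools::md5sum(path))
    frames <- .stage("load", read_frames(path), timings, quiet)
  } else {
    sim <- cfg$simulate
    if (is.null(sim)) stop("config needs either input$frames_rds or simulate")
    spec <- default_phantom_spec(
      n_steps = sim$n_steps %||% 20L,
      total_stress_kpa = sim$total_stress_kpa %||% 20,
      snr_db = sim$snr_db %||% 30,
      n_x = sim$n_x %||% 64L,
      seed = sim$seed %||% cfg$seed,
      tissue_params = constitutive_params(sim$Em_kpa %||% 300,
                                          sim$B_kpa %||% 4,
                                          sim$vt %||% 0.05),
      Esil_kpa = sim$Esil_kpa %||% 100)
    gen <- .stage("simulate", make_frames(spec), timings, quiet)
    frames <- gen$frames
    truth <- gen$truth
    write_frames(frames, file.path(out, "frames.rds"))
    jsonlite::write_json(truth[c("stress_kpa", "layer_names",
                                 "decorrelation_steps")],
                         file.path(out, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  meth <- cfg$processing$strain_method %||% "vector"
  wz <- cfg$processing$window_axial_px %||% 8L
  wx <- cfg$processing$window_lateral_px %||% 8L
  series <- .stage("strain", {
    incs <- vector("list", length(frames) - 1L)
    for (i in seq_along(incs)) {
      incs[[i]] <- if (meth == "vector")
        strain_vector(frames[[i]], frames[[i + 1L]], window = c(wz, wx))
      else
        strain_leastsquares(phase_difference(frames[[i]], frames[[i + 1L]]),
                            window = c(wz, wx))
    }
    lapply(seq_along(incs), function(k) accumulate_strain(incs[seq_len(k)]))
  }, timings, quiet)

  t_roi <- .roi_from_cfg(cfg$processing$tissue_roi %||%
                           list(rows = c(46, 80), cols = c(9, 24)))
  s_roi <- .roi_from_cfg(cfg$processing$silicone_roi %||%
                           list(rows = c(8, 24), cols = c(9, 24)))
  cal <- silicone_calibration(cfg$simulate$Esil_kpa %||% 100, roi = s_roi)

  curve <- .stage("curve", build_curve(series, t_roi, s_roi, cal),
                  timings, quiet)
  write_curve_csv(curve, file.path(out, "curve.csv"))

  fit <- .stage("fit", fit_constitutive(curve,
                                        loss = cfg$fitting$loss %||% "linear"),
                timings, quiet)
  write_fit_json(fit, file.path(out, "fit.json"))
  dc <- derived_curves(fit)
  for (nm in names(dc)) {
    df <- dc[[nm]]
    df[] <- lapply(df, .fmt_num)
    utils::write.csv(df, file.path(out, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  }

  map <- NULL
  if (!is.null(cfg$maps)) {
    map <- .stage("map", standardized_modulus_map(
      series, cal, cfg$maps$sigma_std_kpa %||% 4,
      tissue_rows = cfg$maps$tissue_rows %||% c(46, 80),
      tissue_cols = cfg$maps$tissue_cols %||% c(1, ncol(series[[1]]$S)),
      window_px = cfg$maps$window_px %||% 8L), timings, quiet)
    write_map_tiff(map, file.path(out, "modulus_map.tiff"))
  }

  manifest <- list(package = "coce",
                   version = as.character(utils::packageVersion("coce")),
                   seed = cfg$seed,
                   config = unclass(cfg),
                   input_md5 = checksums,
                   fitted = list(Em_kpa = fit$params$Em, B_kpa = fit$params$B,
                                 vt = fit$params$vt))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(curve = curve, fit = fit, derived = dc, map = map,
                 truth = truth, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
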