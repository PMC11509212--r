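## Readers and writers for the package's on-disk formats.
## CSV: comma-separated, dot decimal, UTF-8, mandatory header, numbers
## written with 9 significant digits. JSON via jsonlite. Complex frame
## sequences as RDS; elastogram maps additionally as scaled 16-bit TIFF
## with a JSON sidecar carrying the scale.

.fmt_num <- function(x) signif(x, 9)

#' Write / read a stress-strain curve as CSV
#'
#' Columns `strain,stress_kpa` with a mandatory header row.
#'
#' @param curve A [stress_strain_curve()].
#' @param path Output file path.
#' @return `write_curve_csv` returns `path` invisibly;
#'   `read_curve_csv` returns a [stress_strain_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  df <- curve$data
  df[] <- lapply(df, .fmt_num)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("strain", "stress_kpa") %in% names(df)))
    stop("curve CSV must have columns strain,stress_kpa")
  stress_strain_curve(df$strain, df$stress_kpa)
}

#' Write / read a pore distribution (CSV + JSON sidecar)
#'
#' CSV columns `axis_value,density`; the sidecar `<path>.json` holds
#' `axis_kind` and the total content `vt`.
#'
#' @param dist A [pore_distribution()].
#' @param path CSV output path.
#' @return `path` invisibly / a [pore_distribution()].
#' @export
write_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "pore_distribution"))
  utils::write.csv(data.frame(axis_value = .fmt_num(dist$grid),
                              density = .fmt_num(dist$density)),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(list(axis_kind = dist$axis,
                            total_content = dist$total_content),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution_csv
#' @export
read_distribution_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pore_distribution(df$axis_value, df$density, axis = side$axis_kind,
                    total_content = side$total_content)
}

#' Write / read a constitutive fit as JSON
#'
#' Stores parameters, standard errors, residual RMS and optimizer
#' diagnostics.
#'
#' @param fit A [fit_constitutive()] result.
#' @param path Output path.
#' @return `path` invisibly / a list mirroring the JSON.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(list(
    params = list(Em_kpa = fit$params$Em, B_kpa = fit$params$B,
                  vt = fit$params$vt),
    standard_errors = as.list(fit$se),
    residual_rms = fit$residual_rms,
    converged = fit$converged,
    diagnostics = fit$info),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Save / load a frame sequence with metadata
#'
#' Serializes the complex frame list (with per-frame metadata) to RDS.
#'
#' @param frames List of [oct_frame()] objects.
#' @param path Output `.rds` path.
#' @return `path` invisibly / the frame list.
#' @export
write_frames <- function(frames, path) {
  stopifnot(all(vapply(frames, inherits, logical(1), "oct_frame")))
  saveRDS(frames, path)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  frames <- readRDS(path)
  stopifnot(all(vapply(frames, inherits, logical(1), "oct_frame")))
  frames
}

#' Export a tangent-modulus map as 16-bit TIFF
#'
#' Scales the map linearly into the 16-bit range; the scale, offset,
#' standardized stress and mask fraction go to a `<path>.json` sidecar
#' so values can be recovered exactly up to quantization.
#'
#' @param map A [standardized_modulus_map()] result.
#' @param path Output `.tiff` path.
#' @return `path` invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "tangent_modulus_map"))
  vals <- map$Eeff
  vals[!map$mask] <- NA
  lo <- min(vals, na.rm = TRUE); hi <- max(vals, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  img <- (vals - lo) / scale
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  jsonlite::write_json(list(offset_kpa = lo, scale_kpa = scale,
                            sigma_std_kpa = map$sigma_std,
                            window_px = map$window_px,
                            valid_fraction = mean(map$mask)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
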