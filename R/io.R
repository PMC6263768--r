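# Plain-text matrix container with explicit axis metadata. Complex payloads
# are stored as paired real/imaginary planes; numbers are written with 17
# significant digits so that read(write(x)) is bit-identical.

FMT <- "%.17g"

#' @noRd
fmt_plane <- function(m) {
  apply(m, 1L, function(r) paste(sprintf(FMT, r), collapse = "\t"))
}

#' @noRd
header_line <- function(key, value) {
  sprintf("#%s\t%s", key, paste(sprintf(FMT, as.numeric(value)), collapse = ","))
}

#' Write a radar matrix object to a text container
#'
#' Serializes an [echo_matrix()], `subband_cube`, [enhanced_matrix()] or
#' bare matrix to a self-describing tab-separated text file. Header lines
#' (prefixed `#`) carry the object kind, dimensions, axis metadata (sweep
#' parameters or explicit axes) and a complex-storage flag; complex payloads
#' follow as a real plane then an imaginary plane. The round trip through
#' [read_radar_matrix()] is bit-identical.
#'
#' @param x Object to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_radar_matrix <- function(x, path) UseMethod("write_radar_matrix")

#' @noRd
write_container <- function(path, kind, meta, planes) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#sfcw-matrix\tv1"), sprintf("#kind\t%s", kind)), con)
  for (k in names(meta)) writeLines(header_line(k, meta[[k]]), con)
  for (p in names(planes)) {
    writeLines(sprintf("#plane\t%s", p), con)
    writeLines(fmt_plane(planes[[p]]), con)
  }
  invisible(path)
}

#' @export
write_radar_matrix.echo_matrix <- function(x, path) {
  sw <- x$sweep
  write_container(path, "echo",
                  list(f0 = sw$f0, delta_f = sw$delta_f, M = sw$M,
                       Ts = sw$Ts, N = sw$N, complex = 1,
                       dims = dim(x$data)),
                  list(real = Re(x$data), imag = Im(x$data)))
}

#' @export
write_radar_matrix.subband_cube <- function(x, path) {
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(2L, 1L, 3L)), nrow = d[1L] * d[2L])
  meta <- list(subband_count = d[1L], L = x$params$L, delta_l = x$params$delta_l,
               complex = 1, dims = d,
               domain = if (identical(x$domain, "frequency")) 0 else 1)
  if (!is.null(x$sweep))
    meta <- c(meta, list(f0 = x$sweep$f0, delta_f = x$sweep$delta_f,
                         M = x$sweep$M, Ts = x$sweep$Ts, N = x$sweep$N))
  write_container(path, "cube", meta, list(real = Re(flat), imag = Im(flat)))
}

#' @export
write_radar_matrix.enhanced_matrix <- function(x, path) {
  write_container(path, "enhanced",
                  list(complex = 0, dims = dim(x$data),
                       range_axis = x$range_axis, freq_axis = x$freq_axis,
                       band = x$band),
                  list(real = x$data))
}

#' @export
write_radar_matrix.matrix <- function(x, path) {
  if (is.complex(x)) {
    write_container(path, "matrix", list(complex = 1, dims = dim(x)),
                    list(real = Re(x), imag = Im(x)))
  } else {
    write_container(path, "matrix", list(complex = 0, dims = dim(x)),
                    list(real = x))
  }
}

#' Read a radar matrix container
#'
#' Parses a file written by [write_radar_matrix()] and reconstructs the
#' original object (an [echo_matrix()], `subband_cube`,
#' [enhanced_matrix()], or bare matrix).
#'
#' @param path Path to a container file.
#' @return The deserialized object.
#' @export
read_radar_matrix <- function(path) {
  if (!file.exists(path)) {
    stop(structure(class = c("sfcw_missing_file_error", "error", "condition"),
                   list(message = sprintf("no such file: %s", path),
                        call = sys.call())))
  }
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- strsplit(sub("^#", "", lines[is_hdr]), "\t", fixed = TRUE)
  keys <- vapply(hdr, `[`, "", 1L)
  vals <- vapply(hdr, function(x) if (length(x) > 1L) x[2L] else "", "")
  if (!identical(keys[1L], "sfcw-matrix"))
    stop_validation("not an sfcw-matrix container")
  meta <- as.list(vals[!(keys %in% c("sfcw-matrix", "kind", "plane"))])
  names(meta) <- keys[!(keys %in% c("sfcw-matrix", "kind", "plane"))]
  meta <- lapply(meta, function(v) as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]]))
  kind <- vals[keys == "kind"][1L]
  # split payload rows into planes by the preceding "#plane" header
  hdr_idx <- which(is_hdr)
  plane_rows <- split(which(!is_hdr),
                      findInterval(which(!is_hdr), hdr_idx[keys == "plane"]))
  planes <- lapply(plane_rows, function(rows) {
    do.call(rbind, lapply(strsplit(lines[rows], "\t", fixed = TRUE), as.numeric))
  })
  names(planes) <- vals[keys == "plane"]
  payload <- if (isTRUE(meta$complex == 1)) {
    matrix(complex(real = planes$real, imaginary = planes$imag),
           nrow = nrow(planes$real))
  } else {
    planes$real
  }
  switch(kind,
    echo = echo_matrix(payload,
                       sweep_config(meta$f0, meta$delta_f, meta$M, meta$Ts, meta$N)),
    enhanced = enhanced_matrix(payload, meta$range_axis, meta$freq_axis,
                               band = meta$band),
    cube = {
      d <- as.integer(meta$dims)
      a <- aperm(array(payload, dim = c(d[2L], d[1L], d[3L])), c(2L, 1L, 3L))
      structure(list(data = a,
                     params = segmentation_params(meta$L, meta$delta_l),
                     sweep = if (!is.null(meta$f0))
                       sweep_config(meta$f0, meta$delta_f, meta$M, meta$Ts, meta$N)
                     else NULL,
                     subband_count = d[1L],
                     domain = if (meta$domain == 0) "frequency" else "range"),
                class = "subband_cube")
    },
    payload)
}

#' Export a power-range plot as delimited text
#'
#' Two-column tab-separated file (`range_m`, `power_db`) with `#`-prefixed
#' header lines carrying the peak location and the SNCR estimate.
#'
#' @param plot A `power_range_plot`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_power_range_plot <- function(plot, path) {
  stopifnot(inherits(plot, "power_range_plot"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#peak_range_m\t%.6f", plot$peak_range),
               sprintf("#sncr_db\t%.4f", plot$sncr),
               "range_m\tpower_db"), con)
  writeLines(sprintf("%.6f\t%.6f", plot$range_axis, plot$values), con)
  invisible(path)
}

#' Default run configuration
#'
#' The simulation conditions used throughout the package: the reference
#' stepped-frequency sweep (f0 = 500 MHz, step 10 MHz, 501 frequencies,
#' slow-time period 5 ms, 2001 samples — 5 GHz bandwidth, 15 m unambiguous
#' range, 30 s record), a unit-reflectivity breathing target at 3 m with
#' 5 mm displacement at 0.2 Hz, an empty scene, and the default
#' segmentation/pipeline/identification parameters.
#'
#' @return Nested configuration list, serializable with
#'   [write_run_config()].
#' @export
default_run_config <- function() {
  list(
    sweep = list(f0 = 500e6, delta_f = 10e6, M = 501L, Ts = 0.005, N = 2001L),
    target = list(alpha = 1, d0 = 3, delta_d = 0.005, fb = 0.2),
    scene = list(static_scatterers = list(), spectrum_profile = "flat",
                 noise_sigma = 0),
    segmentation = list(L = 100L, delta_l = 10L),
    pipeline = list(averaging_stage = "AaT", range_resample_factor = 10L,
                    motion_filter_order = 160L, lowpass_order = 321L,
                    lowpass_cutoff = 0.5, background_mode = "moving_average",
                    short_mode = FALSE),
    identification = list(tol_range_bins = 3L, tol_freq_bins = 2L),
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Missing groups or fields fall back to [default_run_config()].
#'
#' @param path Path to a YAML file.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(structure(class = c("sfcw_missing_file_error", "error", "condition"),
                   list(message = sprintf("no such file: %s", path),
                        call = sys.call())))
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (grp in names(base)) {
    if (is.list(base[[grp]])) {
      for (k in names(base[[grp]]))
        if (!is.null(cfg[[grp]][[k]])) base[[grp]][[k]] <- cfg[[grp]][[k]]
    } else if (!is.null(cfg[[grp]])) {
      base[[grp]] <- cfg[[grp]]
    }
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param config Nested configuration list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build validated parameter objects from a configuration list.
#' @noRd
config_objects <- function(cfg) {
  sw <- cfg$sweep
  tg <- cfg$target
  sc <- cfg$scene
  scat <- NULL
  if (length(sc$static_scatterers) > 0) {
    scat <- do.call(rbind, lapply(sc$static_scatterers, function(s) {
      data.frame(range = s$range,
                 reflectivity = complex(real = s$reflectivity_re %||% s$reflectivity,
                                        imaginary = s$reflectivity_im %||% 0))
    }))
  }
  pp <- cfg$pipeline
  list(
    sweep = sweep_config(sw$f0, sw$delta_f, sw$M, sw$Ts, sw$N),
    target = breathing_target(tg$alpha, tg$d0, tg$delta_d, tg$fb),
    scene = clutter_scene(scat, sc$spectrum_profile, sc$noise_sigma),
    seg = segmentation_params(cfg$segmentation$L, cfg$segmentation$delta_l),
    pipe = pipeline_params(pp$averaging_stage, pp$range_resample_factor,
                           pp$motion_filter_order, pp$lowpass_order,
                           pp$lowpass_cutoff, pp$background_mode,
                           pp$short_mode),
    tol = c(cfg$identification$tol_range_bins, cfg$identification$tol_freq_bins),
    seed = as.integer(cfg$seed)
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
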