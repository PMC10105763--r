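#' Write an MBR stack as a multi-page TIFF with a YAML sidecar
#'
#' One 32-bit page per frame, page order = time order.  The TIFF format
#' written by the available encoder stores normalized samples, so values are
#' divided by a full-scale factor on write; the factor, together with the
#' frame times, the seed and the generating phantom spec (when present), is
#' recorded in a `<path>.yaml` sidecar and the values are restored exactly
#' on read — units are arbitrary LSFG units throughout and are never
#' rescaled beyond this round-trip.
#'
#' @param seq An `lsfg_sequence`.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(seq, path) {
  stopifnot(inherits(seq, "lsfg_sequence"))
  d <- dim(seq$values)
  scale <- tiff_scale(max(seq$values))
  pages <- lapply(seq_len(d[3]), function(j) seq$values[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(times = as.numeric(seq$times), scale = scale)
  spec <- seq$meta$spec
  if (!is.null(spec)) {
    meta$seed <- spec$seed
    meta$spec <- serialize_phantom_spec(spec)
  }
  yaml::write_yaml(meta, sidecar_path(path), precision = 15L)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".yaml")

# power-of-two full-scale factor, so repeated write/read cycles re-quantize
# to the same grid (idempotent storage)
tiff_scale <- function(mx) {
  if (!is.finite(mx) || mx <= 0) return(1)
  2^ceiling(log2(mx))
}

serialize_phantom_spec <- function(spec) {
  regions <- lapply(spec$regions, function(r) {
    r <- unclass(r)
    r$harmonics <- lapply(r$harmonics, as.numeric)
    r
  })
  list(height = spec$height, width = spec$width, n_frames = spec$n_frames,
       duration_s = spec$duration_s, cardiac_freq_hz = spec$cardiac_freq_hz,
       noise_shape = if (is.finite(spec$noise_shape)) spec$noise_shape
                     else "Inf",
       seed = spec$seed, regions = regions)
}

deserialize_phantom_spec <- function(x) {
  regions <- lapply(x$regions, function(r) {
    h <- if (length(r$harmonics)) r$harmonics else NULL
    switch(r$geometry,
      background = region_background(r$mean_mbr, r$pulse_ratio, r$phase,
                                     h, r$name),
      disk = region_disk(unlist(r$center), r$radius, r$mean_mbr,
                         r$pulse_ratio, r$phase, h, r$name),
      vessel = region_vessel(unlist(r$from), unlist(r$to), r$half_width,
                             r$mean_mbr, r$pulse_ratio, r$phase, h, r$name))
  })
  phantom_spec(x$height, x$width, x$n_frames, x$duration_s,
               x$cardiac_freq_hz, regions,
               noise_shape = if (identical(x$noise_shape, "Inf")) Inf
                             else x$noise_shape,
               seed = x$seed)
}

#' Read an MBR stack from a multi-page TIFF
#'
#' Reads all pages (which must share one shape) into an H x W x T stack.
#' Frame times and the value scale come from the YAML sidecar written by
#' [write_stack()]; without a sidecar, times default to the standard
#' acquisition pattern `t_j = j * 4 / 118` seconds and values are used as
#' stored.
#'
#' @param path TIFF path.
#' @return An `lsfg_sequence`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2) {
    stop("stack has fewer than 2 pages: cannot form a time series",
         call. = FALSE)
  }
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("pages have inconsistent shapes", call. = FALSE)
  }
  vals <- array(unlist(pages), dim = c(shapes[1, 1], shapes[2, 1],
                                       length(pages)))
  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    y <- yaml::read_yaml(sc)
    times <- as.numeric(y$times)
    if (!is.null(y$scale)) vals <- vals * y$scale
    if (!is.null(y$spec)) {
      meta$spec <- tryCatch(deserialize_phantom_spec(y$spec),
                            error = function(e) NULL)
    }
  } else {
    times <- (seq_along(pages) - 1) * 4 / 118
  }
  if (length(times) != length(pages)) {
    stop("sidecar times do not match the page count", call. = FALSE)
  }
  new_lsfg_sequence(vals, times, meta = meta)
}

#' Pipeline run configuration
#'
#' Bundles every parameter of a full analysis run: the input (a stack path
#' or a phantom spec), the spectrum grid, the cardiac band, the scaling
#' constant C, the SLIC parameters, the rubber bands and the output
#' directory.  Validated on construction: the band must lie within the grid
#' range and the rubber bands inside the frame (checked at run time when
#' the frame size is known).
#'
#' @param input Path to a multi-page TIFF, or a [phantom_spec()].
#' @param out_dir Output directory; created if missing.
#' @param grid An [spectrum_grid()].
#' @param band Cardiac band in Hz.
#' @param C Beat-strength scaling constant.
#' @param params [slic_params()].
#' @param onh_band,chd_band Optional [rubber_band]s.
#' @param seed Integer seed governing all randomness of the run.
#' @return A validated `run_config`.
#' @export
run_config <- function(input, out_dir, grid = spectrum_grid(),
                       band = c(0.5, 3), C = 2, params = slic_params(),
                       onh_band = NULL, chd_band = NULL, seed = 1L) {
  if (!(is.character(input) || inherits(input, "phantom_spec"))) {
    stop("input must be a TIFF path or a phantom_spec", call. = FALSE)
  }
  if (band[1] >= band[2]) stop("band must be (low, high)", call. = FALSE)
  if (band[2] < min(grid$freqs) || band[1] > max(grid$freqs)) {
    stop("band lies outside the spectrum grid", call. = FALSE)
  }
  if (!any(grid$freqs >= band[1] & grid$freqs <= band[2])) {
    stop("band contains no grid frequency", call. = FALSE)
  }
  if (C <= 0) stop("C must be positive", call. = FALSE)
  structure(list(input = input, out_dir = out_dir, grid = grid, band = band,
                 C = C, params = params, onh_band = onh_band,
                 chd_band = chd_band, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  x <- unclass(config)
  x$out_dir <- NULL  # the hash names the analysis, not where it lands
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Loads or generates the stack, computes the rubber-band and superpixel
#' regional BOM parameters, the superpixel BOM map, and writes everything
#' under `config$out_dir`: `region_boms.csv` (both methods),
#' `bom_map.tif` + `labels.tif` (32-bit TIFF, values scaled per their
#' sidecars), and `run_summary.yaml` logging every parameter actually used
#' and the config hash that produced the outputs.  Deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `region_report` tibble, the
#'   `bom_map`, the output `paths`, and the `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  if (inherits(config$input, "phantom_spec")) {
    spec <- config$input
    spec$seed <- config$seed
    sq <- generate_sequence(spec)
  } else {
    sq <- read_stack(config$input)
  }
  d <- dim(sq$values)
  report <- dplyr::bind_rows(
    region_boms(sq, config$onh_band, config$chd_band,
                method = "rubber_band", params = config$params,
                grid = config$grid, band = config$band, C = config$C),
    region_boms(sq, config$onh_band, config$chd_band,
                method = "superpixel", params = config$params,
                grid = config$grid, band = config$band, C = config$C)
  )
  smap <- superpixel_bom_map(sq, params = config$params, grid = config$grid,
                             band = config$band, C = config$C)
  paths <- list(
    region_csv = file.path(config$out_dir, "region_boms.csv"),
    bom_map = file.path(config$out_dir, "bom_map.tif"),
    labels = file.path(config$out_dir, "labels.tif"),
    summary = file.path(config$out_dir, "run_summary.yaml")
  )
  rep_out <- report
  rep_out$config_hash <- hash
  write.csv(rep_out, paths$region_csv, row.names = FALSE)
  write_map_tiff(smap$map, paths$bom_map)
  write_map_tiff(smap$labeling$labels, paths$labels)
  yaml::write_yaml(list(
    config_hash = hash,
    seed = config$seed,
    frame = list(height = d[1], width = d[2], n_frames = d[3]),
    grid = list(m = config$grid$m, f_min = min(config$grid$freqs),
                f_max = max(config$grid$freqs)),
    band_hz = as.numeric(config$band),
    C = config$C,
    slic = unclass(config$params),
    n_superpixels = smap$labeling$n_labels
  ), paths$summary)
  invisible(list(region_report = report, bom_map = smap, paths = paths,
                 config_hash = hash))
}

# Single-page 32-bit TIFF with a scale sidecar (same convention as
# write_stack).
write_map_tiff <- function(map, path) {
  scale <- tiff_scale(max(map))
  tiff::writeTIFF(map / scale, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  yaml::write_yaml(list(scale = scale), sidecar_path(path), precision = 15L)
  invisible(path)
}

#' Read a single two-column trace file
#'
#' Plain-text traces: whitespace- or comma-separated `time value` rows,
#' optionally with a header.
#'
#' @param path File path.
#' @return An [lsfg_series()].
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = header, sep = sep)
  lsfg_series(df[[2]], df[[1]])
}
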