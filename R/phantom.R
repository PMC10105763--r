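#' Region of a synthetic flow phantom
#'
#' Each region carries a mean flow level, a ground-truth pulse ratio (the
#' peak-to-peak pulsatile amplitude divided by the mean — the BOM the
#' pipeline should recover with `C = 2`), a cardiac phase, and optional
#' harmonics.  Geometries: the mandatory full-frame `background`, a
#' `disk` (emulating the optic nerve head), and a `vessel` segment of given
#' half-width (a bright vessel over darker tissue).  Regions are rendered in
#' list order with hard edges; later regions overwrite earlier ones.
#'
#' @param mean_mbr Mean flow level, arbitrary LSFG units, > 0.
#' @param pulse_ratio Ground-truth peak-to-peak / mean, in `[0, 2)` so the
#'   noise-free signal stays non-negative.
#' @param phase Cardiac phase in radians.
#' @param harmonics Optional list of `c(multiple, relative_amplitude)` pairs;
#'   harmonic `m` contributes
#'   `(pulse_ratio/2) * rel * sin(2*pi*m*f*t + m*phase)`.  The total
#'   amplitude fraction must keep the signal non-negative.
#' @param name Region name used in reports; defaults shown per constructor.
#' @return A `region_spec` list.
#' @name region_spec
NULL

new_region <- function(geometry, mean_mbr, pulse_ratio, phase, harmonics,
                       name, extra = list()) {
  if (mean_mbr <= 0) stop("mean_mbr must be positive", call. = FALSE)
  if (pulse_ratio < 0 || pulse_ratio >= 2) {
    stop("pulse_ratio must lie in [0, 2) so flow never goes negative",
         call. = FALSE)
  }
  if (!is.null(harmonics)) {
    if (is.matrix(harmonics)) harmonics <- split(harmonics, row(harmonics))
    rel <- vapply(harmonics, function(h) abs(h[2]), numeric(1))
    if ((pulse_ratio / 2) * (1 + sum(rel)) > 1) {
      stop("harmonics push the noise-free signal negative", call. = FALSE)
    }
  }
  structure(c(list(geometry = geometry, mean_mbr = mean_mbr,
                   pulse_ratio = pulse_ratio, phase = phase,
                   harmonics = harmonics, name = name), extra),
            class = "region_spec")
}

#' @rdname region_spec
#' @export
region_background <- function(mean_mbr = 30, pulse_ratio = 0.2, phase = 0,
                              harmonics = NULL, name = "background") {
  new_region("background", mean_mbr, pulse_ratio, phase, harmonics, name)
}

#' @rdname region_spec
#' @param center Length-2 `(row, col)` center in pixels (1-based).
#' @param radius Disk radius in pixels.
#' @export
region_disk <- function(center, radius, mean_mbr, pulse_ratio, phase = 0,
                        harmonics = NULL, name = "disk") {
  stopifnot(length(center) == 2, radius > 0)
  new_region("disk", mean_mbr, pulse_ratio, phase, harmonics, name,
             extra = list(center = as.numeric(center),
                          radius = as.numeric(radius)))
}

#' @rdname region_spec
#' @param from,to Length-2 `(row, col)` segment endpoints in pixels.
#' @param half_width Half-width of the rendered vessel in pixels.
#' @export
region_vessel <- function(from, to, half_width, mean_mbr, pulse_ratio,
                          phase = 0, harmonics = NULL, name = "vessel") {
  stopifnot(length(from) == 2, length(to) == 2, half_width > 0)
  new_region("vessel", mean_mbr, pulse_ratio, phase, harmonics, name,
             extra = list(from = as.numeric(from), to = as.numeric(to),
                          half_width = as.numeric(half_width)))
}

#' Specify a synthetic LSFG phantom
#'
#' Defines an H x W x T pulsatile flow stack: per-region sinusoidal MBR
#' signals (with known amplitude-to-mean ratio, i.e. known ground-truth BOM)
#' sampled uniformly over the acquisition window, with optional
#' i.i.d. multiplicative gamma speckle noise (mean 1, shape `noise_shape`;
#' larger shape = less noise, `Inf` = noise-free).  Defaults follow the
#' LSFG-NAVI acquisition pattern of 118 frames over 4 s.
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Number of frames (>= 4).
#' @param duration_s Acquisition duration in seconds.
#' @param cardiac_freq_hz Cardiac frequency in Hz, within `[0.5, 3]`
#'   (30--180 bpm); default 1.2 Hz = 72 bpm.
#' @param regions List of [region_spec] objects; the first must be the
#'   background.
#' @param noise_shape Gamma shape parameter k of the multiplicative speckle
#'   noise; `Inf` disables noise.
#' @param seed Integer seed making noisy generation reproducible.
#' @return A `phantom_spec` list.
#' @examples
#' spec <- phantom_spec(32, 32, regions = list(region_background(30, 0.2)))
#' seq32 <- generate_sequence(spec)
#' ground_truth_bom(spec)
#' @export
phantom_spec <- function(height, width, n_frames = 118L, duration_s = 4,
                         cardiac_freq_hz = 1.2,
                         regions = list(region_background()),
                         noise_shape = Inf, seed = 1L) {
  stopifnot(height >= 1, width >= 1)
  if (n_frames < 4) stop("n_frames must be at least 4", call. = FALSE)
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  if (cardiac_freq_hz < 0.5 || cardiac_freq_hz > 3) {
    stop("cardiac_freq_hz must lie in [0.5, 3] Hz", call. = FALSE)
  }
  if (!length(regions) || !identical(regions[[1]]$geometry, "background")) {
    stop("the first region must be the background", call. = FALSE)
  }
  if (!all(vapply(regions, inherits, logical(1), "region_spec"))) {
    stop("regions must be region_spec objects", call. = FALSE)
  }
  nm <- vapply(regions, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("region names must be unique", call. = FALSE)
  if (!is.infinite(noise_shape) && noise_shape <= 0) {
    stop("noise_shape must be positive (or Inf for noise-free)",
         call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames),
                 duration_s = as.numeric(duration_s),
                 cardiac_freq_hz = as.numeric(cardiac_freq_hz),
                 regions = regions, noise_shape = noise_shape,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec: %dx%dx%d, %.3g s, f = %.3g Hz, %d region(s), k = %s>\n",
    x$height, x$width, x$n_frames, x$duration_s, x$cardiac_freq_hz,
    length(x$regions), format(x$noise_shape)))
  invisible(x)
}

# Distance from pixel centers to a segment, vectorized over pixels.
segment_distance <- function(r, c, from, to) {
  vx <- to[1] - from[1]
  vy <- to[2] - from[2]
  len2 <- vx * vx + vy * vy
  if (len2 == 0) {
    return(sqrt((r - from[1])^2 + (c - from[2])^2))
  }
  u <- pmin(pmax(((r - from[1]) * vx + (c - from[2]) * vy) / len2, 0), 1)
  sqrt((r - from[1] - u * vx)^2 + (c - from[2] - u * vy)^2)
}

#' Per-pixel region masks of a phantom
#'
#' Renders each region's hard-edged mask after draw-order resolution (later
#' regions win), so exactly one region owns each pixel.  Useful as ground
#' truth for segmentation tests.
#'
#' @param spec A [phantom_spec()].
#' @return A named list of H x W logical matrices, one per region.
#' @export
region_masks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height
  W <- spec$width
  rr <- matrix(rep(seq_len(H), W), H, W)
  cc <- matrix(rep(seq_len(W), each = H), H, W)
  owner <- matrix(1L, H, W)  # background
  for (i in seq_along(spec$regions)[-1]) {
    reg <- spec$regions[[i]]
    inside <- switch(reg$geometry,
      disk = (rr - reg$center[1])^2 + (cc - reg$center[2])^2 <= reg$radius^2,
      vessel = segment_distance(rr, cc, reg$from, reg$to) <= reg$half_width,
      stop("unknown geometry: ", reg$geometry, call. = FALSE)
    )
    owner[inside] <- i
  }
  masks <- lapply(seq_along(spec$regions), function(i) owner == i)
  names(masks) <- vapply(spec$regions, `[[`, character(1), "name")
  masks
}

# Noise-free temporal signal of one region on the phantom's time grid.
region_signal <- function(reg, t, f) {
  s <- 1 + (reg$pulse_ratio / 2) * sin(2 * pi * f * t + reg$phase)
  if (!is.null(reg$harmonics)) {
    for (h in reg$harmonics) {
      s <- s + (reg$pulse_ratio / 2) * h[2] *
        sin(2 * pi * h[1] * f * t + h[1] * reg$phase)
    }
  }
  reg$mean_mbr * s
}

#' Generate a synthetic MBR image sequence
#'
#' Renders the phantom's regions (draw order resolves overlap: later wins)
#' and evaluates each pixel's noise-free signal
#' `mean_mbr * (1 + (pulse_ratio/2) * sin(2*pi*f*t + phase) + harmonics)` on
#' the uniform time grid `t_j = j * duration_s / n_frames`,
#' `j = 0 ... n_frames - 1`.  If `noise_shape` is finite, every sample is
#' multiplied by an independent gamma variate with mean 1 and shape k, the
#' one-parameter multiplicative model of speckle noise.  Generation is
#' deterministic given `spec$seed` and leaves the caller's RNG state
#' untouched.
#'
#' @param spec A [phantom_spec()].
#' @return An `lsfg_sequence`: `values` (H x W x T array, all >= 0), `times`
#'   (seconds), and `meta` (the spec).
#' @export
generate_sequence <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height
  W <- spec$width
  T <- spec$n_frames
  t <- (seq_len(T) - 1) * spec$duration_s / T
  masks <- region_masks(spec)
  owner <- matrix(1L, H, W)
  for (i in seq_along(masks)) owner[masks[[i]]] <- i
  sig <- t(vapply(spec$regions, region_signal, numeric(T),
                  t = t, f = spec$cardiac_freq_hz))  # regions x T
  vals <- sig[as.vector(owner), , drop = FALSE]      # (H*W) x T
  if (is.finite(spec$noise_shape)) {
    k <- spec$noise_shape
    vals <- withr::with_seed(spec$seed,
      vals * matrix(rgamma(length(vals), shape = k, rate = k),
                    nrow(vals), ncol(vals)))
  }
  new_lsfg_sequence(array(vals, dim = c(H, W, T)), t, meta = list(spec = spec))
}

new_lsfg_sequence <- function(values, times, meta = list()) {
  stopifnot(length(dim(values)) == 3, length(times) == dim(values)[3])
  if (any(values < 0)) stop("MBR values must be non-negative", call. = FALSE)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(values = values, times = as.numeric(times), meta = meta),
            class = "lsfg_sequence")
}

#' @export
print.lsfg_sequence <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<lsfg_sequence: %d x %d pixels, %d frames over %.3g s>\n",
              d[1], d[2], d[3], diff(range(x$times)) +
                median(diff(x$times))))
  invisible(x)
}

#' Ground-truth BOM of each phantom region
#'
#' Returns each region's pulse ratio — the BOM value the analysis pipeline
#' should recover with the default scaling `C = 2`.
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric vector, one entry per region.
#' @export
ground_truth_bom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  setNames(vapply(spec$regions, `[[`, numeric(1), "pulse_ratio"),
           vapply(spec$regions, `[[`, character(1), "name"))
}

#' Temporal mean map of a sequence
#'
#' @param seq An `lsfg_sequence`.
#' @return H x W matrix of per-pixel temporal means.
#' @export
temporal_mean_map <- function(seq) {
  stopifnot(inherits(seq, "lsfg_sequence"))
  rowMeans(matrix(seq$values, prod(dim(seq$values)[1:2]),
                  dim(seq$values)[3])) |>
    matrix(dim(seq$values)[1], dim(seq$values)[2])
}
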