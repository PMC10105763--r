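#' Construct an MBR time series
#'
#' A time series of mean blur rate (MBR) values on a strictly increasing time
#' grid, the unit of analysis for all waveform parameters.  Most users obtain
#' one from [roi_time_series()] or [generate_sequence()] rather than building
#' it by hand.
#'
#' @param y Numeric vector of MBR values (arbitrary LSFG units).
#' @param t Numeric vector of acquisition times in seconds, same length as
#'   `y`, strictly increasing.
#' @return An object of class `lsfg_series` with fields `y` and `t`.
#' @examples
#' s <- lsfg_series(20 + 2 * sin(2 * pi * 1.2 * seq(0, 4, length.out = 118)),
#'                  seq(0, 4, length.out = 118))
#' temporal_average(s)
#' @export
lsfg_series <- function(y, t) {
  y <- as.numeric(y)
  t <- as.numeric(t)
  if (length(y) != length(t)) {
    stop("`y` and `t` must have the same length", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(y) || anyNA(t)) stop("series must not contain NA", call. = FALSE)
  structure(list(y = y, t = t), class = "lsfg_series")
}

#' @export
print.lsfg_series <- function(x, ...) {
  cat(sprintf("<lsfg_series: %d samples over %.3g s, mean %.4g>\n",
              length(x$y), diff(range(x$t)), mean(x$y)))
  invisible(x)
}

#' Coerce to an MBR time series
#'
#' Accepts an `lsfg_series`, or a data frame whose first two columns are time
#' (seconds) and value.  Columns named `time`/`t` and `value`/`y`/`mbr` are
#' preferred when present.
#'
#' @param x Object to coerce.
#' @return An `lsfg_series`.
#' @export
as_lsfg_series <- function(x) {
  if (inherits(x, "lsfg_series")) return(x)
  if (is.data.frame(x)) {
    nm <- tolower(names(x))
    tcol <- which(nm %in% c("time", "t"))[1]
    ycol <- which(nm %in% c("value", "y", "mbr"))[1]
    if (is.na(tcol) || is.na(ycol)) {
      tcol <- 1L
      ycol <- 2L
    }
    return(lsfg_series(x[[ycol]], x[[tcol]]))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to lsfg_series", call. = FALSE)
}

#' @export
as.data.frame.lsfg_series <- function(x, ...) {
  data.frame(time = x$t, value = x$y)
}

#' Temporal average of an MBR series
#'
#' @param series An `lsfg_series` (or coercible data frame).
#' @return The arithmetic mean of the MBR values (`MBR_avg`).
#' @export
temporal_average <- function(series) {
  series <- as_lsfg_series(series)
  if (length(series$y) < 1) stop("empty series", call. = FALSE)
  mean(series$y)
}

#' Center an MBR series on its temporal average
#'
#' Subtracts `MBR_avg` so the pulsatile component can be analysed in
#' isolation; the returned series has mean zero.
#'
#' @inheritParams temporal_average
#' @return An `lsfg_series` with `mean(y) == 0`.
#' @export
center_series <- function(series) {
  series <- as_lsfg_series(series)
  lsfg_series(series$y - mean(series$y), series$t)
}

#' Frequency grid for the power spectrum
#'
#' Defines the reporting frequencies of the waveform power spectrum.  The
#' default is 100 elements at 0.1, 0.2, ..., 10.0 Hz.
#'
#' @param m Number of frequency elements.
#' @param f_min,f_max Lowest and highest frequency in Hz.
#' @param freqs Optional explicit frequency vector (overrides the others);
#'   must be positive and strictly increasing.
#' @return An object of class `lsfg_grid` holding `freqs` and `m`.
#' @export
spectrum_grid <- function(m = 100, f_min = 0.1, f_max = 10, freqs = NULL) {
  if (is.null(freqs)) {
    freqs <- seq(f_min, f_max, length.out = m)
  }
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0) || (length(freqs) > 1 && any(diff(freqs) <= 0))) {
    stop("grid frequencies must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(list(freqs = freqs, m = length(freqs)), class = "lsfg_grid")
}

#' @export
print.lsfg_grid <- function(x, ...) {
  cat(sprintf("<lsfg_grid: %d frequencies, %.3g-%.3g Hz>\n",
              x$m, min(x$freqs), max(x$freqs)))
  invisible(x)
}

# Precompute the sine/cosine dictionary and its per-frequency 2x2 Gram terms
# for one time grid.  Shared across every series on that grid (all pixels of
# a stack), which is what makes map-scale fitting cheap.
spectrum_engine <- function(t, grid) {
  freqs <- grid$freqs
  w <- 2 * pi * t
  Fs <- vapply(freqs, function(f) sin(w * f), numeric(length(t)))
  Fc <- vapply(freqs, function(f) cos(w * f), numeric(length(t)))
  ss <- colSums(Fs * Fs)
  cc <- colSums(Fc * Fc)
  sc <- colSums(Fs * Fc)
  det <- pmax(ss * cc - sc * sc, .Machine$double.eps)
  half <- diff(freqs)
  half <- c(half, half[length(half)]) / 2  # local half grid step
  list(t = t, freqs = freqs, Fs = Fs, Fc = Fc,
       ss = ss, cc = cc, sc = sc, det = det, half = half)
}

# Energy explained by a single-frequency sin/cos least-squares fit of the
# residual, vectorized over all grid frequencies.
proj_energy <- function(eng, r) {
  rs <- as.vector(crossprod(eng$Fs, r))
  rc <- as.vector(crossprod(eng$Fc, r))
  a <- (eng$cc * rs - eng$sc * rc) / eng$det
  b <- (eng$ss * rc - eng$sc * rs) / eng$det
  a * rs + b * rc
}

# Same quantity at one arbitrary (off-grid) frequency, with an intercept
# column so that the window DC of a non-integer-period tone does not bias
# the refined frequency.  Closed-form 3x3 normal equations: this sits in
# the innermost refinement loop.
ls_energy_at <- function(t, r, f) {
  w <- 2 * pi * f * t
  s <- sin(w)
  c <- cos(w)
  M <- matrix(0, 3, 3)
  M[1, 1] <- length(t)
  M[1, 2] <- M[2, 1] <- sum(s)
  M[1, 3] <- M[3, 1] <- sum(c)
  M[2, 2] <- sum(s * s)
  M[2, 3] <- M[3, 2] <- sum(s * c)
  M[3, 3] <- sum(c * c)
  rhs <- c(sum(r), sum(r * s), sum(r * c))
  x <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(x)) return(0)
  sum(x * rhs)  # explained energy
}

# Greedy sparse fit (orthogonal matching pursuit) on the sine/cosine
# dictionary.  Each iteration picks the grid frequency explaining the most
# residual energy, optionally refines it continuously within +/- half a grid
# step, then refits all selected atoms jointly.  Returns the selected atom
# frequencies and their joint-fit coefficients.
fit_omp <- function(eng, y, max_components, tol, refine) {
  toten <- sum(y * y)
  empty <- list(freq = numeric(0), a = numeric(0), b = numeric(0))
  if (toten <= 0) return(empty)
  t <- eng$t
  r <- y
  sel <- numeric(0)
  a <- b <- numeric(0)
  for (k in seq_len(max_components)) {
    e <- proj_energy(eng, r)
    i <- which.max(e)
    if (e[i] <= tol * toten) break
    fsel <- eng$freqs[i]
    if (refine) {
      lo <- max(fsel - eng$half[i], .Machine$double.eps)
      hi <- fsel + eng$half[i]
      opt <- optimize(function(f) ls_energy_at(t, r, f), c(lo, hi),
                      maximum = TRUE, tol = eng$half[i] * 1e-3)
      if (opt$objective > e[i]) fsel <- opt$maximum
    }
    if (any(abs(sel - fsel) < 1e-9)) break  # refusing to re-pick an atom
    sel <- c(sel, fsel)
    # the joint refit carries an intercept column: centering removes the
    # mean of the sampled window, not the DC left by a tone spanning a
    # non-integer number of periods, and without the column that DC leaks
    # into the atom amplitudes
    D <- cbind(1,
               vapply(sel, function(f) sin(2 * pi * f * t), numeric(length(t))),
               vapply(sel, function(f) cos(2 * pi * f * t), numeric(length(t))))
    x <- qr.solve(D, y)
    r <- y - as.vector(D %*% x)
    ns <- length(sel)
    a <- x[1 + seq_len(ns)]
    b <- x[1 + ns + seq_len(ns)]
    if (sum(r * r) <= tol * toten) break
  }
  list(freq = sel, a = a, b = b)
}

# Joint ridge-regularized least squares over the full 2M-column dictionary.
fit_ridge_ls <- function(eng, y, ridge) {
  D <- cbind(eng$Fs, eng$Fc)
  m2 <- ncol(D)
  G <- crossprod(D) + ridge * diag(m2)
  x <- tryCatch(
    solve(G, crossprod(D, y)),
    error = function(e) {
      stop("ridge system is singular (2M unknowns exceed the number of ",
           "samples); use ridge > 0", call. = FALSE)
    }
  )
  m <- length(eng$freqs)
  list(a = x[seq_len(m)], b = x[m + seq_len(m)])
}

#' Fit the waveform power spectrum of a centered MBR series
#'
#' Estimates sine/cosine coefficients \eqn{a_i, b_i} of the series on a fixed
#' frequency grid and reports the spectral magnitude
#' \eqn{P(f_i) = \sqrt{a_i^2 + b_i^2}}.
#'
#' Two estimators are available.  The default, `"omp"`, is a greedy sparse
#' fit (orthogonal matching pursuit) on the sine/cosine dictionary: atoms are
#' selected one at a time by residual energy, refined continuously within
#' half a grid step, refit jointly, and finally binned to the nearest grid
#' frequency.  A sparse fit is required because the default grid spacing
#' (0.1 Hz) is far below the Rayleigh resolution of a 4-s recording
#' (0.25 Hz): adjacent dictionary columns are strongly correlated, and any
#' dense minimum-norm solution spreads a single tone's energy across
#' neighbours.  The sparse fit recovers an on-grid tone's amplitude to
#' machine precision and an off-grid tone (up to half a grid step away)
#' within a few hundredths of a percent.
#'
#' `"ridge"` solves the dense problem
#' \eqn{\min_X \|Y - FX\|^2 + \lambda\|X\|^2} over all 2M columns.  It is
#' provided for comparison; note the energy-spreading caveat above.
#'
#' @param series A centered `lsfg_series` (see [center_series()]); at least 4
#'   samples.
#' @param grid An [spectrum_grid()].
#' @param estimator `"omp"` (sparse, default) or `"ridge"` (dense).
#' @param ridge Ridge penalty \eqn{\lambda} for the dense estimator; default
#'   `1e-6 * length(series$y)`.  Must be positive when the dictionary has
#'   more columns than there are samples.
#' @param max_components Maximum number of sparse atoms.
#' @param tol Relative residual-energy stopping tolerance of the sparse fit.
#' @param refine Logical; continuously refine each atom's frequency.
#' @return An object of class `lsfg_spectrum`: `freqs`, `a`, `b`, `p`
#'   (all length M), plus `atoms` (a tibble of refined atom frequencies and
#'   coefficients, `"omp"` only) and `estimator`.
#' @examples
#' t <- seq(0, 4, length.out = 118)[-118]
#' s <- center_series(lsfg_series(20 + 2 * sin(2 * pi * 1.2 * t), t))
#' sp <- fit_spectrum(s)
#' sp$p[which.max(sp$p)]  # ~2, the tone amplitude
#' @export
fit_spectrum <- function(series, grid = spectrum_grid(),
                         estimator = c("omp", "ridge"),
                         ridge = NULL, max_components = 10L,
                         tol = 1e-10, refine = TRUE) {
  series <- as_lsfg_series(series)
  estimator <- match.arg(estimator)
  if (length(series$y) < 4) stop("need at least 4 samples", call. = FALSE)
  eng <- spectrum_engine(series$t, grid)
  res <- fit_spectrum_engine(eng, series$y, estimator = estimator,
                             ridge = ridge, max_components = max_components,
                             tol = tol, refine = refine)
  res
}

# Core fit against a prebuilt engine; used directly by the map-scale paths.
fit_spectrum_engine <- function(eng, y, estimator = "omp", ridge = NULL,
                                max_components = 10L, tol = 1e-10,
                                refine = TRUE) {
  m <- length(eng$freqs)
  if (estimator == "ridge") {
    if (is.null(ridge)) ridge <- 1e-6 * length(y)
    if (ridge <= 0 && 2 * m > length(y)) {
      stop("ridge system is singular (2M unknowns exceed the number of ",
           "samples); use ridge > 0", call. = FALSE)
    }
    fit <- fit_ridge_ls(eng, y, max(ridge, 0))
    a <- fit$a
    b <- fit$b
    atoms <- NULL
  } else {
    fit <- fit_omp(eng, y, max_components = max_components, tol = tol,
                   refine = refine)
    # bin refined atoms to the nearest grid frequency; coefficients add
    # coherently within a bin, so near-duplicate atoms representing one
    # physical component combine to its amplitude
    a <- b <- numeric(m)
    if (length(fit$freq)) {
      bin <- vapply(fit$freq, function(f) which.min(abs(eng$freqs - f)), 1L)
      for (j in seq_along(bin)) {
        a[bin[j]] <- a[bin[j]] + fit$a[j]
        b[bin[j]] <- b[bin[j]] + fit$b[j]
      }
    }
    atoms <- tibble::tibble(freq = fit$freq, a = fit$a, b = fit$b,
                            amp = sqrt(fit$a^2 + fit$b^2))
  }
  structure(list(freqs = eng$freqs, a = a, b = b, p = sqrt(a^2 + b^2),
                 atoms = atoms, estimator = estimator),
            class = "lsfg_spectrum")
}

#' @export
print.lsfg_spectrum <- function(x, ...) {
  i <- which.max(x$p)
  cat(sprintf("<lsfg_spectrum (%s): M = %d, peak p = %.4g at %.3g Hz>\n",
              x$estimator, length(x$freqs), x$p[i], x$freqs[i]))
  invisible(x)
}

#' @export
as.data.frame.lsfg_spectrum <- function(x, ...) {
  data.frame(freq_hz = x$freqs, a = x$a, b = x$b, p = x$p)
}

#' Beat strength: scaled in-band spectral maximum
#'
#' The beat strength is \eqn{BS = C \cdot \max_i P(f_i)} over grid
#' frequencies inside the cardiac band, where it is proportional to the
#' peak-to-peak pulsatile flow.  Ties break toward the lower frequency.
#'
#' @param spectrum An `lsfg_spectrum`.
#' @param band Length-2 numeric, cardiac band in Hz (inclusive).  The default
#'   0.5--3 Hz spans 30--180 bpm.
#' @param C Positive scaling constant; the default 2 makes BOM the exact
#'   pulsatility-index analogue (peak-to-peak / mean) for a pure sinusoid.
#' @return A list with `bs` and `peak_freq_hz`.
#' @export
beat_strength <- function(spectrum, band = c(0.5, 3), C = 2) {
  stopifnot(inherits(spectrum, "lsfg_spectrum"))
  if (C <= 0) stop("C must be positive", call. = FALSE)
  idx <- which(spectrum$freqs >= band[1] & spectrum$freqs <= band[2])
  if (!length(idx)) {
    stop("band [", band[1], ", ", band[2], "] Hz contains no grid frequency",
         call. = FALSE)
  }
  p <- spectrum$p[idx]
  j <- which.max(p)  # first maximum = lowest frequency on ties
  list(bs = C * p[j], peak_freq_hz = spectrum$freqs[idx[j]])
}

#' Compute the BOM resistivity index of one MBR series
#'
#' Composes the full waveform pipeline: temporal average, centering, power
#' spectrum, in-band beat strength, then \eqn{BOM = BS / MBR_{avg}}.  BOM is
#' dimensionless and heart-rate independent; with `C = 2` it equals
#' peak-to-peak pulsatile flow divided by mean flow for a sinusoidal
#' waveform, i.e. the pulsatility-index analogue.
#'
#' @inheritParams fit_spectrum
#' @inheritParams beat_strength
#' @param series An `lsfg_series` (or data frame with time/value columns)
#'   with positive mean.
#' @return An object of class `lsfg_waveform` with fields `mbr_avg`, `bs`,
#'   `bom`, `peak_freq_hz`, `C`, `band`, and the fitted `spectrum`.
#' @examples
#' t <- seq(0, 4, length.out = 118)[-118]
#' w <- bom(lsfg_series(20 + 2 * sin(2 * pi * 1.25 * t), t))
#' w$bom  # ~0.2
#' @export
bom <- function(series, grid = spectrum_grid(), band = c(0.5, 3), C = 2,
                estimator = c("omp", "ridge"), ridge = NULL,
                max_components = 10L, tol = 1e-10, refine = TRUE) {
  series <- as_lsfg_series(series)
  estimator <- match.arg(estimator)
  mbr_avg <- temporal_average(series)
  if (mbr_avg <= 0) stop("mean flow must be positive", call. = FALSE)
  centered <- center_series(series)
  spec <- fit_spectrum(centered, grid = grid, estimator = estimator,
                       ridge = ridge, max_components = max_components,
                       tol = tol, refine = refine)
  bs <- beat_strength(spec, band = band, C = C)
  structure(list(mbr_avg = mbr_avg, bs = bs$bs, bom = bs$bs / mbr_avg,
                 peak_freq_hz = bs$peak_freq_hz, C = C, band = band,
                 spectrum = spec),
            class = "lsfg_waveform")
}

#' @export
print.lsfg_waveform <- function(x, ...) {
  cat(sprintf(
    "<lsfg_waveform: BOM = %.4g (BS = %.4g, MBR_avg = %.4g, peak %.3g Hz)>\n",
    x$bom, x$bs, x$mbr_avg, x$peak_freq_hz))
  invisible(x)
}

#' @export
as.data.frame.lsfg_waveform <- function(x, ...) {
  data.frame(mbr_avg = x$mbr_avg, bs = x$bs, bom = x$bom,
             peak_freq_hz = x$peak_freq_hz, C = x$C,
             band_low_hz = x$band[1], band_high_hz = x$band[2])
}

#' Blowout score (BOS) of an MBR series
#'
#' Legacy per-heartbeat waveform parameter: for each beat window,
#' \eqn{100 \cdot 2\,\min(y) / (\max(y) + \min(y))}, averaged over beats.
#' A low BOS corresponds to high resistivity, so BOS and BOM are negatively
#' related.  Unlike BOM, BOS requires heartbeat segmentation, supplied here
#' as explicit index windows (see [beat_windows()]).
#'
#' @inheritParams temporal_average
#' @param beats A list of length-2 integer vectors `(start, end)` (inclusive
#'   sample indices), or a 2-column matrix; each window needs at least 3
#'   samples and positive values.
#' @return BOS as a percentage in (0, 100] for positive signals.
#' @export
bos <- function(series, beats) {
  series <- as_lsfg_series(series)
  if (is.matrix(beats)) beats <- split(beats, row(beats))
  vals <- vapply(beats, function(w) {
    w <- as.integer(w)
    idx <- seq(w[1], w[2])
    if (length(idx) < 3) stop("beat window has fewer than 3 samples",
                              call. = FALSE)
    yw <- series$y[idx]
    if (any(yw <= 0)) stop("non-positive values inside a beat window",
                           call. = FALSE)
    100 * 2 * min(yw) / (max(yw) + min(yw))
  }, numeric(1))
  mean(vals)
}

#' Beat windows from a known cardiac frequency
#'
#' Splits a series into complete cardiac periods given the pulse frequency —
#' a convenience for phantoms, where the frequency is known exactly.
#'
#' @inheritParams temporal_average
#' @param freq_hz Cardiac frequency in Hz.
#' @return A list of `(start, end)` index pairs, one per complete beat.
#' @export
beat_windows <- function(series, freq_hz) {
  series <- as_lsfg_series(series)
  period <- 1 / freq_hz
  t0 <- series$t[1]
  k <- floor((series$t - t0) / period)
  windows <- lapply(split(seq_along(k), k), range)
  # keep only complete periods (the window's span covers most of a period)
  dt <- median(diff(series$t))
  keep <- vapply(windows, function(w) {
    n_expected <- period / dt
    (w[2] - w[1] + 1) >= floor(0.9 * n_expected) && (w[2] - w[1] + 1) >= 3
  }, logical(1))
  unname(windows[keep])
}
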