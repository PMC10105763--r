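#' SLIC parameters for flow-driven superpixel segmentation
#'
#' @param S Grid spacing in pixels.  The default 14 keeps superpixels small
#'   enough (about 200 pixels) to preserve the shape of large retinal
#'   vessels.
#' @param compactness Positive weight of the flow term relative to the
#'   spatial term in the clustering distance.  Flow differences are first
#'   normalized by the map's interquartile range (floored at the median
#'   flow level), so `compactness` is unit-free; the default 0.1 is
#'   strongly flow-dominant, which keeps superpixels from straddling
#'   vessel edges.
#' @param max_iter Safety cap on assignment iterations; the loop normally
#'   stops earlier, when no pixel changes cluster.
#' @param min_size_frac A label whose largest connected fragment is smaller
#'   than `min_size_frac * S^2` pixels is absorbed by its neighbours.
#' @return A `slic_params` list.
#' @export
slic_params <- function(S = 14L, compactness = 0.1, max_iter = 50L,
                        min_size_frac = 0.25) {
  if (S < 1) stop("S must be at least 1", call. = FALSE)
  if (compactness <= 0) stop("compactness must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be at least 1", call. = FALSE)
  structure(list(S = as.integer(S), compactness = compactness,
                 max_iter = as.integer(max_iter),
                 min_size_frac = min_size_frac),
            class = "slic_params")
}

#' Initial superpixel cluster centers
#'
#' Centers are placed `S` pixels apart horizontally and vertically, starting
#' `floor(S/2)` pixels in, with every other row staggered by `floor(S/2)`
#' pixels (hexagonal packing).  Staggered centers that would fall outside
#' the frame are clipped to the last column, preserving the
#' `ceiling(H/S) * ceiling(W/S)` count.
#'
#' @param shape Length-2 integer `(H, W)` frame shape in pixels.
#' @param S Grid spacing in pixels; the frame must be at least `S` in both
#'   dimensions.
#' @return A K x 2 matrix of `(row, col)` centers, 1-based.
#' @export
initialize_centers <- function(shape, S) {
  H <- shape[1]
  W <- shape[2]
  S <- as.integer(S)
  if (H < S || W < S) {
    stop("image must be at least S pixels in each dimension", call. = FALSE)
  }
  base <- S %/% 2L
  rows <- pmin(1L + base + S * (0:(ceiling(H / S) - 1L)), H)
  n_col <- ceiling(W / S)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    offset <- if (i %% 2L == 0L) base else 0L  # stagger every other row
    cols <- pmin(1L + base + offset + S * (0:(n_col - 1L)), W)
    cols <- unique(cols)
    out[[i]] <- cbind(row = rep(rows[i], length(cols)), col = cols)
  }
  do.call(rbind, out)
}

# Dense 4-connected component labeling of a label field by iterative
# min-propagation: each pixel repeatedly takes the smallest component id
# among its 4-neighbours that share its label, until a fixed point.
label_components <- function(labels) {
  H <- nrow(labels)
  W <- ncol(labels)
  comp <- matrix(seq_len(H * W), H, W)
  repeat {
    old <- comp
    if (H > 1) {
      same <- labels[-H, , drop = FALSE] == labels[-1, , drop = FALSE]
      m <- pmin(comp[-H, , drop = FALSE], comp[-1, , drop = FALSE])
      a <- comp[-H, , drop = FALSE]; a[same] <- m[same]
      b <- comp[-1, , drop = FALSE]; b[same] <- m[same]
      comp[-H, ] <- a
      comp[-1, ] <- b
    }
    if (W > 1) {
      same <- labels[, -W, drop = FALSE] == labels[, -1, drop = FALSE]
      m <- pmin(comp[, -W, drop = FALSE], comp[, -1, drop = FALSE])
      a <- comp[, -W, drop = FALSE]; a[same] <- m[same]
      b <- comp[, -1, drop = FALSE]; b[same] <- m[same]
      comp[, -W] <- a
      comp[, -1] <- b
    }
    if (identical(comp, old)) break
  }
  matrix(match(comp, sort(unique(as.vector(comp)))), H, W)
}

# Adjacency pairs (comp_a, comp_b) across 4-neighbour edges of a component
# field, both orientations.
component_adjacency <- function(comp) {
  H <- nrow(comp)
  W <- ncol(comp)
  pairs <- NULL
  if (H > 1) {
    a <- as.vector(comp[-H, ])
    b <- as.vector(comp[-1, ])
    keep <- a != b
    pairs <- rbind(pairs, cbind(a[keep], b[keep]), cbind(b[keep], a[keep]))
  }
  if (W > 1) {
    a <- as.vector(comp[, -W])
    b <- as.vector(comp[, -1])
    keep <- a != b
    pairs <- rbind(pairs, cbind(a[keep], b[keep]), cbind(b[keep], a[keep]))
  }
  unique(pairs)
}

# Post-pass: make every label 4-connected.  Each label keeps its largest
# component (unless that is itself below the minimum size, in which case the
# whole label is absorbed); every other fragment is merged into the adjacent
# resolved label with the most similar mean flow (ties to the larger label),
# so that e.g. a tissue strip cut off by a crossing vessel rejoins tissue
# rather than the vessel.
enforce_connectivity <- function(labels, min_size, mean_map) {
  comp <- label_components(labels)
  nc <- max(comp)
  comp_size <- tabulate(as.vector(comp), nc)
  comp_label <- labels[match(seq_len(nc), as.vector(comp))]
  comp_mean <- as.vector(
    rowsum(as.vector(mean_map), as.vector(comp))) / comp_size
  # main component per label: the largest (ties to the lower component id)
  ord <- order(comp_label, -comp_size, seq_len(nc))
  main_of_label <- setNames(
    ord[!duplicated(comp_label[ord])],
    comp_label[ord][!duplicated(comp_label[ord])]
  )
  resolved <- rep(NA_integer_, nc)  # final label per component
  for (lab in names(main_of_label)) {
    mc <- main_of_label[[lab]]
    if (comp_size[mc] >= min_size) resolved[mc] <- as.integer(lab)
  }
  if (all(is.na(resolved))) {
    # degenerate: every label below the size floor; keep the largest one
    resolved[which.max(comp_size)] <- comp_label[which.max(comp_size)]
  }
  adj <- component_adjacency(comp)
  adj_list <- split(adj[, 2], adj[, 1])
  label_size <- tapply(comp_size, comp_label, sum)
  label_mean <- setNames(comp_mean[main_of_label],
                         names(main_of_label))
  while (anyNA(resolved)) {
    progress <- FALSE
    for (ci in which(is.na(resolved))) {
      nb <- adj_list[[as.character(ci)]]
      nb_lab <- resolved[nb]
      nb_lab <- nb_lab[!is.na(nb_lab)]
      if (!length(nb_lab)) next
      cand <- unique(nb_lab)
      d_flow <- abs(label_mean[as.character(cand)] - comp_mean[ci])
      best <- which(d_flow <= min(d_flow) + 1e-12)
      if (length(best) > 1) {
        best <- best[which.max(label_size[as.character(cand[best])])]
      }
      resolved[ci] <- cand[best]
      progress <- TRUE
    }
    if (!progress) {  # cannot happen on a connected grid, but stay safe
      resolved[is.na(resolved)] <- comp_label[is.na(resolved)]
    }
  }
  out <- matrix(resolved[as.vector(comp)], nrow(labels), ncol(labels))
  # dense relabel, preserving label order
  matrix(match(as.vector(out), sort(unique(as.vector(out)))),
         nrow(labels), ncol(labels))
}

labeling_stats <- function(labels, mean_map) {
  H <- nrow(labels)
  W <- ncol(labels)
  lab <- as.vector(labels)
  rr <- rep(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  sums <- rowsum(cbind(rr, cc, as.vector(mean_map), 1), lab)
  k <- as.integer(rownames(sums))
  tibble::tibble(
    label = k,
    row = sums[, 1] / sums[, 4],
    col = sums[, 2] / sums[, 4],
    mean_mbr = sums[, 3] / sums[, 4],
    size = as.integer(sums[, 4])
  )
}

#' Flow-driven SLIC superpixel segmentation
#'
#' Segments a temporal-mean MBR map into superpixels with a SLIC adaptation
#' in which the flow value takes the place of color.  Starting from
#' [initialize_centers()], each center claims pixels inside its
#' `2S x 2S` search window by the combined distance
#' \deqn{D = \sqrt{(d_{mbr}/compactness)^2 + (d_{xy}/S)^2},}
#' where `d_mbr` is the absolute flow difference normalized by the map's
#' interquartile range (falling back to the standard deviation, then to 1,
#' when degenerate) and `d_xy` the Euclidean pixel distance.  Assignments
#' and centroids are updated until no pixel changes cluster (or `max_iter`
#' is reached); a post-pass then makes every label 4-connected and absorbs
#' fragments below `min_size_frac * S^2` pixels.
#'
#' @param mean_map H x W numeric matrix of temporal-mean MBR values (finite,
#'   non-negative); see [temporal_mean_map()].  Constant maps are legal and
#'   yield a near-regular grid.
#' @param params A [slic_params()].
#' @return An `lsfg_labeling`: `labels` (H x W integer matrix, dense labels
#'   1..K covering every pixel), `centroids` (a tibble with per-label
#'   centroid, mean flow and size) and `n_labels`.
#' @examples
#' lab <- slic_segment(matrix(30, 56, 56), slic_params(S = 14))
#' lab$n_labels
#' @export
slic_segment <- function(mean_map, params = slic_params()) {
  stopifnot(is.matrix(mean_map))
  if (any(!is.finite(mean_map)) || any(mean_map < 0)) {
    stop("mean_map must be finite and non-negative", call. = FALSE)
  }
  H <- nrow(mean_map)
  W <- ncol(mean_map)
  S <- params$S
  # flow term scale: the map's interquartile range, floored at the median
  # flow level.  Contrasts are thereby measured against the larger of the
  # map's spread and its level: genuine structure (vessel/tissue contrasts,
  # tens of percent of the level) still dominates the spatial term at the
  # default compactness, while a structureless map — pure speckle around a
  # constant level, ~1% after temporal averaging — degrades gracefully to
  # spatial clustering instead of chasing noise.  The floor also covers
  # structured maps whose minority class is narrower than a quartile.
  scale <- max(stats::IQR(mean_map), median(mean_map))
  if (is.na(scale) || scale <= 0) scale <- 1
  v <- mean_map / scale
  centers <- initialize_centers(c(H, W), S)
  K <- nrow(centers)
  cr <- centers[, 1]
  cg <- centers[, 2]
  cv <- v[cbind(round(cr), round(cg))]
  inv_c2 <- 1 / params$compactness^2
  inv_s2 <- 1 / S^2
  labels <- matrix(0L, H, W)
  for (iter in seq_len(params$max_iter)) {
    best_d <- matrix(Inf, H, W)
    new_labels <- matrix(0L, H, W)
    for (k in seq_len(K)) {
      r0 <- max(1L, as.integer(round(cr[k])) - S)
      r1 <- min(H, as.integer(round(cr[k])) + S)
      c0 <- max(1L, as.integer(round(cg[k])) - S)
      c1 <- min(W, as.integer(round(cg[k])) + S)
      dr2 <- (seq(r0, r1) - cr[k])^2
      dc2 <- (seq(c0, c1) - cg[k])^2
      d <- (v[r0:r1, c0:c1, drop = FALSE] - cv[k])^2 * inv_c2 +
        outer(dr2, dc2, `+`) * inv_s2
      win_best <- best_d[r0:r1, c0:c1, drop = FALSE]
      upd <- d < win_best
      if (any(upd)) {
        win_best[upd] <- d[upd]
        best_d[r0:r1, c0:c1] <- win_best
        win_lab <- new_labels[r0:r1, c0:c1, drop = FALSE]
        win_lab[upd] <- k
        new_labels[r0:r1, c0:c1] <- win_lab
      }
    }
    if (any(new_labels == 0L)) {
      # a pixel outside every search window (cannot occur with the default
      # placement, but guard against exotic center drift)
      for (p in which(new_labels == 0L)) {
        pr <- (p - 1L) %% H + 1L
        pc <- (p - 1L) %/% H + 1L
        d <- (v[pr, pc] - cv)^2 * inv_c2 + ((pr - cr)^2 + (pc - cg)^2) * inv_s2
        new_labels[p] <- which.min(d)
      }
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    if (converged) break
    st <- labeling_stats(labels, v)
    cr[st$label] <- st$row
    cg[st$label] <- st$col
    cv[st$label] <- st$mean_mbr
  }
  labels <- enforce_connectivity(labels, params$min_size_frac * S^2,
                                 mean_map)
  centroids <- labeling_stats(labels, mean_map)
  structure(list(labels = labels, centroids = centroids,
                 n_labels = max(labels), params = params),
            class = "lsfg_labeling")
}

#' @export
print.lsfg_labeling <- function(x, ...) {
  cat(sprintf("<lsfg_labeling: %d superpixels over %d x %d (mean size %.1f)>\n",
              x$n_labels, nrow(x$labels), ncol(x$labels),
              length(x$labels) / x$n_labels))
  invisible(x)
}

# BOM of each row of an N x T value matrix sharing one time grid.  One
# spectrum engine serves all series; this is the fast path behind both map
# functions and the bias experiment.
bom_of_series_matrix <- function(Y, times, grid = spectrum_grid(),
                                 band = c(0.5, 3), C = 2,
                                 max_components = 10L, tol = 1e-10,
                                 refine = TRUE) {
  eng <- spectrum_engine(times, grid)
  in_band <- which(eng$freqs >= band[1] & eng$freqs <= band[2])
  if (!length(in_band)) {
    stop("band [", band[1], ", ", band[2], "] Hz contains no grid frequency",
         call. = FALSE)
  }
  n <- nrow(Y)
  mbr_avg <- unname(rowMeans(Y))
  if (any(mbr_avg <= 0)) stop("mean flow must be positive", call. = FALSE)
  bs <- peak <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_omp(eng, Y[i, ] - mbr_avg[i], max_components = max_components,
                   tol = tol, refine = refine)
    pa <- pb <- numeric(length(eng$freqs))
    if (length(fit$freq)) {
      bin <- vapply(fit$freq, function(f) which.min(abs(eng$freqs - f)), 1L)
      for (j in seq_along(bin)) {
        pa[bin[j]] <- pa[bin[j]] + fit$a[j]
        pb[bin[j]] <- pb[bin[j]] + fit$b[j]
      }
    }
    p <- sqrt(pa^2 + pb^2)
    jj <- which.max(p[in_band])
    bs[i] <- C * p[in_band][jj]
    peak[i] <- eng$freqs[in_band][jj]
  }
  tibble::tibble(mbr_avg = mbr_avg, bs = bs, peak_freq_hz = peak,
                 bom = bs / mbr_avg)
}

#' Superpixel BOM map
#'
#' Spatially averages the stack over each superpixel per frame, computes one
#' BOM per superpixel from the averaged series, and paints each pixel with
#' its superpixel's BOM.  Only K spectra are computed — the efficiency
#' mechanism that makes map generation clinically practical compared with
#' the pixel-wise map.
#'
#' @param seq An `lsfg_sequence`.
#' @param labeling An `lsfg_labeling` matching the stack's spatial shape, or
#'   `NULL` to segment the temporal-mean map with `params`.
#' @param params [slic_params()] used when `labeling` is `NULL`.
#' @inheritParams bom
#' @return An `lsfg_bom_map`: `map` (H x W BOM field), `per_label` (tibble
#'   with one waveform result per superpixel), and the `labeling`.
#' @export
superpixel_bom_map <- function(seq, labeling = NULL, params = slic_params(),
                               grid = spectrum_grid(), band = c(0.5, 3),
                               C = 2, max_components = 10L, tol = 1e-10,
                               refine = TRUE) {
  stopifnot(inherits(seq, "lsfg_sequence"))
  d <- dim(seq$values)
  if (is.null(labeling)) {
    labeling <- slic_segment(temporal_mean_map(seq), params)
  }
  stopifnot(inherits(labeling, "lsfg_labeling"))
  if (!all(dim(labeling$labels) == d[1:2])) {
    stop("labeling shape does not match the stack", call. = FALSE)
  }
  sizes <- tabulate(as.vector(labeling$labels), labeling$n_labels)
  if (any(sizes == 0)) stop("labeling contains an empty label", call. = FALSE)
  X <- matrix(seq$values, d[1] * d[2], d[3])
  sums <- rowsum(X, as.vector(labeling$labels))
  Y <- sums / sizes[as.integer(rownames(sums))]
  res <- bom_of_series_matrix(Y, seq$times, grid = grid, band = band, C = C,
                              max_components = max_components, tol = tol,
                              refine = refine)
  res <- dplyr::left_join(
    dplyr::bind_cols(tibble::tibble(label = as.integer(rownames(sums))), res),
    labeling$centroids[, c("label", "row", "col", "size")],
    by = "label")
  map <- matrix(res$bom[labeling$labels], d[1], d[2])
  structure(list(map = map, per_label = res, labeling = labeling,
                 band = band, C = C),
            class = "lsfg_bom_map")
}

#' @export
print.lsfg_bom_map <- function(x, ...) {
  cat(sprintf("<lsfg_bom_map: %d x %d, %d superpixels, BOM %.3g-%.3g>\n",
              nrow(x$map), ncol(x$map), nrow(x$per_label),
              min(x$map), max(x$map)))
  invisible(x)
}

#' Pixel-wise BOM map
#'
#' BOM of every pixel's own time series.  Exhaustive and slow by design —
#' it is the oracle the superpixel map is checked against (the two agree
#' exactly at `S = 1`) — so intended for small frames.
#'
#' @inheritParams superpixel_bom_map
#' @return H x W numeric matrix of per-pixel BOM values.
#' @export
pixelwise_bom_map <- function(seq, grid = spectrum_grid(), band = c(0.5, 3),
                              C = 2, max_components = 10L, tol = 1e-10,
                              refine = TRUE) {
  stopifnot(inherits(seq, "lsfg_sequence"))
  d <- dim(seq$values)
  Y <- matrix(seq$values, d[1] * d[2], d[3])
  res <- bom_of_series_matrix(Y, seq$times, grid = grid, band = band, C = C,
                              max_components = max_components, tol = tol,
                              refine = refine)
  matrix(res$bom, d[1], d[2])
}
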