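test_that("rectangle masks use half-open ranges with exact pixel counts", {
  m <- make_mask(rb_rect(c(11, 11), 200, 200), c(220, 220))
  expect_equal(m$pixel_count, 40000)
  expect_equal(make_mask(rb_rect(c(3, 5), 1, 1), c(10, 10))$pixel_count, 1)
  expect_error(make_mask(rb_rect(c(30, 1), 200, 200), c(220, 220)),
               "outside the frame")
})

test_that("ellipse masks match brute-force center inclusion", {
  shape <- c(120, 120)
  m <- make_mask(rb_ellipse(c(60, 60), c(50, 50)), shape)
  # independent double loop over the inclusion rule
  count <- 0L
  for (r in 1:120) for (c in 1:120) {
    if ((r - 60)^2 + (c - 60)^2 <= 50^2) count <- count + 1L
  }
  expect_equal(m$pixel_count, count)
  expect_lt(abs(m$pixel_count - pi * 50^2), 0.02 * pi * 50^2)
  expect_error(make_mask(rb_ellipse(c(10, 60), c(50, 50)), shape),
               "outside the frame")
})

test_that("roi time series is the per-frame mean over masked pixels", {
  vals <- array(0, c(2, 1, 2))
  vals[1, 1, ] <- c(1, 3)
  vals[2, 1, ] <- c(3, 5)
  sq <- structure(list(values = vals, times = c(0, 1), meta = list()),
                  class = "lsfg_sequence")
  s <- roi_time_series(sq, matrix(TRUE, 2, 1))
  expect_equal(s$y, c(2, 4))

  spec <- phantom_spec(5, 5, cardiac_freq_hz = 1.25,
                       regions = list(region_background(30, 0.2)))
  sq <- generate_sequence(spec)
  s <- roi_time_series(sq, matrix(TRUE, 5, 5))
  expect_equal(s$y, sq$values[1, 1, ])  # uniform stack: any pixel's series
  expect_error(roi_time_series(sq, matrix(FALSE, 5, 5)), "no pixel|empty")
})

test_that("spatial averaging reduces the trace variance by about n", {
  spec <- phantom_spec(40, 40, regions = list(region_background(30, 0)),
                       noise_shape = 50, seed = 21)
  sq <- generate_sequence(spec)
  v_pixel <- var(sq$values[1, 1, ])
  v_roi <- var(roi_time_series(sq, matrix(TRUE, 40, 40))$y)
  ratio <- v_roi / v_pixel
  expect_lt(ratio, 1 / 200)  # 1600 pixels: expect ~1/1600
})

test_that("histogram threshold separates vessels from tissue and matches
           the exhaustive Otsu oracle", {
  m <- matrix(10, 40, 40)
  m[, 18:22] <- 40
  onh <- make_mask(rb_ellipse(c(20, 20), c(15, 15)), c(40, 40))
  vt <- segment_vessels_tissue(m, onh)
  expect_gt(vt$threshold, 10)
  expect_lt(vt$threshold, 40)
  expect_identical(vt$vessel, onh$mask & (m == 40))
  expect_identical(vt$tissue, onh$mask & (m == 10))
  # partition invariant
  expect_true(all((vt$vessel | vt$tissue) == onh$mask))
  expect_false(any(vt$vessel & vt$tissue))
  # oracle agreement: both thresholds cut the same bimodal histogram
  oracle <- otsu_oracle(m[onh$mask])
  expect_identical(m[onh$mask] > vt$threshold, m[onh$mask] > oracle)
})

test_that("constant map inside the mask degrades to all-tissue", {
  onh <- make_mask(rb_ellipse(c(10, 10), c(6, 6)), c(20, 20))
  expect_warning(vt <- segment_vessels_tissue(matrix(5, 20, 20), onh),
                 "constant")
  expect_true(all(vt$tissue == onh$mask))
  expect_false(any(vt$vessel))
})

test_that("vessel delineation recovers the phantom geometry at low noise", {
  spec <- phantom_spec(120, 120, cardiac_freq_hz = 1.5, regions = list(
    region_background(25, 0.5, name = "tissue"),
    region_vessel(from = c(5, 60), to = c(115, 60), half_width = 7,
                  mean_mbr = 45, pulse_ratio = 0.7, name = "vessel")),
    noise_shape = 200, seed = 3)
  sq <- generate_sequence(spec)
  onh <- make_mask(rb_ellipse(c(60, 60), c(40, 40)), c(120, 120))
  vt <- segment_vessels_tissue(temporal_mean_map(sq), onh)
  gt <- region_masks(spec)$vessel & onh$mask
  jaccard <- sum(vt$vessel & gt) / sum(vt$vessel | gt)
  expect_gte(jaccard, 0.95)
})

test_that("uniform pulsatile stack gives equal regional BOMs for both
           methods", {
  spec <- phantom_spec(70, 70, cardiac_freq_hz = 1.5,
                       regions = list(region_background(30, 0.4)))
  sq <- generate_sequence(spec)
  onh <- rb_ellipse(c(35, 35), c(22, 22))
  chd <- rb_rect(c(4, 4), 20, 20)
  # constant mean map: degenerate threshold, vessel class dropped
  w_rb <- capture_warnings(rb <- region_boms(sq, onh, chd,
                                             method = "rubber_band"))
  w_sp <- capture_warnings(sp <- region_boms(sq, onh, chd,
                                             method = "superpixel"))
  expect_match(w_rb, "no pixels", all = FALSE)
  expect_match(w_sp, "no pixels", all = FALSE)
  for (df in list(rb, sp)) {
    expect_setequal(df$region, c("BOM.A", "BOM.T", "BOM.CHD"))
    expect_true(all(abs(df$bom - 0.4) / 0.4 < 0.01))
  }
})

test_that("vessels raise TCR above the surrounding-tissue BOM", {
  spec <- phantom_spec(84, 84, cardiac_freq_hz = 1.5, regions = list(
    region_background(25, 0.5, name = "tissue"),
    region_vessel(from = c(1, 42), to = c(84, 42), half_width = 8,
                  mean_mbr = 45, pulse_ratio = 0.7, name = "vessel")),
    noise_shape = 200, seed = 13)
  sq <- generate_sequence(spec)
  onh <- rb_ellipse(c(42, 42), c(28, 28))
  for (method in c("rubber_band", "superpixel")) {
    df <- region_boms(sq, onh_band = onh, method = method)
    expect_gt(df$bom[df$region == "TCR"],
              df$bom[df$region == "BOM.T"])
    # mixed-series BOM.A lies between the regional truths (common phase)
    expect_gt(df$bom[df$region == "BOM.A"], 0.5 * 0.99)
    expect_lt(df$bom[df$region == "BOM.A"], 0.7 * 1.01)
  }
})

test_that("one superpixel spanning the CHD band reproduces the rubber-band
           value exactly", {
  spec <- phantom_spec(24, 24, cardiac_freq_hz = 1.5,
                       regions = list(region_background(30, 0.3)),
                       noise_shape = 80, seed = 4)
  sq <- generate_sequence(spec)
  band <- rb_rect(c(5, 5), 12, 12)
  mask <- make_mask(band, c(24, 24))
  labels <- matrix(1L, 24, 24)
  labels[mask$mask] <- 2L
  labels <- matrix(as.integer(labels), 24, 24)
  labeling <- structure(list(
    labels = labels,
    centroids = lsfgbom:::labeling_stats(labels, temporal_mean_map(sq)),
    n_labels = 2L, params = slic_params()), class = "lsfg_labeling")
  sp <- superpixel_bom_map(sq, labeling = labeling)
  rb <- bom(roi_time_series(sq, mask))
  expect_equal(sp$per_label$bom[sp$per_label$label == 2], rb$bom,
               tolerance = 1e-9)
})
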