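test_that("initial centers follow the staggered placement rule", {
  expect_equal(nrow(initialize_centers(c(14, 14), 14)), 1)
  c28 <- initialize_centers(c(28, 28), 14)
  expect_equal(nrow(c28), 4)
  expect_equal(c28[c28[, "row"] == 8, "col"], c(8, 22))   # first row
  expect_equal(unname(c28[c28[, "row"] == 22, "col"][1]), 15)  # stagger 7
  expect_equal(nrow(initialize_centers(c(280, 280), 14)), 400)
  expect_error(initialize_centers(c(10, 30), 14), "at least S")
})

test_that("S = 1 yields the identity partition", {
  set.seed(5)
  m <- matrix(runif(64, 10, 40), 8, 8)
  lab <- slic_segment(m, slic_params(S = 1))
  expect_equal(lab$n_labels, 64)
  expect_equal(sort(unique(as.vector(lab$labels))), 1:64)
  expect_true(all(tabulate(lab$labels, 64) == 1))
})

test_that("uniform map segments into near-regular superpixels of size S^2", {
  lab <- slic_segment(matrix(30, 70, 70), slic_params(S = 14))
  expect_equal(lab$n_labels, 25)
  sizes <- lab$centroids$size
  expect_equal(mean(sizes), 196)
  expect_lt(abs(mean(sizes) / 196 - 1), 0.10)
})

test_that("a two-valued step aligned with the grid is never straddled", {
  m <- cbind(matrix(10, 56, 28), matrix(40, 56, 28))
  lab <- slic_segment(m, slic_params(S = 14))
  for (k in seq_len(lab$n_labels)) {
    vals <- unique(m[lab$labels == k])
    expect_length(vals, 1)
  }
  # boundary recall: every step-edge pixel pair is a label boundary
  expect_true(all(lab$labels[, 28] != lab$labels[, 29]))
})

test_that("labels partition every pixel and survive a connectivity audit", {
  set.seed(77)
  for (i in 1:5) {
    spec <- phantom_spec(48, 48, regions = list(
      region_background(30, 0.3),
      region_disk(center = runif(2, 15, 35), radius = runif(1, 5, 10),
                  mean_mbr = 55, pulse_ratio = 0.6, name = "d")),
      noise_shape = sample(c(50, 100, Inf), 1), seed = i)
    lab <- slic_segment(temporal_mean_map(generate_sequence(spec)),
                        slic_params(S = 8))
    v <- as.vector(lab$labels)
    expect_true(all(v >= 1))
    expect_equal(sort(unique(v)), seq_len(lab$n_labels))  # dense, no gaps
    expect_equal(sum(lab$centroids$size), 48 * 48)
    for (k in seq_len(lab$n_labels)) {
      expect_true(is_4_connected(lab$labels == k))
    }
  }
})

test_that("superpixel map at S = 1 equals the pixel-wise oracle", {
  spec <- phantom_spec(10, 10, cardiac_freq_hz = 1.5,
                       regions = list(region_background(30, 0.4)),
                       noise_shape = 100, seed = 9)
  sq <- generate_sequence(spec)
  lab1 <- slic_segment(temporal_mean_map(sq), slic_params(S = 1))
  sp <- superpixel_bom_map(sq, labeling = lab1)
  px <- pixelwise_bom_map(sq)
  expect_lt(max(abs(sp$map - px)), 1e-9)
  expect_equal(nrow(sp$per_label), 100)
})

test_that("noise-free two-region phantom recovers each region's BOM
           within 1% per superpixel", {
  spec <- phantom_spec(84, 84, cardiac_freq_hz = 1.5, regions = list(
    region_background(25, 0.5, name = "tissue"),
    region_vessel(from = c(1, 42), to = c(84, 42), half_width = 8,
                  mean_mbr = 45, pulse_ratio = 0.7, name = "vessel")))
  sq <- generate_sequence(spec)
  sp <- superpixel_bom_map(sq, params = slic_params(S = 14))
  expect_lt(nrow(sp$per_label), 84 * 84)  # far fewer spectra than pixels
  boms <- sp$per_label$bom
  near <- pmin(abs(boms - 0.5) / 0.5, abs(boms - 0.7) / 0.7)
  expect_true(all(near < 0.01))
})

test_that("pixel-wise map handles constant and uniform pulsatile stacks", {
  spec0 <- phantom_spec(6, 6, regions = list(region_background(30, 0)))
  expect_true(all(pixelwise_bom_map(generate_sequence(spec0)) == 0))
  spec <- phantom_spec(6, 6, cardiac_freq_hz = 1.5,
                       regions = list(region_background(30, 0.2)))
  pm <- pixelwise_bom_map(generate_sequence(spec))
  expect_true(all(abs(pm - 0.2) < 0.002))
})

test_that("slic parameter validation", {
  expect_error(slic_params(S = 0), "S must")
  expect_error(slic_params(compactness = 0), "compactness")
  expect_error(slic_params(max_iter = 0), "max_iter")
  expect_error(slic_segment(matrix(c(1, -1, 2, 3), 2, 2)), "non-negative")
})
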