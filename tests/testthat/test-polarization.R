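# Centroid polarization index and aspect-ratio gating.

square_mask <- function(grid, rows, cols) {
  m <- matrix(0L, grid, grid)
  m[rows, cols] <- 1L
  m
}

test_that("object_centroid: symmetry, single pixel, moment oracle", {
  img <- cell_image(square_mask(20, 10:12, 10:12))
  expect_equal(object_centroid(img), c(x = 11, y = 11))
  img1 <- cell_image(square_mask(10, 5, 7))
  expect_equal(object_centroid(img1), c(x = 7, y = 5))
  blob <- rand_rotated_ellipse(21)
  expect_equal(object_centroid(cell_image(blob)), oracle_centroid(blob),
               tolerance = 1e-12)
})

test_that("signal_centroid: uniform, point mass, and offset generator", {
  m <- square_mask(20, 8:14, 6:12)
  uni <- cell_image(m, list(ch = m * 7))
  expect_equal(signal_centroid(uni, "ch"), object_centroid(uni))
  pt <- matrix(0, 20, 20); pt[9, 11] <- 5
  img <- cell_image(m, list(ch = pt))
  expect_equal(signal_centroid(img, "ch"), c(x = 11, y = 9))
  # generator contract: offset recovered within 0.5 px (exact, noise-free)
  sim <- simulate_cell_image(image_sim_params(
    grid_size = 64, cell_axes = c(20, 14), pixel_size = 0.5,
    signal_offset = c(4, -2)))
  delta <- signal_centroid(sim, "signal") - object_centroid(sim)
  expect_equal(unname(delta), c(4, -2), tolerance = 0.5)
  # weighted centroid against the longhand oracle
  blob <- rand_rotated_ellipse(5)
  withr::with_seed(6, w <- matrix(runif(length(blob), 1, 3), nrow(blob)))
  expect_equal(signal_centroid(cell_image(blob, list(ch = w * blob)), "ch"),
               oracle_centroid(blob, w), tolerance = 1e-12)
  expect_error(signal_centroid(cell_image(m, list(ch = m * 0)), "ch"),
               "intensity")
})

test_that("polarization_index follows the coordinate-ratio formula", {
  expect_equal(polarization_index(c(50, 40), c(50, 40)), 0)
  expect_equal(polarization_index(c(100, 100), c(110, 90)), 0.01)
  expect_equal(polarization_index(c(100, 100), c(200, 100)), -1)
  # zero whenever centroids coincide, wherever the cell sits
  for (pos in list(c(3, 9), c(120, 40), c(55.5, 77.25))) {
    expect_equal(polarization_index(pos, pos), 0)
  }
  expect_error(polarization_index(c(0, 10), c(1, 1)), "zero coordinate")
})

test_that("centroid_displacement is the translation-invariant companion", {
  sim <- simulate_cell_image(image_sim_params(
    grid_size = 64, cell_axes = c(24, 20), pixel_size = 0.5,
    signal_offset = c(3, 4)))
  expect_equal(centroid_displacement(sim, "signal"), 5 * 0.5,
               tolerance = 1e-9)
})

test_that("aspect_ratio: circle, 2:1 and 4:1 ellipses, invariances", {
  disc <- simulate_cell_image(image_sim_params(
    grid_size = 128, cell_axes = c(44, 44), pixel_size = 1))
  expect_gte(aspect_ratio(disc), 0.95)
  e2 <- simulate_cell_image(image_sim_params(
    grid_size = 128, cell_axes = c(48, 24), pixel_size = 1))
  expect_lt(abs(aspect_ratio(e2) - 0.5), 0.02)
  e4 <- simulate_cell_image(image_sim_params(
    grid_size = 128, cell_axes = c(48, 12), pixel_size = 1))
  expect_lt(abs(aspect_ratio(e4) - 0.25), 0.02)
  # 90-degree rotation and uniform scaling leave the ratio unchanged
  rot <- cell_image(t(e2$mask))
  expect_lt(abs(aspect_ratio(rot) - aspect_ratio(e2)), 0.02)
  big <- simulate_cell_image(image_sim_params(
    grid_size = 256, cell_axes = c(96, 48), pixel_size = 1))
  expect_lt(abs(aspect_ratio(big) - aspect_ratio(e2)), 0.02)
  line <- matrix(0L, 10, 10); line[5, 2:9] <- 1L
  expect_error(aspect_ratio(cell_image(line)), "degenerate")
})

test_that("classification gates", {
  expect_equal(classify_polarization(c(0.4, 0.9, 0.6, 0.5, 0.8)),
               c("polarized", "unpolarized", "intermediate",
                 "intermediate", "intermediate"))
  expect_error(classify_polarization(1.2), "0, 1")
  expect_error(classify_polarization(0.5, low = 0.9, high = 0.8), "low")
})

test_that("percent_polarized sums to 100 and ignores out-of-focus cells", {
  rec <- data.frame(ar = c(0.3, 0.3, 0.9, 0.9),
                    classification = c("polarized", "polarized",
                                       "unpolarized", "unpolarized"),
                    in_focus = TRUE)
  expect_equal(percent_polarized(rec),
               c(polarized = 50, intermediate = 0, unpolarized = 50))
  all_pol <- data.frame(ar = 0.2, classification = "polarized",
                        in_focus = TRUE)
  expect_equal(percent_polarized(all_pol)[["polarized"]], 100)
  # permutation invariance and the sum-to-100 identity
  withr::with_seed(2, pop <- simulate_flow_population(500, 0.55, seed = 12))
  p1 <- percent_polarized(pop)
  p2 <- percent_polarized(pop[sample(nrow(pop)), ])
  expect_identical(p1, p2)
  expect_equal(sum(p1), 100)
  # out-of-focus records are excluded from the denominator
  rec$in_focus <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(percent_polarized(rec)[["polarized"]], 100)
})

test_that("simulated population recovers the generating fraction", {
  pop <- simulate_flow_population(10000, 0.4, seed = 99)
  expect_lt(abs(percent_polarized(pop)[["polarized"]] - 40), 2)
  # degenerate mixtures with tight class distributions classify perfectly
  tight <- list(polarized = c(60, 140), unpolarized = c(270, 30))
  ends <- simulate_flow_population(200, 1, ar_params = tight, seed = 1)
  expect_equal(percent_polarized(ends)[["polarized"]], 100)
  none <- simulate_flow_population(200, 0, ar_params = tight, seed = 1)
  expect_equal(percent_polarized(none)[["unpolarized"]], 100)
  expect_error(simulate_flow_population(100, 1.5), "frac_polarized")
})
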