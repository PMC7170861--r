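# Front-half biosensor ratio and relative time series.

uniform_frame <- function(mask, t = 0, dir = c(1, 0), value = 7) {
  biosensor_frame(cell_image(mask, list(ch = mask * value),
                             source_direction = dir), t)
}

test_that("front partition: sizes, symmetry, and the sort oracle", {
  disc <- simulate_cell_image(image_sim_params(
    grid_size = 64, cell_axes = c(20, 20), pixel_size = 1,
    source_direction = c(1, 0)))
  fp <- front_partition(disc)
  n_mask <- sum(disc$mask)
  expect_length(fp$front_area, ceiling(n_mask / 2))
  expect_length(fp$front_perimeter, ceiling(length(fp$perimeter) / 2))
  # front pixels sit at or beyond the centroid along +x (one tie layer)
  cx <- object_centroid(disc)[["x"]]
  xs <- arrayInd(fp$front_area, dim(disc$mask))[, 2]
  expect_gte(min(xs), floor(cx) - 1)
  # arbitrary blob and direction: equals the independent oracle
  blob <- rand_rotated_ellipse(17)
  dir <- unname(c(cos(0.7), sin(0.7)))
  img <- cell_image(blob, source_direction = dir)
  fpb <- front_partition(img)
  expect_equal(sort(fpb$front_area),
               oracle_front_half(blob, which(blob != 0), dir))
  per_idx <- which(perimeter_mask(blob))
  expect_equal(sort(fpb$front_perimeter),
               oracle_front_half(blob, per_idx, dir))
  expect_error(front_partition(cell_image(blob)), "source_direction")
})

test_that("uniform-intensity cells have ratio 1 for any shape/direction", {
  for (s in 1:10) {
    blob <- rand_rotated_ellipse(s)
    withr::with_seed(s, th <- runif(1, 0, 2 * pi))
    fr <- uniform_frame(blob, dir = c(cos(th), sin(th)))
    expect_equal(pip3_ratio(fr, "ch"), 1, tolerance = 1e-12)
  }
})

test_that("ratio recomputes from emitted pixels of an enriched cell", {
  img <- simulate_cell_image(image_sim_params(
    grid_size = 64, cell_axes = c(20, 14), pixel_size = 0.5,
    membrane_enrichment = 2, source_direction = c(1, 0)))
  fr <- biosensor_frame(img, 0)
  fp <- front_partition(img)
  ch <- img$channels$signal
  expect_equal(pip3_ratio(fr, "signal"),
               mean(ch[fp$front_perimeter]) / mean(ch[fp$front_area]),
               tolerance = 1e-12)
  # enrichment pushes the ratio above 1
  expect_gt(pip3_ratio(fr, "signal"), 1)
  # sum mode uses integrated intensity
  expect_equal(pip3_ratio(fr, "signal", mode = "sum"),
               sum(ch[fp$front_perimeter]) / sum(ch[fp$front_area]),
               tolerance = 1e-12)
})

test_that("interior-only intensity gives ratio 0", {
  m <- rand_rotated_ellipse(3)
  ch <- m * 5
  ch[perimeter_mask(m)] <- 0
  fr <- biosensor_frame(cell_image(m, list(ch = ch),
                                   source_direction = c(0, 1)), 0)
  expect_equal(pip3_ratio(fr, "ch"), 0)
})

test_that("ratio is invariant to intensity scaling and 90-deg rotation", {
  blob <- rand_rotated_ellipse(9)
  withr::with_seed(9, ch <- blob * matrix(runif(length(blob), 1, 4),
                                          nrow(blob)))
  dir <- c(1, 0)
  r1 <- pip3_ratio(cell_image(blob, list(ch = ch),
                              source_direction = dir), "ch")
  r_scaled <- pip3_ratio(cell_image(blob, list(ch = 13 * ch),
                                    source_direction = dir), "ch")
  expect_equal(r_scaled, r1, tolerance = 1e-12)
  # rotate image and source together: (x, y) -> (-y, x)
  rot_mask <- t(blob)[ncol(blob):1, ]
  rot_ch <- t(ch)[ncol(ch):1, ]
  r_rot <- pip3_ratio(cell_image(rot_mask, list(ch = rot_ch),
                                 source_direction = c(0, -1)), "ch")
  expect_equal(r_rot, r1, tolerance = 0.05)
})

test_that("relative series normalizes to the t=0 baseline", {
  m <- rand_rotated_ellipse(2)
  frames <- lapply(0:3, function(k) uniform_frame(m, t = 10 * k))
  rs <- relative_series(frames, "ch")
  expect_equal(rs$relative, rep(1, 4))
  # ramp series: per-frame ratios match the element-wise division oracle
  mk_ratio_frame <- function(target, t) {
    ch <- m * 1
    ch[perimeter_mask(m)] <- target
    biosensor_frame(cell_image(m, list(ch = ch),
                               source_direction = c(1, 0)), t)
  }
  fr2 <- Map(mk_ratio_frame, c(2, 3, 4), c(0, 10, 20))
  rs2 <- relative_series(fr2, "ch")
  expected <- vapply(fr2, pip3_ratio, numeric(1), channel = "ch")
  expect_equal(rs2$ratio, expected, tolerance = 1e-12)
  expect_equal(rs2$relative, expected / expected[1], tolerance = 1e-12)
  expect_equal(rs2$relative[1], 1)
  expect_error(relative_series(rev(fr2), "ch"), "increasing")
})

test_that("series from the enrichment-schedule generator is monotone", {
  sched <- c(1, 1.3, 1.8, 2.5, 3)
  frames <- simulate_biosensor_series(
    sched, params = image_sim_params(grid_size = 64, cell_axes = c(18, 12),
                                     pixel_size = 0.5,
                                     source_direction = c(1, 0)))
  rs <- relative_series(frames, "signal")
  expect_true(all(diff(rs$relative) > 0))
  expect_equal(rs$t, seq(0, 40, by = 10))
})

test_that("group_mean_series averages across cells per timepoint", {
  s1 <- data.frame(t = c(0, 10), ratio = c(1, 2), relative = c(1, 2))
  s2 <- data.frame(t = c(0, 10), ratio = c(1, 4), relative = c(1, 4))
  gm <- group_mean_series(list(s1, s2))
  expect_equal(gm$mean, c(1, 3))
  expect_equal(gm$sem, c(0, sd(c(2, 4)) / sqrt(2)))
  ident <- group_mean_series(list(s1, s1, s1))
  expect_equal(ident$sem, c(0, 0))
  # 20 seeded series vs a direct summary oracle
  series <- lapply(1:20, function(s) {
    withr::with_seed(s, data.frame(t = c(0, 10, 20), ratio = NA,
                                   relative = c(1, rexp(2) + 0.5)))
  })
  gm20 <- group_mean_series(series)
  vals <- sapply(series, `[[`, "relative")
  expect_equal(gm20$mean, rowMeans(vals), tolerance = 1e-12)
  expect_equal(gm20$sem, apply(vals, 1, sd) / sqrt(20), tolerance = 1e-12)
  bad <- data.frame(t = c(0, 5), ratio = NA, relative = c(1, 2))
  expect_error(group_mean_series(list(s1, bad)), "time grid")
})
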