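test_that("band-pass noise has the specified spectral content", {
  fs <- filter_spec()
  expect_equal(fs$bandwidth, 3 / (2 * 120))
  ## DC leakage far below the pass-band peak
  expect_lte(filter_amplitude(fs, 0), 0.1 * filter_amplitude(fs, fs$mu))

  tex <- bandpass_noise(c(96, 128), seed = 1)
  expect_equal(dim(tex), c(96, 128))
  expect_equal(mean(tex), 0, tolerance = 1e-12)
  expect_identical(bandpass_noise(c(64, 64), seed = 2),
                   bandpass_noise(c(64, 64), seed = 2))
  expect_error(bandpass_noise(c(32, 128)), "at least 64")

  ## radially averaged amplitude spectrum peaks at the spectral centre
  tex <- bandpass_noise(c(256, 256), seed = 3)
  am <- Mod(fft(tex))
  fx <- matrix(rep(c(0:(128), -(127:1)) / 256, each = 256), 256, 256)
  fy <- matrix(rep(c(0:(128), -(127:1)) / 256, times = 256), 256, 256)
  d <- sqrt(fx^2 + fy^2)
  bins <- cut(d, breaks = seq(0, 0.5, by = 0.008))
  prof <- tapply(am, bins, mean)
  peak_bin <- unname(which.max(prof))
  expect_lte(abs(0.008 * (peak_bin - 0.5) - 0.048), 0.008)
})

test_that("posterisation splits exactly at the median", {
  dark <- lab_color(40, 5, 10); light <- lab_color(55, 5, 10)
  for (s in 1:5) {
    tex <- bandpass_noise(c(128, 128), seed = s)
    post <- posterise(tex, dark, light)
    expect_equal(mean(post$patch_map$labels == 0), 0.5)
  }
  ## swapping the colours relabels without moving the boundary
  tex <- bandpass_noise(c(64, 64), seed = 9)
  a <- posterise(tex, dark, light)
  b <- posterise(tex, light, dark)
  expect_identical(a$patch_map$labels, b$patch_map$labels)
  expect_equal(a$lab[, , 1][a$patch_map$labels == 0],
               rep(40, sum(a$patch_map$labels == 0)))
  expect_equal(b$lab[, , 1][b$patch_map$labels == 0],
               rep(55, sum(b$patch_map$labels == 0)))

  expect_error(posterise(matrix(1, 10, 10), dark, light), "degenerate")
})

test_that("posterised patch breadth tracks the pass-band wavelength", {
  dark <- lab_color(40, 0, 0); light <- lab_color(55, 0, 0)
  b <- vapply(1:20, function(s) {
    tex <- bandpass_noise(c(128, 128), seed = s)
    patch_breadth(posterise(tex, dark, light)$patch_map$labels)
  }, numeric(1))
  expect_lte(abs(median(b) - 21), 6)
})

test_that("boundary distance matches the brute-force oracle", {
  ## 2x2 checkerboard: all pixels adjacent to the other class
  cb <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(boundary_distance(cb), matrix(0, 2, 2))

  ## half-split: distance increments by one per column
  hs <- half_split_patch_map(10, 10, 5)
  expect_equal(hs$dist[1, ], c(4, 3, 2, 1, 0, 0, 1, 2, 3, 4))

  ## label inversion leaves the distances untouched
  expect_equal(boundary_distance(1 - hs$labels), hs$dist)

  ## randomised small images against the all-pairs oracle
  set.seed(42)
  for (i in 1:25) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    labels <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
    if (length(unique(as.vector(labels))) < 2) next
    expect_equal(boundary_distance(labels),
                 brute_force_boundary_distance(labels))
  }

  expect_error(boundary_distance(matrix(1, 4, 4)), "both patch classes")
})

test_that("edge enhancement obeys the ramp laws in every variant", {
  dark <- lab_color(45, 4, 12); light <- lab_color(55, 6, 18)
  pm <- half_split_patch_map(40, 80, 40)
  is_light <- pm$labels == 1

  ## none: identity with the posterised image
  none <- apply_edge_enhancement(pm, dark, light, edge_profile("none"))
  expect_equal(unique(none[, , 1][is_light]), 55)
  expect_equal(unique(none[, , 1][!is_light]), 45)

  both <- apply_edge_enhancement(pm, dark, light,
                                 edge_profile("both", offset = 40,
                                              width = 16))
  ## boundary-adjacent light pixels carry the full offset; the ramp ends at
  ## the patch value for dist >= width, monotone in between
  expect_equal(unique(both[, , 1][is_light & pm$dist == 0]), 95)
  expect_equal(unique(both[, , 1][is_light & pm$dist >= 16]), 55)
  ramp <- both[1, 41:80, 1]
  expect_true(all(diff(ramp) <= 1e-12))
  expect_equal(both[1, 41 + 16, 1], 55)  # continuity: patch value at width
  ## dark side mirrors downwards
  expect_equal(unique(both[, , 1][!is_light & pm$dist == 0]), 5)
  expect_equal(unique(both[, , 1][!is_light & pm$dist >= 16]), 45)
  ## A and B keep the patch colour
  expect_equal(unique(both[, , 2][is_light]), 6)
  expect_equal(unique(both[, , 3][!is_light]), 12)
  ## never beyond patch L +/- offset
  expect_true(all(both[, , 1][is_light] <= 95 + 1e-12))
  expect_true(all(both[, , 1][!is_light] >= 5 - 1e-12))

  ## no_high: only the dark gradient; light patches untouched
  nh <- apply_edge_enhancement(pm, dark, light,
                               edge_profile("no_high", offset = 40,
                                            width = 16))
  expect_equal(unique(nh[, , 1][is_light]), 55)
  expect_equal(unique(nh[, , 1][!is_light & pm$dist == 0]), 5)

  ## no_low: only the light gradient; dark patches untouched
  nl <- apply_edge_enhancement(pm, dark, light,
                               edge_profile("no_low", offset = 40,
                                            width = 16))
  expect_equal(unique(nl[, , 1][!is_light]), 45)
  expect_equal(unique(nl[, , 1][is_light & pm$dist == 0]), 95)

  ## square: constant bands, no gradient
  sq <- apply_edge_enhancement(pm, dark, light,
                               edge_profile("square", offset = 40,
                                            width = 16))
  expect_equal(unique(sq[, , 1][is_light & pm$dist < 16]), 95)
  expect_equal(unique(sq[, , 1][is_light & pm$dist >= 16]), 55)
  expect_equal(unique(sq[, , 1][!is_light & pm$dist < 16]), 5)

  ## offset 0 is the identity for every variant
  for (v in c("both", "no_low", "no_high", "square")) {
    z <- apply_edge_enhancement(pm, dark, light,
                                edge_profile(v, offset = 0, width = 16))
    expect_equal(z[, , 1], none[, , 1])
  }

  ## clipping flags instead of failing
  bright <- lab_color(90, 0, 0)
  clip <- apply_edge_enhancement(pm, dark, bright,
                                 edge_profile("both", offset = 40,
                                              width = 16))
  expect_true(attr(clip, "gamut_clipped"))
  expect_lte(max(clip[, , 1]), 100)
})

test_that("snake targets have the requested extent and are connected", {
  m <- snake_mask(350, 0)
  cols_hit <- range(which(colSums(m) > 0))
  expect_lte(abs(diff(cols_hit) + 1 - 350), 1)
  ## vertical presentation
  mv <- snake_mask(350, pi / 2)
  rows_hit <- range(which(rowSums(mv) > 0))
  expect_lte(abs(diff(rows_hit) + 1 - 350), 1)
  ## single connected component
  lab <- EBImage::bwlabel(matrix(as.numeric(m), nrow(m), ncol(m)))
  expect_equal(max(lab), 1)

  pop <- filter_population(synth_forest_population(1000, seed = 1))
  t1 <- make_target(pop, prof = edge_profile("both", 40, 16), length = 120,
                    seed = 7)
  t2 <- make_target(pop, prof = edge_profile("both", 40, 16), length = 120,
                    seed = 7)
  expect_identical(t1$lab, t2$lab)
  expect_identical(t1$mask, t2$mask)
})

test_that("stimulus composition replaces exactly the masked pixels", {
  pop <- filter_population(synth_forest_population(1000, seed = 1))
  cv <- scene_canvas(400, 200)
  bg <- render_background(cv, 150, pop, seed = 2)
  tg <- make_target(pop, prof = edge_profile("both", 40, 16), length = 60,
                    orientation = 0.4, seed = 3)

  st <- compose_stimulus(bg, tg, cell = 6, seed = 4)
  diffmask <- apply(abs(st$canvas$pixels - bg$pixels), c(1, 2), sum) > 0
  expect_equal(sum(diffmask), sum(tg$mask))
  bb <- st$target_bbox
  expect_true(all(which(diffmask, arr.ind = TRUE)[, 1] >= bb["y0"]))
  expect_true(all(which(diffmask, arr.ind = TRUE)[, 2] <= bb["x1"]))

  ## seeded placements always land inside the requested cell
  for (s in 1:250) {
    cell <- sample(1:8, 1)
    st <- compose_stimulus(bg, tg, cell = cell, seed = s)
    b <- st$target_bbox
    cb <- edgecamo:::cell_bounds(bg, cell)
    expect_true(b["x0"] >= cb["x0"] && b["x1"] <= cb["x1"] &&
                  b["y0"] >= cb["y0"] && b["y1"] <= cb["y1"])
  }

  ## an oversized target cannot be placed
  big <- make_target(pop, prof = edge_profile("none"), length = 150,
                     seed = 5)
  expect_error(compose_stimulus(bg, big, cell = 1, seed = 1),
               "does not fit")

  ## central leaf-free band stays leaf-free
  cv2 <- scene_canvas(300, 400)
  keep <- c(120, 180, 80, 320)
  bg2 <- render_background(cv2, 400, pop, keepout = keep, seed = 6)
  painted <- attr(bg2, "painted")
  expect_equal(sum(painted[keep[3]:keep[4], keep[1]:keep[2]]), 0)
})
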