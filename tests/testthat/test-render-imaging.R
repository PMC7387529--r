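test_that("centre distance inverts the circle-circle chord relation", {
  # equal radii closed form: r0 = sqrt(R^2 - d^2/4)
  expect_equal(doublet_center_distance(60, 100, 100), 160, tolerance = 1e-8)
  expect_equal(doublet_center_distance(0, 70, 90), 160)   # tangent disks
  expect_equal(doublet_center_distance(100, 100, 100), 0) # full coalescence
  # unequal radii: verify the half-chord of the returned distance
  d <- doublet_center_distance(40, 60, 90)
  xa <- (d^2 + 60^2 - 90^2) / (2 * d)
  expect_equal(sqrt(60^2 - xa^2), 40, tolerance = 1e-8)
})

test_that("rendered doublet mask area matches the analytic union area", {
  for (geom in list(c(100, 100, 60), c(80, 60, 30))) {
    s <- neck_series(time_h = 1, neck_radius_um = geom[3],
                     radius_a_um = geom[1], radius_b_um = geom[2])
    fr <- render_fusion_frames(s, pixel_size = 1, image_shape = c(450, 450))
    d <- doublet_center_distance(geom[3], geom[1], geom[2])
    union_area <- pi * geom[1]^2 + pi * geom[2]^2 - lens_area(geom[1], geom[2], d)
    expect_equal(sum(fr[, , 1]), union_area, tolerance = 0.02)
  }
})

test_that("segmentation rejects blank frames and keeps the doublet", {
  expect_error(segment_doublet(matrix(0, 64, 64)), "no object found")
  s <- neck_series(time_h = 1, neck_radius_um = 30,
                   radius_a_um = 60, radius_b_um = 60)
  fr <- render_fusion_frames(s, pixel_size = 2, image_shape = c(150, 150))
  m <- segment_doublet(fr[, , 1], 2)
  expect_equal(m$n_components, 1)
  expect_equal(sum(m$mask), sum(fr[, , 1] > 0.5))
})

test_that("measured geometry matches the generating circles within a pixel", {
  s <- neck_series(time_h = 1, neck_radius_um = 60,
                   radius_a_um = 100, radius_b_um = 100)
  fr <- render_fusion_frames(s, pixel_size = 1, image_shape = c(450, 450))
  g <- measure_pair_geometry(segment_doublet(fr[, , 1], 1))
  expect_equal(g$neck_radius_um, 60, tolerance = 1 / 60)   # within 1 px
  expect_equal(g$radius_a_um, 100, tolerance = 1 / 100)
  expect_equal(g$radius_b_um, 100, tolerance = 1 / 100)
})

test_that("separated pairs give zero neck, fused single disks are undefined", {
  # two disjoint disks built directly
  img <- matrix(0, 200, 200)
  for (c0 in list(c(60, 100, 30), c(150, 100, 25))) {
    xs <- matrix(seq_len(200) - 0.5, 200, 200, byrow = TRUE)
    ys <- matrix(seq_len(200) - 0.5, 200, 200)
    img[(xs - c0[1])^2 + (ys - c0[2])^2 <= c0[3]^2] <- 1
  }
  m <- segment_doublet(img, 1)
  expect_equal(m$n_components, 2)
  g <- measure_pair_geometry(m)
  expect_equal(g$neck_radius_um, 0)
  expect_equal(g$status, "separated")
  expect_equal(sort(c(g$radius_a_um, g$radius_b_um)), c(25, 30),
               tolerance = 0.04)  # area-equivalent radii
  # fully fused: unimodal width profile
  s <- neck_series(time_h = 1, neck_radius_um = 80,
                   radius_a_um = 80, radius_b_um = 80)
  fr <- render_fusion_frames(s, pixel_size = 2, image_shape = c(120, 120))
  expect_error(measure_pair_geometry(segment_doublet(fr[, , 1], 2)),
               "neck undefined")
})

test_that("measurement is rotation-equivariant within a pixel", {
  set.seed(11)
  for (ang in runif(4, 0, pi)) {
    s <- neck_series(time_h = 1, neck_radius_um = 45,
                     radius_a_um = 90, radius_b_um = 70)
    fr <- render_fusion_frames(s, pixel_size = 2, image_shape = c(220, 220),
                               angle = ang)
    g <- measure_pair_geometry(segment_doublet(fr[, , 1], 2))
    expect_lt(abs(g$neck_radius_um - 45), 2)   # < 1 px at 2 um/px
  }
})

test_that("pixel-size scaling changes measured lengths by < 2%", {
  s <- neck_series(time_h = 1, neck_radius_um = 55,
                   radius_a_um = 95, radius_b_um = 85)
  g1 <- measure_pair_geometry(segment_doublet(
    render_fusion_frames(s, 1, c(420, 420))[, , 1], 1))
  g2 <- measure_pair_geometry(segment_doublet(
    render_fusion_frames(s, 2, c(210, 210))[, , 1], 2))
  expect_equal(g1$neck_radius_um, g2$neck_radius_um, tolerance = 0.02)
  expect_equal(g1$radius_a_um, g2$radius_a_um, tolerance = 0.02)
})

test_that("tracking a rendered stack round-trips the series", {
  s <- noiseless_series(tau = 10, R = 100)
  fr <- render_fusion_frames(s, pixel_size = 1, image_shape = c(512, 512))
  tr <- track_series(fr)
  expect_equal(nrow(tr), 9)
  ok <- !tr$missing
  expect_gte(sum(ok), 6)   # late frames are fully fused, flagged missing
  expect_lt(max(abs(tr$neck_radius_um[ok] - s$neck_radius_um[ok])), 1)
  expect_equal(attr(tr, "R0_um"), 100, tolerance = 0.01)
  # noiseless fusion is monotone; measurement preserves that within 1 px
  expect_true(all(diff(tr$neck_radius_um[ok]) > -1))
})

test_that("image stacks round-trip through multi-page TIFF", {
  s <- noiseless_series(tau = 10, R = 60, times = c(1, 2, 4))
  fr <- render_fusion_frames(s, pixel_size = 2, image_shape = c(128, 128))
  path <- withr::local_tempfile(fileext = ".tif")
  write_frames_tiff(fr, path)
  fr2 <- read_frames_tiff(path)
  expect_equal(dim(fr2), dim(fr))
  expect_equal(attr(fr2, "pixel_size"), 2)
  expect_lt(max(abs(fr2 - fr)), 0.01)   # 8-bit quantisation only
})
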