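fr <- image_frame(36857, 25808, microns_per_pixel = 0.65)

test_that("embedding constants follow from frame geometry", {
  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  expect_equal(emb$pixels_per_degree, 258080)
  expect_equal(emb$anchor, c(latitude_deg = 0, longitude_deg = 0))

  emb2 <- make_embedding(fr, pixels_per_degree = 1000)
  expect_equal(emb2$top_latitude_deg, 25.808)

  expect_equal(make_embedding(image_frame(1, 1),
                              top_latitude_deg = 1)$pixels_per_degree, 1)
})

test_that("embedding rejects out-of-domain parameters", {
  expect_error(make_embedding(fr, top_latitude_deg = 0), "positive")
  expect_error(make_embedding(fr, top_latitude_deg = 95), "90")
  expect_error(make_embedding(fr), "exactly one")
  expect_error(make_embedding(fr, top_latitude_deg = 0.1,
                              pixels_per_degree = 1000), "exactly one")
  expect_error(make_embedding(fr, pixels_per_degree = 100), "90")
  expect_error(image_frame(-1, 10), "positive")
})

test_that("embed_points maps corners as published and inverts exactly", {
  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  ll <- embed_points(emb, 0, 0)
  expect_equal(ll$latitude_deg, 0)
  expect_equal(ll$longitude_deg, 0)
  ur <- embed_points(emb, 36857, 25808)
  expect_equal(ur$latitude_deg, 0.1)
  expect_equal(ur$longitude_deg, 36857 / 258080)

  emb2 <- make_embedding(fr, pixels_per_degree = 1000)
  ur2 <- embed_points(emb2, 36857, 25808)
  expect_equal(ur2$latitude_deg, 25.808)
  expect_equal(ur2$longitude_deg, 36.857)

  # round trip on a grid of interior points
  set.seed(11)
  x <- runif(200, 0, fr$width_px)
  y <- runif(200, 0, fr$height_px)
  p <- embed_points(emb, x, y)
  back <- unembed_points(emb, p$longitude_deg, p$latitude_deg)
  expect_equal(back$x_px, x, tolerance = 1e-12)
  expect_true(max(abs(back$y_px - y)) < 1e-9)

  expect_error(embed_points(emb, 0, 90.1 * 258080), "90")
  expect_error(embed_points(emb, NaN, 1), "finite")
})

test_that("ew_scale_factor is secant latitude with the right shape", {
  expect_equal(ew_scale_factor(0), 1)
  expect_equal(ew_scale_factor(60), 2)
  expect_equal(ew_scale_factor(0.1), 1.000001523, tolerance = 1e-9)
  grid <- seq(-89, 89, by = 0.5)
  sf <- ew_scale_factor(grid)
  expect_true(all(sf >= 1))
  expect_identical(which(sf == 1), which(grid == 0))
  pos <- sf[grid >= 0]
  expect_true(all(diff(pos) > 0))   # strictly increasing in |latitude|
  expect_error(ew_scale_factor(90), "90")
})

test_that("max distortion is the top-edge width stretch, monotone in top latitude", {
  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  expect_equal(max_distortion_px(emb), 36857 * (ew_scale_factor(0.1) - 1))
  expect_lt(max_distortion_px(emb), 1)

  emb2 <- make_embedding(fr, pixels_per_degree = 1000)
  expect_equal(max_distortion_px(emb2),
               36857 * (1 / cospi(25.808 / 180) - 1))
  expect_gt(max_distortion_px(emb2), 0.10 * 36857)

  tops <- c(0.05, 0.1, 1, 5, 25, 60)
  d <- vapply(tops, function(t)
    max_distortion_px(make_embedding(fr, top_latitude_deg = t)), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("pixel/physical/earth conversions agree with the published table", {
  expect_equal(px_to_physical(25808, fr), 16775.2)
  expect_equal(physical_to_px(20, fr), 30.8, tolerance = 2e-3)
  expect_equal(px_to_physical(0, fr), 0)
  expect_equal(physical_to_px(px_to_physical(123.4, fr), fr), 123.4)

  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  expect_equal(px_to_earth_m(physical_to_px(20, fr), emb), 13.2,
               tolerance = 5e-3)
  expect_equal(px_to_earth_m(25808, emb), 11.1e3, tolerance = 2e-3)
  expect_equal(earth_m_to_px(px_to_earth_m(77, emb), emb), 77)
  expect_error(px_to_physical(-1, fr), "nonnegative")
  expect_error(px_to_earth_m(-1, emb), "nonnegative")
})

test_that("aspect ratio is preserved in the planar (low-latitude) limit", {
  emb <- make_embedding(fr, top_latitude_deg = 1e-4)
  expect_equal(px_to_earth_m(fr$width_px, emb) /
                 px_to_earth_m(fr$height_px, emb),
               fr$width_px / fr$height_px)
})

test_that("embedding config round-trips through the key-value file", {
  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  path <- tempfile(fileext = ".cfg")
  write_embedding_config(emb, path, flip_y = TRUE)
  back <- read_embedding_config(path)
  expect_equal(back$pixels_per_degree, emb$pixels_per_degree)
  expect_equal(back$top_latitude_deg, emb$top_latitude_deg)
  expect_equal(back$frame$microns_per_pixel, 0.65)
  expect_true(attr(back, "flip_y"))
  unlink(path)
})
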