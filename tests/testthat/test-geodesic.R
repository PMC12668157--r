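test_that("haversine distance matches closed forms and geosphere", {
  expect_equal(haversine_m(0, 0, 0, 0), 0)
  expect_equal(haversine_m(0, 0, 0.1, 0), 0.1 * pi * 6371000 / 180)
  expect_equal(haversine_m(0, 0, 0, 180), pi * 6371000)
  expect_equal(haversine_m(10, 20, 30, 40), haversine_m(30, 40, 10, 20))

  set.seed(7)
  lat1 <- runif(50, -80, 80); lon1 <- runif(50, -179, 179)
  lat2 <- runif(50, -80, 80); lon2 <- runif(50, -179, 179)
  expect_equal(haversine_m(lat1, lon1, lat2, lon2),
               geosphere::distHaversine(cbind(lon1, lat1),
                                        cbind(lon2, lat2), r = 6371000),
               tolerance = 1e-9)
})

test_that("pairs_within finds exactly the close pairs, deterministically ordered", {
  # equilateral triangle with ~10 m sides, radius 13.2 m
  s <- 10 / meters_per_degree()
  tri <- data.frame(cell_id = c("a", "b", "c"),
                    longitude_deg = c(0, s, s / 2),
                    latitude_deg = c(0, 0, s * sqrt(3) / 2))
  pr <- pairs_within(tri, 13.2)
  expect_equal(nrow(pr), 3L)
  expect_equal(pr$cell_id_a, c("a", "a", "b"))
  expect_equal(pr$cell_id_b, c("b", "c", "c"))
  expect_true(all(abs(pr$distance_m - 10) < 0.01))

  far <- data.frame(cell_id = 1:2, longitude_deg = c(0, 20 / meters_per_degree()),
                    latitude_deg = 0)
  expect_equal(nrow(pairs_within(far, 13.2)), 0L)
  # closed ball: a pair exactly at the radius is kept
  expect_equal(nrow(pairs_within(far, haversine_m(0, far$longitude_deg[1],
                                                  0, far$longitude_deg[2]))),
               1L)
  dup <- data.frame(cell_id = c("x", "x"), longitude_deg = 0, latitude_deg = 0)
  expect_error(pairs_within(dup, 1), "duplicate")
  expect_error(pairs_within(tri, -1), "positive")
})

test_that("pairs_within equals the all-pairs oracle on random instances", {
  for (seed in 1:10) {
    set.seed(seed)
    pts <- random_geopoints(sample(20:600, 1), extent_deg = 0.008)
    r <- runif(1, 5, 80)
    got <- pairs_within(pts, r)
    want <- oracle_pairs(pts, r)
    expect_identical(pair_keys(got), pair_keys(want))
  }
})

test_that("neighbor_counts tallies same-label pairings", {
  s <- 5 / meters_per_degree()
  tri <- data.frame(cell_id = c("t1", "t2", "t3", "o1"),
                    longitude_deg = c(0, s, 0, 4 * s),
                    latitude_deg = c(0, 0, s, 0))
  pr <- pairs_within(tri, 13.2)
  labels <- c(t1 = "Tumor", t2 = "Tumor", t3 = "Tumor", o1 = "Other")
  counts <- neighbor_counts(pr, labels, "Tumor")
  expect_equal(counts, c(t1 = 2L, t2 = 2L, t3 = 2L))

  # a tumor cell with only non-tumor neighbors reports 0
  labels2 <- c(t1 = "Tumor", t2 = "Other", t3 = "Other", o1 = "Tumor")
  counts2 <- neighbor_counts(pr, labels2, "Tumor")
  expect_equal(counts2[["t1"]], 0L)

  expect_error(neighbor_counts(pr, labels[-1], "Tumor"), "unlabeled")
})

test_that("a planted mutual blob of 11 tumor cells gives modal count 10", {
  set.seed(5)
  blob <- data.frame(cell_id = sprintf("t%02d", 1:11),
                     longitude_deg = rnorm(11, 0, 2e-6),
                     latitude_deg = rnorm(11, 0, 2e-6))
  pr <- pairs_within(blob, 13.2)
  labels <- setNames(rep("Tumor", 11), blob$cell_id)
  counts <- neighbor_counts(pr, labels, "Tumor")
  expect_equal(as.integer(names(which.max(table(counts)))), 10L)
  # count sum identity: sum over tumor cells = 2 x tumor-tumor pairs
  expect_equal(sum(counts), 2L * nrow(pr))
})

test_that("geo_dbscan recovers planted blobs and flags isolates as noise", {
  set.seed(13)
  pts <- planted_geo_blobs(n_blobs = 2, n_per_blob = 5,
                           spread_deg = 2e-6, sep_deg = 0.01)  # ~1.1 km apart
  cl <- geo_dbscan(pts, eps_m = 100, min_points = 3)
  expect_equal(length(unique(cl$cluster_id)), 2L)
  expect_false(anyNA(cl$cluster_id))
  # each planted blob maps to exactly one recovered cluster
  expect_equal(unname(vapply(split(cl$cluster_id, pts$blob),
                             function(x) length(unique(x)), integer(1))),
               c(1L, 1L))

  lone <- data.frame(cell_id = "z", longitude_deg = 0, latitude_deg = 0)
  expect_true(is.na(geo_dbscan(lone, 10, 2)$cluster_id))

  same <- data.frame(cell_id = sprintf("s%d", 1:6), longitude_deg = 0.001,
                     latitude_deg = 0.001)
  cl2 <- geo_dbscan(same, 1, 6)
  expect_equal(cl2$cluster_id, rep(1L, 6))

  expect_equal(nrow(geo_dbscan(data.frame(cell_id = character(0),
                                          longitude_deg = numeric(0),
                                          latitude_deg = numeric(0)),
                               10, 3)), 0L)
})

test_that("geo_dbscan is invariant to input order up to renumbering", {
  set.seed(21)
  pts <- planted_geo_blobs(3, 12, spread_deg = 5e-6, sep_deg = 0.004)
  pts <- rbind(pts, data.frame(longitude_deg = 0.02, latitude_deg = 0.02,
                               blob = NA, cell_id = "zzlone"))
  cl <- geo_dbscan(pts, eps_m = 30, min_points = 4)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- sample(nrow(pts))
    clp <- geo_dbscan(pts[perm, ], eps_m = 30, min_points = 4)
    m <- merge(cl, clp, by = "cell_id")
    expect_identical(m$cluster_id.x, m$cluster_id.y)  # ids renumbered canonically
    expect_identical(m$is_core.x, m$is_core.y)
  }
})

test_that("geo_dbscan agrees with planar DBSCAN at low latitude", {
  fr <- image_frame(36857, 25808)
  emb <- make_embedding(fr, top_latitude_deg = 0.1)
  set.seed(31)
  # planted pixel-space blobs well inside the frame
  xy <- do.call(rbind, lapply(1:3, function(b)
    cbind(rnorm(40, 8000 * b, 50), rnorm(40, 5000 * b, 50))))
  ids <- sprintf("q%03d", seq_len(nrow(xy)))
  pts <- cbind(data.frame(cell_id = ids), embed_points(emb, xy[, 1], xy[, 2]))
  eps_px <- 120
  geo <- geo_dbscan(pts, eps_m = px_to_earth_m(eps_px, emb), min_points = 5)
  planar <- oracle_planar_dbscan(xy, eps_px, 5)
  keep <- !is.na(planar) & !is.na(geo$cluster_id)
  expect_equal(mclust::adjustedRandIndex(geo$cluster_id[keep],
                                         planar[keep]), 1)
  expect_identical(is.na(geo$cluster_id), is.na(planar))
})
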