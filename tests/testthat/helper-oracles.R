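# Independent oracles used to cross-check the package implementations.
# Each deliberately takes a different route from the code under test.

# all-pairs geodesic within-radius oracle, distances via geosphere
oracle_pairs <- function(points, radius_m) {
  n <- nrow(points)
  if (n < 2L) {
    return(data.frame(cell_id_a = character(0), cell_id_b = character(0)))
  }
  j <- rep.int(seq_len(n), seq_len(n) - 1L)
  i <- sequence(seq_len(n) - 1L)
  d <- geosphere::distHaversine(
    cbind(points$longitude_deg[i], points$latitude_deg[i]),
    cbind(points$longitude_deg[j], points$latitude_deg[j]),
    r = 6371000)
  keep <- d <= radius_m
  i <- i[keep]; j <- j[keep]
  r <- rank(xtfrm(points$cell_id))
  swap <- r[i] > r[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  out <- data.frame(cell_id_a = points$cell_id[i],
                    cell_id_b = points$cell_id[j])
  out[order(r[i], r[j]), , drop = FALSE]
}

pair_keys <- function(pairs) {
  sort(paste(pairs$cell_id_a, pairs$cell_id_b, sep = "|"))
}

# brute-force planar DBSCAN (first-come border assignment); noise = NA
oracle_planar_dbscan <- function(xy, eps, min_pts) {
  d <- as.matrix(dist(xy))
  n <- nrow(xy)
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(nb) >= min_pts
  labels <- rep(0L, n)
  cl <- 0L
  for (s in seq_len(n)) {
    if (!core[s] || labels[s] != 0L) next
    cl <- cl + 1L
    queue <- s
    labels[s] <- cl
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels[labels == 0L] <- NA_integer_
  labels
}

# all-pairs sort kNN oracle via base dist()
oracle_knn_ids <- function(cells, k) {
  d <- as.matrix(dist(cbind(cells$x_centroid, cells$y_centroid)))
  diag(d) <- Inf
  tie <- rank(xtfrm(cells$cell_id))
  t(vapply(seq_len(nrow(cells)), function(i) {
    cells$cell_id[order(d[i, ], tie)[seq_len(k)]]
  }, cells$cell_id[seq_len(k)]))
}

# straight-line two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
}

# uniform random geo-point cloud near the equator
random_geopoints <- function(n, extent_deg = 0.01) {
  data.frame(cell_id = sprintf("c%05d", seq_len(n)),
             longitude_deg = runif(n, 0, extent_deg),
             latitude_deg = runif(n, 0, extent_deg))
}

# well-separated geodesic blobs; returns points + true blob membership
planted_geo_blobs <- function(n_blobs, n_per_blob, spread_deg = 2e-6,
                              sep_deg = 0.002) {
  pts <- do.call(rbind, lapply(seq_len(n_blobs), function(b) {
    data.frame(longitude_deg = rnorm(n_per_blob, b * sep_deg, spread_deg),
               latitude_deg = rnorm(n_per_blob, b * sep_deg, spread_deg),
               blob = b)
  }))
  pts$cell_id <- sprintf("b%04d", seq_len(nrow(pts)))
  pts
}
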