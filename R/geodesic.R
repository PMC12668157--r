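#' Great-circle distance between geographic points
#'
#' Haversine distance on the reference sphere (radius 6,371,000 m), the
#' geodesic metric underlying all within-radius and clustering operations.
#' Symmetric, zero only for identical points, and numerically stable for
#' the sub-kilometre separations typical of embedded cell centroids.
#'
#' @param lat1,lon1,lat2,lon2 Latitudes and longitudes in degrees,
#'   recycled to a common length.
#' @return Distance(s) in metres.
#' @export
#' @examples
#' haversine_m(0, 0, 0.1, 0)   # one tenth of a degree of arc: 11,119.5 m
haversine_m <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  lat1 <- rep_len(lat1, n); lon1 <- rep_len(lon1, n)
  lat2 <- rep_len(lat2, n); lon2 <- rep_len(lon2, n)
  if (any(abs(c(lat1, lat2)) > 90)) {
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  }
  sdlat <- sinpi((lat2 - lat1) / 360)
  sdlon <- sinpi((lon2 - lon1) / 360)
  a <- sdlat * sdlat +
    cospi(lat1 / 180) * cospi(lat2 / 180) * sdlon * sdlon
  2 * .EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# validate a geo-point table: cell_id + longitude_deg/latitude_deg
.check_geopoints <- function(points) {
  need <- c("cell_id", "longitude_deg", "latitude_deg")
  miss <- setdiff(need, names(points))
  if (length(miss)) {
    stop("`points` must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(points$cell_id)) {
    stop("duplicate cell_id values in `points`", call. = FALSE)
  }
  invisible(points)
}

# upper-triangle index pairs of 1..m (i < j)
.all_pairs_idx <- function(m) {
  if (m < 2L) return(cbind(a = integer(0), b = integer(0)))
  j <- rep.int(seq_len(m), seq_len(m) - 1L)
  i <- sequence(seq_len(m) - 1L)
  cbind(a = i, b = j)
}

#' Enumerate all point pairs within a geodesic radius
#'
#' Finds every unordered pair of cells whose great-circle distance is at
#' most `radius_m` (closed ball: the conventional inclusive DWithin
#' predicate). A latitude/longitude grid with bucket size equal to the
#' radius (longitude buckets widened by the secant of the extreme
#' latitude) restricts distance evaluation to neighboring buckets, so
#' cost scales with the number of true near pairs rather than n^2.
#'
#' @param points A data.frame with columns `cell_id` (unique),
#'   `longitude_deg`, `latitude_deg` — e.g. `cbind(cells["cell_id"],
#'   embed_points(...))`.
#' @param radius_m Pairing radius in metres (> 0).
#' @return A data.frame with columns `cell_id_a`, `cell_id_b`,
#'   `distance_m`, one row per unordered pair, with `cell_id_a <
#'   cell_id_b` under the natural ordering of the id type and rows sorted
#'   by (`cell_id_a`, `cell_id_b`).
#' @export
#' @examples
#' pts <- data.frame(cell_id = 1:3, longitude_deg = c(0, 0, 1e-4),
#'                   latitude_deg = c(0, 1e-4, 0))
#' pairs_within(pts, radius_m = 15)
pairs_within <- function(points, radius_m) {
  .check_geopoints(points)
  .check_pos(radius_m, "radius_m")
  n <- nrow(points)
  empty <- data.frame(cell_id_a = points$cell_id[0],
                      cell_id_b = points$cell_id[0],
                      distance_m = numeric(0))
  if (n < 2L) return(empty)
  lat <- points$latitude_deg
  lon <- points$longitude_deg

  dlat <- radius_m / .METERS_PER_DEGREE
  maxlat <- min(89.99, max(abs(lat)) + dlat)
  dlon <- dlat / cospi(maxlat / 180)
  gi <- floor(lat / dlat)
  gj <- floor(lon / dlon)
  key <- paste(gi, gj, sep = ",")
  buckets <- split(seq_len(n), key)
  bi <- vapply(buckets, function(ix) gi[ix[1L]], numeric(1))
  bj <- vapply(buckets, function(ix) gj[ix[1L]], numeric(1))

  # neighbor-bucket offsets covering each adjacent bucket pair exactly once
  offs <- rbind(c(1, -1), c(1, 0), c(1, 1), c(0, 1))
  pa <- vector("list", length(buckets) * 5L)
  pb <- pa
  k <- 0L
  for (b in seq_along(buckets)) {
    ia <- buckets[[b]]
    if (length(ia) > 1L) {
      pr <- .all_pairs_idx(length(ia))
      k <- k + 1L
      pa[[k]] <- ia[pr[, "a"]]
      pb[[k]] <- ia[pr[, "b"]]
    }
    for (o in seq_len(nrow(offs))) {
      nb <- buckets[[paste(bi[b] + offs[o, 1L], bj[b] + offs[o, 2L],
                           sep = ",")]]
      if (!is.null(nb)) {
        k <- k + 1L
        pa[[k]] <- rep(ia, times = length(nb))
        pb[[k]] <- rep(nb, each = length(ia))
      }
    }
  }
  if (k == 0L) return(empty)
  a <- unlist(pa[seq_len(k)], use.names = FALSE)
  b <- unlist(pb[seq_len(k)], use.names = FALSE)
  d <- haversine_m(lat[a], lon[a], lat[b], lon[b])
  keep <- d <= radius_m
  a <- a[keep]; b <- b[keep]; d <- d[keep]
  if (!length(a)) return(empty)

  # orient each pair so id_a precedes id_b in the ids' natural ordering
  r <- rank(xtfrm(points$cell_id))
  swap <- r[a] > r[b]
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(cell_id_a = points$cell_id[a],
                    cell_id_b = points$cell_id[b],
                    distance_m = d)
  out[order(r[a], r[b]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Count same-label neighbors per cell
#'
#' Given a within-radius pair table and per-cell phenotype labels, counts
#' for each cell carrying `target_label` how many of its paired cells also
#' carry that label — e.g. for each tumor cell, the number of neighboring
#' tumor cells, a local-density readout. Target-label cells with no such
#' neighbor report 0.
#'
#' @param pairs A pair table from [pairs_within()].
#' @param labels Named character vector mapping `cell_id` to phenotype
#'   label (every id appearing in `pairs` must be present).
#' @param target_label The phenotype to count (e.g. `"Tumor"`).
#' @return A named integer vector over all cells labeled `target_label`.
#' @export
neighbor_counts <- function(pairs, labels, target_label) {
  ids <- unique(c(as.character(pairs$cell_id_a),
                  as.character(pairs$cell_id_b)))
  missing <- setdiff(ids, names(labels))
  if (length(missing)) {
    stop("unlabeled cell id(s) in pair table: ",
         paste(head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...", call. = FALSE)
  }
  target <- names(labels)[labels == target_label]
  counts <- setNames(integer(length(target)), target)
  la <- labels[as.character(pairs$cell_id_a)]
  lb <- labels[as.character(pairs$cell_id_b)]
  both <- la == target_label & lb == target_label
  if (any(both)) {
    tab <- table(c(as.character(pairs$cell_id_a)[both],
                   as.character(pairs$cell_id_b)[both]))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Density-based spatial clustering with geodesic distance (DBSCAN)
#'
#' DBSCAN over embedded cell points using great-circle distance: a point
#' is a core point iff at least `min_points` points (counting itself) lie
#' within `eps_m`; clusters are the connected components of core points
#' within `eps_m` of each other, plus border points within `eps_m` of a
#' core point; everything else is noise.
#'
#' Determinism: cluster ids are renumbered 1..K by the smallest member id,
#' and a border point reachable from several clusters joins the cluster of
#' its lowest-ordered core neighbor.
#'
#' @param points A geo-point table as for [pairs_within()]; may be empty.
#' @param eps_m Neighborhood radius in metres (> 0); the closed ball
#'   (`<= eps_m`) is used, as in [pairs_within()].
#' @param min_points Minimum neighborhood size (self-inclusive) for a core
#'   point; >= 1.
#' @return A data.frame with one row per input cell: `cell_id`,
#'   `cluster_id` (integer 1..K, `NA` for noise) and `is_core`.
#' @export
geo_dbscan <- function(points, eps_m, min_points) {
  if (NROW(points) == 0L) {
    return(data.frame(cell_id = character(0), cluster_id = integer(0),
                      is_core = logical(0)))
  }
  .check_geopoints(points)
  .check_pos(eps_m, "eps_m")
  if (!is.numeric(min_points) || length(min_points) != 1L || min_points < 1) {
    stop("`min_points` must be a single number >= 1", call. = FALSE)
  }
  n <- nrow(points)
  r <- rank(xtfrm(points$cell_id))
  pr <- pairs_within(points, eps_m)
  ia <- match(pr$cell_id_a, points$cell_id)
  ib <- match(pr$cell_id_b, points$cell_id)

  deg <- tabulate(c(ia, ib), nbins = n)
  core <- (deg + 1L) >= min_points

  # clusters: connected components of the core-core eps graph
  cluster <- rep(NA_integer_, n)
  if (any(core)) {
    cc <- core[ia] & core[ib]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ia[cc]), to = as.character(ib[cc])),
      directed = FALSE,
      vertices = data.frame(name = as.character(which(core))))
    memb <- igraph::components(g)$membership
    vidx <- as.integer(names(memb))
    cluster[vidx] <- as.integer(memb)

    # border points adopt their lowest-ordered core neighbor's cluster
    is_border_a <- !core[ia] & core[ib]
    is_border_b <- !core[ib] & core[ia]
    bp <- c(ia[is_border_a], ib[is_border_b])
    bc <- c(ib[is_border_a], ia[is_border_b])
    if (length(bp)) {
      o <- order(bp, r[bc])
      first <- !duplicated(bp[o])
      cluster[bp[o][first]] <- cluster[bc[o][first]]
    }

    # renumber clusters 1..K by smallest member id
    assigned <- which(!is.na(cluster))
    lead <- vapply(split(r[assigned], cluster[assigned]), min, numeric(1))
    remap <- setNames(rank(lead), names(lead))
    cluster[assigned] <- as.integer(remap[as.character(cluster[assigned])])
  }
  data.frame(cell_id = points$cell_id, cluster_id = cluster,
             is_core = core)
}
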