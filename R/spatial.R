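#' Cell centroids from a labeled pixel set
#'
#' The centroid of a segmented object is the arithmetic mean of its member
#' pixel coordinates; this computes it per object label from a
#' long-format labeled pixel table.
#'
#' @param labeled_pixels data.frame with columns `x_px`, `y_px`,
#'   `object_label`.
#' @return data.frame with one row per label: `object_label`, `x_px`,
#'   `y_px` (mean coordinates), sorted by label.
#' @export
centroids_from_labels <- function(labeled_pixels) {
  need <- c("x_px", "y_px", "object_label")
  miss <- setdiff(need, names(labeled_pixels))
  if (length(miss)) {
    stop("`labeled_pixels` is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(labeled_pixels) == 0L) {
    return(data.frame(object_label = character(0), x_px = numeric(0),
                      y_px = numeric(0)))
  }
  sp <- split(seq_len(nrow(labeled_pixels)), labeled_pixels$object_label)
  out <- data.frame(
    object_label = names(sp),
    x_px = vapply(sp, function(i) mean(labeled_pixels$x_px[i]), numeric(1)),
    y_px = vapply(sp, function(i) mean(labeled_pixels$y_px[i]), numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' k nearest neighbors in pixel space
#'
#' Euclidean k-nearest-neighbor search over cell centroids, self
#' excluded. Equal-distance ties are broken by ascending cell id so
#' results are order-invariant.
#'
#' @param cells Cell table with `cell_id`, `x_centroid`, `y_centroid`.
#' @param k Number of neighbors, `1 <= k < nrow(cells)`.
#' @return An object of class `knn_result`: a list with `cell_id` (length
#'   n), `neighbor_ids` (n x k matrix, nearest first) and
#'   `neighbor_distances_px` (n x k matrix, nondecreasing per row).
#' @export
knn <- function(cells, k) {
  .check_cells(cells)
  n <- nrow(cells)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k >= n) {
    stop(sprintf("`k` must satisfy 1 <= k < n cells (n = %d)", n),
         call. = FALSE)
  }
  k <- as.integer(k)
  x <- cells$x_centroid
  y <- cells$y_centroid
  tie <- rank(xtfrm(cells$cell_id))
  nid <- matrix(cells$cell_id[1L], n, k)
  nd <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    d2[i] <- Inf
    ord <- order(d2, tie)[seq_len(k)]
    nid[i, ] <- cells$cell_id[ord]
    nd[i, ] <- sqrt(d2[ord])
  }
  structure(list(cell_id = cells$cell_id, neighbor_ids = nid,
                 neighbor_distances_px = nd, k = k),
            class = "knn_result")
}

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf("<knn_result> %d cells, k = %d neighbors (px distances)\n",
              length(x$cell_id), x$k))
  invisible(x)
}

#' Mean marker intensity over each cell's k-NN neighborhood
#'
#' For every cell, the arithmetic mean of `marker` over its k nearest
#' neighbors (self excluded), the local-context value used by the k-NN
#' spatial correlation.
#'
#' @param cells Cell table containing `marker`.
#' @param knn_res A [knn()] result computed on the same cells.
#' @param marker Marker column name.
#' @return Named numeric vector mapping `cell_id` to neighborhood mean.
#' @export
neighborhood_mean <- function(cells, knn_res, marker) {
  stopifnot(inherits(knn_res, "knn_result"))
  .check_cells(cells)
  if (!marker %in% names(cells)) {
    stop(sprintf("marker column '%s' is missing from the cell table",
                 marker), call. = FALSE)
  }
  v <- setNames(cells[[marker]], as.character(cells$cell_id))
  m <- matrix(v[as.character(knn_res$neighbor_ids)],
              nrow = length(knn_res$cell_id))
  setNames(rowMeans(m), as.character(knn_res$cell_id))
}

#' k-NN spatial correlation between two markers
#'
#' The Pearson correlation, across cells, between each cell's `marker_a`
#' intensity and the mean `marker_b` intensity of its k nearest
#' neighbors. With A = B = a tumor marker (e.g. keratin) this measures
#' how strongly marker-high cells sit in marker-high neighborhoods — high
#' values indicate spatial clustering of the marker-positive population;
#' under random spatial assignment of intensities it is near zero.
#'
#' @param cells Cell table containing both markers; at least 3 cells.
#' @param marker_a,marker_b Marker column names (may be equal).
#' @param k Neighborhood size, `k < nrow(cells)`.
#' @return A single correlation coefficient in `[-1, 1]`.
#' @export
spatial_correlation <- function(cells, marker_a, marker_b, k) {
  .check_cells(cells)
  if (nrow(cells) < 3L) {
    stop("need at least 3 cells for a spatial correlation", call. = FALSE)
  }
  for (m in unique(c(marker_a, marker_b))) {
    if (!m %in% names(cells)) {
      stop(sprintf("marker column '%s' is missing from the cell table", m),
           call. = FALSE)
    }
  }
  kr <- knn(cells, k)
  va <- cells[[marker_a]]
  nb <- unname(neighborhood_mean(cells, kr, marker_b))
  if (stats::sd(va) == 0 || stats::sd(nb) == 0) {
    stop("spatial correlation is undefined: zero variance in ",
         if (stats::sd(va) == 0) sprintf("'%s'", marker_a)
         else sprintf("the %d-NN mean of '%s'", as.integer(k), marker_b),
         call. = FALSE)
  }
  stats::cor(va, nb)
}
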