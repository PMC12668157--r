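#' Describe a whole-slide image frame
#'
#' An `image_frame` records the pixel extent of one whole-slide multiplexed
#' image and its physical pixel pitch. Cell centroids from segmentation
#' tables live in this frame, with the origin at the lower-left corner and
#' y increasing upward (tables using the top-left imaging convention can be
#' flipped on read; see [read_cell_table()]).
#'
#' @param width_px Image width in pixels (> 0).
#' @param height_px Image height in pixels (> 0).
#' @param microns_per_pixel Physical pixel pitch, micrometres per pixel
#'   (> 0). The melanoma whole-slide images this mirrors use 0.65 um/px.
#' @return An object of class `image_frame`.
#' @export
#' @examples
#' image_frame(36857, 25808, microns_per_pixel = 0.65)
image_frame <- function(width_px, height_px, microns_per_pixel = 0.65) {
  .check_pos(width_px, "width_px")
  .check_pos(height_px, "height_px")
  .check_pos(microns_per_pixel, "microns_per_pixel")
  structure(
    list(width_px = width_px, height_px = height_px,
         microns_per_pixel = microns_per_pixel),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %g x %g px at %g um/px (%.1f x %.1f um)\n",
              x$width_px, x$height_px, x$microns_per_pixel,
              x$width_px * x$microns_per_pixel,
              x$height_px * x$microns_per_pixel))
  invisible(x)
}

#' Build a pixel-to-geographic embedding for an image frame
#'
#' Defines the linear mapping from pixel coordinates to geographic degrees:
#' the lower-left corner of the image is anchored at (0 deg N, 0 deg E) and
#' both axes are scaled isotropically by one `pixels_per_degree` factor, so
#' longitude = x / pixels_per_degree and latitude = y / pixels_per_degree.
#' The factor is fixed either by choosing the latitude of the top edge
#' (`top_latitude_deg`, giving `pixels_per_degree = height_px /
#' top_latitude_deg`) or directly via `pixels_per_degree`.
#'
#' Keeping the image close to the equator keeps the east-west metric
#' distortion from Earth curvature small; see [ew_scale_factor()] and
#' [max_distortion_px()]. A 25,808-px-high image topped at 0.1 deg N gives
#' the scaling of 1/258,080 degrees per pixel.
#'
#' @param frame An [image_frame()].
#' @param top_latitude_deg Latitude (degrees N, in (0, 90)) at which the top
#'   edge of the image should sit. Exactly one of `top_latitude_deg` and
#'   `pixels_per_degree` must be given.
#' @param pixels_per_degree Pixels per angular degree (> 0); the implied top
#'   latitude `height_px / pixels_per_degree` must lie in (0, 90).
#' @return An object of class `geo_embedding` with fields
#'   `pixels_per_degree`, `anchor` (lat 0, lon 0), `meters_per_degree`,
#'   `top_latitude_deg` and the `frame`.
#' @export
#' @examples
#' fr <- image_frame(36857, 25808)
#' make_embedding(fr, top_latitude_deg = 0.1)      # 258,080 px per degree
#' make_embedding(fr, pixels_per_degree = 1000)    # top edge at 25.808 N
make_embedding <- function(frame, top_latitude_deg = NULL,
                           pixels_per_degree = NULL) {
  stopifnot(inherits(frame, "image_frame"))
  if (is.null(top_latitude_deg) == is.null(pixels_per_degree)) {
    stop("give exactly one of `top_latitude_deg` or `pixels_per_degree`",
         call. = FALSE)
  }
  if (is.null(pixels_per_degree)) {
    .check_pos(top_latitude_deg, "top_latitude_deg")
    if (top_latitude_deg >= 90) {
      stop("`top_latitude_deg` must be below 90 degrees", call. = FALSE)
    }
    pixels_per_degree <- frame$height_px / top_latitude_deg
  } else {
    .check_pos(pixels_per_degree, "pixels_per_degree")
    top_latitude_deg <- frame$height_px / pixels_per_degree
    if (top_latitude_deg >= 90) {
      stop("implied top latitude is at or above 90 degrees; increase ",
           "`pixels_per_degree`", call. = FALSE)
    }
  }
  structure(
    list(pixels_per_degree = pixels_per_degree,
         anchor = c(latitude_deg = 0, longitude_deg = 0),
         meters_per_degree = .METERS_PER_DEGREE,
         top_latitude_deg = top_latitude_deg,
         frame = frame),
    class = "geo_embedding"
  )
}

#' @export
print.geo_embedding <- function(x, ...) {
  cat(sprintf(paste0(
    "<geo_embedding> %g px per degree, anchor (0N, 0E)\n",
    "  top edge at %.6g N; %.6g m per degree (spherical Earth)\n"),
    x$pixels_per_degree, x$top_latitude_deg, x$meters_per_degree))
  invisible(x)
}

#' Embed pixel centroids as geographic points
#'
#' Scales pixel coordinates to angular degrees: longitude = x /
#' pixels_per_degree, latitude = y / pixels_per_degree, anchored at the
#' lower-left corner (0 N, 0 E). `unembed_points()` inverts the mapping.
#'
#' @param embedding A [make_embedding()] result.
#' @param x_px,y_px Numeric vectors of pixel coordinates (finite, recycled
#'   to a common length).
#' @return `embed_points()`: a data.frame with columns `longitude_deg`,
#'   `latitude_deg`. `unembed_points()`: a data.frame with `x_px`, `y_px`.
#' @export
#' @examples
#' emb <- make_embedding(image_frame(36857, 25808), top_latitude_deg = 0.1)
#' embed_points(emb, 36857, 25808)   # upper-right corner: 0.1 N, 0.1428 E
embed_points <- function(embedding, x_px, y_px) {
  stopifnot(inherits(embedding, "geo_embedding"))
  n <- max(length(x_px), length(y_px))
  x_px <- rep_len(as.numeric(x_px), n)
  y_px <- rep_len(as.numeric(y_px), n)
  if (!all(is.finite(x_px)) || !all(is.finite(y_px))) {
    stop("pixel coordinates must be finite", call. = FALSE)
  }
  lat <- y_px / embedding$pixels_per_degree
  lon <- x_px / embedding$pixels_per_degree
  if (any(abs(lat) >= 90)) {
    stop("embedded latitude reaches or exceeds 90 degrees; the embedding ",
         "does not cover these points", call. = FALSE)
  }
  data.frame(longitude_deg = lon, latitude_deg = lat)
}

#' @param longitude_deg,latitude_deg Numeric vectors of embedded
#'   coordinates in degrees.
#' @rdname embed_points
#' @export
unembed_points <- function(embedding, longitude_deg, latitude_deg) {
  stopifnot(inherits(embedding, "geo_embedding"))
  data.frame(x_px = longitude_deg * embedding$pixels_per_degree,
             y_px = latitude_deg * embedding$pixels_per_degree)
}

#' East-west scale factor at a latitude
#'
#' On a sphere a step of one degree of longitude shortens by cos(latitude)
#' away from the equator, so an east-west pixel step embedded at latitude
#' phi is stretched by sec(phi) relative to the same step at the equator.
#' This is the metric distortion a geodesic distance calculation sees for
#' an image embedded isotropically in degrees.
#'
#' @param latitude_deg Latitude in degrees, |latitude| < 90. Vectorized.
#' @return The dimensionless ratio sec(latitude), >= 1.
#' @export
#' @examples
#' ew_scale_factor(0.1)     # 1.000001523
#' ew_scale_factor(25.808)  # about 1.1108: over 10% stretch
ew_scale_factor <- function(latitude_deg) {
  if (!all(is.finite(latitude_deg)) || any(abs(latitude_deg) >= 90)) {
    stop("`latitude_deg` must be finite and strictly between -90 and 90",
         call. = FALSE)
  }
  1 / cospi(latitude_deg / 180)
}

#' Worst-case east-west distortion of an embedded image
#'
#' The east-west metric stretch grows with latitude, so it is largest along
#' the top edge of the embedded image. The worst-case length error across
#' the full image width is `width_px * (ew_scale_factor(top_latitude) - 1)`
#' pixels. An image topped at 0.1 deg N distorts by well under one pixel;
#' topped at 25.8 deg N the top edge is stretched by more than 10%.
#'
#' @param embedding A [make_embedding()] result.
#' @param frame An [image_frame()]; defaults to the frame the embedding was
#'   built for.
#' @return Worst-case east-west length error, in pixels.
#' @export
#' @examples
#' fr <- image_frame(36857, 25808)
#' max_distortion_px(make_embedding(fr, top_latitude_deg = 0.1))  # < 1 px
max_distortion_px <- function(embedding, frame = embedding$frame) {
  stopifnot(inherits(embedding, "geo_embedding"),
            inherits(frame, "image_frame"))
  top <- frame$height_px / embedding$pixels_per_degree
  frame$width_px * (ew_scale_factor(top) - 1)
}

#' Convert between pixels, physical micrometres, and embedded metres
#'
#' `px_to_physical()` and `physical_to_px()` convert lengths between pixels
#' and micrometres using the frame's pixel pitch. `px_to_earth_m()` and
#' `earth_m_to_px()` convert pixel lengths to the metres they span on the
#' reference sphere under an embedding: `(px / pixels_per_degree) *
#' meters_per_degree`. A 20-um cell-neighborhood radius (30.8 px at
#' 0.65 um/px) corresponds to about 13.3 m on Earth under the 258,080
#' px-per-degree mapping.
#'
#' @param px,um,m Nonnegative numeric vectors of lengths.
#' @param frame An [image_frame()].
#' @param embedding A [make_embedding()] result.
#' @return A numeric vector of converted lengths.
#' @export
#' @examples
#' fr <- image_frame(36857, 25808, 0.65)
#' px_to_physical(25808, fr)            # 16775.2 um
#' physical_to_px(20, fr)               # 30.77 px
#' emb <- make_embedding(fr, top_latitude_deg = 0.1)
#' px_to_earth_m(physical_to_px(20, fr), emb)   # ~13.3 m
px_to_physical <- function(px, frame) {
  stopifnot(inherits(frame, "image_frame"))
  .check_length(px)
  px * frame$microns_per_pixel
}

#' @rdname px_to_physical
#' @export
physical_to_px <- function(um, frame) {
  stopifnot(inherits(frame, "image_frame"))
  .check_length(um)
  um / frame$microns_per_pixel
}

#' @rdname px_to_physical
#' @export
px_to_earth_m <- function(px, embedding) {
  stopifnot(inherits(embedding, "geo_embedding"))
  .check_length(px)
  px / embedding$pixels_per_degree * embedding$meters_per_degree
}

#' @rdname px_to_physical
#' @export
earth_m_to_px <- function(m, embedding) {
  stopifnot(inherits(embedding, "geo_embedding"))
  .check_length(m)
  m / embedding$meters_per_degree * embedding$pixels_per_degree
}

.check_length <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("lengths must be finite and nonnegative", call. = FALSE)
  }
  invisible(x)
}

#' Read and write embedding parameters as a key-value config file
#'
#' Serializes the embedding (pixels per degree, pixel pitch, y-flip flag,
#' metres per degree, frame extent) as plain `key = value` lines so a run
#' can be reproduced from its config.
#'
#' @param embedding A [make_embedding()] result.
#' @param path File path.
#' @param flip_y Logical, recorded for provenance: whether source tables
#'   used the top-left (y-down) imaging convention and were flipped on read.
#' @return `write_embedding_config()` returns `path` invisibly;
#'   `read_embedding_config()` returns a `geo_embedding`.
#' @export
write_embedding_config <- function(embedding, path, flip_y = FALSE) {
  stopifnot(inherits(embedding, "geo_embedding"))
  fr <- embedding$frame
  lines <- c(
    sprintf("pixels_per_degree = %.17g", embedding$pixels_per_degree),
    sprintf("meters_per_degree = %.17g", embedding$meters_per_degree),
    sprintf("width_px = %.17g", fr$width_px),
    sprintf("height_px = %.17g", fr$height_px),
    sprintf("microns_per_pixel = %.17g", fr$microns_per_pixel),
    sprintf("flip_y = %s", if (isTRUE(flip_y)) "true" else "false")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_embedding_config
#' @export
read_embedding_config <- function(path) {
  kv <- read_keyvalue_config(path)
  need <- c("pixels_per_degree", "width_px", "height_px",
            "microns_per_pixel")
  miss <- setdiff(need, names(kv))
  if (length(miss)) {
    stop("embedding config is missing key(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fr <- image_frame(as.numeric(kv[["width_px"]]),
                    as.numeric(kv[["height_px"]]),
                    as.numeric(kv[["microns_per_pixel"]]))
  emb <- make_embedding(
    fr, pixels_per_degree = as.numeric(kv[["pixels_per_degree"]]))
  attr(emb, "flip_y") <- identical(tolower(kv[["flip_y"]]), "true")
  emb
}
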