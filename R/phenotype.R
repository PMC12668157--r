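#' Define a marker gate rule
#'
#' A gate rule thresholds one marker-intensity column. `quantile` rules
#' are resolved on the cohort being classified (the q-quantile of the
#' observed intensity distribution, e.g. the third quartile for a
#' keratin-positivity gate); `absolute` rules use a fixed intensity cut,
#' as for manually calibrated multi-marker tumor gates (SOX10, S100B,
#' CD63). Rules combine conjunctively in [classify_cells()].
#'
#' @param marker Marker column name (e.g. `"Keratin_570_cellRingMask"`).
#' @param kind `"quantile"` or `"absolute"`.
#' @param value Quantile in (0, 1) for `kind = "quantile"`, otherwise a
#'   finite absolute intensity.
#' @return An object of class `gate_rule`.
#' @export
#' @examples
#' gate_rule("Keratin_570_cellRingMask", "quantile", 0.75)
gate_rule <- function(marker, kind = c("quantile", "absolute"), value) {
  kind <- match.arg(kind)
  stopifnot(is.character(marker), length(marker) == 1L, nzchar(marker))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop("`value` must be a single finite number", call. = FALSE)
  }
  if (kind == "quantile" && (value <= 0 || value >= 1)) {
    stop("quantile threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(list(marker = marker, kind = kind, value = value),
            class = "gate_rule")
}

#' @export
print.gate_rule <- function(x, ...) {
  cat(sprintf("<gate_rule> %s > %s%s\n", x$marker,
              if (x$kind == "quantile") sprintf("Q(%g)", x$value)
              else format(x$value),
              if (x$kind == "quantile") " of cohort" else ""))
  invisible(x)
}

#' Quantile of an intensity distribution
#'
#' Linear-interpolation quantile between closest order statistics
#' (`stats::quantile` type 7), the gate-threshold convention used
#' throughout: the third quartile of intensities 1..8 is 6.25.
#'
#' @param values Non-empty numeric vector of intensities.
#' @param q Quantile fraction in (0, 1).
#' @return The interpolated quantile, a single number.
#' @export
quantile_threshold <- function(values, q) {
  if (length(values) == 0L) {
    stop("cannot take a quantile of an empty intensity vector",
         call. = FALSE)
  }
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1) {
    stop("`q` must be a single fraction strictly in (0, 1)", call. = FALSE)
  }
  unname(stats::quantile(values, probs = q, type = 7, names = FALSE))
}

# standard cell-table validation: cell_id + centroid columns
.check_cells <- function(cells) {
  need <- c("cell_id", "x_centroid", "y_centroid")
  miss <- setdiff(need, names(cells))
  if (length(miss)) {
    stop("cell table must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cells$cell_id)) {
    stop("duplicate cell_id values in cell table", call. = FALSE)
  }
  invisible(cells)
}

#' Assign phenotype labels by marker-threshold gating
#'
#' A cell receives `label` iff its intensity strictly exceeds the resolved
#' threshold for every rule (conjunctive gating); all other cells are
#' labeled `"Other"`. Quantile rules are resolved on the cohort passed in,
#' so apply any [region_filter()] first if the gate should reflect the
#' region's intensity distribution.
#'
#' @param cells Cell table: data.frame with `cell_id`, `x_centroid`,
#'   `y_centroid` and one column per gated marker.
#' @param rules List of [gate_rule()]s (possibly empty: every cell then
#'   gets `label`, the vacuous conjunction).
#' @param label Phenotype label for cells passing all gates.
#' @param other Label for the remainder (default `"Other"`).
#' @return Named character vector mapping `cell_id` to `label`/`other`.
#' @export
#' @examples
#' cells <- data.frame(cell_id = 1:8, x_centroid = 1:8, y_centroid = 0,
#'                     Keratin = 1:8)
#' classify_cells(cells, list(gate_rule("Keratin", "quantile", 0.75)),
#'                "Tumor")   # cells 7 and 8 exceed Q3 = 6.25
classify_cells <- function(cells, rules, label, other = "Other") {
  .check_cells(cells)
  pass <- rep(TRUE, nrow(cells))
  for (rule in rules) {
    stopifnot(inherits(rule, "gate_rule"))
    if (!rule$marker %in% names(cells)) {
      stop(sprintf("marker column '%s' is missing from the cell table",
                   rule$marker), call. = FALSE)
    }
    v <- cells[[rule$marker]]
    thr <- if (rule$kind == "quantile") {
      quantile_threshold(v, rule$value)
    } else {
      rule$value
    }
    pass <- pass & (v > thr)
  }
  setNames(ifelse(pass, label, other), as.character(cells$cell_id))
}

#' Restrict cells to a rectangular region of interest
#'
#' Keeps cells whose centroid lies inside the closed axis-aligned
#' rectangle (boundary cells retained), preserving input order — e.g. the
#' invasive-melanoma region delimited by lower-left (23076.9, 9615.3) px
#' and upper-right (30384.6, 15000) px.
#'
#' @param cells Cell table (see [classify_cells()]).
#' @param lower_left,upper_right Numeric length-2 `(x, y)` pixel corners;
#'   `lower_left` must be strictly below `upper_right` componentwise.
#' @return The retained subset of `cells`, original order preserved.
#' @export
region_filter <- function(cells, lower_left, upper_right) {
  .check_cells(cells)
  stopifnot(length(lower_left) == 2L, length(upper_right) == 2L)
  if (!all(lower_left < upper_right)) {
    stop("`lower_left` must be strictly below `upper_right` in both ",
         "coordinates", call. = FALSE)
  }
  keep <- cells$x_centroid >= lower_left[1L] &
    cells$x_centroid <= upper_right[1L] &
    cells$y_centroid >= lower_left[2L] &
    cells$y_centroid <= upper_right[2L]
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
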