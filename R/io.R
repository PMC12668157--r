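# Table and config readers/writers. Dialect: comma vs tab inferred from
# the file extension (.csv vs anything else), UTF-8, header row required.
# Lines starting with '#' are header comments (tool version, config hash)
# and are skipped on read.

.delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  out <- utils::read.table(path, sep = .delim_for(path), header = TRUE,
                           comment.char = "#", quote = "\"",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(out) == 0L && ncol(out) == 0L) {
    stop(sprintf("empty table: %s", path), call. = FALSE)
  }
  out
}

.pkg_version <- function() {
  as.character(utils::packageVersion("geocyto"))
}

# write a delimited table with a provenance header comment
.write_delim_auto <- function(df, path, config_hash = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# geocyto %s%s", .pkg_version(),
                     if (is.null(config_hash)) ""
                     else paste0("; config_hash=", config_hash)), con)
  utils::write.table(df, con, sep = .delim_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a plain key-value config file
#'
#' Parses `key = value` lines (one per line; `#` starts a comment;
#' blank lines ignored) into a named character vector, the config format
#' used for embedding parameters and run configs.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_keyvalue_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  has_eq <- grepl("=", lines, fixed = TRUE)
  if (!all(has_eq)) {
    stop(sprintf("config line without '=': '%s'", lines[!has_eq][1L]),
         call. = FALSE)
  }
  key <- trimws(sub("=.*$", "", lines))
  val <- trimws(sub("^[^=]*=", "", lines))
  setNames(val, key)
}

#' Read a segmented-cell table
#'
#' Reads a Level-4-style cell table (CSV or TSV by extension) into the
#' standard cell-table layout: `cell_id`, `x_centroid`, `y_centroid` plus
#' every marker-intensity column. Rows whose mapped coordinate fields do
#' not parse as numbers are rejected with their data-row numbers in a
#' warning; the remaining rows are kept.
#'
#' @param path File path.
#' @param column_map Named character vector mapping the standard names
#'   (`cell_id`, `x_centroid`, `y_centroid`) to the file's column names
#'   (default `CellID`, `X_centroid`, `Y_centroid`).
#' @param flip_y If `TRUE`, convert from the top-left (y-down) imaging
#'   convention to the lower-left origin used here: `y <- height_px - y`.
#' @param height_px Image height in pixels; required when `flip_y`.
#' @return A cell table data.frame; the count of accepted rows is
#'   reported via `message()`.
#' @export
read_cell_table <- function(path,
                            column_map = c(cell_id = "CellID",
                                           x_centroid = "X_centroid",
                                           y_centroid = "Y_centroid"),
                            flip_y = FALSE, height_px = NULL) {
  raw <- .read_delim_auto(path)
  need <- c("cell_id", "x_centroid", "y_centroid")
  if (!all(need %in% names(column_map))) {
    stop("`column_map` must map cell_id, x_centroid and y_centroid",
         call. = FALSE)
  }
  # fall back to the standard names for files written by this package
  for (std in need) {
    if (!column_map[[std]] %in% names(raw) && std %in% names(raw)) {
      column_map[[std]] <- std
    }
  }
  miss <- setdiff(unname(column_map[need]), names(raw))
  if (length(miss)) {
    stop("mapped column(s) missing from ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(raw[[column_map[["x_centroid"]]]]))
  y <- suppressWarnings(as.numeric(raw[[column_map[["y_centroid"]]]]))
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    warning(sprintf("rejected %d row(s) with unparseable centroids (data row %s)",
                    length(bad), paste(head(bad, 10L), collapse = ", ")),
            call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- data.frame(cell_id = raw[[column_map[["cell_id"]]]][keep],
                    x_centroid = x[keep], y_centroid = y[keep])
  if (isTRUE(flip_y)) {
    if (is.null(height_px)) {
      stop("`height_px` is required when `flip_y = TRUE`", call. = FALSE)
    }
    out$y_centroid <- height_px - out$y_centroid
  }
  markers <- setdiff(names(raw), unname(column_map[need]))
  for (mk in markers) {
    v <- suppressWarnings(as.numeric(raw[[mk]][keep]))
    out[[mk]] <- if (all(is.finite(v) | is.na(raw[[mk]][keep]))) v
                 else raw[[mk]][keep]
  }
  .check_cells(out)
  message(sprintf("read_cell_table: accepted %d of %d row(s) from %s",
                  nrow(out), nrow(raw), path))
  out
}

#' @param cells A cell table.
#' @param config_hash Optional hash string recorded in the header
#'   comment.
#' @rdname read_cell_table
#' @export
write_cell_table <- function(cells, path, config_hash = NULL) {
  .check_cells(cells)
  .write_delim_auto(cells, path, config_hash)
}

#' Read and write tidy expression tables
#'
#' TSV/CSV with header columns `cell_barcode`, `feature`, `value`.
#'
#' @param path File path (`.csv` comma-separated, otherwise tabs).
#' @param table A tidy expression table.
#' @param config_hash Optional hash string for the header comment.
#' @return `read_tidy_table()` the table; `write_tidy_table()` the path,
#'   invisibly.
#' @export
read_tidy_table <- function(path) {
  raw <- .read_delim_auto(path)
  miss <- setdiff(c("cell_barcode", "feature", "value"), names(raw))
  if (length(miss)) {
    stop("tidy table file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  raw$value <- as.numeric(raw$value)
  .check_tidy(raw)
  raw
}

#' @rdname read_tidy_table
#' @export
write_tidy_table <- function(table, path, config_hash = NULL) {
  .check_tidy(table)
  .write_delim_auto(table, path, config_hash)
}

#' Read gate rules from a config table
#'
#' CSV/TSV with header `marker`, `kind` (`quantile`/`absolute`), `value`
#' and `label`; all rules must share one target label (conjunctive gate).
#'
#' @param path File path.
#' @return A list with `rules` (list of [gate_rule()]) and `label`.
#' @export
read_gate_rules <- function(path) {
  raw <- .read_delim_auto(path)
  miss <- setdiff(c("marker", "kind", "value", "label"), names(raw))
  if (length(miss)) {
    stop("gate-rule file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  label <- unique(raw$label)
  if (length(label) != 1L) {
    stop("gate-rule file must target a single label; found: ",
         paste(label, collapse = ", "), call. = FALSE)
  }
  rules <- lapply(seq_len(nrow(raw)), function(i) {
    gate_rule(raw$marker[i], raw$kind[i], as.numeric(raw$value[i]))
  })
  list(rules = rules, label = label)
}

#' Export points as GeoJSON
#'
#' Writes an RFC 7946 FeatureCollection of Point features, coordinates in
#' `[longitude, latitude]` order, with every other column of `df` carried
#' as feature properties (cell ids, phenotype labels, cluster ids, ...).
#'
#' @param df data.frame with `longitude_deg` and `latitude_deg` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  miss <- setdiff(c("longitude_deg", "latitude_deg"), names(df))
  if (length(miss)) {
    stop("`df` is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  props <- setdiff(names(df), c("longitude_deg", "latitude_deg"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$longitude_deg[i],
                                         df$latitude_deg[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
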