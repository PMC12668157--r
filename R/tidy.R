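# Long-format ("tidy") single-cell expression store: one row per observed
# (cell barcode, feature) pair. Zeros are never materialized — the sparse
# convention — so row count equals the number of nonzero matrix entries.

.check_tidy <- function(table) {
  need <- c("cell_barcode", "feature", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("tidy table must have columns ", paste(need, collapse = ", "),
         "; missing: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dup <- duplicated(paste0(table$cell_barcode, "\r", table$feature))
  if (any(dup)) {
    stop("duplicate (cell_barcode, feature) row(s), first: ",
         table$cell_barcode[dup][1L], " / ", table$feature[dup][1L],
         call. = FALSE)
  }
  invisible(table)
}

#' Convert a cell-by-feature matrix to a tidy long table
#'
#' Flattens a rectangular expression matrix into long format with one row
#' per nonzero entry (`cell_barcode`, `feature`, `value`); zero entries
#' are omitted, so [pivot_to_matrix()] inverts the operation up to
#' zero-fill.
#'
#' @param mat Numeric matrix, cells in rows, features in columns.
#' @param cell_barcodes,features Row/column identifiers; default to
#'   `dimnames(mat)`. Must be unique.
#' @return data.frame with columns `cell_barcode`, `feature`, `value`,
#'   ordered by cell then feature.
#' @export
ingest_matrix <- function(mat, cell_barcodes = rownames(mat),
                          features = colnames(mat)) {
  stopifnot(is.matrix(mat))
  if (is.null(cell_barcodes) || is.null(features)) {
    stop("cell and feature identifiers are required (dimnames or ",
         "explicit arguments)", call. = FALSE)
  }
  if (length(cell_barcodes) != nrow(mat) || length(features) != ncol(mat)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(cell_barcodes)) {
    stop("duplicate cell barcodes", call. = FALSE)
  }
  if (anyDuplicated(features)) stop("duplicate feature ids", call. = FALSE)
  nz <- which(mat != 0, arr.ind = TRUE)
  out <- data.frame(cell_barcode = cell_barcodes[nz[, 1L]],
                    feature = features[nz[, 2L]],
                    value = mat[nz])
  out <- out[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select tidy-table rows for a set of cell barcodes
#'
#' @param table A tidy expression table.
#' @param barcodes Character vector of barcodes; barcodes absent from the
#'   table simply contribute no rows.
#' @return The matching rows, input order preserved (stable).
#' @export
query_cells <- function(table, barcodes) {
  .check_tidy(table)
  out <- table[table$cell_barcode %in% barcodes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total-count scaling and log1p transform of a tidy table
#'
#' Standard single-cell normalization: each cell's counts are scaled so
#' the cell total equals `target_sum` (10,000 by default), then
#' `log(1 + x)` (natural log) is applied. Per-cell feature rank order is
#' preserved, and the per-cell totals are conserved:
#' `sum(expm1(value))` equals `target_sum` for every cell.
#'
#' Some contributing datasets ship `log2(x + 1)`-transformed values
#' rather than raw counts; pass `input_transform = "log2p1"` to invert
#' that transform before normalizing.
#'
#' @param table Tidy table of raw counts (values >= 0; every cell must
#'   have a positive total).
#' @param target_sum Per-cell total after scaling (default 10,000).
#' @param input_transform `"counts"` (default) or `"log2p1"`.
#' @return Tidy table with normalized `value`s.
#' @export
#' @examples
#' tt <- data.frame(cell_barcode = "c1", feature = c("g1", "g2"),
#'                  value = c(2, 3))
#' normalize_log1p(tt, target_sum = 10)   # log(5), log(7)
normalize_log1p <- function(table, target_sum = 10000,
                            input_transform = c("counts", "log2p1")) {
  .check_tidy(table)
  input_transform <- match.arg(input_transform)
  .check_pos(target_sum, "target_sum")
  v <- table$value
  if (input_transform == "log2p1") v <- 2^v - 1
  if (any(v < 0)) stop("negative counts in tidy table", call. = FALSE)
  totals <- rowsum(v, group = table$cell_barcode)
  zero <- rownames(totals)[totals[, 1L] <= 0]
  if (length(zero)) {
    stop("cell(s) with zero total count cannot be normalized: ",
         paste(head(zero, 5L), collapse = ", "),
         if (length(zero) > 5L) ", ...", call. = FALSE)
  }
  scale <- target_sum / totals[table$cell_barcode, 1L]
  out <- table
  out$value <- log1p(v * scale)
  out
}

#' Pivot a tidy table to a dense cell-by-feature matrix
#'
#' Builds the dense rectangle for the requested cells and features,
#' zero-filling absent (cell, feature) pairs; rows and columns follow the
#' requested order. Requested ids need not appear in the table (their
#' rows/columns are all zero).
#'
#' @param table Tidy expression table.
#' @param cell_barcodes,features Identifier vectors defining the output
#'   rectangle; default to the distinct ids present, in first-appearance
#'   order.
#' @return Numeric matrix with `dimnames` set.
#' @export
pivot_to_matrix <- function(table, cell_barcodes = unique(table$cell_barcode),
                            features = unique(table$feature)) {
  .check_tidy(table)
  mat <- matrix(0, length(cell_barcodes), length(features),
                dimnames = list(cell_barcodes, features))
  keep <- table$cell_barcode %in% cell_barcodes &
    table$feature %in% features
  sub <- table[keep, , drop = FALSE]
  mat[cbind(match(sub$cell_barcode, cell_barcodes),
            match(sub$feature, features))] <- sub$value
  mat
}

#' Export a tidy table as MatrixMarket (MTX) with id sidecars
#'
#' Writes `<prefix>.mtx` (sparse coordinate format, cells in rows),
#' `<prefix>.barcodes.tsv` and `<prefix>.features.tsv`, the conventional
#' hand-off to single-cell toolchains.
#'
#' @param table Tidy expression table.
#' @param prefix Output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_tidy_mtx <- function(table, prefix) {
  .check_tidy(table)
  cells <- unique(table$cell_barcode)
  feats <- unique(table$feature)
  m <- Matrix::sparseMatrix(
    i = match(table$cell_barcode, cells),
    j = match(table$feature, feats),
    x = table$value, dims = c(length(cells), length(feats)))
  paths <- paste0(prefix, c(".mtx", ".barcodes.tsv", ".features.tsv"))
  Matrix::writeMM(m, paths[1L])
  writeLines(as.character(cells), paths[2L])
  writeLines(as.character(feats), paths[3L])
  invisible(paths)
}
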