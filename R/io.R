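#' Read a MatrixMarket sparse count matrix with sidecar id files
#'
#' 10x-style triplet: coordinate-format MTX plus one-id-per-line features
#' and barcodes files whose lengths must match the matrix dimensions.
#'
#' @param matrix_path MTX file.
#' @param features_path gene ids, one per line (first tab-separated field
#'   is used).
#' @param barcodes_path sample ids, one per line.
#' @param nonint what to do with non-integer entries: `"warn"` (truncate
#'   with a warning) or `"error"`.
#' @return an `ExpressionMatrix` on the `counts` layer (sparse).
#' @export
read_mtx <- function(matrix_path, features_path, barcodes_path,
                     nonint = c("warn", "error")) {
  nonint <- match.arg(nonint)
  m <- methods::as(methods::as(Matrix::readMM(matrix_path), "generalMatrix"),
                   "CsparseMatrix")
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
  bcs <- utils::read.delim(barcodes_path, header = FALSE,
                           stringsAsFactors = FALSE)[, 1]
  if (length(feats) != nrow(m))
    stop(sprintf("features file %s has %d ids but matrix has %d rows",
                 features_path, length(feats), nrow(m)))
  if (length(bcs) != ncol(m))
    stop(sprintf("barcodes file %s has %d ids but matrix has %d columns",
                 barcodes_path, length(bcs), ncol(m)))
  if (any(m@x != round(m@x))) {
    if (nonint == "error") stop("non-integer entries in count matrix")
    warning("non-integer entries truncated")
    m@x <- trunc(m@x)
  }
  dimnames(m) <- list(feats, bcs)
  expression_matrix(m, "counts")
}

#' Write a sparse count matrix as MTX + features + barcodes
#'
#' @param matrix an `ExpressionMatrix` on the `counts` layer.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `""`).
#' @return invisibly, the three file paths.
#' @export
write_mtx <- function(matrix, dir, prefix = "") {
  assert_layer(matrix, "counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "features.tsv",
                                           "barcodes.tsv")))
  v <- methods::as(methods::as(Matrix::Matrix(matrix$values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(v, paths[1])
  writeLines(gene_ids(matrix), paths[2])
  writeLines(sample_ids(matrix), paths[3])
  invisible(paths)
}

#' Read / write a nuclei point table (CSV: id, x_um, y_um, diameter_um)
#'
#' @param path CSV file.
#' @param domain optional domain override `c(xmin, xmax, ymin, ymax)`.
#' @return a [point_pattern()].
#' @export
read_point_csv <- function(path, domain = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x_um", "y_um") %in% names(df)))
  point_pattern(df$x_um, df$y_um, domain = domain,
                diameter = if ("diameter_um" %in% names(df)) df$diameter_um,
                id = df$id)
}

#' @rdname read_point_csv
#' @param pattern a [point_pattern()].
#' @export
write_point_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "PointPattern"))
  df <- pattern$points
  names(df)[names(df) == "x"] <- "x_um"
  names(df)[names(df) == "y"] <- "y_um"
  if ("diameter" %in% names(df))
    names(df)[names(df) == "diameter"] <- "diameter_um"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene x grid expression TSV with a grid-coordinate CSV
#'
#' @param tsv_path gene x grid table, first column gene ids, header row of
#'   grid ids.
#' @param coords_path CSV with columns `grid_id`, `row`, `col`,
#'   `x_center_um`, `y_center_um` (optionally `included`).
#' @param layer layer tag of the values (default `"counts"`).
#' @return list with `matrix` (`ExpressionMatrix`) and `layout`
#'   ([grid_layout()]); grids missing coordinates are dropped with a
#'   warning.
#' @export
read_grid_table <- function(tsv_path, coords_path, layer = "counts") {
  tab <- utils::read.delim(tsv_path, row.names = 1, check.names = FALSE)
  coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  stopifnot(all(c("grid_id", "row", "col") %in% names(coords)))
  if (anyDuplicated(coords$grid_id))
    stop("duplicated grid_id in ", coords_path)
  pitch <- if (nrow(coords) > 0 && "x_center_um" %in% names(coords))
    coords$x_center_um[1] / (coords$col[1] - 0.5) else 1
  layout <- grid_layout(coords, pitch = pitch)
  m <- as.matrix(tab)
  known <- colnames(m) %in% layout$grid_id
  if (!all(known)) {
    warning(sprintf("dropping %d grid(s) without coordinates", sum(!known)))
    m <- m[, known, drop = FALSE]
  }
  layout <- layout[match(colnames(m), layout$grid_id), , drop = FALSE]
  meta <- data.frame(x = layout$x_center_um, y = layout$y_center_um,
                     row.names = layout$grid_id)
  list(matrix = expression_matrix(m, layer, meta), layout = layout)
}

#' @rdname read_grid_table
#' @param matrix an `ExpressionMatrix` of grids.
#' @param layout a [grid_layout()].
#' @export
write_grid_table <- function(matrix, layout, tsv_path, coords_path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  m <- as_dense(matrix$values)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.csv(as.data.frame(layout)[, c("grid_id", "row", "col",
                                             "x_center_um", "y_center_um",
                                             "included")],
                   coords_path, row.names = FALSE, quote = FALSE)
  invisible(c(tsv_path, coords_path))
}

#' Write / read a synthetic ground-truth bundle as JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path JSON file.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  # named atomic vectors must become JSON objects so names survive the trip
  prep <- function(x) {
    if (is.list(x)) lapply(x, prep)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(prep(unclass(truth)), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  # scalar objects come back as one-element lists when types are mixed
  norm <- function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.null(e) ||
                     (is.atomic(e) && length(e) == 1), logical(1)))) {
      vals <- lapply(x, function(e) if (is.null(e)) NA else e)
      num <- vapply(vals, function(e) is.numeric(e) || is.na(e), logical(1))
      chr <- vapply(vals, function(e) is.character(e) || is.na(e), logical(1))
      if (all(num) || all(chr)) unlist(vals) else vals
    } else if (is.list(x)) lapply(x, norm) else x
  }
  do.call(synthetic_truth, lapply(obj, norm))
}

#' Write an hclust dendrogram as Newick
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  # recursive serialisation; heights become branch lengths
  labs <- hc$labels
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(hc$merge) + 1))
  h_of <- function(node) if (node < 0) 0 else hc$height[node]
  rec <- function(node) {
    if (node < 0) return(labs[-node])
    kids <- hc$merge[node, ]
    sprintf("(%s:%g,%s:%g)", rec(kids[1]), h_of(node) - h_of(kids[1]),
            rec(kids[2]), h_of(node) - h_of(kids[2]))
  }
  writeLines(paste0(rec(nrow(hc$merge)), ";"), path)
  invisible(path)
}

#' Write a marker table as TSV
#'
#' @param markers a `MarkerTable`.
#' @param path output TSV.
#' @export
write_marker_tsv <- function(markers, path) {
  utils::write.table(as.data.frame(markers), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
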