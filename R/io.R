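# Reading and writing expression matrices, label tables, coordinate tables and
# result tables. Matrices are plain base matrices with gene rownames and
# cell/spot colnames; MatrixMarket triplets are handled through the Matrix
# package (10x-style matrix.mtx + features.tsv + barcodes.tsv).

#' Read an expression matrix
#'
#' Reads a genes-by-cells (or genes-by-spots) count matrix from a MatrixMarket
#' triplet directory/file or a dense TSV/CSV table. For MTX input the companion
#' gene and barcode files (`features.tsv`/`genes.tsv` and `barcodes.tsv`,
#' optionally named `<prefix>_features.tsv` etc. next to the `.mtx` file) must
#' exist. For TSV/CSV the first column holds gene identifiers and the header
#' row holds column identifiers.
#'
#' @param path Path to a `.mtx` file, a directory containing `matrix.mtx`, or a
#'   dense TSV/CSV file.
#' @param format One of `"auto"`, `"mtx"`, `"tsv"`, `"csv"`. `"auto"` infers
#'   from the file extension.
#' @param genes_as_rows For MTX input, whether the stored matrix is
#'   genes x cells (the 10x convention, default) or cells x genes
#'   (transposed dialect).
#' @return A numeric matrix, genes as rows, with attribute `is_integer`
#'   indicating raw counts.
#' @export
read_matrix <- function(path, format = c("auto", "mtx", "tsv", "csv"),
                        genes_as_rows = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx(\\.gz)?$", path)) "mtx"
              else if (grepl("\\.csv$", path)) "csv" else "tsv"
  }
  if (format == "mtx") {
    m <- read_mtx_triplet(path, genes_as_rows)
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "")
    genes <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  }
  validate_expression_matrix(m, paste0("matrix at '", path, "'"))
  attr(m, "is_integer") <- is_count_matrix(m)
  m
}

read_mtx_triplet <- function(path, genes_as_rows = TRUE) {
  if (dir.exists(path)) {
    dirp <- path
    mtx <- file.path(dirp, "matrix.mtx")
    if (!file.exists(mtx)) {
      hits <- list.files(dirp, pattern = "\\.mtx$", full.names = TRUE)
      if (length(hits) != 1L) stop("no unique .mtx file found in ", path)
      mtx <- hits[[1L]]
    }
  } else {
    mtx <- path
    dirp <- dirname(path)
  }
  find_side <- function(names) {
    prefix <- sub("(matrix)?\\.mtx$", "", basename(mtx))
    cands <- c(file.path(dirp, names),
               file.path(dirp, paste0(prefix, names)))
    cands <- cands[file.exists(cands)]
    if (!length(cands)) {
      stop("companion file (", paste(names, collapse = " or "),
           ") not found next to ", mtx)
    }
    cands[[1L]]
  }
  genes_file <- find_side(c("features.tsv", "genes.tsv"))
  cells_file <- find_side("barcodes.tsv")
  sm <- Matrix::readMM(mtx)
  genes <- utils::read.table(genes_file, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.table(cells_file, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  m <- as_dense(sm)
  if (!genes_as_rows) m <- t(m)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match features (", length(genes), ") / barcodes (",
         length(cells), ")")
  }
  rownames(m) <- genes
  colnames(m) <- cells
  m
}

#' Write an expression matrix
#'
#' Writes a matrix either as a dense TSV/CSV (gene identifiers in the first
#' column, named `gene`) or as a MatrixMarket triplet directory
#' (`matrix.mtx` + `features.tsv` + `barcodes.tsv`).
#'
#' @param m Matrix with gene rownames and column names.
#' @param path Output file (tsv/csv) or directory (mtx).
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  validate_expression_matrix(m)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    sm <- Matrix::sparseMatrix(i = row(m)[m != 0], j = col(m)[m != 0],
                               x = m[m != 0], dims = dim(m))
    Matrix::writeMM(sm, file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-cell cell-type labels
#'
#' Expects a TSV/CSV with header columns `cell_id` and `cell_type`. When a
#' companion expression matrix is supplied, every matrix column must be
#' labeled (unlabeled cells are a hard error) and labels for cells missing
#' from the matrix are reported with a warning.
#'
#' @param path Label table path.
#' @param matrix Optional expression matrix to validate against.
#' @return Named character vector mapping cell id to cell-type name.
#' @export
read_labels <- function(path, matrix = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  need <- c("cell_id", "cell_type")
  if (!all(need %in% names(tab))) {
    stop("label file must have columns 'cell_id' and 'cell_type'; found: ",
         paste(names(tab), collapse = ", "))
  }
  labels <- stats::setNames(as.character(tab$cell_type),
                            as.character(tab$cell_id))
  validate_labels(labels, matrix)
}

validate_labels <- function(labels, matrix = NULL) {
  dup <- unique(names(labels)[duplicated(names(labels))])
  if (length(dup)) {
    stop("duplicated cell_id in labels: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (anyNA(labels) || any(labels == "")) stop("empty cell_type in labels")
  if (!is.null(matrix)) {
    missing <- setdiff(colnames(matrix), names(labels))
    if (length(missing)) {
      stop(length(missing), " matrix cells are unlabeled: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    extra <- setdiff(names(labels), colnames(matrix))
    if (length(extra)) {
      warning(length(extra), " labeled cells absent from the matrix: ",
              paste(utils::head(extra, 5), collapse = ", "))
    }
  }
  labels
}

#' One-hot membership matrix from labels
#'
#' @param labels Named character vector (cell id -> type).
#' @param cells Cell ids defining row order (default: label order).
#' @return Cells x types 0/1 matrix; each row sums to 1.
#' @export
onehot_labels <- function(labels, cells = names(labels)) {
  labels <- labels[cells]
  if (anyNA(labels)) stop("labels missing for some requested cells")
  types <- sort(unique(labels))
  A <- matrix(0, length(cells), length(types),
              dimnames = list(cells, types))
  A[cbind(seq_along(cells), match(labels, types))] <- 1
  A
}

#' Read spot coordinates
#'
#' Expects a TSV/CSV with header columns `spot_id`, `x`, `y` (numeric, array
#' units of the platform). When a spatial matrix is supplied, spot ids must
#' cover its columns.
#'
#' @param path Coordinate table path.
#' @param matrix Optional spatial expression matrix to validate against.
#' @return `data.frame` with columns `spot_id`, `x`, `y`.
#' @export
read_coordinates <- function(path, matrix = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("coordinate file must have columns 'spot_id', 'x', 'y'; found: ",
         paste(names(tab), collapse = ", "))
  }
  xy <- suppressWarnings(cbind(as.numeric(tab$x), as.numeric(tab$y)))
  if (anyNA(xy) || any(!is.finite(xy))) {
    stop("non-numeric or non-finite coordinates in ", path)
  }
  out <- data.frame(spot_id = as.character(tab$spot_id),
                    x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  dup <- unique(out$spot_id[duplicated(out$spot_id)])
  if (length(dup)) {
    stop("duplicated spot_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!is.null(matrix)) {
    missing <- setdiff(colnames(matrix), out$spot_id)
    if (length(missing)) {
      stop(length(missing), " spots lack coordinates: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  out
}

#' Write a result table as TSV
#'
#' All result tables are TSV with a header row; numeric columns are written at
#' 6 significant digits so outputs are diff-able across platforms.
#'
#' @param tab `data.frame` or matrix (written with an `id` first column built
#'   from rownames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path) {
  if (is.matrix(tab)) {
    tab <- data.frame(id = rownames(tab) %||% seq_len(nrow(tab)), tab,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  tab[] <- lapply(tab, fmt6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_labels <- function(labels, path) {
  write_result_table(data.frame(cell_id = names(labels), cell_type = labels,
                                stringsAsFactors = FALSE), path)
}

write_coordinates <- function(coords, path) {
  write_result_table(coords, path)
}
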