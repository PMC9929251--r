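#' Construct a gene expression matrix record
#'
#' Bundles a sparse cells-by-genes matrix of UMI counts with its cell and
#' gene identifiers, after validating that the counts are non-negative
#' integers and the identifiers are unique and consistent with the matrix
#' dimensions.
#'
#' @param counts A matrix or sparse \code{Matrix} of non-negative integer
#'   counts, oriented cells-by-genes.
#' @param cell_ids Character vector of unique cell barcodes (rows).
#' @param gene_ids Character vector of unique gene/feature ids (columns).
#' @param gene_symbols Optional character vector of gene symbols, kept as
#'   metadata (symbols need not be unique; identity is keyed by id).
#'
#' @return An object of class \code{gene_expression_matrix}: a list with
#'   elements \code{counts} (a \code{dgCMatrix}), \code{cell_ids},
#'   \code{gene_ids} and \code{gene_symbols}.
#' @export
gene_expression_matrix <- function(counts, cell_ids, gene_ids,
                                   gene_symbols = NULL) {
  if (is(counts, "nMatrix")) counts <- as(counts, "dMatrix")
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(counts) != length(cell_ids)) {
    abort(sprintf(
      "matrix has %d rows but %d cell ids were supplied",
      nrow(counts), length(cell_ids)
    ), class = "scpoolr_validation_error")
  }
  if (ncol(counts) != length(gene_ids)) {
    abort(sprintf(
      "matrix has %d columns but %d gene ids were supplied",
      ncol(counts), length(gene_ids)
    ), class = "scpoolr_validation_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("cell ids must be unique", class = "scpoolr_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort("gene ids must be unique", class = "scpoolr_validation_error")
  }
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x)))) {
    abort("counts must be non-negative integers",
      class = "scpoolr_validation_error"
    )
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  if (!is.null(gene_symbols) && length(gene_symbols) != length(gene_ids)) {
    abort("gene_symbols must match gene_ids in length",
      class = "scpoolr_validation_error"
    )
  }
  structure(
    list(
      counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
      gene_symbols = gene_symbols
    ),
    class = "gene_expression_matrix"
  )
}

#' @export
print.gene_expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<gene_expression_matrix> %d cells x %d genes, %d nonzero counts\n",
    nrow(x$counts), ncol(x$counts), length(x$counts@x)
  ))
  invisible(x)
}

#' @export
dim.gene_expression_matrix <- function(x) dim(x$counts)

find_10x_file <- function(path, stems) {
  for (stem in stems) {
    for (ext in c("", ".gz")) {
      f <- file.path(path, paste0(stem, ext))
      if (file.exists(f)) return(f)
    }
  }
  abort(sprintf(
    "no file matching '%s' found in %s",
    paste(stems, collapse = "' or '"), path
  ), class = "scpoolr_io_error")
}

read_id_column <- function(path) {
  df <- readr::read_tsv(path,
    col_names = FALSE, show_col_types = FALSE,
    progress = FALSE
  )
  df
}

#' Read a 10x Genomics-style MatrixMarket triplet
#'
#' Reads \code{matrix.mtx}, \code{barcodes.tsv} and \code{features.tsv} (or
#' \code{genes.tsv}), plain or gzipped, from a directory and returns the
#' counts oriented cells-by-genes regardless of the on-disk orientation.
#' Orientation is auto-detected by matching the matrix dimensions against
#' the lengths of the barcode and feature lists; a square matrix with
#' equally many barcodes and features is ambiguous and requires an explicit
#' \code{orientation}.
#'
#' @param path Directory containing the triplet.
#' @param orientation One of \code{"auto"} (default), \code{"genes_by_cells"}
#'   (the usual 10x on-disk layout) or \code{"cells_by_genes"}.
#' @return A [gene_expression_matrix()].
#' @export
read_10x_mtx <- function(path,
                         orientation = c("auto", "genes_by_cells",
                                         "cells_by_genes")) {
  orientation <- match.arg(orientation)
  if (!dir.exists(path)) {
    abort(sprintf("directory not found: %s", path),
      class = "scpoolr_io_error"
    )
  }
  mtx_file <- find_10x_file(path, "matrix.mtx")
  bc_file <- find_10x_file(path, "barcodes.tsv")
  ft_file <- find_10x_file(path, c("features.tsv", "genes.tsv"))

  m <- if (grepl("\\.gz$", mtx_file)) {
    con <- gzfile(mtx_file)
    on.exit(try(close(con), silent = TRUE), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(mtx_file)
  }
  barcodes <- read_id_column(bc_file)[[1]]
  features <- read_id_column(ft_file)
  gene_ids <- features[[1]]
  gene_symbols <- if (ncol(features) >= 2) features[[2]] else NULL

  nb <- length(barcodes)
  ng <- length(gene_ids)
  if (orientation == "auto") {
    gc_ok <- nrow(m) == ng && ncol(m) == nb
    cg_ok <- nrow(m) == nb && ncol(m) == ng
    if (gc_ok && cg_ok) {
      abort(paste(
        "matrix is square with equally many barcodes and features;",
        "orientation is ambiguous, pass `orientation` explicitly"
      ), class = "scpoolr_validation_error")
    }
    if (gc_ok) {
      orientation <- "genes_by_cells"
    } else if (cg_ok) {
      orientation <- "cells_by_genes"
    } else {
      abort(sprintf(
        "matrix is %d x %d but there are %d barcodes and %d features",
        nrow(m), ncol(m), nb, ng
      ), class = "scpoolr_validation_error")
    }
  } else {
    dims_ok <- if (orientation == "genes_by_cells") {
      nrow(m) == ng && ncol(m) == nb
    } else {
      nrow(m) == nb && ncol(m) == ng
    }
    if (!dims_ok) {
      abort(sprintf(
        "matrix is %d x %d, inconsistent with %d barcodes / %d features as %s",
        nrow(m), ncol(m), nb, ng, orientation
      ), class = "scpoolr_validation_error")
    }
  }
  if (orientation == "genes_by_cells") m <- Matrix::t(m)
  gene_expression_matrix(m, barcodes, gene_ids, gene_symbols)
}

#' Write a gene expression matrix as a 10x-style triplet
#'
#' Emits \code{matrix.mtx} in the conventional genes-by-cells on-disk
#' orientation plus \code{barcodes.tsv} and \code{features.tsv}.
#'
#' @param gem A [gene_expression_matrix()].
#' @param path Output directory (created if missing).
#' @return Invisibly, the directory written to.
#' @export
write_10x_mtx <- function(gem, path) {
  stopifnot(inherits(gem, "gene_expression_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(gem$counts), file.path(path, "matrix.mtx"))
  writeLines(gem$cell_ids, file.path(path, "barcodes.tsv"))
  symbols <- gem$gene_symbols %||% gem$gene_ids
  readr::write_tsv(
    tibble(id = gem$gene_ids, symbol = symbols),
    file.path(path, "features.tsv"),
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

annotation_required_cols <- c(
  "cell_id", "donor", "batch", "stimulus", "status", "cluster"
)

#' Validate and normalize a per-cell annotation table
#'
#' Checks the experimental-design invariants the pipeline relies on: every
#' cell of the matched expression matrix is annotated, stimulus and status
#' take known levels, and each donor maps to exactly one batch and one
#' status (donors are nested in batch and status by design).  Cells in the
#' table that are absent from the matrix are dropped with a message.
#'
#' @param annotation A data frame with columns \code{cell_id}, \code{donor},
#'   \code{batch}, \code{stimulus}, \code{status}, \code{cluster}, and
#'   optionally \code{batch_labels} (a list-column of per-batch-run cluster
#'   labels used by the label-consistency filter).
#' @param matrix Optional [gene_expression_matrix()]; when given, the
#'   annotation is restricted to and ordered as its \code{cell_ids}.
#' @param stimulus_levels,status_levels Allowed factor levels.
#' @return A tibble ordered as the matrix cells, with factor columns.
#' @export
cell_annotation <- function(annotation, matrix = NULL,
                            stimulus_levels = c("TNF", "Null"),
                            status_levels = c("JIA", "Control")) {
  annotation <- as_tibble(annotation)
  missing_cols <- setdiff(annotation_required_cols, names(annotation))
  if (length(missing_cols)) {
    abort(sprintf(
      "annotation is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), class = "scpoolr_validation_error")
  }
  if (anyDuplicated(annotation$cell_id)) {
    abort("annotation cell_id values must be unique",
      class = "scpoolr_validation_error"
    )
  }
  bad_stim <- setdiff(unique(as.character(annotation$stimulus)),
                      stimulus_levels)
  if (length(bad_stim)) {
    abort(sprintf(
      "unknown stimulus level(s): %s", paste(bad_stim, collapse = ", ")
    ), class = "scpoolr_validation_error")
  }
  bad_status <- setdiff(unique(as.character(annotation$status)),
                        status_levels)
  if (length(bad_status)) {
    abort(sprintf(
      "unknown status level(s): %s", paste(bad_status, collapse = ", ")
    ), class = "scpoolr_validation_error")
  }

  if (!is.null(matrix)) {
    stopifnot(inherits(matrix, "gene_expression_matrix"))
    missing_cells <- setdiff(matrix$cell_ids, annotation$cell_id)
    if (length(missing_cells)) {
      abort(sprintf(
        "%d matrix cell(s) missing from annotation (first: %s)",
        length(missing_cells),
        paste(head(missing_cells, 5), collapse = ", ")
      ), class = "scpoolr_validation_error")
    }
    extras <- setdiff(annotation$cell_id, matrix$cell_ids)
    if (length(extras)) {
      inform(sprintf(
        "dropping %d annotated cell(s) absent from the matrix",
        length(extras)
      ))
    }
    annotation <- annotation[match(matrix$cell_ids, annotation$cell_id), ]
  }

  annotation <- dplyr::mutate(
    annotation,
    cell_id = as.character(.data$cell_id),
    donor = factor(.data$donor),
    batch = factor(.data$batch),
    stimulus = factor(.data$stimulus, levels = stimulus_levels),
    status = factor(.data$status, levels = status_levels),
    cluster = factor(.data$cluster)
  )

  # donor -> batch and donor -> status must be functions (nesting)
  for (col in c("batch", "status")) {
    map <- dplyr::distinct(
      annotation, .data$donor, .data[[col]]
    )
    dup <- map$donor[duplicated(map$donor)]
    if (length(dup)) {
      abort(sprintf(
        "donor(s) mapped to more than one %s: %s",
        col, paste(unique(dup), collapse = ", ")
      ), class = "scpoolr_validation_error")
    }
  }
  annotation
}

#' Read a per-cell annotation table
#'
#' Reads a delimited table (TSV or CSV, by extension), then validates and
#' aligns it to the expression matrix with [cell_annotation()].  Columns
#' named \code{batch_label_*}, if present, are gathered into the
#' \code{batch_labels} list-column consumed by [filter_label_consistency()].
#'
#' @inheritParams cell_annotation
#' @param path Path to the table.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path, matrix = NULL,
                            stimulus_levels = c("TNF", "Null"),
                            status_levels = c("JIA", "Control")) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path),
      class = "scpoolr_io_error"
    )
  }
  reader <- if (grepl("\\.csv(\\.gz)?$", path)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  df <- reader(path, show_col_types = FALSE, progress = FALSE)
  label_cols <- grep("^batch_label", names(df), value = TRUE)
  if (length(label_cols)) {
    labs <- df[label_cols]
    df$batch_labels <- lapply(
      seq_len(nrow(df)),
      function(i) {
        v <- as.character(unlist(labs[i, ], use.names = FALSE))
        v[!is.na(v)]
      }
    )
    df <- df[setdiff(names(df), label_cols)]
  }
  cell_annotation(df, matrix,
    stimulus_levels = stimulus_levels, status_levels = status_levels
  )
}

#' Write a tabular result as TSV
#'
#' Writes any of the package's tabular results (or a plain data frame /
#' named matrix) as a tab-separated file with header, at full precision so
#' that re-reading reproduces the values exactly.
#'
#' @param x A data frame, or a matrix with dimnames (written with a leading
#'   label column).
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_table <- function(x, path) {
  if (is.matrix(x)) {
    x <- as_tibble(x, rownames = "label")
  }
  if (!is.data.frame(x)) {
    abort("write_table expects a data frame or a matrix",
      class = "scpoolr_validation_error"
    )
  }
  x <- as_tibble(x)
  x <- x[!vapply(x, is.list, logical(1))]
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
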