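#' Flag cells with a high mitochondrial read fraction
#'
#' A cell fails when its mitochondrial fraction is strictly greater than
#' \code{threshold} (so a cell at exactly the threshold is retained).
#' Cells with zero total counts cannot be assessed and fail with reason
#' \code{"zero counts"}.
#'
#' @param gem A [gene_expression_matrix()].
#' @param mito_genes Character vector of mitochondrial gene ids, or
#'   \code{NULL} to match gene symbols (falling back to ids) with
#'   \code{mito_prefix}.
#' @param threshold Maximum tolerated mitochondrial fraction (default 0.15).
#' @param mito_prefix Prefix identifying mitochondrial genes when
#'   \code{mito_genes} is not given (default \code{"MT-"}).
#' @return A tibble with columns \code{cell_id}, \code{mito_fraction},
#'   \code{pass}.
#' @export
filter_mito <- function(gem, mito_genes = NULL, threshold = 0.15,
                        mito_prefix = "MT-") {
  stopifnot(inherits(gem, "gene_expression_matrix"))
  if (is.null(mito_genes)) {
    names_for_match <- gem$gene_symbols %||% gem$gene_ids
    mito_genes <- gem$gene_ids[startsWith(names_for_match, mito_prefix)]
  }
  mito_genes <- intersect(mito_genes, gem$gene_ids)
  if (!length(mito_genes)) {
    abort("no mitochondrial genes found; cannot compute mito fraction",
      class = "scpoolr_validation_error"
    )
  }
  totals <- Matrix::rowSums(gem$counts)
  mito <- Matrix::rowSums(gem$counts[, mito_genes, drop = FALSE])
  frac <- unname(ifelse(totals > 0, mito / totals, NA_real_))
  tibble(
    cell_id = gem$cell_ids,
    mito_fraction = frac,
    pass = !is.na(frac) & frac <= threshold
  )
}

#' Flag cells with an outlying number of detected genes
#'
#' Computes a per-cell complexity metric (detected genes, i.e. genes with a
#' nonzero count, by default; total UMIs as an option) and fails cells lying
#' more than \code{k_sd} sample standard deviations above the mean.  The
#' filter is one-sided (high outliers are candidate multiplets) and the
#' statistics are computed once on the full input population, not
#' iteratively.
#'
#' @param gem A [gene_expression_matrix()].
#' @param k_sd Number of standard deviations defining an outlier (default 3).
#' @param metric \code{"detected_genes"} (default) or \code{"total_counts"}.
#' @return A tibble with columns \code{cell_id}, \code{metric}, \code{pass}.
#' @export
filter_gene_count_outliers <- function(gem, k_sd = 3,
                                       metric = c("detected_genes",
                                                  "total_counts")) {
  stopifnot(inherits(gem, "gene_expression_matrix"))
  metric <- match.arg(metric)
  if (nrow(gem$counts) < 2) {
    abort("outlier filter requires at least 2 cells",
      class = "scpoolr_validation_error"
    )
  }
  m <- if (metric == "detected_genes") {
    pos <- gem$counts
    pos@x <- as.numeric(pos@x > 0)
    Matrix::rowSums(pos)
  } else {
    Matrix::rowSums(gem$counts)
  }
  m <- unname(m)
  s <- sd(m)
  cutoff <- mean(m) + k_sd * s
  # sd == 0 (all cells identical) removes nothing
  pass <- if (s == 0) rep(TRUE, length(m)) else m <= cutoff
  tibble(cell_id = gem$cell_ids, metric = as.numeric(m), pass = pass)
}

#' Flag cells whose cluster label is irreproducible across batch runs
#'
#' A cell passes when at least \code{min_matches} of its per-batch-run
#' cluster labels agree with its total-dataset label.  Cells lacking
#' batch labels fail by default; set \code{missing = "pass"} to wave them
#' through with a warning.
#'
#' @param annotation An annotation tibble carrying \code{cluster} (the
#'   total-dataset label) and a \code{batch_labels} list-column of
#'   per-batch-run labels.
#' @param min_matches Minimum number of agreeing batch-run labels
#'   (default 2, i.e. the two-of-four rule).
#' @param missing How to treat cells with no batch labels: \code{"fail"}
#'   (default) or \code{"pass"}.
#' @return A tibble with columns \code{cell_id}, \code{n_matches},
#'   \code{pass}.
#' @export
filter_label_consistency <- function(annotation, min_matches = 2,
                                     missing = c("fail", "pass")) {
  missing <- match.arg(missing)
  if (!"batch_labels" %in% names(annotation)) {
    abort("annotation has no batch_labels column",
      class = "scpoolr_validation_error"
    )
  }
  total <- as.character(annotation$cluster)
  n_matches <- purrr::map2_int(
    annotation$batch_labels, total,
    function(labs, tot) {
      if (is.null(labs) || !length(labs)) return(NA_integer_)
      sum(as.character(labs) == tot)
    }
  )
  pass <- !is.na(n_matches) & n_matches >= min_matches
  if (anyNA(n_matches)) {
    if (missing == "pass") {
      warn(sprintf(
        "%d cell(s) have no batch labels; passing them through",
        sum(is.na(n_matches))
      ))
      pass[is.na(n_matches)] <- TRUE
    }
  }
  tibble(
    cell_id = as.character(annotation$cell_id),
    n_matches = n_matches, pass = pass
  )
}

#' Run all cell-level QC filters and tabulate removals
#'
#' Applies the mitochondrial-fraction, detected-gene outlier and (when
#' batch labels are available) label-consistency filters, each computed on
#' the original input population so the flags are order-independent.  A
#' removed cell is attributed to exactly one reason using the fixed order
#' mito, then outlier, then consistency.
#'
#' @inheritParams filter_mito
#' @inheritParams filter_gene_count_outliers
#' @param annotation A validated annotation tibble (see [cell_annotation()]);
#'   required for the consistency filter, otherwise optional.
#' @param min_matches Passed to [filter_label_consistency()].
#' @param missing Passed to [filter_label_consistency()].
#' @return An object of class \code{qc_report}: a list with \code{flags}
#'   (per-cell tibble of filter outcomes and first-failing reason) and
#'   \code{counts} (named removal tallies).  \code{tidy()} returns the
#'   flags, \code{glance()} the tallies.
#' @export
qc_cells <- function(gem, annotation = NULL, mito_genes = NULL,
                     threshold = 0.15, mito_prefix = "MT-", k_sd = 3,
                     metric = "detected_genes",
                     min_matches = 2, missing = "fail") {
  mito <- filter_mito(gem, mito_genes, threshold, mito_prefix)
  outl <- filter_gene_count_outliers(gem, k_sd, metric)
  cons <- if (!is.null(annotation) && "batch_labels" %in% names(annotation)) {
    filter_label_consistency(annotation, min_matches, missing)
  } else {
    tibble(cell_id = gem$cell_ids, n_matches = NA_integer_, pass = TRUE)
  }
  cons <- cons[match(gem$cell_ids, cons$cell_id), ]

  reason <- rep(NA_character_, length(gem$cell_ids))
  reason[!cons$pass] <- "consistency"
  reason[!outl$pass] <- "outlier"
  reason[!mito$pass] <- ifelse(
    is.na(mito$mito_fraction[!mito$pass]), "zero counts", "mito"
  )
  flags <- tibble(
    cell_id = gem$cell_ids,
    mito_fraction = mito$mito_fraction,
    pass_mito = mito$pass,
    pass_outlier = outl$pass,
    pass_consistency = cons$pass,
    retained = mito$pass & outl$pass & cons$pass,
    reason = reason
  )
  counts <- c(
    n_input = nrow(flags),
    n_removed_mito = sum(flags$reason %in% c("mito", "zero counts")),
    n_removed_outlier = sum(flags$reason %in% "outlier"),
    n_removed_consistency = sum(flags$reason %in% "consistency"),
    n_retained = sum(flags$retained)
  )
  structure(list(flags = flags, counts = counts), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n <- x$counts
  cat(sprintf(
    paste0(
      "<qc_report> %d cells: %d retained (%.1f%%); removed %d mito, ",
      "%d outlier, %d consistency\n"
    ),
    n[["n_input"]], n[["n_retained"]],
    100 * n[["n_retained"]] / n[["n_input"]],
    n[["n_removed_mito"]], n[["n_removed_outlier"]],
    n[["n_removed_consistency"]]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.qc_report <- function(x, ...) x$flags

#' @exportS3Method generics::glance
glance.qc_report <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' Subset a dataset to QC-retained cells
#'
#' @param gem A [gene_expression_matrix()].
#' @param annotation Matching annotation tibble.
#' @param report A \code{qc_report} from [qc_cells()].
#' @return A list with filtered \code{matrix} and \code{annotation}.
#' @export
apply_qc <- function(gem, annotation, report) {
  keep <- report$flags$cell_id[report$flags$retained]
  gem2 <- gene_expression_matrix(
    gem$counts[keep, , drop = FALSE], keep, gem$gene_ids, gem$gene_symbols
  )
  ann2 <- annotation[annotation$cell_id %in% keep, ]
  ann2 <- ann2[match(keep, ann2$cell_id), ]
  list(matrix = gem2, annotation = ann2)
}
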