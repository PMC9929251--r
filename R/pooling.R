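#' Randomly assign cells to fixed-size pseudocells
#'
#' Within each stratum — a (donor, stimulus, cluster) combination, i.e. one
#' sample and cell type — cells are shuffled uniformly at random and chunked
#' into \code{floor(n / k)} pseudocells of exactly \code{k} cells; the
#' \code{n mod k} leftover cells of that iteration are left unassigned.
#' Each iteration reshuffles independently, producing pseudo-replicates of
#' the pooling.
#'
#' @param annotation A validated annotation tibble with \code{cell_id},
#'   \code{donor}, \code{batch}, \code{stimulus}, \code{status},
#'   \code{cluster}.
#' @param k Pool size (cells per pseudocell), a positive integer.
#' @param iterations Number of independent pooling replicates (default 3).
#' @param seed Optional integer seed; when given, the draw is made from a
#'   locally seeded RNG stream and is fully reproducible.
#' @return A long tibble with one row per assigned cell: columns
#'   \code{pseudocell_id}, \code{cell_id}, \code{donor}, \code{batch},
#'   \code{stimulus}, \code{status}, \code{cluster}, \code{iteration},
#'   \code{pool_size}.  Pseudocell ids follow the deterministic scheme
#'   \code{<donor>_<stimulus>_<cluster>_k<k>_it<i>_p<j>}.
#' @export
assign_pseudocells <- function(annotation, k, iterations = 3, seed = NULL) {
  stopifnot(k >= 1, k == round(k), iterations >= 1)
  draw <- function() assign_pseudocells_impl(annotation, k, iterations)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

assign_pseudocells_impl <- function(annotation, k, iterations) {
  ann <- dplyr::mutate(
    as_tibble(annotation),
    donor = as.character(.data$donor),
    stimulus = as.character(.data$stimulus),
    cluster = as.character(.data$cluster)
  )
  strata <- dplyr::group_split(
    dplyr::arrange(ann, .data$donor, .data$stimulus, .data$cluster),
    .data$donor, .data$stimulus, .data$cluster
  )
  out <- vector("list", length(strata) * iterations)
  idx <- 1L
  for (it in seq_len(iterations)) {
    for (s in strata) {
      n <- nrow(s)
      n_pc <- n %/% k
      if (n_pc == 0) next
      perm <- sample.int(n)
      used <- perm[seq_len(n_pc * k)]
      assigned <- s[used, ]
      assigned$iteration <- it
      assigned$pool_size <- as.integer(k)
      assigned$pseudocell_id <- sprintf(
        "%s_%s_%s_k%d_it%d_p%d",
        assigned$donor, assigned$stimulus, assigned$cluster,
        k, it, rep(seq_len(n_pc), each = k)
      )
      out[[idx]] <- assigned
      idx <- idx + 1L
    }
  }
  out <- dplyr::bind_rows(out[seq_len(idx - 1L)])
  if (!nrow(out)) {
    return(tibble(
      pseudocell_id = character(), cell_id = character(),
      donor = character(), batch = character(), stimulus = character(),
      status = character(), cluster = character(),
      iteration = integer(), pool_size = integer()
    ))
  }
  dplyr::select(
    out, "pseudocell_id", "cell_id", "donor", "batch", "stimulus",
    "status", "cluster", "iteration", "pool_size"
  )
}

#' Sum member-cell counts into raw pseudocell counts
#'
#' For every pseudocell, the counts of its member cells are summed per gene,
#' yielding an integer pseudo-bulk matrix.
#'
#' @param gem A [gene_expression_matrix()].
#' @param assignments Long assignment tibble from [assign_pseudocells()]
#'   (a single iteration; see [run_scpool()] for the full sweep).
#' @return A sparse pseudocells-by-genes matrix of summed counts with
#'   pseudocell ids as rownames.
#' @export
aggregate_counts <- function(gem, assignments) {
  stopifnot(inherits(gem, "gene_expression_matrix"))
  unknown <- setdiff(assignments$cell_id, gem$cell_ids)
  if (length(unknown)) {
    abort(sprintf(
      "assignment references cell(s) absent from the matrix (first: %s)",
      unknown[[1]]
    ), class = "scpoolr_validation_error")
  }
  pc_ids <- unique(assignments$pseudocell_id)
  ind <- Matrix::sparseMatrix(
    i = match(assignments$pseudocell_id, pc_ids),
    j = match(assignments$cell_id, gem$cell_ids),
    x = 1,
    dims = c(length(pc_ids), nrow(gem$counts))
  )
  raw <- ind %*% gem$counts
  raw <- as(as(raw, "CsparseMatrix"), "generalMatrix")
  dimnames(raw) <- list(pc_ids, gem$gene_ids)
  raw
}

#' Normalize pseudocell counts to counts per 100,000
#'
#' Divides each pseudocell row by its total count and multiplies by 1e5, so
#' that every row sums to exactly 100,000 (up to floating point).
#'
#' @param raw Sparse pseudocells-by-genes matrix of summed counts.
#' @return Matrix of the same shape on the CP100K scale.
#' @export
normalize_cp100k <- function(raw) {
  totals <- Matrix::rowSums(raw)
  if (any(totals <= 0)) {
    abort(sprintf(
      "%d pseudocell(s) have zero total counts; upstream QC should prevent this",
      sum(totals <= 0)
    ), class = "scpoolr_validation_error")
  }
  cp <- Matrix::Diagonal(x = 1e5 / totals) %*% raw
  dimnames(cp) <- dimnames(raw)
  cp
}

new_pseudocell_matrix <- function(raw, cp100k, factors, assignments) {
  structure(
    list(
      raw = raw, cp100k = cp100k, factors = factors,
      assignments = assignments, gene_ids = colnames(raw)
    ),
    class = "pseudocell_matrix"
  )
}

#' @export
print.pseudocell_matrix <- function(x, ...) {
  cat(sprintf(
    "<pseudocell_matrix> %d pseudocells x %d genes (k = %s, iteration %s)\n",
    nrow(x$raw), ncol(x$raw),
    paste(unique(x$factors$pool_size), collapse = ","),
    paste(unique(x$factors$iteration), collapse = ",")
  ))
  invisible(x)
}

build_pseudocell_matrix <- function(gem, assignments) {
  raw <- aggregate_counts(gem, assignments)
  cp <- normalize_cp100k(raw)
  factors <- dplyr::distinct(
    assignments, .data$pseudocell_id, .data$donor, .data$batch,
    .data$stimulus, .data$status, .data$cluster, .data$iteration,
    .data$pool_size
  )
  factors <- factors[match(rownames(raw), factors$pseudocell_id), ]
  new_pseudocell_matrix(raw, cp, factors, assignments)
}

#' Run the full pseudocell pooling sweep
#'
#' Pools a QC-filtered dataset at every requested pool size, independently
#' re-drawing the random partition for each of \code{iterations} replicates,
#' and returns one pseudocell matrix per (size, iteration) pair.  Clusters
#' too small to support a pseudocell at a given size are simply absent from
#' that matrix.
#'
#' @param gem A [gene_expression_matrix()] (QC already applied).
#' @param annotation Matching validated annotation tibble.
#' @param sizes Pool sizes to sweep (default \code{c(5, 10, 15, 20)}).
#' @param iterations Pooling replicates per size (default 3).
#' @param seed Integer seed governing all random assignment draws.
#' @return A tibble with columns \code{pool_size}, \code{iteration} and a
#'   list-column \code{pm} of \code{pseudocell_matrix} objects.
#' @export
run_scpool <- function(gem, annotation, sizes = c(5, 10, 15, 20),
                       iterations = 3, seed = NULL) {
  draw <- function() {
    purrr::map(sizes, function(k) {
      assign_pseudocells_impl(annotation, k, iterations)
    })
  }
  all_assign <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  grid <- tidyr::expand_grid(
    pool_size = as.integer(sizes), iteration = seq_len(iterations)
  )
  grid$pm <- purrr::pmap(grid, function(pool_size, iteration) {
    a <- all_assign[[match(pool_size, as.integer(sizes))]]
    a <- a[a$iteration == iteration, ]
    if (!nrow(a)) return(NULL)
    build_pseudocell_matrix(gem, a)
  })
  grid
}

#' Restrict a pseudocell matrix to one cell type
#'
#' @param pm A \code{pseudocell_matrix}.
#' @param cell_type Cluster label to keep.
#' @return A \code{pseudocell_matrix} containing only that cluster's
#'   pseudocells.
#' @export
subset_pseudocells <- function(pm, cell_type) {
  stopifnot(inherits(pm, "pseudocell_matrix"))
  keep <- pm$factors$pseudocell_id[pm$factors$cluster == cell_type]
  if (!length(keep)) {
    abort(sprintf("cell type '%s' absent from pseudocell matrix", cell_type),
      class = "scpoolr_validation_error"
    )
  }
  new_pseudocell_matrix(
    pm$raw[keep, , drop = FALSE],
    pm$cp100k[keep, , drop = FALSE],
    pm$factors[pm$factors$pseudocell_id %in% keep, ],
    pm$assignments[pm$assignments$pseudocell_id %in% keep, ]
  )
}
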