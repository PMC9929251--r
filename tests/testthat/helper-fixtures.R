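# deterministic toy objects used across test files

toy_counts <- function(m) {
  gene_expression_matrix(
    Matrix::Matrix(m, sparse = TRUE),
    cell_ids = sprintf("c%d", seq_len(nrow(m))),
    gene_ids = sprintf("g%d", seq_len(ncol(m)))
  )
}

# n cells of one donor/stimulus/cluster stratum
toy_annotation <- function(n, donor = "J01", stimulus = "TNF",
                           status = "JIA", batch = 1, cluster = "T",
                           prefix = "c") {
  tibble::tibble(
    cell_id = sprintf("%s%d", prefix, seq_len(n)),
    donor = donor, batch = batch, stimulus = stimulus,
    status = status, cluster = cluster
  )
}

# random sparse count matrix plus matching multi-stratum annotation
random_dataset <- function(n_cells = 60, n_genes = 30, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_cells * n_genes, 2), n_cells, n_genes)
    m[sample(length(m), length(m) * 0.5)] <- 0
    m[, 1] <- m[, 1] + 1 # avoid all-zero cells
    gem <- toy_counts(m)
    ann <- tibble::tibble(
      cell_id = gem$cell_ids,
      donor = rep(c("J01", "J02", "C01", "C02"), length.out = n_cells),
      stimulus = rep(c("TNF", "Null"), each = 2, length.out = n_cells),
      cluster = rep(c("T", "NK"), length.out = n_cells)
    )
    ann$batch <- ifelse(ann$donor %in% c("J01", "J02"), 1, 2)
    ann$status <- ifelse(startsWith(ann$donor, "J"), "JIA", "Control")
    list(gem = gem, annotation = cell_annotation(ann, gem))
  })
}

gzip_in_place <- function(path) {
  raw_lines <- readLines(path)
  con <- gzfile(paste0(path, ".gz"), "w")
  writeLines(raw_lines, con)
  close(con)
  unlink(path)
}
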