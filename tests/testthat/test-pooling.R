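test_that("a 63-cell stratum yields floor(n/k) pseudocells of exactly k cells", {
  ann <- toy_annotation(63)
  expected <- c(`5` = 12L, `10` = 6L, `15` = 4L, `20` = 3L)
  for (k in c(5, 10, 15, 20)) {
    a <- assign_pseudocells(ann, k = k, iterations = 1, seed = 1)
    expect_equal(length(unique(a$pseudocell_id)), unname(expected[as.character(k)]))
    expect_true(all(table(a$pseudocell_id) == k))
    expect_equal(nrow(a), (63 %/% k) * k) # leftovers unassigned
  }
})

test_that("strata smaller than the pool size yield zero pseudocells", {
  a <- assign_pseudocells(toy_annotation(4), k = 5, iterations = 2, seed = 1)
  expect_equal(nrow(a), 0)
})

test_that("assignments are disjoint partitions within each stratum and iteration", {
  ds <- random_dataset(n_cells = 80, seed = 3)
  a <- assign_pseudocells(ds$annotation, k = 3, iterations = 3, seed = 5)
  grp <- dplyr::group_by(a, donor, stimulus, cluster, iteration)
  per <- dplyr::summarise(
    grp,
    n_assigned = dplyr::n(),
    n_unique = dplyr::n_distinct(cell_id),
    n_pc = dplyr::n_distinct(pseudocell_id),
    .groups = "drop"
  )
  expect_true(all(per$n_assigned == per$n_unique)) # no cell in two pools
  expect_true(all(per$n_assigned == per$n_pc * 3))
  # member cells share the pseudocell's stratum by construction of the id
  expect_true(all(startsWith(
    a$pseudocell_id, paste(a$donor, a$stimulus, a$cluster, sep = "_")
  )))
})

test_that("pseudocell counts per stratum match floor(n/k) for the annotation", {
  ds <- random_dataset(n_cells = 70, seed = 8)
  sizes <- table(paste(ds$annotation$donor, ds$annotation$stimulus,
                       ds$annotation$cluster))
  a <- assign_pseudocells(ds$annotation, k = 4, iterations = 1, seed = 2)
  got <- table(paste(a$donor, a$stimulus, a$cluster)) / 4
  for (s in names(got)) {
    expect_equal(unname(got[s]), unname(floor(sizes[s] / 4)))
  }
})

test_that("permuting cell order changes membership but never pool counts", {
  ds <- random_dataset(n_cells = 50, seed = 12)
  a1 <- assign_pseudocells(ds$annotation, k = 3, iterations = 1, seed = 9)
  perm <- withr::with_seed(1, ds$annotation[sample.int(nrow(ds$annotation)), ])
  a2 <- assign_pseudocells(perm, k = 3, iterations = 1, seed = 9)
  expect_equal(sort(unique(a1$pseudocell_id)), sort(unique(a2$pseudocell_id)))
})

test_that("aggregation sums member-cell counts and conserves totals", {
  # 5 cells each with count 2 for one gene -> pseudocell value 10
  gem <- toy_counts(matrix(2, 5, 1))
  a <- assign_pseudocells(toy_annotation(5), k = 5, iterations = 1, seed = 1)
  raw <- aggregate_counts(gem, a)
  expect_equal(unname(raw[1, 1]), 10)

  # row total equals the sum of member-cell totals
  set.seed(6)
  m <- matrix(rpois(5 * 4, 3), 5, 4)
  m <- m * (rowSums(m) > 0) + (rowSums(m) == 0) # guard all-zero cells
  gem2 <- toy_counts(m)
  raw2 <- aggregate_counts(gem2, a)
  expect_equal(unname(Matrix::rowSums(raw2)), sum(m))

  # all-zero member cells give an all-zero pseudocell row
  gem3 <- toy_counts(matrix(0, 5, 2))
  raw3 <- aggregate_counts(gem3, a)
  expect_equal(sum(raw3), 0)

  bad <- a
  bad$cell_id[1] <- "ghost"
  expect_error(aggregate_counts(gem, bad), "ghost")
})

test_that("CP100K rows are forced to sum to 100,000", {
  raw <- Matrix::Matrix(rbind(
    c(1, 1, 2),
    c(25000, 25000, 50000),
    c(3, 0, 0)
  ), sparse = TRUE)
  rownames(raw) <- c("p1", "p2", "p3")
  colnames(raw) <- c("g1", "g2", "g3")
  cp <- normalize_cp100k(raw)
  expect_equal(unname(as.matrix(cp)[1, ]), c(25000, 25000, 50000))
  expect_equal(unname(as.matrix(cp)[2, ]), c(25000, 25000, 50000))
  expect_equal(unname(as.matrix(cp)[3, ]), c(1e5, 0, 0))
  expect_error(
    normalize_cp100k(Matrix::Matrix(rbind(c(1, 1), c(0, 0)), sparse = TRUE)),
    "zero total"
  )
})

test_that("run_scpool produces one matrix per size and iteration, reproducibly", {
  ds <- random_dataset(n_cells = 80, seed = 10)
  res <- run_scpool(ds$gem, ds$annotation, sizes = c(5, 20), iterations = 3,
                    seed = 33)
  expect_equal(nrow(res), 6)
  expect_equal(sort(unique(res$pool_size)), c(5L, 20L))

  res2 <- run_scpool(ds$gem, ds$annotation, sizes = c(5, 20), iterations = 3,
                     seed = 33)
  for (i in seq_len(nrow(res))) {
    if (is.null(res$pm[[i]])) {
      expect_null(res2$pm[[i]])
    } else {
      expect_identical(as.matrix(res$pm[[i]]$raw), as.matrix(res2$pm[[i]]$raw))
      expect_identical(res$pm[[i]]$assignments, res2$pm[[i]]$assignments)
    }
  }

  # conservation: pooled counts never exceed the cell total
  total_cells <- sum(ds$gem$counts)
  for (pm in res$pm) {
    if (is.null(pm)) next
    expect_lte(sum(pm$raw), total_cells)
    # per-pseudocell totals equal the sum of member cell totals
    member_totals <- Matrix::rowSums(ds$gem$counts)[pm$assignments$cell_id]
    expected <- tapply(member_totals, pm$assignments$pseudocell_id, sum)
    got <- Matrix::rowSums(pm$raw)
    expect_equal(as.numeric(got[names(expected)]), as.numeric(expected))
  }
})

test_that("equal-sized strata divisible by k conserve every count", {
  # 2 strata of 6 cells each, k = 3 divides both: nothing discarded
  gem <- toy_counts(matrix(rpois(12 * 3, 3) + 1, 12, 3))
  ann <- dplyr::bind_rows(
    toy_annotation(6),
    dplyr::mutate(toy_annotation(6, prefix = "d"), cluster = "NK")
  )
  ann$cell_id <- gem$cell_ids
  a <- assign_pseudocells(ann, k = 3, iterations = 1, seed = 4)
  raw <- aggregate_counts(gem, a)
  expect_equal(sum(raw), sum(gem$counts))
})
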