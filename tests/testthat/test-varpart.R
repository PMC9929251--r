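# build a pseudocell matrix with exact CP100K values by using 1-cell pools
# on rows whose totals are chosen to make the normalization land on the
# target values
cp_fixture <- function() {
  counts <- rbind(
    c(10, 5, 0, 999985),
    c(10, 5, 0, 999985),
    c(10, 5, 33, 999952)
  ) # row totals 1e6 -> cp100k = counts / 10
  gem <- gene_expression_matrix(
    Matrix::Matrix(counts, sparse = TRUE),
    sprintf("c%d", 1:3), c("gA", "gB", "gC", "filler")
  )
  ann <- toy_annotation(3)
  res <- run_scpool(gem, ann, sizes = 1, iterations = 1, seed = 1)
  res$pm[[1]]
}

test_that("expressed-gene filter is inclusive at mean CP100K of 1", {
  pm <- cp_fixture()
  genes <- filter_expressed_genes(pm)
  # gA: (1,1,1) mean 1 -> kept; gB: (0.5,...) -> dropped; gC: (0,0,3.3) kept
  expect_true("gA" %in% genes)
  expect_false("gB" %in% genes)
  expect_true("gC" %in% genes)
})

test_that("expression transform maps CP100K of 0 and 1 correctly", {
  pm <- cp_fixture()
  lg <- transform_expression(pm, "log2p1")
  expect_equal(unname(lg[, "gA"]), rep(1, 3)) # log2(1 + 1) = 1
  expect_equal(unname(lg[1, "gC"]), 0)        # log2(0 + 1) = 0
  raw <- transform_expression(pm, "raw")
  expect_equal(unname(raw[, "gB"]), rep(0.5, 3))
})

test_that("constant expression yields the degenerate residual-only record", {
  fa <- tibble::tibble(
    stimulus = rep(c("TNF", "Null"), 10),
    status = "JIA", batch = 1,
    donor = rep(c("d1", "d2"), each = 10)
  )
  vc <- fit_variance_components(rep(3, 20), fa)
  expect_false(vc$converged)
  expect_equal(unname(vc$fraction[["Residual"]]), 1)
  expect_equal(sum(vc$sigma2), 0)
})

test_that("REML and MoM agree with the closed-form EMS oracle on balanced designs", {
  sim <- simulate_pseudocell_expression(
    20, c(donor = 0.4, stimulus = 0.2), n_donors = 6, n_control = 0,
    n_batches = 1, pseudocells_per_sample = 8, seed = 31
  )
  n_checked <- 0
  for (g in seq_len(20)) {
    y <- sim$expr[, g]
    ems <- ems_two_way(y, sim$factors$donor, sim$factors$stimulus)
    if (any(ems <= 0)) next # oracle equivalence holds on interior estimates
    n_checked <- n_checked + 1
    reml <- fit_variance_components(y, sim$factors)
    mom <- fit_variance_components(y, sim$factors, method = "MoM")
    got_reml <- unname(reml$sigma2[c("Donor", "Stimulus", "Residual")])
    got_mom <- unname(mom$sigma2[c("Donor", "Stimulus", "Residual")])
    expect_equal(got_reml, unname(ems), tolerance = 1e-6)
    expect_equal(got_mom, unname(ems), tolerance = 1e-10)
  }
  expect_gte(n_checked, 5)
})

test_that("fractions lie in [0,1] and sum to one across random fits", {
  sim <- simulate_pseudocell_expression(
    30, c(donor = 0.3, batch = 0.1), n_donors = 8, n_control = 2,
    n_batches = 4, pseudocells_per_sample = 4, seed = 77
  )
  for (g in seq_len(30)) {
    vc <- fit_variance_components(sim$expr[, g], sim$factors, method = "MoM")
    expect_true(all(vc$fraction >= 0 & vc$fraction <= 1))
    expect_equal(sum(vc$fraction), 1, tolerance = 1e-9)
  }
})

test_that("pure noise attributes almost all variance to the residual", {
  sim <- simulate_pseudocell_expression(
    200, c(donor = 0), n_donors = 8, n_control = 0, n_batches = 1,
    pseudocells_per_sample = 10, seed = 41
  )
  donor_fracs <- vapply(seq_len(200), function(g) {
    vc <- fit_variance_components(sim$expr[, g], sim$factors, method = "MoM")
    vc$fraction[["Donor"]]
  }, numeric(1))
  expect_lte(mean(donor_fracs), 0.1)
})

test_that("partition_cell_type matches gene-by-gene fits and summarizes them", {
  ds <- random_dataset(n_cells = 120, n_genes = 15, seed = 19)
  res <- run_scpool(ds$gem, ds$annotation, sizes = 5, iterations = 1,
                    seed = 3)
  pm <- res$pm[[1]]
  vp <- partition_cell_type(pm, "T")
  expect_s3_class(vp, "scpool_varpart")
  expect_true(all(vp$results$fraction >= 0 & vp$results$fraction <= 1))
  sums <- tapply(vp$results$fraction, vp$results$gene_id, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-8)

  # independent-fit contract: the batched path (template refits) equals
  # fitting each gene on its own
  sub <- subset_pseudocells(pm, "T")
  genes <- filter_expressed_genes(sub)
  expr <- transform_expression(sub, genes = genes)
  for (g in sample(genes, 3)) {
    solo <- fit_variance_components(expr[, g], sub$factors)
    batched <- vp$results[vp$results$gene_id == g, ]
    expect_equal(
      batched$fraction[match(names(solo$fraction), batched$effect)],
      unname(solo$fraction),
      tolerance = 1e-6
    )
  }

  # summary arithmetic over the expressed genes
  donor_rows <- vp$results[vp$results$effect == "Donor", ]
  s <- vp$summary[vp$summary$effect == "Donor", ]
  expect_equal(s$mean_fraction, mean(donor_rows$fraction))
  expect_equal(s$frac_genes_gt5, mean(donor_rows$fraction > 0.05))
  expect_equal(s$n_genes, nrow(donor_rows))
})

test_that("gene ranking orders by fraction with variance then id tie-breaks", {
  res <- tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    effect = "Donor",
    variance = c(1, 3, 2, 1),
    fraction = c(0.3, 0.7, 0.5, 0.5)
  )
  expect_equal(rank_genes(res, "Donor", top_k = 1), "gB")
  # tie at 0.5: higher raw variance first
  expect_equal(rank_genes(res, "Donor", top_k = 3), c("gB", "gC", "gD"))
  # k beyond the gene count returns the full sorted list
  expect_equal(length(rank_genes(res, "Donor", top_k = 100)), 4)
  expect_error(rank_genes(res, "Stimulus"), "unknown effect")

  tie <- tibble::tibble(
    gene_id = c("gB", "gA"), effect = "Donor",
    variance = c(1, 1), fraction = c(0.5, 0.5)
  )
  expect_equal(rank_genes(tie, "Donor"), c("gA", "gB")) # lexicographic
})

test_that("a cell type with no expressed genes warns and returns empty results", {
  pm <- cp_fixture()
  expect_warning(
    vp <- partition_cell_type(pm, "T", min_mean_cp100k = 1e7),
    "no expressed genes"
  )
  expect_equal(nrow(vp$results), 0)
  expect_error(partition_cell_type(pm, "missing_type"), "absent")
})
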