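small_blocks <- function(...) {
  defaults <- list(
    n_genes = 20, frac_donor = 0, frac_stimulus = 0, frac_status = 0,
    frac_batch = 0, frac_interaction = 0, total_var = 1,
    base_log2_mean = 3, base_log2_sd = 0, dispersion = 2
  )
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

test_that("identical seeds reproduce the dataset bit for bit", {
  cfg <- simulation_config(
    n_cell_types = 2, cells_per_sample = 30, gene_blocks = small_blocks()
  )
  s1 <- simulate_dataset(cfg, seed = 42)
  s2 <- simulate_dataset(cfg, seed = 42)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(s1$annotation, s2$annotation)
  s3 <- simulate_dataset(cfg, seed = 43)
  expect_false(identical(as.matrix(s1$matrix$counts),
                         as.matrix(s3$matrix$counts)))
})

test_that("infeasible effect fractions are rejected", {
  expect_error(
    simulation_config(gene_blocks = small_blocks(frac_donor = 0.8,
                                                 frac_stimulus = 0.3)),
    "sum to at most 1"
  )
  expect_error(simulation_config(n_case = 5), "n_case")
  expect_error(simulation_config(n_batches = 3), "divide")
  expect_error(
    simulate_pseudocell_expression(5, c(donor = 0.7, batch = 0.5)),
    "sum to at most 1"
  )
})

test_that("the ground-truth record reproduces every generative mean", {
  cfg <- simulation_config(
    n_donors = 2, n_case = 1, n_control = 1, n_batches = 2,
    n_cell_types = 1, cells_per_sample = 1,
    gene_blocks = small_blocks(n_genes = 2, frac_donor = 0.3,
                               frac_stimulus = 0.1, base_log2_sd = 1),
    reference_pool_size = 10
  )
  sim <- simulate_dataset(cfg, seed = 7)
  truth <- sim$truth
  mu <- expected_counts(truth)
  # recompute one entry by hand from the recorded components
  g <- truth$gene_truth
  for (gi in 1:2) {
    for (si in seq_len(nrow(truth$samples))) {
      s <- truth$samples[si, ]
      manual <- exp(
        g$base_log2_mean[gi] * log(2) -
          ((g$frac_donor[gi] + g$frac_stimulus[gi] + g$frac_status[gi] +
              g$frac_batch[gi] + g$frac_interaction[gi]) *
             g$total_var_ln[gi] + g$cell_noise_var[gi]) / 2 +
          truth$effects$donor[s$donor, gi] +
          truth$effects$stimulus[s$stimulus, gi] +
          truth$effects$status[s$status, gi] +
          truth$effects$batch[as.character(s$batch), gi] +
          truth$effects$interaction[paste(s$stimulus, s$status, sep = "."), gi] +
          g$cell_noise_var[gi] / 2
      )
      expect_equal(unname(mu[s$sample_id, gi]), manual)
    }
  }
})

test_that("marginal count moments match the configured NB at large n", {
  # one sample, no effects, no log-noise: counts are pure NB(mu, size)
  cfg <- simulation_config(
    n_donors = 1, n_case = 1, n_control = 0, n_batches = 1,
    n_cell_types = 1, cells_per_sample = 10000,
    gene_blocks = small_blocks(n_genes = 4, total_var = 0,
                               base_log2_mean = 3, dispersion = 2)
  )
  sim <- simulate_dataset(cfg, seed = 99)
  x <- as.matrix(sim$matrix$counts[sim$annotation$stimulus == "TNF", ])
  mu_hat <- colMeans(x)
  expect_equal(unname(mu_hat), rep(8, 4), tolerance = 0.05)
  # method-of-moments dispersion: size = mu^2 / (var - mu)
  size_hat <- mu_hat^2 / (apply(x, 2, var) - mu_hat)
  expect_equal(unname(size_hat), rep(2, 4), tolerance = 0.25)
})

test_that("donor effects propagate through pooling into variance fractions", {
  cfg <- simulation_config(
    n_donors = 8, n_case = 8, n_control = 0, n_batches = 1,
    n_cell_types = 1, cells_per_sample = 60,
    gene_blocks = small_blocks(n_genes = 60, frac_donor = 0.5,
                               base_log2_mean = 5, base_log2_sd = 0.5,
                               dispersion = 10),
    reference_pool_size = 5
  )
  sim <- simulate_dataset(cfg, seed = 13)
  res <- run_scpool(sim$matrix, sim$annotation, sizes = 5, iterations = 1,
                    seed = 14)
  vp <- partition_cell_type(res$pm[[1]], "type01", method = "MoM")
  donor_mean <- vp$summary$mean_fraction[vp$summary$effect == "Donor"]
  expect_gt(donor_mean, 0.3)
  null_cfg <- simulation_config(
    n_donors = 8, n_case = 8, n_control = 0, n_batches = 1,
    n_cell_types = 1, cells_per_sample = 60,
    gene_blocks = small_blocks(n_genes = 60, base_log2_mean = 5,
                               base_log2_sd = 0.5, dispersion = 10),
    reference_pool_size = 5
  )
  sim0 <- simulate_dataset(null_cfg, seed = 13)
  res0 <- run_scpool(sim0$matrix, sim0$annotation, sizes = 5, iterations = 1,
                     seed = 14)
  vp0 <- partition_cell_type(res0$pm[[1]], "type01", method = "MoM")
  donor_null <- vp0$summary$mean_fraction[vp0$summary$effect == "Donor"]
  expect_lt(donor_null, donor_mean)
})

test_that("QC corruption hooks plant detectable defects", {
  cfg <- simulation_config(
    n_cell_types = 2, cells_per_sample = 40,
    gene_blocks = small_blocks(n_genes = 30, base_log2_mean = 2),
    n_mito_genes = 3, frac_high_mito = 0.1,
    simulate_batch_labels = TRUE, frac_inconsistent_labels = 0.05
  )
  sim <- simulate_dataset(cfg, seed = 55)
  expect_true(any(startsWith(sim$matrix$gene_symbols, "MT-")))
  rep <- qc_cells(sim$matrix, sim$annotation)
  flags <- rep$flags
  # the planted high-mito cells fail the mito filter
  planted <- flags$cell_id %in% sim$truth$high_mito_cells
  expect_true(all(!flags$pass_mito[planted]))
  # the planted inconsistent cells fail the 2-of-4 rule
  bad <- flags$cell_id %in% sim$truth$inconsistent_cells
  expect_true(all(!flags$pass_consistency[bad]))
  expect_true(all(flags$pass_consistency[!bad]))
})

test_that("simulated proportion tables are valid and truth-consistent", {
  cfg <- simulation_config(n_cell_types = 5, cells_per_sample = 500)
  sim <- simulate_proportions(cfg, seed = 3)
  pt <- sim$proportions
  type_cols <- setdiff(names(pt), c("sample_id", "donor", "stimulus",
                                    "status", "batch", "n_cells"))
  expect_equal(length(type_cols), 5)
  expect_equal(unname(rowSums(pt[type_cols])), rep(1, nrow(pt)))
  expect_equal(nrow(pt), 16)
  expect_equal(unname(rowSums(sim$truth$probs)), rep(1, 16), tolerance = 1e-12)
  sim2 <- simulate_proportions(cfg, seed = 3)
  expect_identical(pt, sim2$proportions)
})

test_that("pseudocell-level simulator realizes the requested design shape", {
  sim <- simulate_pseudocell_expression(
    10, c(donor = 0.5), n_donors = 4, n_control = 2, n_batches = 2,
    pseudocells_per_sample = 3, seed = 2
  )
  expect_equal(dim(sim$expr), c(4 * 2 * 3, 10))
  expect_equal(dplyr::n_distinct(sim$factors$donor), 4)
  expect_equal(dplyr::n_distinct(sim$factors$status), 2)
  expect_equal(dplyr::n_distinct(sim$factors$batch), 2)
  # per-gene variance is near the configured total
  v <- apply(sim$expr, 2, var)
  expect_equal(mean(v), 1, tolerance = 0.5)
})
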