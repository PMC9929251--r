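#' Configuration for the synthetic single-cell experiment generator
#'
#' Describes a crossed stimulation experiment of the kind the pooling
#' pipeline targets: a set of donors split into cases and controls,
#' processed in batches of equal size, each donor cultured under every
#' stimulus.  Defaults mirror the motivating study design: 8 donors (6
#' cases, 2 controls), 4 batches of 2 donors, TNF vs unstimulated
#' cultures, 17 cell types, about 2,900 cells per sample, and 2,000 genes.
#'
#' Gene-level effect sizes are specified as fractions of a total log-scale
#' expression variance, so that variance-partition recovery targets are
#' directly the configured inputs.  The residual fraction is the
#' complement and is realized as per-cell log-normal noise calibrated so
#' that, after pooling \code{reference_pool_size} cells, the pseudocell
#' residual variance matches the configured fraction (cell-level noise
#' averages out under pooling; the calibration inverts that).
#'
#' @param n_donors,n_case,n_control Donor counts; cases and controls must
#'   sum to the donor total.
#' @param n_batches Number of processing batches; must divide
#'   \code{n_donors}.
#' @param stimuli Two stimulus labels, stimulated first.
#' @param n_cell_types Number of cell types.
#' @param cells_per_sample Expected cells per sample (Poisson-dispersed).
#' @param n_genes Total genes when \code{gene_blocks} is left at default.
#' @param gene_blocks Tibble describing blocks of genes sharing effect-size
#'   settings: columns \code{n_genes}, \code{frac_donor},
#'   \code{frac_stimulus}, \code{frac_status}, \code{frac_batch},
#'   \code{frac_interaction}, \code{total_var} (log2-scale variance),
#'   \code{base_log2_mean}, \code{base_log2_sd}, \code{dispersion}
#'   (negative binomial size).
#' @param reference_pool_size Pool size at which the residual calibration
#'   is exact (default 10).
#' @param baseline_proportions Cell-type baseline proportions (default: a
#'   geometric decay spanning roughly a 19-fold abundance range,
#'   normalized).
#' @param prop_stimulus_shift,prop_status_shift,prop_interaction_shift
#'   Logit-scale shifts of cell-type proportions (scalar or one value per
#'   cell type).
#' @param prop_donor_sd,prop_batch_sd Logit-scale standard deviations of
#'   donor and batch effects on proportions.
#' @param n_mito_genes Number of genes designated mitochondrial
#'   (symbols \code{MT-*}); 0 disables the QC corruption hooks.
#' @param frac_high_mito Fraction of cells given an inflated mitochondrial
#'   load (a QC corruption, not biology).
#' @param simulate_batch_labels Attach per-batch-run cluster labels (for
#'   the label-consistency filter)?
#' @param frac_inconsistent_labels Fraction of cells whose batch-run labels
#'   disagree with the total-dataset label in all but one run.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(n_donors = 8, n_case = 6, n_control = 2,
                              n_batches = 4,
                              stimuli = c("TNF", "Null"),
                              n_cell_types = 17,
                              cells_per_sample = 2900,
                              n_genes = 2000,
                              gene_blocks = NULL,
                              reference_pool_size = 10,
                              baseline_proportions = NULL,
                              prop_stimulus_shift = 0,
                              prop_status_shift = 0,
                              prop_interaction_shift = 0,
                              prop_donor_sd = 0.15,
                              prop_batch_sd = 0.05,
                              n_mito_genes = 0,
                              frac_high_mito = 0,
                              simulate_batch_labels = FALSE,
                              frac_inconsistent_labels = 0) {
  if (n_case + n_control != n_donors) {
    abort("n_case + n_control must equal n_donors",
      class = "scpoolr_validation_error"
    )
  }
  if (n_batches >= 1 && n_donors %% n_batches != 0) {
    abort("n_batches must divide n_donors",
      class = "scpoolr_validation_error"
    )
  }
  if (is.null(gene_blocks)) {
    gene_blocks <- tibble(
      n_genes = n_genes,
      frac_donor = 0.05, frac_stimulus = 0.02, frac_status = 0.005,
      frac_batch = 0.01, frac_interaction = 0.005,
      total_var = 1, base_log2_mean = 1, base_log2_sd = 1.5,
      dispersion = 2
    )
  }
  gene_blocks <- as_tibble(gene_blocks)
  frac_cols <- c("frac_donor", "frac_stimulus", "frac_status",
                 "frac_batch", "frac_interaction")
  fsum <- rowSums(gene_blocks[frac_cols])
  if (any(gene_blocks[frac_cols] < 0) || any(fsum > 1)) {
    abort("effect variance fractions must be >= 0 and sum to at most 1",
      class = "scpoolr_validation_error"
    )
  }
  if (is.null(baseline_proportions)) {
    w <- exp(-log(19) / max(n_cell_types - 1, 1) *
               (seq_len(n_cell_types) - 1))
    baseline_proportions <- w / sum(w)
  }
  if (length(baseline_proportions) != n_cell_types) {
    abort("baseline_proportions must have one entry per cell type",
      class = "scpoolr_validation_error"
    )
  }
  expand <- function(x) {
    if (length(x) == 1) rep(x, n_cell_types) else x
  }
  structure(
    list(
      n_donors = n_donors, n_case = n_case, n_control = n_control,
      n_batches = n_batches, stimuli = stimuli,
      n_cell_types = n_cell_types, cells_per_sample = cells_per_sample,
      gene_blocks = gene_blocks,
      reference_pool_size = reference_pool_size,
      baseline_proportions = baseline_proportions / sum(baseline_proportions),
      prop_stimulus_shift = expand(prop_stimulus_shift),
      prop_status_shift = expand(prop_status_shift),
      prop_interaction_shift = expand(prop_interaction_shift),
      prop_donor_sd = prop_donor_sd, prop_batch_sd = prop_batch_sd,
      n_mito_genes = n_mito_genes, frac_high_mito = frac_high_mito,
      simulate_batch_labels = simulate_batch_labels,
      frac_inconsistent_labels = frac_inconsistent_labels
    ),
    class = "simulation_config"
  )
}

make_donor_map <- function(n_donors, n_control, n_batches) {
  n_case <- n_donors - n_control
  donors <- c(
    if (n_case > 0) sprintf("J%02d", seq_len(n_case)),
    if (n_control > 0) sprintf("C%02d", seq_len(n_control))
  )
  status <- c(rep("JIA", n_case), rep("Control", n_control))
  nb <- max(n_batches, 1)
  tibble(
    donor = donors, status = status,
    batch = as.integer(rep(seq_len(nb), each = n_donors %/% nb))
  )
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# residual calibration: cell-level log-normal noise of variance v averages
# out under pooling of k cells; v is chosen so the pooled log variance
# matches the target t (moment matching of the mean of log-normals)
cell_noise_variance <- function(t, k) {
  if (t <= 0) return(0)
  log(1 + k * (exp(t) - 1))
}

sample_cell_types <- function(cfg, donor_map, samples, n_cells, truth_env) {
  types <- sprintf("type%02d", seq_len(cfg$n_cell_types))
  donor_eff <- matrix(
    rnorm(cfg$n_donors * cfg$n_cell_types, 0, cfg$prop_donor_sd),
    cfg$n_donors, cfg$n_cell_types,
    dimnames = list(donor_map$donor, types)
  )
  batch_eff <- matrix(
    rnorm(cfg$n_batches * cfg$n_cell_types, 0, cfg$prop_batch_sd),
    cfg$n_batches, cfg$n_cell_types,
    dimnames = list(as.character(seq_len(cfg$n_batches)), types)
  )
  probs <- matrix(NA_real_, nrow(samples), cfg$n_cell_types,
                  dimnames = list(samples$sample_id, types))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    is_stim <- s$stimulus == cfg$stimuli[[1]]
    is_case <- s$status == "JIA"
    alpha <- log(cfg$baseline_proportions) +
      cfg$prop_stimulus_shift * is_stim +
      cfg$prop_status_shift * is_case +
      cfg$prop_interaction_shift * (is_stim && is_case) +
      donor_eff[s$donor, ] +
      batch_eff[as.character(s$batch), ]
    probs[i, ] <- softmax(alpha)
  }
  truth_env$proportion_truth <- list(
    donor_effects = donor_eff, batch_effects = batch_eff, probs = probs
  )
  unlist(lapply(seq_len(nrow(samples)), function(i) {
    sample(types, n_cells[[i]], replace = TRUE, prob = probs[i, ])
  }), use.names = FALSE)
}

#' Simulate a synthetic single-cell counts dataset with known ground truth
#'
#' Draws a full experiment from a [simulation_config()]: cells per sample
#' are Poisson, each cell's type follows sample-specific proportions
#' (baseline plus logit-scale stimulus/status/interaction shifts plus
#' donor and batch effects), and each gene's counts are negative binomial
#' with a log-mean composed of a baseline plus zero-mean normal donor,
#' batch, stimulus, status and interaction effects whose variances realize
#' the configured fractions.  The per-cell residual log-noise is
#' calibrated to the configured residual fraction at the reference pool
#' size (see [simulation_config()]).  The log-mean is shifted by half the
#' total log-variance so the marginal expected count of a gene equals its
#' configured baseline.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; the same seed reproduces the dataset
#'   bit-for-bit.
#' @return A list with \code{matrix} (a [gene_expression_matrix()]),
#'   \code{annotation} (validated tibble) and \code{truth} (every drawn
#'   effect, the noise calibration, and the proportion model draws).
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  run <- function() simulate_dataset_impl(cfg)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_dataset_impl <- function(cfg) {
  donor_map <- make_donor_map(cfg$n_donors, cfg$n_control, cfg$n_batches)
  samples <- tidyr::expand_grid(
    donor = donor_map$donor, stimulus = cfg$stimuli
  )
  samples <- dplyr::left_join(samples, donor_map, by = "donor")
  samples$sample_id <- paste(samples$donor, samples$stimulus, sep = "_")

  n_cells <- rpois(nrow(samples), cfg$cells_per_sample)
  n_cells <- pmax(n_cells, 1L)
  truth_env <- new.env(parent = emptyenv())
  cell_type <- sample_cell_types(cfg, donor_map, samples, n_cells, truth_env)

  cells <- samples[rep(seq_len(nrow(samples)), n_cells), ]
  cells$cluster <- cell_type
  cells$cell_id <- sprintf("cell%06d", seq_len(nrow(cells)))

  blocks <- cfg$gene_blocks
  n_genes_total <- sum(blocks$n_genes)
  gene_ids <- sprintf("gene%05d", seq_len(n_genes_total))
  gene_symbols <- gene_ids
  if (cfg$n_mito_genes > 0) {
    idx <- seq_len(min(cfg$n_mito_genes, n_genes_total))
    gene_symbols[idx] <- sprintf("MT-%d", idx)
  }

  ln2sq <- log(2)^2
  block_of_gene <- rep(seq_len(nrow(blocks)), blocks$n_genes)
  gene_truth <- tibble(
    gene_id = gene_ids,
    block = block_of_gene,
    base_log2_mean = rnorm(
      n_genes_total,
      blocks$base_log2_mean[block_of_gene],
      blocks$base_log2_sd[block_of_gene]
    )
  )
  for (eff in c("donor", "stimulus", "status", "batch", "interaction")) {
    gene_truth[[paste0("frac_", eff)]] <-
      blocks[[paste0("frac_", eff)]][block_of_gene]
  }
  gene_truth$total_var_ln <- blocks$total_var[block_of_gene] * ln2sq
  gene_truth$dispersion <- blocks$dispersion[block_of_gene]
  resid_target <- (1 - gene_truth$frac_donor - gene_truth$frac_stimulus -
                     gene_truth$frac_status - gene_truth$frac_batch -
                     gene_truth$frac_interaction) * gene_truth$total_var_ln
  gene_truth$cell_noise_var <- vapply(
    resid_target, cell_noise_variance, numeric(1),
    k = cfg$reference_pool_size
  )

  draw_effects <- function(levels, frac) {
    m <- matrix(
      rnorm(length(levels) * n_genes_total) *
        rep(sqrt(frac * gene_truth$total_var_ln), each = length(levels)),
      nrow = length(levels), dimnames = list(levels, gene_ids)
    )
    m
  }
  inter_levels <- paste(
    rep(cfg$stimuli, times = 2),
    rep(c("JIA", "Control"), each = 2),
    sep = "."
  )
  effects <- list(
    donor = draw_effects(donor_map$donor, gene_truth$frac_donor),
    stimulus = draw_effects(cfg$stimuli, gene_truth$frac_stimulus),
    status = draw_effects(c("JIA", "Control"), gene_truth$frac_status),
    batch = draw_effects(as.character(seq_len(cfg$n_batches)),
                         gene_truth$frac_batch),
    interaction = draw_effects(inter_levels, gene_truth$frac_interaction)
  )

  # log-mean per sample x gene (natural log), centered so the marginal
  # expected count equals 2^base_log2_mean
  var_adjust <- (gene_truth$frac_donor + gene_truth$frac_stimulus +
                   gene_truth$frac_status + gene_truth$frac_batch +
                   gene_truth$frac_interaction) * gene_truth$total_var_ln +
    gene_truth$cell_noise_var
  log_mu_sample <- matrix(
    rep(gene_truth$base_log2_mean * log(2) - var_adjust / 2,
        each = nrow(samples)),
    nrow(samples), n_genes_total,
    dimnames = list(samples$sample_id, gene_ids)
  )
  inter_key <- paste(samples$stimulus, samples$status, sep = ".")
  log_mu_sample <- log_mu_sample +
    effects$donor[samples$donor, , drop = FALSE] +
    effects$stimulus[samples$stimulus, , drop = FALSE] +
    effects$status[samples$status, , drop = FALSE] +
    effects$batch[as.character(samples$batch), , drop = FALSE] +
    effects$interaction[inter_key, , drop = FALSE]

  # draw counts gene-chunk by gene-chunk, keeping only nonzeros
  n_cells_total <- nrow(cells)
  sample_of_cell <- match(cells$sample_id, samples$sample_id)
  chunk_size <- max(1L, floor(2e7 / n_cells_total))
  chunks <- split(seq_len(n_genes_total),
                  ceiling(seq_len(n_genes_total) / chunk_size))
  trips <- vector("list", length(chunks))
  for (ci in seq_along(chunks)) {
    gidx <- chunks[[ci]]
    lm <- log_mu_sample[sample_of_cell, gidx, drop = FALSE]
    noise_sd <- rep(sqrt(gene_truth$cell_noise_var[gidx]),
                    each = n_cells_total)
    lm <- lm + rnorm(length(lm)) * noise_sd
    size <- rep(gene_truth$dispersion[gidx], each = n_cells_total)
    x <- rnbinom(length(lm), mu = exp(lm), size = size)
    nz <- which(x > 0)
    trips[[ci]] <- list(
      i = ((nz - 1L) %% n_cells_total) + 1L,
      j = gidx[((nz - 1L) %/% n_cells_total) + 1L],
      x = x[nz]
    )
  }
  counts <- Matrix::sparseMatrix(
    i = unlist(lapply(trips, `[[`, "i")),
    j = unlist(lapply(trips, `[[`, "j")),
    x = unlist(lapply(trips, `[[`, "x")),
    dims = c(n_cells_total, n_genes_total)
  )

  high_mito_cells <- integer()
  if (cfg$n_mito_genes > 0 && cfg$frac_high_mito > 0) {
    midx <- seq_len(min(cfg$n_mito_genes, n_genes_total))
    high_mito_cells <- sample.int(
      n_cells_total, round(cfg$frac_high_mito * n_cells_total)
    )
    sub <- counts[high_mito_cells, midx, drop = FALSE]
    totals <- Matrix::rowSums(counts[high_mito_cells, , drop = FALSE])
    # boost mitochondrial load well past any sane threshold
    counts[high_mito_cells, midx] <- as.matrix(sub) + ceiling(totals / 2)
  }

  ann <- tibble(
    cell_id = cells$cell_id, donor = cells$donor, batch = cells$batch,
    stimulus = cells$stimulus, status = cells$status,
    cluster = cells$cluster
  )
  inconsistent_cells <- integer()
  if (cfg$simulate_batch_labels) {
    n_runs <- 4L
    labels <- lapply(seq_len(nrow(ann)), function(i) {
      rep(ann$cluster[[i]], n_runs)
    })
    if (cfg$frac_inconsistent_labels > 0) {
      inconsistent_cells <- sample.int(
        nrow(ann), round(cfg$frac_inconsistent_labels * nrow(ann))
      )
      other <- "misc"
      for (i in inconsistent_cells) {
        l <- labels[[i]]
        l[seq_len(n_runs - 1L)] <- other
        labels[[i]] <- l
      }
    }
    ann$batch_labels <- labels
  }

  gem <- gene_expression_matrix(counts, ann$cell_id, gene_ids, gene_symbols)
  ann <- cell_annotation(ann, gem, stimulus_levels = cfg$stimuli)

  truth <- list(
    config = cfg,
    donor_map = donor_map,
    samples = samples,
    gene_truth = gene_truth,
    effects = effects,
    log_mu_sample = log_mu_sample,
    proportion_truth = truth_env$proportion_truth,
    high_mito_cells = ann$cell_id[high_mito_cells],
    inconsistent_cells = ann$cell_id[inconsistent_cells]
  )
  list(matrix = gem, annotation = ann, truth = truth)
}

#' Expected counts implied by a simulation ground-truth record
#'
#' Recomputes, from the recorded baseline, effect draws and noise
#' calibration alone, the expected count of every gene in every sample
#' (the generative mean, marginal over per-cell noise and the negative
#' binomial draw).
#'
#' @param truth The \code{truth} element returned by [simulate_dataset()].
#' @return A samples-by-genes matrix of expected counts per cell.
#' @export
expected_counts <- function(truth) {
  exp(truth$log_mu_sample +
        rep(truth$gene_truth$cell_noise_var / 2,
            each = nrow(truth$log_mu_sample)))
}

#' Simulate Gaussian pseudocell-level expression with known fractions
#'
#' Generates per-pseudocell expression directly on the (log) scale the
#' variance-partition model operates on: for each gene, donor, stimulus,
#' status, batch and interaction effects are drawn from zero-mean normals
#' whose variances are the requested fractions of \code{total_var}, and
#' the residual is drawn per pseudocell.  This bypasses counts and pooling
#' and is the reference bed for estimator calibration; set
#' \code{n_control = 0} and \code{n_batches = 1} for a clean balanced
#' donor-by-stimulus design.
#'
#' @param n_genes Number of genes to draw.
#' @param fractions Named numeric vector with any of \code{donor},
#'   \code{stimulus}, \code{status}, \code{batch}, \code{interaction};
#'   missing entries are 0 and the residual is the complement.
#' @param n_donors,n_control,n_batches Design shape (controls and batches
#'   may be 0/1 to hold status or batch constant).
#' @param stimuli Stimulus labels.
#' @param pseudocells_per_sample Pseudocells per (donor, stimulus) sample.
#' @param total_var Total per-gene variance (default 1).
#' @param seed Integer seed.
#' @return A list with \code{expr} (pseudocells-by-genes matrix),
#'   \code{factors} (per-pseudocell design tibble) and \code{truth}
#'   (the realized fractions).
#' @export
simulate_pseudocell_expression <- function(n_genes, fractions,
                                           n_donors = 8, n_control = 0,
                                           n_batches = 1,
                                           stimuli = c("TNF", "Null"),
                                           pseudocells_per_sample = 10,
                                           total_var = 1, seed = NULL) {
  f <- setNames(rep(0, 5),
                c("donor", "stimulus", "status", "batch", "interaction"))
  f[names(fractions)] <- fractions
  if (any(f < 0) || sum(f) > 1) {
    abort("fractions must be >= 0 and sum to at most 1",
      class = "scpoolr_validation_error"
    )
  }
  run <- function() {
    donor_map <- make_donor_map(n_donors, n_control, max(n_batches, 1))
    factors <- tidyr::expand_grid(
      donor = donor_map$donor, stimulus = stimuli,
      rep = seq_len(pseudocells_per_sample)
    )
    factors <- dplyr::left_join(factors, donor_map, by = "donor")
    n <- nrow(factors)
    inter <- paste(factors$stimulus, factors$status, sep = ".")
    draw_one <- function(keys, var) {
      lev <- unique(keys)
      eff <- rnorm(length(lev), 0, sqrt(var))
      eff[match(keys, lev)]
    }
    expr <- vapply(seq_len(n_genes), function(g) {
      draw_one(factors$donor, f[["donor"]] * total_var) +
        draw_one(factors$stimulus, f[["stimulus"]] * total_var) +
        draw_one(factors$status, f[["status"]] * total_var) +
        draw_one(as.character(factors$batch), f[["batch"]] * total_var) +
        draw_one(inter, f[["interaction"]] * total_var) +
        rnorm(n, 0, sqrt((1 - sum(f)) * total_var))
    }, numeric(n))
    colnames(expr) <- sprintf("gene%05d", seq_len(n_genes))
    factors$pseudocell_id <- sprintf(
      "%s_%s_p%d", factors$donor, factors$stimulus, factors$rep
    )
    rownames(expr) <- factors$pseudocell_id
    list(
      expr = expr,
      factors = dplyr::select(factors, "pseudocell_id", "donor",
                              "stimulus", "status", "batch"),
      truth = list(fractions = f, total_var = total_var)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate per-sample cell-type proportions with known effects
#'
#' Draws multinomial cell-type counts for every sample of the configured
#' design, with sample-specific probabilities built from baseline
#' proportions plus logit-scale stimulus, status and interaction shifts
#' and donor and batch random effects, then converts them to a proportion
#' table ready for [fit_proportion_model()].
#'
#' @param cfg A [simulation_config()]; the \code{prop_*} fields control
#'   the generative effects.
#' @param seed Integer seed.
#' @return A list with \code{proportions} (the proportion table) and
#'   \code{truth} (probabilities and drawn effects).
#' @export
simulate_proportions <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  run <- function() {
    donor_map <- make_donor_map(cfg$n_donors, cfg$n_control, cfg$n_batches)
    samples <- tidyr::expand_grid(
      donor = donor_map$donor, stimulus = cfg$stimuli
    )
    samples <- dplyr::left_join(samples, donor_map, by = "donor")
    samples$sample_id <- paste(samples$donor, samples$stimulus, sep = "_")
    n_cells <- pmax(rpois(nrow(samples), cfg$cells_per_sample), 1L)
    truth_env <- new.env(parent = emptyenv())
    types <- sample_cell_types(cfg, donor_map, samples, n_cells, truth_env)
    stopifnot(length(types) == sum(n_cells))
    probs <- truth_env$proportion_truth$probs
    type_names <- colnames(probs)
    counts <- t(vapply(seq_len(nrow(samples)), function(i) {
      as.numeric(rmultinom(1, n_cells[[i]], probs[i, ]))
    }, numeric(length(type_names))))
    props <- counts / rowSums(counts)
    colnames(props) <- type_names
    pt <- dplyr::bind_cols(
      tibble(
        sample_id = samples$sample_id, donor = samples$donor,
        stimulus = samples$stimulus, status = samples$status,
        batch = samples$batch, n_cells = as.integer(n_cells)
      ),
      as_tibble(props)
    )
    list(proportions = pt, truth = truth_env$proportion_truth)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate one cell type's proportions on the raw scale
#'
#' A minimal Gaussian generator for power and type-I error studies of the
#' proportion mixed model: per-sample proportion = baseline + stimulus
#' shift + status shift + interaction shift + donor effect + batch effect
#' + noise, clipped to (0, 1).  Effects are on the proportion scale.
#'
#' @param n_donors,n_control,n_batches Design shape.
#' @param stimuli Stimulus labels, stimulated first.
#' @param baseline Baseline proportion.
#' @param stimulus_shift Additive shift under the stimulated condition.
#' @param status_shift Additive shift for case donors.
#' @param interaction_shift Additional shift for stimulated cases.
#' @param donor_sd,batch_sd,noise_sd Standard deviations of the donor
#'   effect, batch effect and residual noise.
#' @param seed Integer seed.
#' @return A proportion table with a single cell-type column
#'   \code{type01}.
#' @export
simulate_proportion_response <- function(n_donors = 8, n_control = 2,
                                         n_batches = 4,
                                         stimuli = c("TNF", "Null"),
                                         baseline = 0.1,
                                         stimulus_shift = 0,
                                         status_shift = 0,
                                         interaction_shift = 0,
                                         donor_sd = 0.02, batch_sd = 0,
                                         noise_sd = 0.01, seed = NULL) {
  run <- function() {
    donor_map <- make_donor_map(n_donors, n_control, n_batches)
    samples <- tidyr::expand_grid(
      donor = donor_map$donor, stimulus = stimuli
    )
    samples <- dplyr::left_join(samples, donor_map, by = "donor")
    donor_eff <- setNames(rnorm(n_donors, 0, donor_sd), donor_map$donor)
    batch_eff <- setNames(rnorm(n_batches, 0, batch_sd),
                          as.character(seq_len(n_batches)))
    is_stim <- samples$stimulus == stimuli[[1]]
    is_case <- samples$status == "JIA"
    y <- baseline + stimulus_shift * is_stim + status_shift * is_case +
      interaction_shift * (is_stim & is_case) +
      donor_eff[samples$donor] + batch_eff[as.character(samples$batch)] +
      rnorm(nrow(samples), 0, noise_sd)
    y <- pmin(pmax(y, 1e-4), 1 - 1e-4)
    tibble(
      sample_id = paste(samples$donor, samples$stimulus, sep = "_"),
      donor = samples$donor, stimulus = samples$stimulus,
      status = samples$status, batch = samples$batch,
      n_cells = 1000L, type01 = unname(y)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
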