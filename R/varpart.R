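#' Genes expressed in a cell type's pseudocells
#'
#' A gene is called expressed when its mean CP100K value across the cell
#' type's pseudocells is at least \code{min_mean_cp100k} (inclusive, so a
#' gene averaging exactly 1 read per 100,000 is retained).
#'
#' @param pm A \code{pseudocell_matrix} restricted to one cell type (see
#'   [subset_pseudocells()]).
#' @param min_mean_cp100k Expression threshold on the CP100K scale
#'   (default 1).
#' @return Character vector of expressed gene ids.
#' @export
filter_expressed_genes <- function(pm, min_mean_cp100k = 1) {
  stopifnot(inherits(pm, "pseudocell_matrix"))
  if (nrow(pm$cp100k) == 0) {
    warn("no pseudocells; returning an empty expressed-gene set")
    return(character())
  }
  means <- Matrix::colSums(pm$cp100k) / nrow(pm$cp100k)
  pm$gene_ids[means >= min_mean_cp100k]
}

#' Transform pseudocell expression prior to model fitting
#'
#' @param pm A \code{pseudocell_matrix}.
#' @param mode \code{"log2p1"} (default), giving \code{log2(CP100K + 1)},
#'   or \code{"raw"} for the untransformed CP100K values.
#' @param genes Optional gene ids to restrict to.
#' @return A dense pseudocells-by-genes matrix.
#' @export
transform_expression <- function(pm, mode = c("log2p1", "raw"),
                                 genes = NULL) {
  stopifnot(inherits(pm, "pseudocell_matrix"))
  mode <- match.arg(mode)
  m <- pm$cp100k
  if (!is.null(genes)) m <- m[, genes, drop = FALSE]
  m <- as.matrix(m)
  if (mode == "log2p1") m <- log2(m + 1)
  m
}

# Decide which random effects the design supports: a factor enters the
# model only with >= 2 observed levels, and the interaction only when it is
# not aliased with stimulus or status alone.
vp_design <- function(factors) {
  f <- list(
    Stimulus = droplevels(factor(factors$stimulus)),
    Status = droplevels(factor(factors$status)),
    Batch = droplevels(factor(factors$batch)),
    Donor = droplevels(factor(factors$donor))
  )
  inter <- droplevels(interaction(f$Stimulus, f$Status, drop = TRUE))
  f[["Stimulus:Status"]] <- inter
  include <- vapply(f, nlevels, integer(1)) >= 2
  if (include[["Stimulus:Status"]]) {
    include[["Stimulus:Status"]] <-
      nlevels(inter) > nlevels(f$Stimulus) &&
      nlevels(inter) > nlevels(f$Status)
  }
  list(factors = f, include = include)
}

vp_zero_result <- function() {
  eff <- vp_effects()
  sigma2 <- setNames(rep(0, length(eff)), eff)
  fraction <- sigma2
  fraction[["Residual"]] <- 1
  structure(
    list(sigma2 = sigma2, fraction = fraction, converged = FALSE,
         backend = NA_character_),
    class = "variance_components"
  )
}

vp_pack <- function(sigma2_est, converged, backend) {
  eff <- vp_effects()
  sigma2 <- setNames(rep(0, length(eff)), eff)
  sigma2[names(sigma2_est)] <- pmax(sigma2_est, 0)
  tot <- sum(sigma2)
  fraction <- if (tot > 0) sigma2 / tot else {
    f <- sigma2
    f[["Residual"]] <- 1
    f
  }
  structure(
    list(sigma2 = sigma2, fraction = fraction, converged = converged,
         backend = backend),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> backend %s, converged: %s\n",
    x$backend, x$converged
  ))
  print(round(x$fraction, 4))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variance_components <- function(x, ...) {
  tibble(
    effect = names(x$sigma2),
    variance = unname(x$sigma2),
    fraction = unname(x$fraction)
  )
}

vp_reml_control <- function() {
  lme4::lmerControl(
    optimizer = "bobyqa",
    optCtrl = list(rhobeg = 0.2, rhoend = 1e-10, maxfun = 50000),
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.nobs.vs.nlev = "ignore",
    check.nobs.vs.nRE = "ignore"
  )
}

# Fit the crossed random-intercepts model by REML via lme4.  Every gene is
# fitted fresh from the same standard starting point, so results are
# independent of the order in which genes are processed.
vp_fit_reml <- function(y, design) {
  included <- names(design$include)[design$include]
  dat <- as.data.frame(design$factors[included])
  names(dat) <- paste0("f", seq_along(included))
  dat$y <- y
  form <- as.formula(paste(
    "y ~ 1 +",
    paste(sprintf("(1 | f%d)", seq_along(included)), collapse = " + ")
  ))
  # optimizer grumbles surface through optinfo and trigger the MoM
  # fallback; they are not user-actionable here
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = dat, REML = TRUE, control = vp_reml_control())
  ))
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- setNames(vc$vcov, vc$grp)
  keymap <- setNames(included, paste0("f", seq_along(included)))
  keymap[["Residual"]] <- "Residual"
  names(est) <- keymap[names(est)]
  conv_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  list(est = est, converged = conv_ok, fit = fit)
}

# MINQUE(0) / Haseman-Elston style method-of-moments estimator: solve the
# linear system matching the quadratic forms y' P A_e P y to their
# expectations, where A_e is the same-level indicator matrix of effect e
# and P the centering projection.  Closed form, no iteration; used both as
# the REML fallback and (independently re-derived in the tests) as a
# verification oracle on balanced designs.
vp_fit_mom <- function(y, design) {
  included <- names(design$include)[design$include]
  n <- length(y)
  yc <- y - mean(y)
  A <- lapply(design$factors[included], function(f) {
    Z <- model.matrix(~ 0 + f)
    tcrossprod(Z)
  })
  A$Residual <- diag(n)
  center <- function(M) {
    rm <- rowMeans(M)
    M - outer(rm, rep(1, n)) - outer(rep(1, n), rm) + mean(M)
  }
  B <- lapply(A, center)
  k <- length(A)
  S <- matrix(0, k, k, dimnames = list(names(A), names(A)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      S[i, j] <- S[j, i] <- sum(B[[i]] * B[[j]])
    }
  }
  q <- vapply(A, function(Ae) as.numeric(yc %*% Ae %*% yc), numeric(1))
  est <- tryCatch(
    solve(S, q),
    error = function(e) as.numeric(qr.solve(S, q, tol = 1e-10))
  )
  names(est) <- names(A)
  est
}

#' Partition one gene's expression variance across experimental effects
#'
#' Fits the crossed random-intercepts model
#' \deqn{y = \mu + u_{Stimulus} + u_{Status} + u_{Batch} + u_{Donor} +
#'   u_{Stimulus:Status} + \varepsilon}
#' with every design factor treated as a random effect, and reports each
#' component's variance as a fraction of the total.  Estimation is by REML
#' (via \pkg{lme4}); if the optimizer fails, a closed-form method-of-moments
#' (MINQUE(0)) estimator is used and the record is flagged with backend
#' \code{"MoM"}.  Negative raw estimates are clamped to zero before
#' fractions are formed.  Factors with a single observed level are dropped
#' from the model and reported with zero variance.
#'
#' With only two levels each for stimulus and status, their variance
#' estimates are intrinsically noisy; that is a property of the design, not
#' of the estimator.
#'
#' @param y Numeric vector of (transformed) expression, one value per
#'   pseudocell.
#' @param factors Data frame with per-pseudocell columns \code{stimulus},
#'   \code{status}, \code{batch}, \code{donor}.
#' @param method \code{"REML"} (default) or \code{"MoM"} to force the
#'   method-of-moments estimator.
#' @return An object of class \code{variance_components}: named
#'   \code{sigma2} and \code{fraction} vectors over Stimulus, Status,
#'   Batch, Donor, Stimulus:Status and Residual, plus \code{converged} and
#'   \code{backend} flags.  A constant \code{y} yields the degenerate
#'   record with residual fraction 1 and \code{converged = FALSE}.
#' @export
fit_variance_components <- function(y, factors, method = c("REML", "MoM")) {
  method <- match.arg(method)
  y <- as.numeric(y)
  if (nrow(as.data.frame(factors)) != length(y)) {
    abort("y and factors must have matching length",
      class = "scpoolr_validation_error"
    )
  }
  if (sd(y) == 0) return(vp_zero_result())
  design <- vp_design(factors)
  if (!any(design$include)) {
    abort("no effect has two or more observed levels",
      class = "scpoolr_validation_error"
    )
  }
  if (method == "MoM") {
    return(vp_pack(vp_fit_mom(y, design), TRUE, "MoM"))
  }
  res <- tryCatch(vp_fit_reml(y, design), error = function(e) NULL)
  if (is.null(res) || !res$converged) {
    return(vp_pack(vp_fit_mom(y, design), !is.null(res), "MoM"))
  }
  vp_pack(res$est, TRUE, "REML")
}

#' Variance partitioning of every expressed gene in a cell type
#'
#' Applies the expressed-gene filter, the expression transform and
#' [fit_variance_components()] gene by gene, then summarizes the per-effect
#' mean variance fractions and the proportion of genes for which an effect
#' explains more than 5\% of the variance.  Genes are fitted independently,
#' so results are invariant to execution order.
#'
#' @param pm A \code{pseudocell_matrix} (any mix of cell types; the
#'   requested one is extracted).
#' @param cell_type Cluster label to analyse.
#' @param transform Expression transform, see [transform_expression()].
#' @param min_mean_cp100k Expressed-gene threshold, see
#'   [filter_expressed_genes()].
#' @param method Estimation backend, see [fit_variance_components()].
#' @return An object of class \code{scpool_varpart} with elements
#'   \code{results} (long tibble: gene_id, effect, variance, fraction),
#'   \code{gene_info} (per-gene convergence and backend), and
#'   \code{summary} (per-effect mean fraction and >5\% gene proportion).
#'   \code{tidy()} returns \code{results}; \code{glance()} the summary.
#' @export
partition_cell_type <- function(pm, cell_type,
                                transform = c("log2p1", "raw"),
                                min_mean_cp100k = 1,
                                method = c("REML", "MoM")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  sub <- subset_pseudocells(pm, cell_type)
  genes <- filter_expressed_genes(sub, min_mean_cp100k)
  meta <- list(
    cell_type = cell_type,
    pool_size = unique(sub$factors$pool_size),
    iteration = unique(sub$factors$iteration),
    transform = transform, method = method
  )
  if (!length(genes)) {
    warn(sprintf("no expressed genes for cell type '%s'", cell_type))
    return(new_scpool_varpart(
      results = tibble(
        gene_id = character(), effect = character(),
        variance = double(), fraction = double()
      ),
      gene_info = tibble(
        gene_id = character(), converged = logical(), backend = character()
      ),
      meta = meta
    ))
  }
  expr <- transform_expression(sub, transform, genes)
  design <- vp_design(sub$factors)

  fits <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    y <- expr[, i]
    if (sd(y) == 0) {
      fits[[i]] <- vp_zero_result()
      next
    }
    if (method == "MoM") {
      fits[[i]] <- vp_pack(vp_fit_mom(y, design), TRUE, "MoM")
      next
    }
    res <- tryCatch(vp_fit_reml(y, design), error = function(e) NULL)
    if (is.null(res) || !res$converged) {
      fits[[i]] <- vp_pack(vp_fit_mom(y, design), !is.null(res), "MoM")
    } else {
      fits[[i]] <- vp_pack(res$est, TRUE, "REML")
    }
  }

  results <- purrr::map2_dfr(fits, genes, function(f, g) {
    tibble(
      gene_id = g, effect = names(f$fraction),
      variance = unname(f$sigma2), fraction = unname(f$fraction)
    )
  })
  gene_info <- tibble(
    gene_id = genes,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    backend = vapply(fits, `[[`, character(1), "backend")
  )
  new_scpool_varpart(results, gene_info, meta)
}

new_scpool_varpart <- function(results, gene_info, meta) {
  summary <- if (nrow(results)) {
    dplyr::summarise(
      dplyr::group_by(results, .data$effect),
      mean_fraction = mean(.data$fraction),
      frac_genes_gt5 = mean(.data$fraction > 0.05),
      n_genes = dplyr::n(),
      .groups = "drop"
    )
  } else {
    tibble(
      effect = character(), mean_fraction = double(),
      frac_genes_gt5 = double(), n_genes = integer()
    )
  }
  structure(
    c(list(results = results, gene_info = gene_info, summary = summary),
      meta),
    class = "scpool_varpart"
  )
}

#' @export
print.scpool_varpart <- function(x, ...) {
  cat(sprintf(
    "<scpool_varpart> cell type '%s', k = %s, iteration %s: %d genes\n",
    x$cell_type, paste(x$pool_size, collapse = ","),
    paste(x$iteration, collapse = ","), nrow(x$gene_info)
  ))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.scpool_varpart <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.scpool_varpart <- function(x, ...) x$summary

#' Rank genes by a variance component
#'
#' Sorts genes by descending variance fraction for the chosen effect (or by
#' descending raw variance with \code{by = "variance"}); ties are broken by
#' descending raw variance, then lexicographic gene id.
#'
#' @param x A \code{scpool_varpart} object or its long results tibble.
#' @param effect Effect name (one of Stimulus, Status, Batch, Donor,
#'   Stimulus:Status, Residual).
#' @param top_k Number of genes to return (default 100; fewer if fewer
#'   genes were fitted).
#' @param by Ranking key, \code{"fraction"} (default) or \code{"variance"}.
#' @return Character vector of gene ids in rank order.
#' @export
rank_genes <- function(x, effect, top_k = 100,
                       by = c("fraction", "variance")) {
  by <- match.arg(by)
  results <- if (inherits(x, "scpool_varpart")) x$results else as_tibble(x)
  if (!nrow(results)) abort("no fitted genes to rank")
  if (!effect %in% unique(results$effect)) {
    abort(sprintf("unknown effect '%s'", effect),
      class = "scpoolr_validation_error"
    )
  }
  sub <- results[results$effect == effect, ]
  key <- if (by == "fraction") sub$fraction else sub$variance
  ord <- order(-key, -sub$variance, sub$gene_id)
  head(sub$gene_id[ord], top_k)
}
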