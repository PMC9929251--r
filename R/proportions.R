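#' Per-sample cell-type proportions
#'
#' Tabulates, for each sample (one donor under one stimulus), the fraction
#' of its retained cells assigned to each cluster.  Cell types absent from
#' a sample get proportion 0, and every donor must be observed under every
#' stimulus level (a missing sample would otherwise silently get zero
#' cells).
#'
#' @param annotation A validated annotation tibble of QC-retained cells.
#' @return A tibble with one row per sample: \code{sample_id},
#'   \code{donor}, \code{stimulus}, \code{status}, \code{batch},
#'   \code{n_cells}, then one proportion column per cell type.  Rows sum
#'   to 1 across the cell-type columns.
#' @export
compute_proportions <- function(annotation) {
  ann <- as_tibble(annotation)
  donors <- unique(as.character(ann$donor))
  stimuli <- levels(factor(ann$stimulus))
  seen <- dplyr::distinct(ann, .data$donor, .data$stimulus)
  if (nrow(seen) < length(donors) * length(stimuli)) {
    abort("every donor must have cells under every stimulus level",
      class = "scpoolr_validation_error"
    )
  }
  counts <- dplyr::count(
    ann, .data$donor, .data$stimulus, .data$status, .data$batch,
    .data$cluster, .drop = FALSE
  )
  counts <- dplyr::filter(counts, !is.na(.data$cluster))
  # .drop = FALSE completes cluster levels; drop phantom donor/stimulus
  # crossings that have no status/batch (they do not exist as samples)
  totals <- dplyr::summarise(
    dplyr::group_by(counts, .data$donor, .data$stimulus, .data$status,
                    .data$batch),
    n_cells = sum(.data$n), .groups = "drop"
  )
  totals <- dplyr::filter(totals, .data$n_cells > 0)
  wide <- tidyr::pivot_wider(
    counts,
    names_from = "cluster", values_from = "n", values_fill = 0
  )
  wide <- dplyr::inner_join(
    totals, wide,
    by = c("donor", "stimulus", "status", "batch")
  )
  type_cols <- setdiff(
    names(wide), c("donor", "stimulus", "status", "batch", "n_cells")
  )
  if (any(wide$n_cells == 0)) {
    abort("sample with zero cells", class = "scpoolr_validation_error")
  }
  wide[type_cols] <- lapply(wide[type_cols], function(x) x / wide$n_cells)
  dplyr::bind_cols(
    tibble(sample_id = paste(wide$donor, wide$stimulus, sep = "_")),
    wide
  )
}

prop_type_cols <- function(pt) {
  setdiff(
    names(pt),
    c("sample_id", "donor", "stimulus", "status", "batch", "n_cells")
  )
}

# MINQUE(0) for the donor/batch variance components of the proportion
# model, with the fixed effects projected out; used when the REML fit is
# singular.
prop_mom_varfrac <- function(y, X, donor, batch) {
  n <- length(y)
  P <- diag(n) - X %*% solve(crossprod(X), t(X))
  A <- list(
    donor = tcrossprod(model.matrix(~ 0 + donor)),
    batch = tcrossprod(model.matrix(~ 0 + batch)),
    resid = diag(n)
  )
  B <- lapply(A, function(Ae) P %*% Ae %*% P)
  k <- length(A)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in i:k) S[i, j] <- S[j, i] <- sum(B[[i]] * B[[j]])
  }
  q <- vapply(B, function(Be) as.numeric(t(y) %*% Be %*% y), numeric(1))
  est <- pmax(as.numeric(qr.solve(S, q, tol = 1e-10)), 0)
  names(est) <- names(A)
  est
}

#' Mixed-model ANOVA of one cell type's proportions
#'
#' Fits a linear mixed model to the per-sample proportions of one cell
#' type, with fixed effects of stimulus, status and their interaction and
#' random intercepts for donor and batch.  Fixed effects are tested with
#' type-III F statistics using Satterthwaite-approximated denominator
#' degrees of freedom (via \pkg{lmerTest}).  Donor and batch variance
#' fractions are reported relative to the total (donor + batch + residual)
#' variance; when the REML fit is singular the fractions are re-estimated
#' by a method-of-moments fallback and the result is flagged.
#'
#' @param pt Proportion table from [compute_proportions()] (or any tibble
#'   with the same layout).
#' @param cell_type Name of the proportion column to model.
#' @param transform \code{"identity"} (default; raw proportions) or
#'   \code{"logit"} (empirical logit with a 0.5-count offset, using
#'   \code{n_cells}).
#' @return An object of class \code{proportion_anova}; \code{tidy()} gives
#'   the per-term F table, \code{glance()} the variance fractions and
#'   fit flags.
#' @export
fit_proportion_model <- function(pt, cell_type,
                                 transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  if (!cell_type %in% names(pt)) {
    abort(sprintf("cell type '%s' not found in proportion table", cell_type),
      class = "scpoolr_validation_error"
    )
  }
  dat <- tibble(
    y = as.numeric(pt[[cell_type]]),
    stimulus = droplevels(factor(pt$stimulus)),
    status = droplevels(factor(pt$status)),
    donor = droplevels(factor(pt$donor)),
    batch = droplevels(factor(pt$batch))
  )
  for (col in c("stimulus", "status", "donor", "batch")) {
    if (nlevels(dat[[col]]) < 2) {
      abort(sprintf("factor '%s' has a single level", col),
        class = "scpoolr_validation_error"
      )
    }
  }
  per_status <- table(dplyr::distinct(dat, .data$donor, .data$status)$status)
  if (any(per_status < 2)) {
    abort("need at least 2 donors per status level",
      class = "scpoolr_validation_error"
    )
  }
  if (transform == "logit") {
    n <- if ("n_cells" %in% names(pt)) pt$n_cells else rep(1000, nrow(pt))
    dat$y <- log((dat$y + 0.5 / n) / (1 - dat$y + 0.5 / n))
  }

  fit <- lmerTest::lmer(
    y ~ stimulus * status + (1 | donor) + (1 | batch),
    data = dat, REML = TRUE,
    contrasts = list(stimulus = "contr.sum", status = "contr.sum"),
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  )
  singular <- lme4::isSingular(fit, tol = 1e-6)
  at <- as.data.frame(anova(fit, type = 3))
  term_map <- c(
    stimulus = "Stimulus", status = "Status",
    `stimulus:status` = "Stimulus:Status"
  )
  anova_tbl <- tibble(
    term = unname(term_map[rownames(at)]),
    F_value = at[["F value"]],
    df_num = at[["NumDF"]],
    df_den = at[["DenDF"]],
    p_value = at[["Pr(>F)"]]
  )

  vc <- as.data.frame(lme4::VarCorr(fit))
  sig <- setNames(vc$vcov, vc$grp)
  est <- c(donor = unname(sig[["donor"]]), batch = unname(sig[["batch"]]),
           resid = unname(sig[["Residual"]]))
  backend <- "REML"
  if (singular) {
    X <- model.matrix(~ stimulus * status, dat,
      contrasts.arg = list(stimulus = "contr.sum", status = "contr.sum")
    )
    est <- prop_mom_varfrac(dat$y, X, dat$donor, dat$batch)
    backend <- "MoM"
  }
  tot <- sum(est)
  varfrac <- if (tot > 0) est / tot else c(donor = 0, batch = 0, resid = 1)

  structure(
    list(
      cell_type = cell_type, transform = transform,
      anova = anova_tbl,
      var_donor_fraction = unname(varfrac[["donor"]]),
      var_batch_fraction = unname(varfrac[["batch"]]),
      singular = singular, var_backend = backend
    ),
    class = "proportion_anova"
  )
}

#' @export
print.proportion_anova <- function(x, ...) {
  cat(sprintf(
    "<proportion_anova> '%s' (%s response): donor var %.2f, batch var %.2f%s\n",
    x$cell_type, x$transform, x$var_donor_fraction, x$var_batch_fraction,
    if (x$singular) " [singular fit; MoM variance fractions]" else ""
  ))
  print(x$anova)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.proportion_anova <- function(x, ...) {
  dplyr::mutate(x$anova, cell_type = x$cell_type, .before = 1)
}

#' @exportS3Method generics::glance
glance.proportion_anova <- function(x, ...) {
  tibble(
    cell_type = x$cell_type,
    var_donor_fraction = x$var_donor_fraction,
    var_batch_fraction = x$var_batch_fraction,
    singular = x$singular,
    var_backend = x$var_backend,
    transform = x$transform
  )
}

#' Fit the proportion mixed model for every cell type
#'
#' @inheritParams fit_proportion_model
#' @param cell_types Columns to model (default: all cell-type columns).
#' @return A list of \code{proportion_anova} objects, named by cell type.
#' @export
fit_proportion_models <- function(pt, cell_types = NULL,
                                  transform = c("identity", "logit")) {
  transform <- match.arg(transform)
  cell_types <- cell_types %||% prop_type_cols(pt)
  setNames(
    lapply(cell_types, function(ct) {
      fit_proportion_model(pt, ct, transform)
    }),
    cell_types
  )
}

#' Summarize donor and batch variance across cell types
#'
#' Collects each fitted cell type's F tests and donor/batch variance
#' fractions into one table, flags cell types in which donor differences
#' explain more than half of the random variance, and optionally appends
#' Benjamini-Hochberg adjusted p-values (off by default; the raw per-test
#' values are the primary report).
#'
#' @param results List of \code{proportion_anova} objects (see
#'   [fit_proportion_models()]).
#' @param bh Add BH-adjusted p-value columns? Default \code{FALSE}.
#' @return A tibble with one row per cell type.
#' @export
summarize_donor_variance <- function(results, bh = FALSE) {
  if (!length(results)) {
    abort("no results to summarize", class = "scpoolr_validation_error")
  }
  wide <- purrr::map_dfr(results, function(r) {
    a <- r$anova
    row <- tibble(
      cell_type = r$cell_type,
      F_stimulus = a$F_value[a$term == "Stimulus"],
      p_stimulus = a$p_value[a$term == "Stimulus"],
      F_status = a$F_value[a$term == "Status"],
      p_status = a$p_value[a$term == "Status"],
      F_interaction = a$F_value[a$term == "Stimulus:Status"],
      p_interaction = a$p_value[a$term == "Stimulus:Status"],
      var_donor_fraction = r$var_donor_fraction,
      var_batch_fraction = r$var_batch_fraction
    )
    row$donor_dominant <- row$var_donor_fraction > 0.5
    row
  })
  if (bh) {
    for (col in c("p_stimulus", "p_status", "p_interaction")) {
      wide[[paste0(col, "_bh")]] <- stats::p.adjust(wide[[col]], "BH")
    }
  }
  wide
}

#' Paired per-sample proportion plot
#'
#' Shows each cell type's per-sample proportion with the two stimulus
#' conditions of a donor connected by a line, controls and cases
#' distinguished by colour.
#'
#' @param pt Proportion table from [compute_proportions()].
#' @param cell_types Cell types to show (default: all).
#' @return A ggplot object.
#' @export
plot_proportions <- function(pt, cell_types = NULL) {
  cell_types <- cell_types %||% prop_type_cols(pt)
  long <- tidyr::pivot_longer(
    pt[c("donor", "stimulus", "status", cell_types)],
    dplyr::all_of(cell_types),
    names_to = "cell_type", values_to = "proportion"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$stimulus, y = .data$proportion,
      group = .data$donor, colour = .data$status
    )
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~cell_type, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "proportion of sample") +
    ggplot2::theme_bw()
}
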