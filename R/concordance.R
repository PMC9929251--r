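check_ranked_list <- function(x, arg) {
  x <- as.character(x)
  if (!length(x)) {
    abort(sprintf("%s is empty", arg), class = "scpoolr_validation_error")
  }
  if (anyDuplicated(x)) {
    abort(sprintf("%s contains duplicate genes", arg),
      class = "scpoolr_validation_error"
    )
  }
  x
}

align_lists <- function(a, b) {
  a <- check_ranked_list(a, "list a")
  b <- check_ranked_list(b, "list b")
  if (length(a) != length(b)) {
    k <- min(length(a), length(b))
    warn(sprintf(
      "ranked lists have unequal lengths (%d, %d); truncating to %d",
      length(a), length(b), k
    ))
    a <- a[seq_len(k)]
    b <- b[seq_len(k)]
  }
  list(a = a, b = b)
}

#' Concordance curve between two ranked gene lists
#'
#' For each prefix depth \eqn{i = 1, \dots, K}, counts the genes shared by
#' the top-\eqn{i} of both lists: \eqn{C_i = |top_i(a) \cap top_i(b)|}.
#' The curve is non-decreasing with \eqn{0 \le C_i \le i}.
#'
#' @param a,b Character vectors of unique gene ids in rank order.  Lists of
#'   unequal length are truncated to the shorter with a warning.
#' @return Integer vector of cumulative shared-gene counts.
#' @export
concordance_curve <- function(a, b) {
  al <- align_lists(a, b)
  a <- al$a
  b <- al$b
  k <- length(a)
  pos_b <- match(a, b)
  # a shared gene enters the curve at depth max(rank in a, rank in b)
  depth <- pmax(seq_len(k), pos_b)
  depth <- depth[!is.na(depth)]
  counts <- tabulate(depth, nbins = k)
  cumsum(counts)
}

#' Area under the concordance curve (AUCC)
#'
#' Summarizes the concordance curve of two ranked top-\eqn{K} lists as the
#' ratio of its area \eqn{\sum_i C_i} to a maximum-sharing denominator.
#' Two denominators are provided: \code{"paper"} uses \eqn{K^2/2} (the
#' conventional form, under which two identical lists score
#' \eqn{(K+1)/K}, slightly above 1), and \code{"exact"} uses
#' \eqn{K(K+1)/2} so identical lists score exactly 1.  Both are kept
#' because the two conventions circulate; the default is \code{"paper"}.
#'
#' @inheritParams concordance_curve
#' @param normalization \code{"paper"} (\eqn{K^2/2}) or \code{"exact"}
#'   (\eqn{K(K+1)/2}).
#' @return A single numeric score.
#' @export
aucc <- function(a, b, normalization = c("paper", "exact")) {
  normalization <- match.arg(normalization)
  cc <- concordance_curve(a, b)
  k <- length(cc)
  denom <- if (normalization == "paper") k^2 / 2 else k * (k + 1) / 2
  sum(cc) / denom
}

#' Pairwise AUCC matrix over a collection of ranked lists
#'
#' @param lists Named list of ranked gene id vectors; names label the rows
#'   and columns and must be unique.
#' @inheritParams aucc
#' @return A symmetric numeric matrix of AUCC scores.
#' @export
aucc_matrix <- function(lists, normalization = c("paper", "exact")) {
  normalization <- match.arg(normalization)
  if (length(lists) < 2) {
    abort("need at least two ranked lists",
      class = "scpoolr_validation_error"
    )
  }
  labels <- names(lists) %||% as.character(seq_along(lists))
  if (anyDuplicated(labels)) {
    abort("ranked list labels must be unique",
      class = "scpoolr_validation_error"
    )
  }
  n <- length(lists)
  m <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m[i, j] <- m[j, i] <- aucc(lists[[i]], lists[[j]], normalization)
    }
  }
  m
}

#' Heatmap of a pairwise AUCC matrix
#'
#' @param m Symmetric AUCC matrix from [aucc_matrix()].
#' @return A ggplot object.
#' @export
plot_aucc_matrix <- function(m) {
  df <- as_tibble(m, rownames = "list_a")
  df <- tidyr::pivot_longer(df, -"list_a",
    names_to = "list_b", values_to = "aucc"
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$list_a, y = .data$list_b, fill = .data$aucc)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data$aucc)), size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, NA)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "AUCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
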