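#' Rank similarity methods within each activity class
#'
#' Each activity class acts as a rater ranking the methods by recall:
#' within a class row the worst method gets rank 1 and the best rank `n`;
#' tied recalls receive the average of the ranks they span.
#'
#' @param x A [recall_table], or a data frame with a `class_label` column
#'   and one numeric column per method.
#' @return A numeric matrix of ranks, one row per class (rater), one
#'   column per method.
#' @export
rank_rows <- function(x) {
  if (inherits(x, "recall_table")) x <- x$table
  x <- tibble::as_tibble(x)
  methods <- setdiff(names(x), "class_label")
  if (length(methods) < 2) {
    stop_siam("At least 2 methods are required for ranking.", "siam_shape_error")
  }
  vals <- as.matrix(x[methods])
  if (anyNA(vals)) {
    stop_siam("Recall matrix has missing cells.", "siam_shape_error")
  }
  r <- t(apply(vals, 1L, rank))
  dimnames(r) <- list(
    if ("class_label" %in% names(x)) x$class_label else NULL,
    methods
  )
  r
}

#' Kendall coefficient of concordance among activity classes
#'
#' Measures how consistently `m` activity classes (raters) rank `n`
#' similarity methods (objects). From the rank matrix the per-method total
#' ranks `R_i`, their grand mean `m(n+1)/2` and the squared-deviation sum
#' `delta` are formed; then
#' `W = 12 delta / (m^2 (n^3 - n) - m * sum_j T_j)`,
#' where `T_j = sum(t^3 - t)` over the tie groups of rater `j`. With no
#' ties the correction vanishes and W reduces to the classical
#' `12 delta / (m^2 (n^3 - n))`; `tie_correction = FALSE` forces the
#' uncorrected form. If every rater ties every object the statistic is
#' undefined (0/0) and `NaN` is returned.
#' W is 0 for no agreement and 1 for complete agreement;
#' significance uses the large-`m` chi-square approximation
#' `chi^2 = m (n - 1) W` with `n - 1` degrees of freedom.
#'
#' @param x A rank matrix from [rank_rows()], or a [recall_table] /
#'   recall data frame (ranked internally).
#' @param tie_correction Apply the tie-corrected denominator (default
#'   `TRUE`).
#' @return A `concordance` object: list with `rank_matrix`, `m`, `n`,
#'   `totals`, `grand_mean`, `delta`, `W`, `chi_square`, `df`, `p_value`
#'   and a `mean_ranks` tibble sorted by decreasing mean rank.
#' @export
kendall_w <- function(x, tie_correction = TRUE) {
  r <- if (is.matrix(x)) x else rank_rows(x)
  m <- nrow(r)
  n <- ncol(r)
  if (n < 2) {
    stop_siam("Concordance needs at least 2 objects.", "siam_degenerate_error")
  }
  totals <- colSums(r)
  grand_mean <- m * (n + 1) / 2
  delta <- sum((totals - grand_mean)^2)
  ties <- sum(apply(r, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  denom <- m^2 * (n^3 - n) - if (tie_correction) m * ties else 0
  w <- 12 * delta / denom
  chi <- m * (n - 1) * w
  p <- pchisq(chi, df = n - 1, lower.tail = FALSE)
  mean_ranks <- tibble::tibble(
    method = colnames(r) %||% paste0("method", seq_len(n)),
    mean_rank = unname(totals) / m
  )
  mean_ranks <- mean_ranks[order(-mean_ranks$mean_rank, mean_ranks$method), ]
  structure(
    list(
      rank_matrix = r, m = m, n = n,
      totals = totals, grand_mean = grand_mean, delta = delta,
      W = w, chi_square = chi, df = n - 1, p_value = p,
      mean_ranks = mean_ranks,
      tie_correction = tie_correction
    ),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(
    "Kendall W = %.4f (m = %d raters, n = %d objects)\nchi-square = %.3f, df = %d, p = %.3g%s\n",
    x$W, x$m, x$n, x$chi_square, x$df, x$p_value,
    if (x$p_value < 0.05) " (significant at 0.05)" else ""
  ))
  print(x$mean_ranks)
  invisible(x)
}

#' Order methods by mean rank
#'
#' The consensus ordering of the similarity methods implied by a
#' concordance analysis: mean rank `R_i / m` per method, sorted
#' descending (higher mean rank = better method); exact ties are flagged
#' and broken alphabetically for display.
#'
#' @param result A `concordance` object.
#' @return A tibble with columns `method`, `mean_rank`, `tied`.
#' @export
rank_methods <- function(result) {
  stopifnot(inherits(result, "concordance"))
  mr <- result$mean_ranks
  mr$tied <- duplicated(mr$mean_rank) | duplicated(mr$mean_rank, fromLast = TRUE)
  mr
}

#' Tidy a concordance result
#'
#' @param x A `concordance` object.
#' @param ... Unused.
#' @return `tidy()`: the per-method mean-rank tibble; `glance()`: one row
#'   with `W`, `chi_square`, `df`, `p_value`, `m`, `n`.
#' @export
tidy.concordance <- function(x, ...) rank_methods(x)

#' @rdname tidy.concordance
#' @export
glance.concordance <- function(x, ...) {
  tibble::tibble(
    W = x$W, chi_square = x$chi_square, df = x$df,
    p_value = x$p_value, m = x$m, n = x$n
  )
}
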