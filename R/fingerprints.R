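#' Continuous Tanimoto similarity between count fingerprints
#'
#' Computes the continuous (count-vector) form of the Tanimoto coefficient,
#' the long-standing benchmark similarity measure in ligand-based virtual
#' screening: `sum(a * b) / (sum(a^2) + sum(b^2) - sum(a * b))`.
#'
#' @param a,b Non-negative numeric vectors of equal length (count
#'   fingerprints, e.g. folded ECFC_4 counts). At least one entry of each
#'   must be nonzero.
#' @return A single number in `[0, 1]`; `1` exactly when `a` and `b` are
#'   identical nonzero vectors.
#' @examples
#' tanimoto_continuous(c(1, 2, 0), c(0, 2, 1)) # 4 / (5 + 5 - 4) = 2/3
#' @export
tanimoto_continuous <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop_siam("Fingerprints must have equal length.", "siam_shape_error")
  }
  if (any(a < 0) || any(b < 0)) {
    stop_siam("Count fingerprints must be non-negative.", "siam_input_error")
  }
  ab <- sum(a * b)
  denom <- sum(a * a) + sum(b * b) - ab
  if (denom == 0) {
    stop_siam(
      "Tanimoto similarity is undefined when both fingerprints are all-zero.",
      "siam_undefined_error"
    )
  }
  ab / denom
}

# All-pairs continuous Tanimoto for the rows of a count matrix, via one
# cross-product. Returns an n x n symmetric matrix with unit diagonal.
tanimoto_matrix <- function(m) {
  m <- as.matrix(m)
  s <- tcrossprod(m)
  sq <- diag(s)
  denom <- outer(sq, sq, "+") - s
  t <- s / denom
  t[denom == 0] <- NA_real_
  t
}

# Mean of the upper triangle of the pairwise Tanimoto matrix of `m`'s rows.
mean_pairwise_tanimoto <- function(m) {
  t <- tanimoto_matrix(m)
  mean(t[upper.tri(t)])
}

#' Mean pairwise similarity (diversity) of an activity class
#'
#' The structural homogeneity of an activity class is summarised as the mean
#' continuous-Tanimoto similarity over all unordered pairs of its active
#' molecules, the convention used to characterise the MDDR/MUV benchmark
#' classes (roughly 0.10 for heterogeneous classes up to ~0.39 for
#' homogeneous ones).
#'
#' @param library A [screening_library].
#' @param class_label An activity-class label present in the library.
#' @return A single number in `[0, 1]`.
#' @export
mean_pairwise_similarity <- function(library, class_label) {
  stopifnot(is_screening_library(library))
  class_label <- as.character(class_label)
  idx <- which(library$records$class_label == class_label)
  if (length(idx) == 0) {
    stop_siam(
      sprintf("Unknown activity class '%s'.", class_label),
      "siam_lookup_error"
    )
  }
  if (length(idx) < 2) {
    stop_siam(
      sprintf("Class '%s' needs at least 2 actives for pairwise similarity.", class_label),
      "siam_input_error"
    )
  }
  mean_pairwise_tanimoto(library$fingerprints[idx, , drop = FALSE])
}
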