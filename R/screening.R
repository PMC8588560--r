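#' Rank a screening library against one class's query structures
#'
#' Scores every `TEST` molecule in the library against each query
#' (reference) structure of the evaluated activity class and fuses the
#' per-query scores into one score per molecule — by default the MAX group
#' fusion rule conventional in similarity searching with multiple
#' references; `fusion = "mean"` averages instead. Query molecules never
#' appear in the ranking. Ties in score break by molecule id ascending, so
#' rankings replay deterministically.
#'
#' @param library A [screening_library] with roles assigned (see
#'   [select_queries()]).
#' @param class_label The activity class whose queries are screened.
#' @param scorer `"tanimoto"` for the continuous-Tanimoto baseline, or a
#'   trained `siamese_model` / `siamese_fit`.
#' @param fusion `"max"` (default) or `"mean"`.
#' @return A `ranked_list` tibble with columns `id`, `score`,
#'   `class_label`, sorted by decreasing score; attributes record the
#'   method, evaluated class and query ids.
#' @export
score_library <- function(library, class_label, scorer = "tanimoto",
                          fusion = c("max", "mean")) {
  stopifnot(is_screening_library(library))
  fusion <- match.arg(fusion)
  class_label <- as.character(class_label)
  rec <- library$records
  q_idx <- which(rec$class_label == class_label & rec$role == "QUERY")
  if (length(q_idx) == 0) {
    stop_siam(
      sprintf("No query structures assigned for class '%s'.", class_label),
      "siam_input_error"
    )
  }
  t_idx <- which(rec$role == "TEST")
  if (length(t_idx) == 0) {
    stop_siam("Library has no TEST molecules to rank.", "siam_input_error")
  }
  q_fp <- library$fingerprints[q_idx, , drop = FALSE]
  t_fp <- library$fingerprints[t_idx, , drop = FALSE]
  storage.mode(q_fp) <- "double"
  storage.mode(t_fp) <- "double"

  score_mat <- if (identical(scorer, "tanimoto")) {
    s <- tcrossprod(t_fp, q_fp)
    denom <- outer(rowSums(t_fp^2), rowSums(q_fp^2), "+") - s
    s / denom
  } else {
    model <- if (inherits(scorer, "siamese_fit")) scorer$model else scorer
    stopifnot(inherits(model, "siamese_model"))
    vapply(seq_len(nrow(q_fp)), function(qi) {
      qx <- t_fp
      qx[] <- rep(q_fp[qi, ], each = nrow(t_fp))
      as.numeric(forward_matrix(model, qx, t_fp))
    }, numeric(nrow(t_fp)))
  }
  fused <- unname(if (fusion == "max") {
    apply(score_mat, 1L, max)
  } else {
    rowMeans(score_mat)
  })
  out <- tibble::tibble(
    id = rec$id[t_idx],
    score = fused,
    class_label = rec$class_label[t_idx]
  )
  out <- out[order(-out$score, out$id), ]
  attr(out, "method") <- if (identical(scorer, "tanimoto")) "TAN" else "MLP"
  attr(out, "eval_class") <- class_label
  attr(out, "query_ids") <- rec$id[q_idx]
  class(out) <- c("ranked_list", class(out))
  out
}

#' Recall of actives in the top percentage of a ranking
#'
#' `floor(pct/100 * n)` molecules are taken from the head of the ranking;
#' the recall is the percentage of the class's active molecules found in
#' that slice. The slice is never expanded at score ties — the ranking's
#' deterministic order decides the boundary.
#'
#' @param ranked A `ranked_list` (or tibble with an `id` column, ordered).
#' @param actives Character ids of the class's active TEST molecules.
#' @param pct Cutoff percentage in `(0, 100]`.
#' @return Recall as a percentage in `[0, 100]`, full float precision.
#' @export
top_percent_recall <- function(ranked, actives, pct) {
  assert_scalar_number(pct, "pct", lower = 1e-9, upper = 100)
  if (length(actives) == 0) {
    stop_siam("Recall is undefined for an empty active set.", "siam_undefined_error")
  }
  cut <- floor(pct / 100 * nrow(ranked))
  100 * sum(ranked$id[seq_len(cut)] %in% actives) / length(actives)
}

#' Screen a library and assemble recall tables
#'
#' Runs the full retrieval protocol for every activity class at every
#' cutoff: the trained Siamese model (method `MLP`) and the
#' continuous-Tanimoto baseline (method `TAN`) are both screened with the
#' class's query structures, and per-class top-percent recalls are
#' assembled into one [recall_table] per cutoff. Recall denominators count
#' TEST actives only (queries are excluded from ranking and from the
#' denominator). Externally published per-class recall columns for other
#' methods can be merged for side-by-side comparison.
#'
#' @param fit A trained `siamese_fit` (or `siamese_model`).
#' @param library A [screening_library] with roles assigned.
#' @param pcts Cutoff percentages (default `c(1, 5)`).
#' @param fusion Group-fusion rule for [score_library()].
#' @param external Optional named list (by cutoff, e.g. `"1"`) of data
#'   frames with a `class_label` column and one column per external
#'   method, matching the library's classes.
#' @return A named list of [recall_table] objects, one per cutoff
#'   (`"top1"`, `"top5"`, ...).
#' @export
evaluate_benchmark <- function(fit, library, pcts = c(1, 5),
                               fusion = c("max", "mean"), external = NULL) {
  fusion <- match.arg(fusion)
  rec <- library$records
  classes <- library$classes$class_label
  rows <- list()
  for (cl in classes) {
    actives <- rec$id[rec$class_label == cl & rec$role == "TEST"]
    for (method in c("TAN", "MLP")) {
      scorer <- if (method == "TAN") "tanimoto" else fit
      ranked <- score_library(library, cl, scorer, fusion = fusion)
      for (pct in pcts) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          pct = pct, class_label = cl, method = method,
          recall = top_percent_recall(ranked, actives, pct)
        )
      }
    }
  }
  long <- dplyr::bind_rows(rows)
  out <- lapply(pcts, function(pct) {
    wide <- tidyr::pivot_wider(
      long[long$pct == pct, c("class_label", "method", "recall")],
      names_from = "method", values_from = "recall"
    )
    ext <- external[[as.character(pct)]]
    if (!is.null(ext)) {
      ext <- tibble::as_tibble(ext)
      if (!setequal(ext$class_label, wide$class_label)) {
        stop_siam(
          "External recall columns do not cover the library's classes.",
          "siam_join_error"
        )
      }
      wide <- dplyr::left_join(wide, ext, by = "class_label")
    }
    recall_table(wide)
  })
  names(out) <- paste0("top", pcts)
  out
}
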