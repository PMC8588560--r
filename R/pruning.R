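#' Signal-to-noise ratio of weight-matrix columns
#'
#' Each hidden node is represented by one column of its layer's incoming
#' weight matrix; its signal-to-noise ratio is `|mean| / spread` of that
#' column, the criterion used to rank nodes for pruning. The spread is the
#' population standard deviation by default (`sigma = "std"`, the
#' conventional SNR); `sigma = "var"` uses the population variance instead.
#' A constant nonzero column (zero spread, nonzero mean) gets an `Inf`
#' sentinel and is never pruned; an all-zero column scores 0.
#'
#' @param w A weight matrix with at least 2 rows (fan-in x fan-out;
#'   columns are nodes).
#' @param sigma `"std"` (default) or `"var"`.
#' @return A numeric vector of per-column SNR values.
#' @export
column_snr <- function(w, sigma = c("std", "var")) {
  sigma <- match.arg(sigma)
  w <- as.matrix(w)
  if (nrow(w) < 2) {
    stop_siam(
      "Column spread is degenerate for a single-row weight matrix.",
      "siam_degenerate_error"
    )
  }
  mu <- colMeans(w)
  sd_ <- apply(w, 2L, pop_sd)
  spread <- if (sigma == "std") sd_ else sd_^2
  snr <- ifelse(
    spread == 0,
    ifelse(mu == 0, 0, Inf),
    abs(mu) / spread
  )
  unname(snr)
}

# Names and ordering of the prunable layers: all hidden encoder layers,
# then all post-fusion hidden layers. Input cells, the weightless
# distance/fusion layers and the single output unit are never prunable.
prunable_layers <- function(model) {
  c(
    if (length(model$encoder)) paste0("encoder", seq_along(model$encoder)),
    if (length(model$head)) paste0("head", seq_along(model$head))
  )
}

get_layer <- function(model, layer) {
  if (startsWith(layer, "encoder")) {
    i <- as.integer(sub("encoder", "", layer))
    list(l = model$encoder[[i]], mask = model$mask$encoder[[i]])
  } else {
    i <- as.integer(sub("head", "", layer))
    list(l = model$head[[i]], mask = model$mask$head[[i]])
  }
}

#' Prune low-SNR nodes from a Siamese model
#'
#' Ranks every prunable hidden node by the signal-to-noise ratio of its
#' incoming weight column and masks the `floor(ratio * n_prunable)` nodes
#' with the smallest SNR. By default SNRs are pooled across all prunable
#' layers (`scope = "global"`); `scope = "per_layer"` prunes the same
#' fraction within each layer instead. Masking zeroes the node's incoming
#' weight column and suppresses its output, so it contributes exactly zero
#' to every subsequent forward pass; there is no retraining. Ties in SNR
#' break by (layer, column) ascending so pruning replays deterministically.
#' The input model is never modified.
#'
#' @param model A `siamese_model`.
#' @param ratio Fraction of prunable nodes to mask, in `[0, 1)`.
#' @param sigma Spread convention for [column_snr()].
#' @param scope `"global"` (default) or `"per_layer"` ranking pool.
#' @return A list with `model` (the pruned copy) and `report`, a
#'   `prune_report` tibble with one row per prunable node
#'   (`layer`, `column`, `mu`, `sigma`, `snr`, `pruned`).
#' @export
prune <- function(model, ratio, sigma = c("std", "var"),
                  scope = c("global", "per_layer")) {
  stopifnot(inherits(model, "siamese_model"))
  sigma <- match.arg(sigma)
  scope <- match.arg(scope)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 0 || ratio >= 1) {
    stop_siam("`ratio` must lie in [0, 1).", "siam_range_error")
  }
  layers <- prunable_layers(model)
  report <- dplyr::bind_rows(lapply(seq_along(layers), function(li) {
    w <- get_layer(model, layers[li])$l$W
    mu <- colMeans(w)
    sd_ <- apply(w, 2L, pop_sd)
    snr <- column_snr(w, sigma = sigma)
    tibble::tibble(
      layer = layers[li],
      layer_id = li,
      column = seq_len(ncol(w)),
      mu = mu,
      sigma = if (sigma == "std") sd_ else sd_^2,
      snr = snr
    )
  }))

  report$pruned <- FALSE
  if (scope == "global") {
    k <- floor(ratio * nrow(report))
    if (k > 0) {
      ord <- order(report$snr, report$layer_id, report$column)
      report$pruned[ord[seq_len(k)]] <- TRUE
    }
  } else {
    for (li in unique(report$layer_id)) {
      rows <- which(report$layer_id == li)
      k <- floor(ratio * length(rows))
      if (k > 0) {
        ord <- rows[order(report$snr[rows], report$column[rows])]
        report$pruned[ord[seq_len(k)]] <- TRUE
      }
    }
  }

  for (i in which(report$pruned)) {
    layer <- report$layer[i]
    col <- report$column[i]
    if (startsWith(layer, "encoder")) {
      li <- as.integer(sub("encoder", "", layer))
      model$encoder[[li]]$W[, col] <- 0
      model$mask$encoder[[li]][col] <- 0
    } else {
      li <- as.integer(sub("head", "", layer))
      model$head[[li]]$W[, col] <- 0
      model$mask$head[[li]][col] <- 0
    }
  }
  report$layer_id <- NULL
  class(report) <- c("prune_report", class(report))
  list(model = model, report = report)
}

#' Recall across a grid of pruning ratios
#'
#' Evaluates independently pruned copies of one base model over an
#' ascending grid of pruning ratios. The evaluator abstracts the screening
#' protocol: it receives a (pruned) model and returns a tibble with columns
#' `class_label` and `recall`.
#'
#' @param model The trained base `siamese_model` (or `siamese_fit`).
#' @param ratios Ascending pruning ratios, each in `[0, 1)`.
#' @param evaluator `function(model) -> tibble(class_label, recall)`.
#' @param sigma,scope Passed to [prune()].
#' @return A `prune_sweep` tibble with columns `ratio`, `class_label`,
#'   `recall`.
#' @export
prune_sweep <- function(model, ratios, evaluator,
                        sigma = c("std", "var"),
                        scope = c("global", "per_layer")) {
  if (inherits(model, "siamese_fit")) model <- model$model
  sigma <- match.arg(sigma)
  scope <- match.arg(scope)
  if (is.unsorted(ratios)) {
    stop_siam("`ratios` must be sorted ascending.", "siam_input_error")
  }
  out <- dplyr::bind_rows(lapply(ratios, function(r) {
    pruned <- prune(model, r, sigma = sigma, scope = scope)$model
    res <- tibble::as_tibble(evaluator(pruned))
    res$ratio <- r
    res
  }))
  out <- out[, c("ratio", "class_label", "recall")]
  class(out) <- c("prune_sweep", class(out))
  out
}
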