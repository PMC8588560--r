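#' Train the Siamese MLP on labelled molecule pairs
#'
#' Minibatch training with binary cross-entropy loss and the RMSprop
#' optimizer. Pairs are shuffled each epoch under the configured seed, so a
#' run is a pure function of (model, pairs, config). With
#' `validation_split > 0` a tail fraction of the (pre-shuffled) pairs is
#' held out for a per-epoch validation loss, and `patience` epochs without
#' improvement stop training early.
#'
#' @param model A `siamese_model` from [siamese_init()].
#' @param pairs A tibble of labelled pairs (`id_a`, `id_b`, `label`) as
#'   produced by [sample_pairs()].
#' @param library The [screening_library] the pair ids refer to.
#' @param config Optional [siamese_config] overriding `model$config` for
#'   the optimisation settings.
#' @return A `siamese_fit`: list with the trained `model` and a `history`
#'   tibble (epoch, loss, val_loss).
#' @export
train_siamese <- function(model, pairs, library, config = model$config) {
  stopifnot(inherits(model, "siamese_model"), is_screening_library(library))
  if (config$epochs < 1) {
    stop_siam("`epochs` must be at least 1.", "siam_input_error")
  }
  if (nrow(pairs) < 1) {
    stop_siam("At least one training pair is required.", "siam_input_error")
  }
  xa <- library$fingerprints[pairs$id_a, , drop = FALSE]
  xb <- library$fingerprints[pairs$id_b, , drop = FALSE]
  storage.mode(xa) <- "double"
  storage.mode(xb) <- "double"
  y <- as.numeric(pairs$label)

  params <- flatten_params(model)
  cache <- numeric(length(params))
  history <- vector("list", config$epochs)

  withr::with_seed(config$seed, {
    n <- length(y)
    ord <- sample.int(n)
    xa <- xa[ord, , drop = FALSE]
    xb <- xb[ord, , drop = FALSE]
    y <- y[ord]
    n_val <- floor(config$validation_split * n)
    val_idx <- if (n_val > 0) seq.int(n - n_val + 1L, n) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    best_val <- Inf
    best_params <- params
    stall <- 0L

    for (epoch in seq_len(config$epochs)) {
      ep_ord <- sample(tr_idx)
      batch_losses <- c()
      for (start in seq(1L, length(ep_ord), by = config$batch_size)) {
        idx <- ep_ord[start:min(start + config$batch_size - 1L, length(ep_ord))]
        g <- siamese_loss_grad(
          model,
          xa[idx, , drop = FALSE], xb[idx, , drop = FALSE], y[idx]
        )
        if (!is.finite(g$loss)) {
          stop_siam(
            "Training diverged (non-finite loss); try a lower learning rate.",
            "siam_divergence_error"
          )
        }
        batch_losses <- c(batch_losses, g$loss)
        grad <- flatten_grads(g, model)
        cache <- config$rho * cache + (1 - config$rho) * grad^2
        params <- params - config$learning_rate * grad / (sqrt(cache) + config$epsilon)
        model <- unflatten_params(model, params)
      }
      val_loss <- NA_real_
      if (n_val > 0) {
        p_val <- forward_matrix(
          model,
          xa[val_idx, , drop = FALSE], xb[val_idx, , drop = FALSE]
        )
        val_loss <- bce_loss(p_val, y[val_idx])
        if (val_loss < best_val - 1e-9) {
          best_val <- val_loss
          best_params <- params
          stall <- 0L
        } else {
          stall <- stall + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = mean(batch_losses), val_loss = val_loss
      )
      if (n_val > 0 && stall >= config$patience) {
        model <- unflatten_params(model, best_params)
        break
      }
    }
  })

  structure(
    list(model = model, history = dplyr::bind_rows(history)),
    class = "siamese_fit"
  )
}

# --- parameter flattening (shared by the optimizer and gradient checks) ---

flatten_params <- function(model) {
  unlist(lapply(c(model$encoder, model$head, list(model$out)), function(l) {
    c(as.numeric(l$W), l$b)
  }))
}

flatten_grads <- function(g, model) {
  unlist(lapply(c(g$encoder, g$head, list(g$out)), function(l) {
    c(as.numeric(l$W), l$b)
  }))
}

unflatten_params <- function(model, params) {
  pos <- 0L
  take_layer <- function(l) {
    nw <- length(l$W)
    nb <- length(l$b)
    l$W[] <- params[pos + seq_len(nw)]
    l$b <- params[pos + nw + seq_len(nb)]
    pos <<- pos + nw + nb
    l
  }
  model$encoder <- lapply(model$encoder, take_layer)
  model$head <- lapply(model$head, take_layer)
  model$out <- take_layer(model$out)
  model
}

#' Classify held-out pairs with a trained model
#'
#' @param fit A `siamese_fit` (or bare `siamese_model`).
#' @param pairs Pair tibble (`id_a`, `id_b`, `label` optional).
#' @param library The [screening_library] the ids refer to.
#' @param threshold Decision threshold on the similarity score.
#' @return The pair tibble with columns `score` and `predicted` added.
#' @export
predict_pairs <- function(fit, pairs, library, threshold = 0.5) {
  model <- if (inherits(fit, "siamese_fit")) fit$model else fit
  xa <- library$fingerprints[pairs$id_a, , drop = FALSE]
  xb <- library$fingerprints[pairs$id_b, , drop = FALSE]
  storage.mode(xa) <- "double"
  storage.mode(xb) <- "double"
  pairs$score <- as.numeric(forward_matrix(model, xa, xb))
  pairs$predicted <- as.integer(pairs$score >= threshold)
  pairs
}

#' @export
print.siamese_fit <- function(x, ...) {
  cat(sprintf(
    "<siamese_fit> %d epochs, final loss %.4f\n",
    nrow(x$history), x$history$loss[nrow(x$history)]
  ))
  print(x$model)
  invisible(x)
}

#' Tidy the training history of a Siamese fit
#'
#' @param x A `siamese_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch history tibble. `glance()`: a one-row
#'   tibble with epoch count, final losses and parameter count.
#' @export
tidy.siamese_fit <- function(x, ...) x$history

#' @rdname tidy.siamese_fit
#' @export
glance.siamese_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_loss = h$loss[nrow(h)],
    final_val_loss = h$val_loss[nrow(h)],
    n_parameters = n_parameters(x$model),
    nodes_active = sum(unlist(x$model$mask)),
    nodes_total = length(unlist(x$model$mask))
  )
}
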