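#' Configuration of the Siamese MLP similarity model
#'
#' The model takes two count fingerprints, passes each through the same
#' (weight-shared) rectifier encoder, compares the two embeddings with two
#' fixed distance layers — element-wise Manhattan distance `|e_a - e_b|`
#' and exponential Manhattan distance `exp(-|e_a - e_b|)` — concatenates
#' the two distance vectors in a fusion layer, and feeds the result through
#' a trainable rectifier head ending in a single logistic-sigmoid unit.
#' The output near 1 means "high similarity" (same activity class), near 0
#' "high dissimilarity". Training uses binary cross-entropy with the
#' RMSprop optimizer.
#'
#' @param input_dim Fingerprint length (default 1024 input cells).
#' @param encoder_sizes Hidden widths of the shared twin encoder; `integer(0)`
#'   makes the encoder the identity, so the distance layers act on the raw
#'   fingerprints.
#' @param post_fusion_sizes Widths of the trainable layers after the fusion
#'   layer.
#' @param batch_size Minibatch size (default 256).
#' @param epochs Training epochs.
#' @param learning_rate,rho,epsilon RMSprop hyperparameters.
#' @param validation_split Fraction of pairs held out for per-epoch
#'   validation loss (0 disables).
#' @param patience Early-stopping patience in epochs on the validation
#'   loss (`Inf` disables; requires `validation_split > 0`).
#' @param seed Integer seed governing initialisation and shuffling.
#' @return A `siamese_config` object.
#' @export
siamese_config <- function(input_dim = 1024,
                           encoder_sizes = c(512, 256),
                           post_fusion_sizes = c(256, 128, 64),
                           batch_size = 256,
                           epochs = 20,
                           learning_rate = 1e-3,
                           rho = 0.9,
                           epsilon = 1e-8,
                           validation_split = 0,
                           patience = Inf,
                           seed = 1) {
  assert_scalar_number(input_dim, "input_dim", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  assert_scalar_number(epochs, "epochs", lower = 1)
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  if (length(encoder_sizes) && any(encoder_sizes < 1)) {
    stop_siam("All encoder widths must be >= 1.", "siam_input_error")
  }
  if (length(post_fusion_sizes) && any(post_fusion_sizes < 1)) {
    stop_siam("All post-fusion widths must be >= 1.", "siam_input_error")
  }
  structure(
    list(
      input_dim = as.integer(input_dim),
      encoder_sizes = as.integer(encoder_sizes),
      post_fusion_sizes = as.integer(post_fusion_sizes),
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      learning_rate = learning_rate,
      rho = rho,
      epsilon = epsilon,
      validation_split = validation_split,
      patience = patience,
      seed = as.integer(seed)
    ),
    class = "siamese_config"
  )
}

# Embedding width entering the distance layers.
embed_dim <- function(config) {
  if (length(config$encoder_sizes)) {
    config$encoder_sizes[length(config$encoder_sizes)]
  } else {
    config$input_dim
  }
}

#' Initialise a Siamese MLP model
#'
#' Parameters use fan-in-scaled (He) normal initialisation,
#' `N(0, 2 / fan_in)`, with zero biases; both branches reference the same
#' encoder parameters by construction, and the prune mask starts all-ones.
#' Deterministic given `config$seed`.
#'
#' @param config A [siamese_config].
#' @return A `siamese_model` object.
#' @export
siamese_init <- function(config) {
  stopifnot(inherits(config, "siamese_config"))
  init_layer <- function(fan_in, fan_out) {
    list(
      W = matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out),
      b = numeric(fan_out)
    )
  }
  withr::with_seed(config$seed, {
    enc_dims <- c(config$input_dim, config$encoder_sizes)
    encoder <- lapply(seq_along(config$encoder_sizes), function(l) {
      init_layer(enc_dims[l], enc_dims[l + 1L])
    })
    head_dims <- c(2L * embed_dim(config), config$post_fusion_sizes)
    head <- lapply(seq_along(config$post_fusion_sizes), function(l) {
      init_layer(head_dims[l], head_dims[l + 1L])
    })
    out <- init_layer(head_dims[length(head_dims)], 1L)
  })
  structure(
    list(
      config = config,
      encoder = encoder,
      head = head,
      out = out,
      mask = list(
        encoder = lapply(config$encoder_sizes, function(w) rep(1, w)),
        head = lapply(config$post_fusion_sizes, function(w) rep(1, w))
      )
    ),
    class = "siamese_model"
  )
}

#' @export
print.siamese_model <- function(x, ...) {
  cat(sprintf(
    "<siamese_model> input %d | encoder [%s] | fusion 2x%d | head [%s] -> 1 | %d parameters, %d/%d nodes active\n",
    x$config$input_dim,
    paste(x$config$encoder_sizes, collapse = ", "),
    embed_dim(x$config),
    paste(x$config$post_fusion_sizes, collapse = ", "),
    n_parameters(x),
    sum(unlist(x$mask)), length(unlist(x$mask))
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form `sum((fan_in + 1) * fan_out)` over the encoder, post-fusion
#' and output layers (the distance and fusion layers are fixed and have no
#' weights).
#'
#' @param model A `siamese_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  layers <- c(model$encoder, model$head, list(model$out))
  sum(vapply(layers, function(l) length(l$W) + length(l$b), numeric(1)))
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

# Encoder forward over a batch matrix (n x input_dim); returns activations.
encode_matrix <- function(model, x, cache = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != model$config$input_dim) {
    stop_siam(
      sprintf("Fingerprint length %d does not match input_dim %d.",
              ncol(x), model$config$input_dim),
      "siam_shape_error"
    )
  }
  zs <- list()
  as <- list(x)
  a <- x
  for (l in seq_along(model$encoder)) {
    z <- sweep(a %*% model$encoder[[l]]$W, 2L, model$encoder[[l]]$b, "+")
    a <- sweep(relu(z), 2L, model$mask$encoder[[l]], "*")
    if (cache) {
      zs[[l]] <- z
      as[[l + 1L]] <- a
    }
  }
  if (cache) list(embedding = a, z = zs, a = as) else a
}

#' Encode a fingerprint with the shared twin encoder
#'
#' @param model A `siamese_model`.
#' @param fp A count fingerprint (or a matrix of fingerprints in rows).
#' @return The embedding vector (or matrix of embeddings).
#' @export
encode <- function(model, fp) {
  if (is.matrix(fp)) {
    encode_matrix(model, fp)
  } else {
    drop(encode_matrix(model, matrix(as.numeric(fp), nrow = 1L)))
  }
}

#' Fixed distance layers
#'
#' `manhattan_layer()` is the element-wise Manhattan distance
#' `|e_a - e_b|`; `exp_manhattan_layer()` is its exponential transform
#' `exp(-|e_a - e_b|)`, which maps agreement to 1 and large differences
#' towards 0. Both are symmetric in their arguments and have no trainable
#' weights.
#'
#' @param e_a,e_b Embedding vectors (or matrices with embeddings in rows)
#'   of equal shape.
#' @return A vector/matrix of the same shape as the inputs.
#' @export
manhattan_layer <- function(e_a, e_b) {
  if (length(e_a) != length(e_b)) {
    stop_siam("Embeddings must have equal shape.", "siam_shape_error")
  }
  abs(e_a - e_b)
}

#' @rdname manhattan_layer
#' @export
exp_manhattan_layer <- function(e_a, e_b) {
  exp(-manhattan_layer(e_a, e_b))
}

# Full forward pass over batch matrices, optionally caching intermediates
# for backprop.
forward_matrix <- function(model, xa, xb, cache = FALSE) {
  ea <- encode_matrix(model, xa, cache = cache)
  eb <- encode_matrix(model, xb, cache = cache)
  emb_a <- if (cache) ea$embedding else ea
  emb_b <- if (cache) eb$embedding else eb
  d <- abs(emb_a - emb_b)
  ex <- exp(-d)
  f <- cbind(d, ex)
  zs <- list()
  as <- list(f)
  a <- f
  for (l in seq_along(model$head)) {
    z <- sweep(a %*% model$head[[l]]$W, 2L, model$head[[l]]$b, "+")
    a <- sweep(relu(z), 2L, model$mask$head[[l]], "*")
    if (cache) {
      zs[[l]] <- z
      as[[l + 1L]] <- a
    }
  }
  z_out <- drop(a %*% model$out$W) + model$out$b
  p <- sigmoid(z_out)
  if (!cache) return(p)
  list(
    p = p, z_out = z_out, head_z = zs, head_a = as,
    enc_a = ea, enc_b = eb, emb_a = emb_a, emb_b = emb_b, d = d, ex = ex
  )
}

#' Siamese similarity score for a pair of fingerprints
#'
#' Runs the full forward pass: shared encoder on both inputs, Manhattan and
#' exponential-Manhattan distance layers, fusion (concatenation) and the
#' sigmoid-terminated head. The score is symmetric in its arguments by
#' construction and lies strictly inside (0, 1).
#'
#' @param model A `siamese_model`.
#' @param fp_a,fp_b Count fingerprints (vectors, or matrices pairing row i
#'   of `fp_a` with row i of `fp_b`).
#' @return Similarity score(s) in (0, 1).
#' @export
siamese_forward <- function(model, fp_a, fp_b) {
  if (!is.matrix(fp_a)) fp_a <- matrix(as.numeric(fp_a), nrow = 1L)
  if (!is.matrix(fp_b)) fp_b <- matrix(as.numeric(fp_b), nrow = 1L)
  drop(forward_matrix(model, fp_a, fp_b))
}

# Binary cross-entropy of predictions p against 0/1 labels, with clamping
# for numerical safety at saturated sigmoids.
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# Loss and analytic gradients for one batch. Gradients for the shared
# encoder accumulate contributions from both branches. The returned
# gradient lists mirror model$encoder / model$head / model$out.
siamese_loss_grad <- function(model, xa, xb, y) {
  n <- nrow(xa)
  fw <- forward_matrix(model, xa, xb, cache = TRUE)
  loss <- bce_loss(fw$p, y)

  k <- ncol(fw$d)
  dz_out <- matrix((fw$p - y) / n, ncol = 1L)
  a_last <- fw$head_a[[length(fw$head_a)]]
  g_out <- list(W = crossprod(a_last, dz_out), b = sum(dz_out))

  da <- dz_out %*% t(model$out$W)
  g_head <- vector("list", length(model$head))
  for (l in rev(seq_along(model$head))) {
    dz <- da * (fw$head_z[[l]] > 0)
    dz <- sweep(dz, 2L, model$mask$head[[l]], "*")
    g_head[[l]] <- list(
      W = crossprod(fw$head_a[[l]], dz),
      b = colSums(dz)
    )
    da <- dz %*% t(model$head[[l]]$W)
  }

  dd <- da[, seq_len(k), drop = FALSE]
  dex <- da[, k + seq_len(k), drop = FALSE]
  # ex = exp(-d): total derivative wrt d subtracts ex-weighted dex
  dd_total <- dd - dex * fw$ex
  s <- sign(fw$emb_a - fw$emb_b)
  dea <- dd_total * s
  deb <- -dea

  g_enc <- lapply(model$encoder, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  })
  backprop_branch <- function(branch_cache, de) {
    for (l in rev(seq_along(model$encoder))) {
      dz <- de * (branch_cache$z[[l]] > 0)
      dz <- sweep(dz, 2L, model$mask$encoder[[l]], "*")
      g_enc[[l]]$W <<- g_enc[[l]]$W + crossprod(branch_cache$a[[l]], dz)
      g_enc[[l]]$b <<- g_enc[[l]]$b + colSums(dz)
      de <- dz %*% t(model$encoder[[l]]$W)
    }
  }
  if (length(model$encoder)) {
    backprop_branch(fw$enc_a, dea)
    backprop_branch(fw$enc_b, deb)
  }

  list(loss = loss, encoder = g_enc, head = g_head, out = g_out)
}
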