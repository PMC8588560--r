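test_that("initialisation is deterministic and counts parameters in closed form", {
  cfg <- siamese_config(input_dim = 10, encoder_sizes = c(7, 5),
                        post_fusion_sizes = c(6, 3), seed = 8)
  m1 <- siamese_init(cfg)
  m2 <- siamese_init(cfg)
  expect_identical(siamscreen:::flatten_params(m1), siamscreen:::flatten_params(m2))
  # sum((fan_in + 1) * fan_out) over 10->7->5, fusion 2*5=10 ->6->3->1
  expect_equal(
    n_parameters(m1),
    (10 + 1) * 7 + (7 + 1) * 5 + (10 + 1) * 6 + (6 + 1) * 3 + (3 + 1) * 1
  )
})

test_that("an empty encoder applies the distance layers to raw fingerprints", {
  cfg <- siamese_config(input_dim = 4, encoder_sizes = integer(0),
                        post_fusion_sizes = c(3), seed = 2)
  m <- siamese_init(cfg)
  x <- c(1, 4, 0, 2)
  expect_equal(encode(m, x), x)
})

test_that("encoding matches a hand-computed ReLU(Wx + b)", {
  cfg <- siamese_config(input_dim = 2, encoder_sizes = c(2),
                        post_fusion_sizes = c(2), seed = 3)
  m <- siamese_init(cfg)
  m$encoder[[1]]$W <- matrix(c(1, -2, 0.5, 3), 2, 2)
  m$encoder[[1]]$b <- c(-1, 0.25)
  x <- c(2, 1)
  expect_equal(
    encode(m, x),
    pmax(c(2 * 1 + 1 * (-2) - 1, 2 * 0.5 + 1 * 3 + 0.25), 0)
  )
  expect_error(encode(m, c(1, 2, 3)), class = "siam_shape_error")
})

test_that("distance layers follow their definitions", {
  expect_equal(manhattan_layer(c(3, 1), c(1, 4)), c(2, 3))
  expect_equal(manhattan_layer(c(2, 2), c(2, 2)), c(0, 0))
  expect_equal(exp_manhattan_layer(c(5, 5), c(5, 5)), c(1, 1))
  expect_equal(exp_manhattan_layer(c(3, 1), c(1, 4)), exp(-c(2, 3)))
  for (seed in 1:10) {
    p <- random_fp_pair(seed)
    expect_identical(manhattan_layer(p$a, p$b), manhattan_layer(p$b, p$a))
    expect_true(all(exp_manhattan_layer(p$a, p$b) > 0))
    expect_true(all(exp_manhattan_layer(p$a, p$b) <= 1))
  }
  expect_error(manhattan_layer(1:3, 1:4), class = "siam_shape_error")
})

test_that("the forward pass matches a hand-evaluated tiny network", {
  cfg <- siamese_config(input_dim = 2, encoder_sizes = c(2),
                        post_fusion_sizes = c(2), seed = 4)
  m <- siamese_init(cfg)
  m$encoder[[1]]$W <- matrix(c(1, 0, 0, 1), 2, 2)
  m$encoder[[1]]$b <- c(0, 0)
  m$head[[1]]$W <- matrix(c(1, -1, 0.5, 0.25,
                            0.3, 0.7, -0.2, 0.1), 4, 2)
  m$head[[1]]$b <- c(0.1, -0.1)
  m$out$W <- matrix(c(2, -1), 2, 1)
  m$out$b <- 0.2
  a <- c(3, 1); b <- c(1, 2)
  d <- abs(a - b)                      # encoder is identity here
  f <- c(d, exp(-d))
  h <- pmax(c(sum(f * m$head[[1]]$W[, 1]) + 0.1,
              sum(f * m$head[[1]]$W[, 2]) - 0.1), 0)
  expected <- 1 / (1 + exp(-(2 * h[1] - 1 * h[2] + 0.2)))
  expect_equal(siamese_forward(m, a, b), expected)
})

test_that("forward is symmetric in its arguments and strictly inside (0,1)", {
  for (seed in 1:10) {
    m <- tiny_model(seed = seed, generic_point = TRUE)
    p <- random_fp_pair(seed + 100)
    s_ab <- siamese_forward(m, p$a, p$b)
    expect_identical(s_ab, siamese_forward(m, p$b, p$a))
    expect_gt(s_ab, 0)
    expect_lt(s_ab, 1)
  }
})

test_that("encoder parameters are shared by both branches", {
  m <- tiny_model(seed = 5, generic_point = TRUE)
  p <- random_fp_pair(7)
  m2 <- m
  m2$encoder[[1]]$W[1, 1] <- m2$encoder[[1]]$W[1, 1] + 0.5
  # after mutating shared weights the pass stays symmetric: both branches saw
  # the same change
  expect_identical(siamese_forward(m2, p$a, p$b), siamese_forward(m2, p$b, p$a))
  expect_false(identical(siamese_forward(m, p$a, p$b), siamese_forward(m2, p$a, p$b)))
})

test_that("backpropagation matches finite differences at a generic point", {
  m <- tiny_model(seed = 12, generic_point = TRUE)
  withr::with_seed(99, {
    xa <- matrix(as.numeric(rpois(5 * 6, 2)), 5, 6)
    xb <- matrix(as.numeric(rpois(5 * 6, 2)), 5, 6)
  })
  y <- c(1, 0, 1, 0, 1)
  g <- siamscreen:::siamese_loss_grad(m, xa, xb, y)
  ana <- siamscreen:::flatten_grads(g, m)
  par0 <- siamscreen:::flatten_params(m)
  num <- vapply(seq_along(par0), function(i) {
    e <- 1e-6
    pp <- par0; pp[i] <- pp[i] + e
    pm <- par0; pm[i] <- pm[i] - e
    lp <- siamscreen:::bce_loss(
      siamscreen:::forward_matrix(siamscreen:::unflatten_params(m, pp), xa, xb), y)
    lm <- siamscreen:::bce_loss(
      siamscreen:::forward_matrix(siamscreen:::unflatten_params(m, pm), xa, xb), y)
    (lp - lm) / (2 * e)
  }, numeric(1))
  rel <- abs(ana - num) / pmax(1e-6, abs(ana) + abs(num))
  expect_lt(max(rel), 1e-4)
})

test_that("training reduces the loss on learnable data and replays exactly", {
  lib <- small_synth(seed = 51, n_actives = c(15, 15), diversity = c(0.4, 0.4),
                     n_decoys = 60, dim = 128)
  pairs <- sample_pairs(lib, 300, seed = 6)
  cfg <- siamese_config(input_dim = 128, encoder_sizes = c(16),
                        post_fusion_sizes = c(8), epochs = 8,
                        batch_size = 64, seed = 13)
  fit <- train_siamese(siamese_init(cfg), pairs, lib, cfg)
  expect_equal(nrow(fit$history), 8)
  expect_lt(fit$history$loss[8], fit$history$loss[1])
  fit2 <- train_siamese(siamese_init(cfg), pairs, lib, cfg)
  expect_identical(
    siamscreen:::flatten_params(fit$model),
    siamscreen:::flatten_params(fit2$model)
  )
  expect_identical(fit$history, fit2$history)
})

test_that("invalid training configurations are rejected", {
  expect_error(siamese_config(input_dim = 8, epochs = 0), class = "siam_input_error")
  expect_error(siamese_config(input_dim = 8, encoder_sizes = c(4, 0)),
               class = "siam_input_error")
  lib <- tiny_library()
  m <- siamese_init(siamese_config(input_dim = 8, encoder_sizes = c(4),
                                   post_fusion_sizes = c(4)))
  expect_error(train_siamese(m, sample_pairs(lib, 4, 1)[0, ], lib),
               class = "siam_input_error")
})
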