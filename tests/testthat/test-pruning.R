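test_that("column SNR follows |mean| / population-sd with documented sentinels", {
  expect_equal(column_snr(cbind(c(1, -1))), 0)
  expect_equal(column_snr(cbind(c(2, 2, 2))), Inf)
  expect_equal(column_snr(cbind(c(2, 4))), 3 / 1)  # population sd of {2,4} is 1
  expect_equal(column_snr(cbind(c(0, 0), c(1, 3))), c(0, 2))
  expect_equal(column_snr(cbind(c(2, 4)), sigma = "var"), 3)
  expect_error(column_snr(matrix(1, 1, 3)), class = "siam_degenerate_error")
})

test_that("SNR ordering matches a brute-force per-column computation", {
  for (seed in 1:20) {
    w <- withr::with_seed(seed, matrix(rnorm(8 * 12), 8, 12))
    brute <- vapply(seq_len(ncol(w)), function(j) {
      mu <- sum(w[, j]) / nrow(w)
      sd_ <- sqrt(sum((w[, j] - mu)^2) / nrow(w))
      abs(mu) / sd_
    }, numeric(1))
    expect_equal(column_snr(w), brute)
    expect_identical(order(column_snr(w)), order(brute))
  }
})

test_that("ratio-0 pruning is a bit-exact no-op", {
  m <- tiny_model(seed = 31, generic_point = TRUE)
  pr <- prune(m, 0)
  p <- random_fp_pair(3)
  expect_identical(siamese_forward(pr$model, p$a, p$b), siamese_forward(m, p$a, p$b))
  expect_equal(sum(pr$report$pruned), 0)
})

test_that("pruning masks exactly the lowest-SNR columns", {
  cfg <- siamese_config(input_dim = 6, encoder_sizes = integer(0),
                        post_fusion_sizes = c(10), seed = 17)
  m <- siamese_init(cfg)
  pr <- prune(m, 0.5)
  expect_equal(sum(pr$report$pruned), 5)
  brute <- order(column_snr(m$head[[1]]$W))[1:5]
  expect_setequal(pr$report$column[pr$report$pruned], brute)
  expect_true(all(pr$model$head[[1]]$W[, brute] == 0))
  expect_equal(unname(pr$model$mask$head[[1]][brute]), rep(0, 5))
  # the original model is untouched
  expect_false(any(m$mask$head[[1]] == 0))
})

test_that("masked-node count is floor(ratio x n_prunable) across a ratio grid", {
  m <- tiny_model(seed = 33, encoder = c(7, 5), head = c(6, 4))
  n_prunable <- 7 + 5 + 6 + 4
  for (r in c(0, 0.1, 0.25, 0.33, 0.5, 0.77, 0.99)) {
    pr <- prune(m, r)
    expect_equal(sum(pr$report$pruned), floor(r * n_prunable))
    expect_equal(sum(unlist(pr$model$mask) == 0), floor(r * n_prunable))
  }
  expect_error(prune(m, 1), class = "siam_range_error")
  expect_error(prune(m, -0.1), class = "siam_range_error")
})

test_that("per-layer pruning prunes the same fraction within each layer", {
  m <- tiny_model(seed = 35, encoder = c(10), head = c(10))
  pr <- prune(m, 0.3, scope = "per_layer")
  by_layer <- tapply(pr$report$pruned, pr$report$layer, sum)
  expect_true(all(by_layer == 3))
})

test_that("pruning is idempotent at a fixed ratio", {
  m <- tiny_model(seed = 37, generic_point = TRUE)
  pr1 <- prune(m, 0.4)
  pr2 <- prune(pr1$model, 0.4)
  key <- function(rep) paste(rep$layer, rep$column)[rep$pruned]
  expect_setequal(key(pr2$report), key(pr1$report))
  p <- random_fp_pair(5)
  expect_identical(
    siamese_forward(pr2$model, p$a, p$b),
    siamese_forward(pr1$model, p$a, p$b)
  )
})

test_that("pruned models keep forward symmetry and output bounds", {
  for (seed in 1:5) {
    m <- tiny_model(seed = seed + 40, generic_point = TRUE)
    pm <- prune(m, 0.5)$model
    p <- random_fp_pair(seed)
    s <- siamese_forward(pm, p$a, p$b)
    expect_identical(s, siamese_forward(pm, p$b, p$a))
    expect_gt(s, 0)
    expect_lt(s, 1)
  }
})

test_that("prune_sweep evaluates one independently pruned copy per ratio", {
  m <- tiny_model(seed = 51, input_dim = 8, encoder = c(6), head = c(5))
  fake_eval <- function(model) {
    tibble::tibble(
      class_label = c("A", "B"),
      recall = rep(100 * mean(unlist(model$mask)), 2)
    )
  }
  sw <- prune_sweep(m, c(0, 0.25, 0.5), fake_eval)
  expect_equal(nrow(sw), 3 * 2)
  expect_equal(sw$recall[sw$ratio == 0], c(100, 100))
  expect_true(all(diff(sw$recall[sw$class_label == "A"]) <= 0))
  expect_error(prune_sweep(m, c(0.5, 0.2), fake_eval), class = "siam_input_error")
})
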