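make_ranked_library <- function(seed = 61) {
  lib <- small_synth(seed = seed, n_actives = c(12, 12), diversity = c(0.35, 0.25),
                     n_decoys = 100, dim = 128)
  select_queries(lib, n_per_class = 2, seed = seed)
}

test_that("Tanimoto ranking equals a brute-force sort over the test set", {
  lib <- make_ranked_library()
  rec <- lib$records
  q_id <- rec$id[rec$class_label == "class1" & rec$role == "QUERY"][1]
  one_query <- lib
  one_query$records$role[one_query$records$id != q_id &
                           one_query$records$role == "QUERY"] <- "TEST"
  ranked <- score_library(one_query, "class1", "tanimoto")
  t_ids <- one_query$records$id[one_query$records$role == "TEST"]
  brute <- vapply(t_ids, function(id) {
    tanimoto_continuous(lib$fingerprints[id, ], lib$fingerprints[q_id, ])
  }, numeric(1))
  brute <- sort(brute, decreasing = TRUE)
  expect_equal(ranked$score, unname(brute))
  expect_false(q_id %in% ranked$id)
})

test_that("MAX fusion is idempotent under duplicated queries and never hurt by more", {
  lib <- make_ranked_library(seed = 63)
  ranked2 <- score_library(lib, "class1", "tanimoto", fusion = "max")
  # single-query ranking: demote one of the two queries to TEST
  rec <- lib$records
  q_ids <- rec$id[rec$class_label == "class1" & rec$role == "QUERY"]
  single <- lib
  single$records$role[single$records$id == q_ids[2]] <- "TEST"
  ranked1 <- score_library(single, "class1", "tanimoto", fusion = "max")
  common <- intersect(ranked1$id, ranked2$id)
  s1 <- setNames(ranked1$score, ranked1$id)[common]
  s2 <- setNames(ranked2$score, ranked2$id)[common]
  # adding a query can only raise a MAX-fused score
  expect_true(all(s2 >= s1 - 1e-12))
})

test_that("score ties break by molecule id ascending", {
  fp <- rbind(
    c(1L, 0L, 0L, 0L), # query
    c(0L, 1L, 0L, 0L), # z, score 0
    c(0L, 0L, 1L, 0L), # a, score 0
    c(1L, 0L, 0L, 0L)  # m, score 1
  )
  lib <- screening_library(
    tibble::tibble(
      id = c("q", "z", "a", "m"),
      class_label = c("C", "C", "C", "C"),
      role = c("QUERY", "TEST", "TEST", "TEST")
    ),
    fp
  )
  ranked <- score_library(lib, "C", "tanimoto")
  expect_equal(ranked$id, c("m", "a", "z"))
})

test_that("top-percent recall counts the floor-cut slice", {
  ranked <- tibble::tibble(id = sprintf("m%04d", 1:1000))
  actives <- withr::with_seed(71, sample(ranked$id, 50))
  brute <- 100 * sum(ranked$id[1:floor(0.05 * 1000)] %in% actives) / 50
  expect_equal(top_percent_recall(ranked, actives, 5), brute)
  # all actives at the head
  top <- tibble::tibble(id = c(actives, setdiff(ranked$id, actives)))
  expect_equal(top_percent_recall(top, actives, 5), 100)
  expect_equal(top_percent_recall(ranked, ranked$id[1:10][1:10], 1), 100)
  expect_equal(top_percent_recall(tibble::tibble(id = ranked$id[1:100]),
                                  ranked$id[1:10], 2), 20)
  expect_error(top_percent_recall(ranked, character(0), 5),
               class = "siam_undefined_error")
})

test_that("recall is monotone in the cutoff and complete at 100%", {
  ranked <- tibble::tibble(id = sprintf("m%03d", sample(1:500)))
  actives <- sprintf("m%03d", 1:40)
  recalls <- vapply(c(1, 2, 5, 10, 25, 50, 100), function(pct) {
    top_percent_recall(ranked, actives, pct)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
  expect_equal(recalls[length(recalls)], 100)
})

test_that("recall tables compute mean rows and shaded counts", {
  tbl <- recall_table(tibble::tibble(
    class_label = c("c1", "c2", "c3"),
    A = c(10, 20, 30),
    B = c(10, 25, 10)
  ))
  expect_equal(unname(tbl$mean_row), c(20, 15))
  expect_equal(unname(tbl$shaded), c(2, 2))  # c1 ties mark both methods
  single <- recall_table(tibble::tibble(class_label = c("c1", "c2"), A = c(1, 2)))
  expect_equal(unname(single$shaded), 2)
  expect_error(
    recall_table(tibble::tibble(class_label = "c", A = NA_real_)),
    class = "siam_shape_error"
  )
})

test_that("recall tables round-trip through CSV with footer rows", {
  tbl <- recall_table(tibble::tibble(
    class_label = c("c1", "c2"), TAN = c(10.5, 20.25), MLP = c(30, 10)
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recall_table(tbl, path)
  back <- read_recall_table(path)
  expect_equal(back$table, tbl$table)
  expect_equal(unname(attr(back, "printed_mean")), unname(tbl$mean_row))
  expect_equal(unname(attr(back, "printed_shaded")), unname(as.numeric(tbl$shaded)))
})

test_that("benchmark evaluation is deterministic and merges external columns", {
  lib <- make_ranked_library(seed = 67)
  cfg <- siamese_config(input_dim = 128, encoder_sizes = c(16),
                        post_fusion_sizes = c(8), epochs = 2,
                        batch_size = 64, seed = 3)
  fit <- train_siamese(siamese_init(cfg), sample_pairs(lib, 120, 5), lib, cfg)
  t1 <- evaluate_benchmark(fit, lib, pcts = c(1, 5))
  t2 <- evaluate_benchmark(fit, lib, pcts = c(1, 5))
  expect_identical(t1$top1$table, t2$top1$table)
  expect_equal(t1$top1$methods, c("TAN", "MLP"))

  ext <- tibble::tibble(class_label = c("class1", "class2"), SQB = c(11, 22))
  t3 <- evaluate_benchmark(fit, lib, pcts = 1, external = list(`1` = ext))
  expect_equal(t3$top1$methods, c("TAN", "MLP", "SQB"))
  expect_equal(t3$top1$table$SQB, c(11, 22))
  bad <- tibble::tibble(class_label = c("classX", "class2"), SQB = c(1, 2))
  expect_error(evaluate_benchmark(fit, lib, pcts = 1, external = list(`1` = bad)),
               class = "siam_join_error")
})
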