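test_that("target diversity 1 yields identical actives and zero noise", {
  expect_equal(calibrate_noise(1.0, dim = 64, seed = 3), 0)
  lib <- generate_library(library_spec(
    data.frame(n_actives = 10, target_diversity = 1.0),
    n_decoys = 0, dim = 64, seed = 3
  ))
  expect_equal(lib$classes$diversity, 1)
  expect_true(all(apply(lib$fingerprints, 2, function(col) length(unique(col)) == 1)))
})

test_that("generated class diversity lands near its target", {
  spec <- library_spec(
    data.frame(n_actives = 30, target_diversity = 0.12),
    n_decoys = 1500, dim = 1024, seed = 7
  )
  lib <- generate_library(spec)
  expect_gte(lib$classes$diversity, 0.10)
  expect_lte(lib$classes$diversity, 0.14)
})

test_that("generation is a pure function of the seed", {
  spec <- library_spec(
    data.frame(n_actives = c(12, 15), target_diversity = c(0.3, 0.15)),
    n_decoys = 40, dim = 64, seed = 19
  )
  lib1 <- generate_library(spec)
  lib2 <- generate_library(spec)
  expect_identical(lib1$fingerprints, lib2$fingerprints)
  expect_identical(lib1$records, lib2$records)
})

test_that("noise calibration is monotone and replays near the target", {
  n_035 <- calibrate_noise(0.35, dim = 256, seed = 5)
  n_012 <- calibrate_noise(0.12, dim = 256, seed = 5)
  expect_lt(n_035, n_012)
  replay <- siamscreen:::mean_pairwise_tanimoto(
    siamscreen:::draw_class(50, n_035, 256, seed = 777)
  )
  expect_lt(abs(replay - 0.35), 0.03)
})

test_that("pair sampling is balanced, self-pair-free and deterministic", {
  lib <- small_synth(seed = 41)
  pairs <- sample_pairs(lib, 10, seed = 1)
  expect_equal(sum(pairs$label == 1), 5)
  expect_equal(sum(pairs$label == 0), 5)
  pairs_odd <- sample_pairs(lib, 11, seed = 1)
  expect_lte(abs(sum(pairs_odd$label == 1) - sum(pairs_odd$label == 0)), 1)

  big <- sample_pairs(lib, 400, seed = 2)
  expect_true(all(big$id_a != big$id_b))
  cls <- function(ids) lib$records$class_label[match(ids, lib$records$id)]
  expect_true(all(cls(big$id_a[big$label == 1]) == cls(big$id_b[big$label == 1])))
  expect_true(all(cls(big$id_a[big$label == 0]) != cls(big$id_b[big$label == 0])))
  expect_false(any(cls(big$id_a) == "DECOY" & cls(big$id_b) == "DECOY"))

  expect_identical(sample_pairs(lib, 50, seed = 9), sample_pairs(lib, 50, seed = 9))
})

test_that("positive pairs are more similar than negative pairs", {
  lib <- small_synth(seed = 43, n_actives = c(15, 15), diversity = c(0.35, 0.30),
                     n_decoys = 60, dim = 128)
  pairs <- sample_pairs(lib, 300, seed = 4)
  sims <- vapply(seq_len(nrow(pairs)), function(i) {
    tanimoto_continuous(
      lib$fingerprints[pairs$id_a[i], ],
      lib$fingerprints[pairs$id_b[i], ]
    )
  }, numeric(1))
  expect_gt(mean(sims[pairs$label == 1]), mean(sims[pairs$label == 0]))
})

test_that("query selection marks the requested actives per class", {
  lib <- small_synth(seed = 47, n_actives = c(10, 14), n_decoys = 20)
  sel <- select_queries(lib, n_per_class = 10, seed = 2)
  counts <- table(sel$records$class_label[sel$records$role == "QUERY"])
  expect_equal(unname(c(counts["class1"], counts["class2"])), c(10L, 10L))
  # a class with exactly n_per_class actives contributes all of them
  expect_setequal(
    sel$records$id[sel$records$class_label == "class1" & sel$records$role == "QUERY"],
    sel$records$id[sel$records$class_label == "class1"]
  )
  expect_true(all(sel$records$role[sel$records$class_label == "DECOY"] == "TEST"))
  expect_identical(select_queries(lib, 10, seed = 2), sel)
  expect_error(select_queries(lib, 12, seed = 2), "class1",
               class = "siam_selection_error")
})
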