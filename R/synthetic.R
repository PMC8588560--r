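#' Specify a synthetic screening library
#'
#' Describes a benchmark-style library: a set of activity classes, each with
#' an active count and a target structural diversity (mean pairwise
#' continuous Tanimoto among its actives), over a large background of
#' decoys. Defaults emulate the published benchmark structure: class sizes
#' from a few tens (MUV-like) to thousands (MDDR-like) of actives, class
#' diversities from ~0.10 (heterogeneous) to ~0.39 (homogeneous), and
#' decoys drawn from an unbiased sparse background whose own mean pairwise
#' similarity is about 0.05.
#'
#' @param classes A data frame (or tibble) with columns `n_actives`
#'   (integer, at least 10 so ten query structures can be drawn) and
#'   `target_diversity` (in `(0.05, 1]`). An optional `class_label` column
#'   names the classes; labels `class1`, `class2`, ... are used otherwise.
#' @param n_decoys Number of background decoy molecules.
#' @param dim Fingerprint length (default 1024, the standard folded ECFC
#'   width).
#' @param seed Integer seed fixing every random choice in generation.
#' @return A `library_spec` object.
#' @export
library_spec <- function(classes, n_decoys, dim = 1024, seed = 1) {
  classes <- tibble::as_tibble(classes)
  if (!all(c("n_actives", "target_diversity") %in% names(classes))) {
    stop_siam("`classes` needs columns `n_actives` and `target_diversity`.", "siam_input_error")
  }
  if (!"class_label" %in% names(classes)) {
    classes$class_label <- paste0("class", seq_len(nrow(classes)))
  }
  if (any(classes$n_actives < 10)) {
    stop_siam("Each class needs at least 10 actives.", "siam_input_error")
  }
  if (any(classes$target_diversity <= 0.05 | classes$target_diversity > 1)) {
    stop_siam("`target_diversity` must lie in (0.05, 1].", "siam_input_error")
  }
  assert_scalar_number(n_decoys, "n_decoys", lower = 0)
  assert_scalar_number(dim, "dim", lower = 2)
  structure(
    list(
      classes = classes[, c("class_label", "n_actives", "target_diversity")],
      n_decoys = as.integer(n_decoys),
      dim = as.integer(dim),
      seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

# Sparse count background: each position is occupied independently with
# probability `density`, occupied counts are 1 + Poisson(0.3). Two
# independent draws then share ~0.05 mean continuous Tanimoto at the
# default density, matching unbiased (MUV-style) decoy sets.
BACKGROUND_DENSITY <- 0.12

draw_background <- function(n, dim, density = BACKGROUND_DENSITY) {
  draw <- function(k) {
    occ <- matrix(rbinom(k * dim, 1L, density), k, dim)
    occ * (1L + matrix(rpois(k * dim, 0.3), k, dim))
  }
  m <- draw(n)
  repeat {
    empty <- which(rowSums(m) == 0)
    if (length(empty) == 0) break
    # all-zero draws are redrawn so every molecule has support
    m[empty, ] <- draw(length(empty))
  }
  storage.mode(m) <- "integer"
  m
}

# Actives are count-mass perturbations of a shared prototype: each of the
# prototype's counts is moved independently with probability `noise`
# (removed from its position, re-added at a uniformly random one). noise 0
# keeps the prototype; noise 1 fully randomises the support, driving
# pairwise similarity down to the sparse-background level. Total count and
# non-negativity are preserved, so perturbed actives are always valid
# fingerprints.
#
# The randomness (prototype, per-molecule edit-count uniform, removal
# order, add positions) is drawn once per class seed; realising a given
# noise level then takes an edit-count prefix d_i = qbinom(u_i, total,
# noise) of the fixed edit streams. Diversity is therefore a fine-grained,
# near-monotone deterministic function of `noise`, which the bisection
# calibration relies on.
class_structure <- function(n, dim, seed) {
  withr::with_seed(seed, {
    proto <- draw_background(1L, dim)[1L, ]
    total <- sum(proto)
    multiset <- rep.int(seq_len(dim), proto)
    list(
      proto = proto,
      total = total,
      u = runif(n),
      removal_order = lapply(seq_len(n), function(i) multiset[sample.int(total, total)]),
      add_positions = lapply(seq_len(n), function(i) {
        sample.int(dim, total, replace = TRUE)
      })
    )
  })
}

realize_class <- function(st, noise) {
  dim <- length(st$proto)
  n <- length(st$u)
  d <- stats::qbinom(st$u, st$total, min(noise, 1))
  m <- matrix(0L, n, dim)
  for (i in seq_len(n)) {
    if (d[i] == 0) {
      m[i, ] <- st$proto
    } else {
      idx <- seq_len(d[i])
      m[i, ] <- as.integer(
        st$proto -
          tabulate(st$removal_order[[i]][idx], nbins = dim) +
          tabulate(st$add_positions[[i]][idx], nbins = dim)
      )
    }
  }
  m
}

# Draw an activity class (prototype + n perturbed actives) at a given noise
# level under a fixed seed, and measure its realised diversity.
draw_class <- function(n, noise, dim, seed) {
  realize_class(class_structure(n, dim, seed), noise)
}

#' Calibrate the perturbation noise for a target class diversity
#'
#' Bisection on the noise magnitude of the count-perturbation model: a
#' 50-molecule probe class is generated at each candidate noise level
#' (with a fixed seed, so the objective is deterministic) until its mean
#' pairwise Tanimoto falls within `tol` of `target_diversity`. The mapping
#' from noise to diversity is monotone decreasing, with noise 0 giving
#' identical copies (diversity 1).
#'
#' @param target_diversity Target mean pairwise Tanimoto, in `(0.05, 1]`.
#' @param dim Fingerprint length.
#' @param seed Integer seed for the probe draws.
#' @param n_probe Probe class size (default 50).
#' @param tol Acceptance half-width on the realised diversity (default 0.02).
#' @return The calibrated noise level (a single non-negative number).
#' @export
calibrate_noise <- function(target_diversity, dim = 1024, seed = 1,
                            n_probe = 50, tol = 0.02) {
  assert_scalar_number(target_diversity, "target_diversity", lower = 0.05, upper = 1)
  st <- class_structure(n_probe, dim, seed)
  calibrate_noise_for(function(noise) {
    mean_pairwise_tanimoto(realize_class(st, noise))
  }, target_diversity, tol = tol)
}

# Shared bisection driver: `measure(noise)` must be deterministic.
calibrate_noise_for <- function(measure, target, tol = 0.02, noise_max = 1,
                                max_iter = 60) {
  if (target >= 1) return(0)
  lo <- 0
  hi <- noise_max
  d_hi <- measure(hi)
  if (d_hi > target + tol) {
    stop_siam(
      sprintf(
        "Calibration range does not bracket target %.3f: diversity at maximum noise is %.3f.",
        target, d_hi
      ),
      "siam_calibration_error"
    )
  }
  # keep the best noise seen: for short fingerprints the deterministic
  # measure is a step function and the bisection midpoint can step past
  # the closest achievable diversity
  best_noise <- hi
  best_achieved <- d_hi
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    achieved <- measure(mid)
    if (abs(achieved - target) < abs(best_achieved - target)) {
      best_achieved <- achieved
      best_noise <- mid
    }
    if (abs(achieved - target) <= tol) return(mid)
    if (achieved > target) lo <- mid else hi <- mid
  }
  if (abs(best_achieved - target) <= tol) return(best_noise)
  stop_siam(
    sprintf(
      "Noise calibration did not converge: target %.3f, best achieved %.3f.",
      target, best_achieved
    ),
    "siam_calibration_error"
  )
}

#' Generate a synthetic screening library
#'
#' Realises a [library_spec]: each activity class is a sparse prototype
#' fingerprint plus `n_actives` count-perturbed copies, with the
#' perturbation magnitude calibrated per class (by bisection on the actual
#' class draw) so the realised mean pairwise Tanimoto lands within
#' `±0.02` of the class's `target_diversity`; decoys are independent
#' background draws. Fully deterministic given `spec$seed`.
#'
#' @param spec A [library_spec].
#' @return A [screening_library] whose `classes` table reports realised
#'   diversities.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  n_cls <- nrow(spec$classes)
  seeds <- derive_seeds(spec$seed, n_cls + 1L)
  fp_blocks <- vector("list", n_cls + 1L)
  rec_blocks <- vector("list", n_cls + 1L)
  for (k in seq_len(n_cls)) {
    cls <- spec$classes[k, ]
    st <- class_structure(cls$n_actives, spec$dim, seeds[k])
    noise <- calibrate_noise_for(function(noise) {
      mean_pairwise_tanimoto(realize_class(st, noise))
    }, cls$target_diversity)
    m <- realize_class(st, noise)
    fp_blocks[[k]] <- m
    rec_blocks[[k]] <- tibble::tibble(
      id = sprintf("%s_a%04d", cls$class_label, seq_len(cls$n_actives)),
      class_label = cls$class_label
    )
  }
  if (spec$n_decoys > 0) {
    fp_blocks[[n_cls + 1L]] <- withr::with_seed(
      seeds[n_cls + 1L],
      draw_background(spec$n_decoys, spec$dim)
    )
    rec_blocks[[n_cls + 1L]] <- tibble::tibble(
      id = sprintf("decoy_%05d", seq_len(spec$n_decoys)),
      class_label = "DECOY"
    )
  }
  screening_library(
    dplyr::bind_rows(rec_blocks),
    do.call(rbind, fp_blocks)
  )
}

#' Sample labelled training pairs from a library
#'
#' Draws a balanced stream of molecule pairs for pair-similarity training:
#' label 1 for two actives of the same activity class ("high similarity"),
#' label 0 for two molecules with different class labels ("high
#' dissimilarity"; active-decoy and cross-class active pairs both qualify,
#' decoy-decoy pairs never appear). The split is 50/50 up to rounding for
#' odd `n_pairs`, no molecule is paired with itself, and the stream is a
#' pure function of `seed`.
#'
#' @param library A [screening_library].
#' @param n_pairs Number of pairs to draw.
#' @param seed Integer seed.
#' @return A tibble with columns `id_a`, `id_b`, `label` (integer 0/1).
#' @export
sample_pairs <- function(library, n_pairs, seed = 1) {
  stopifnot(is_screening_library(library))
  assert_scalar_number(n_pairs, "n_pairs", lower = 1)
  eligible <- library$classes$class_label[library$classes$n_actives >= 2]
  if (length(eligible) < 2) {
    stop_siam(
      "Balanced pair sampling needs at least 2 classes with at least 2 actives.",
      "siam_sampling_error"
    )
  }
  n_pos <- ceiling(n_pairs / 2)
  n_neg <- n_pairs - n_pos
  rec <- library$records
  withr::with_seed(as.integer(seed), {
    pos_cls <- sample(eligible, n_pos, replace = TRUE)
    pos <- lapply(pos_cls, function(cl) {
      sample(rec$id[rec$class_label == cl], 2L)
    })
    neg <- lapply(seq_len(n_neg), function(i) {
      a <- sample(rec$id, 1L)
      cl_a <- rec$class_label[rec$id == a]
      b <- sample(rec$id[rec$class_label != cl_a], 1L)
      c(a, b)
    })
  })
  tibble::tibble(
    id_a = c(vapply(pos, `[[`, character(1), 1L), vapply(neg, `[[`, character(1), 1L)),
    id_b = c(vapply(pos, `[[`, character(1), 2L), vapply(neg, `[[`, character(1), 2L)),
    label = c(rep(1L, n_pos), rep(0L, n_neg))
  )
}

#' Mark query (reference) structures in a library
#'
#' Randomly selects `n_per_class` actives per activity class as the query
#' set (role `"QUERY"`), mirroring the standard protocol of screening with
#' ten randomly chosen reference structures per class; all other molecules
#' become rankable `"TEST"` records.
#'
#' @param library A [screening_library].
#' @param n_per_class Queries per class (default 10).
#' @param seed Integer seed.
#' @return The library with roles reassigned.
#' @export
select_queries <- function(library, n_per_class = 10, seed = 1) {
  stopifnot(is_screening_library(library))
  too_small <- library$classes$class_label[library$classes$n_actives < n_per_class]
  if (length(too_small)) {
    stop_siam(
      sprintf(
        "Class '%s' has fewer than %d actives; cannot select queries.",
        too_small[1], n_per_class
      ),
      "siam_selection_error"
    )
  }
  rec <- library$records
  rec$role <- "TEST"
  withr::with_seed(as.integer(seed), {
    for (cl in library$classes$class_label) {
      ids <- sample(rec$id[rec$class_label == cl], n_per_class)
      rec$role[rec$id %in% ids] <- "QUERY"
    }
  })
  library$records <- rec
  library
}
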