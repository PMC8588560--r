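# Small deterministic objects shared across test files.

# A hand-built dim-8 library: two 3-active classes plus two decoys.
tiny_library <- function() {
  fp <- rbind(
    c(2L, 1L, 0L, 0L, 3L, 0L, 0L, 0L),
    c(2L, 0L, 1L, 0L, 3L, 0L, 0L, 0L),
    c(1L, 1L, 0L, 0L, 2L, 1L, 0L, 0L),
    c(0L, 0L, 0L, 2L, 0L, 0L, 1L, 2L),
    c(0L, 0L, 1L, 2L, 0L, 0L, 0L, 2L),
    c(0L, 1L, 0L, 2L, 0L, 0L, 1L, 1L),
    c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 1L),
    c(0L, 0L, 2L, 0L, 1L, 0L, 1L, 0L)
  )
  screening_library(
    tibble::tibble(
      id = c("a1", "a2", "a3", "b1", "b2", "b3", "d1", "d2"),
      class_label = c("A", "A", "A", "B", "B", "B", "DECOY", "DECOY")
    ),
    fp
  )
}

# A generated library, small enough for fast tests.
small_synth <- function(seed = 11, n_actives = c(12, 12), diversity = c(0.35, 0.15),
                        n_decoys = 80, dim = 128) {
  generate_library(library_spec(
    data.frame(n_actives = n_actives, target_diversity = diversity),
    n_decoys = n_decoys, dim = dim, seed = seed
  ))
}

# A tiny random model; optionally re-randomise all parameters (including
# biases) so no pre-activation sits exactly on the ReLU kink.
tiny_model <- function(seed = 1, input_dim = 6, encoder = c(5, 4), head = c(4, 3),
                       generic_point = FALSE) {
  cfg <- siamese_config(
    input_dim = input_dim, encoder_sizes = encoder,
    post_fusion_sizes = head, seed = seed
  )
  model <- siamese_init(cfg)
  if (generic_point) {
    par <- siamscreen:::flatten_params(model)
    model <- siamscreen:::unflatten_params(
      model,
      par + withr::with_seed(seed + 1000L, stats::rnorm(length(par), sd = 0.3))
    )
  }
  model
}

random_fp_pair <- function(seed, dim = 6, lambda = 2) {
  withr::with_seed(seed, {
    list(
      a = as.numeric(rpois(dim, lambda)) + c(1, rep(0, dim - 1)),
      b = as.numeric(rpois(dim, lambda)) + c(rep(0, dim - 1), 1)
    )
  })
}

fixture_names <- function() {
  expand.grid(
    dataset = c("ds1", "ds2", "ds3", "muv", "dud"),
    pct = c(1, 5), stringsAsFactors = FALSE
  )
}
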