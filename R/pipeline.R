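#' Default end-to-end pipeline configuration
#'
#' A desk-scale demonstration configuration: three activity classes of 60
#' actives each — one homogeneous (target diversity 0.35), one intermediate
#' (0.20), one heterogeneous (0.12), spanning the difficulty axis of the
#' published benchmarks — over 3000 background decoys with 256-dimensional
#' fingerprints, 2000 balanced training pairs, ten query structures per
#' class, cutoffs 1% and 5%, and a coarse pruning-ratio grid. All sizes are
#' configuration, not contract — the same pipeline runs at full fingerprint
#' width 1024 and larger libraries.
#'
#' @return A nested configuration list; override any entry and pass the
#'   result to [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    library = list(
      classes = data.frame(
        n_actives = c(60, 60, 60),
        target_diversity = c(0.35, 0.20, 0.12)
      ),
      n_decoys = 3000,
      dim = 256
    ),
    n_pairs = 2000,
    n_queries = 10,
    cutoffs = c(1, 5),
    ratios = c(0, 0.1, 0.2, 0.4, 0.6, 0.8),
    fusion = "max",
    sigma = "std",
    tie_correction = TRUE,
    model = list(
      encoder_sizes = c(128, 64),
      post_fusion_sizes = c(64, 32),
      batch_size = 256,
      epochs = 40,
      learning_rate = 1e-3
    ),
    seed = 1
  )
}

#' Read a pipeline configuration from YAML
#'
#' Entries present in the file override [default_pipeline_config()];
#' everything else keeps its default.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  classes <- user$library$classes
  user$library$classes <- NULL
  cfg <- modifyList(default_pipeline_config(), user)
  if (!is.null(classes)) {
    cfg$library$classes <- do.call(rbind.data.frame, lapply(classes, as.data.frame))
  }
  cfg
}

#' Run the full screening pipeline
#'
#' Executes the complete workflow on a synthetic (or user-supplied)
#' library: generate the library, assign query structures, sample balanced
#' training pairs, train the Siamese MLP, assemble TAN/MLP recall tables
#' at every cutoff, sweep SNR node pruning across the ratio grid at the
#' first cutoff, and run the Kendall W concordance analysis on the
#' first-cutoff recall table. Every artifact is written to `out_dir` as
#' plain CSV together with a JSON manifest (configuration, seeds, realised
#' class diversities, package version), so a run is reproducible
#' byte-for-byte from its manifest.
#'
#' @param config A configuration list (see [default_pipeline_config()]),
#'   or a path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional integer overriding `config$seed`.
#' @param library Optional pre-built [screening_library]; skips generation.
#' @return Invisibly, a list with the library, fit, recall tables, sweep
#'   and concordance objects.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         seed = NULL, library = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4L)

  if (is.null(library)) {
    spec <- library_spec(
      config$library$classes,
      n_decoys = config$library$n_decoys,
      dim = config$library$dim,
      seed = seeds[1]
    )
    library <- generate_library(spec)
  }
  library <- select_queries(library, n_per_class = config$n_queries, seed = seeds[2])
  write_library(library, file.path(out_dir, "library.csv"), format = "sparse")

  pairs <- sample_pairs(library, config$n_pairs, seed = seeds[3])
  model_cfg <- do.call(siamese_config, c(
    list(input_dim = library$dim, seed = seeds[4]),
    config$model
  ))
  fit <- train_siamese(siamese_init(model_cfg), pairs, library, model_cfg)
  readr::write_csv(fit$history, file.path(out_dir, "training_history.csv"),
                   progress = FALSE)

  tables <- evaluate_benchmark(fit, library, pcts = config$cutoffs,
                               fusion = config$fusion)
  for (nm in names(tables)) {
    write_recall_table(tables[[nm]], file.path(out_dir, paste0("recall_", nm, ".csv")))
  }

  evaluator <- make_recall_evaluator(library, pct = config$cutoffs[1],
                                     fusion = config$fusion)
  sweep <- prune_sweep(fit, config$ratios, evaluator,
                       sigma = config$sigma)
  readr::write_csv(sweep, file.path(out_dir, "prune_sweep.csv"), progress = FALSE)
  report <- prune(fit$model, config$ratios[length(config$ratios)],
                  sigma = config$sigma)$report
  readr::write_csv(report, file.path(out_dir, "prune_report.csv"), progress = FALSE)

  conc <- kendall_w(tables[[1]], tie_correction = config$tie_correction)
  conc_out <- rank_methods(conc)
  conc_out$cutoff <- config$cutoffs[1]
  conc_out$W <- conc$W
  conc_out$p <- conc$p_value
  readr::write_csv(
    conc_out[, c("cutoff", "W", "p", "method", "mean_rank")],
    file.path(out_dir, "concordance.csv"), progress = FALSE
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("siamscreen")),
    seed = config$seed,
    derived_seeds = seeds,
    config = config[setdiff(names(config), "library")],
    library = list(
      n_molecules = nrow(library$records),
      dim = library$dim,
      classes = library$classes
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(
    library = library, fit = fit, tables = tables,
    sweep = sweep, concordance = conc
  ))
}

#' Build a screening evaluator closure for pruning sweeps
#'
#' Returns a `function(model)` that screens every class of `library` with
#' the given model and reports per-class top-`pct`% recall — the shape
#' [prune_sweep()] expects.
#'
#' @param library A [screening_library] with roles assigned.
#' @param pct Cutoff percentage.
#' @param fusion Group-fusion rule.
#' @return A closure `function(model) -> tibble(class_label, recall)`.
#' @export
make_recall_evaluator <- function(library, pct = 1, fusion = "max") {
  force(library); force(pct); force(fusion)
  function(model) {
    rec <- library$records
    dplyr::bind_rows(lapply(library$classes$class_label, function(cl) {
      actives <- rec$id[rec$class_label == cl & rec$role == "TEST"]
      ranked <- score_library(library, cl, model, fusion = fusion)
      tibble::tibble(
        class_label = cl,
        recall = top_percent_recall(ranked, actives, pct)
      )
    }))
  }
}
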