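#' Recall table: activity classes x similarity methods
#'
#' The standard presentation of screening benchmarks: one row per activity
#' class, one column per similarity method, each cell the recall percentage
#' at a fixed top-percent cutoff. The table carries a mean row (column
#' means over classes) and "shaded cell" marks: within each class row the
#' best method(s) are marked, and each method's shaded count is the number
#' of rows where it attains the row maximum (ties mark every tied method).
#' Cell values keep full float precision; only printing rounds.
#'
#' @param x A data frame with a `class_label` column and one numeric
#'   column per method (recall percentages in `[0, 100]`).
#' @return A `recall_table` object.
#' @export
recall_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"class_label" %in% names(x)) {
    stop_siam("A `class_label` column is required.", "siam_shape_error")
  }
  methods <- setdiff(names(x), "class_label")
  if (length(methods) == 0) {
    stop_siam("At least one method column is required.", "siam_shape_error")
  }
  vals <- as.matrix(x[methods])
  if (anyNA(vals)) {
    stop_siam("Recall matrix has missing cells.", "siam_shape_error")
  }
  if (any(vals < 0 | vals > 100)) {
    stop_siam("Recall values must lie in [0, 100].", "siam_input_error")
  }
  best <- vals == apply(vals, 1L, max)
  structure(
    list(
      table = x,
      methods = methods,
      mean_row = colMeans(vals),
      best = best,
      shaded = colSums(best)
    ),
    class = "recall_table"
  )
}

#' @export
print.recall_table <- function(x, digits = 2, ...) {
  tbl <- x$table
  tbl[x$methods] <- lapply(tbl[x$methods], round, digits)
  print(tbl, n = Inf)
  cat("Mean:  ", paste(sprintf("%s=%.*f", x$methods, digits, x$mean_row), collapse = "  "), "\n")
  cat("Shaded:", paste(sprintf("%s=%d", x$methods, x$shaded), collapse = "  "), "\n")
  invisible(x)
}

#' Tidy a recall table
#'
#' @param x A [recall_table].
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`class_label`, `method`, `recall`,
#'   `best`); `glance()`: one row per method with `mean_recall` and
#'   `shaded` count.
#' @export
tidy.recall_table <- function(x, ...) {
  long <- tidyr::pivot_longer(
    x$table, -"class_label", names_to = "method", values_to = "recall"
  )
  best_long <- tibble::as_tibble(x$best)
  best_long$class_label <- x$table$class_label
  best_long <- tidyr::pivot_longer(
    best_long, -"class_label", names_to = "method", values_to = "best"
  )
  dplyr::left_join(long, best_long, by = c("class_label", "method"))
}

#' @rdname tidy.recall_table
#' @export
glance.recall_table <- function(x, ...) {
  tibble::tibble(
    method = x$methods,
    mean_recall = unname(x$mean_row),
    shaded = unname(x$shaded)
  )
}

#' Read or write recall tables as CSV
#'
#' The on-disk format is the table's data rows plus two footer rows with
#' `class_label` values `__mean__` and `__shaded__`. On read, footer rows
#' are split off and kept as `printed_mean` / `printed_shaded` attributes
#' (useful when the file transcribes an externally published table), and
#' the mean/shaded statistics are recomputed from the data rows.
#'
#' @param path CSV file path.
#' @return `read_recall_table()` returns a [recall_table];
#'   `write_recall_table()` returns `path` invisibly.
#' @export
read_recall_table <- function(path) {
  # na = character(): "NA" is a legitimate class label (e.g. neuraminidase
  # in the DUD benchmark), never a missing value
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = character())
  footer <- x$class_label %in% c("__mean__", "__shaded__")
  tbl <- recall_table(x[!footer, , drop = FALSE])
  methods <- tbl$methods
  if (any(x$class_label == "__mean__")) {
    attr(tbl, "printed_mean") <- unlist(x[x$class_label == "__mean__", methods][1, ])
  }
  if (any(x$class_label == "__shaded__")) {
    attr(tbl, "printed_shaded") <- unlist(x[x$class_label == "__shaded__", methods][1, ])
  }
  tbl
}

#' @rdname read_recall_table
#' @param x A [recall_table] to write.
#' @export
write_recall_table <- function(x, path) {
  stopifnot(inherits(x, "recall_table"))
  out <- x$table
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(class_label = "__mean__", !!!as.list(setNames(unname(x$mean_row), x$methods))),
    tibble::tibble(class_label = "__shaded__", !!!as.list(setNames(as.numeric(x$shaded), x$methods)))
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Published benchmark recall tables shipped with the package
#'
#' Per-class recall percentages of published similarity methods (TAN, BIN,
#' SQB, SDBN, MLP) on the MDDR-DS1/DS2/DS3, MUV and DUD benchmarks at the
#' top-1% and top-5% cutoffs, transcribed from the virtual-screening
#' literature. Shipped for concordance analysis and as regression fixtures
#' for the table arithmetic.
#'
#' @param dataset One of `"ds1"`, `"ds2"`, `"ds3"`, `"muv"`, `"dud"`.
#' @param pct Cutoff percentage, 1 or 5.
#' @return A [recall_table] with `printed_mean` / `printed_shaded`
#'   attributes from the published footers.
#' @export
benchmark_recall_table <- function(dataset = c("ds1", "ds2", "ds3", "muv", "dud"),
                                   pct = 1) {
  dataset <- match.arg(dataset)
  stopifnot(pct %in% c(1, 5))
  path <- system.file(
    "extdata", sprintf("recall_%s_top%d.csv", dataset, pct),
    package = "siamscreen", mustWork = TRUE
  )
  read_recall_table(path)
}

#' Benchmark activity-class structure tables
#'
#' The published class structure of the MDDR-DS1/DS2/DS3 and MUV
#' benchmarks: activity index, class name, number of active molecules and
#' mean pairwise continuous-Tanimoto similarity ("diversity"). Useful as
#' presets for [library_spec()]. `"dud"` returns the DUD subset structure
#' instead (subset name, active and decoy counts; no diversity column is
#' published for DUD).
#'
#' @param dataset One of `"ds1"`, `"ds2"`, `"ds3"`, `"muv"`, `"dud"`.
#' @return A tibble.
#' @export
benchmark_class_structure <- function(dataset = c("ds1", "ds2", "ds3", "muv", "dud")) {
  dataset <- match.arg(dataset)
  path <- system.file(
    "extdata", sprintf("classes_%s.csv", dataset),
    package = "siamscreen", mustWork = TRUE
  )
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = character())
  if ("activity_index" %in% names(out)) {
    out$activity_index <- as.character(out$activity_index)
  }
  out
}
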