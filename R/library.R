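#' Screening library of fingerprinted molecules
#'
#' A screening library bundles molecule records (id, activity-class label,
#' screening role) with their count fingerprints and per-class metadata.
#' Decoy molecules carry the sentinel label `"DECOY"`; roles are `"TEST"`
#' (rankable) or `"QUERY"` (reference structure, excluded from ranking).
#'
#' @param records A data frame with columns `id` (unique character),
#'   `class_label` (character; `"DECOY"` for decoys) and optionally `role`
#'   (`"TEST"`/`"QUERY"`, default `"TEST"`).
#' @param fingerprints An integer matrix, one row per record, `dim` columns
#'   of non-negative counts; every row must have at least one nonzero entry.
#' @param classes Optional per-class metadata tibble with columns
#'   `class_label`, `n_actives`, `diversity`; recomputed from the data when
#'   omitted.
#' @return An object of class `screening_library`.
#' @export
screening_library <- function(records, fingerprints, classes = NULL) {
  records <- tibble::as_tibble(records)
  if (!all(c("id", "class_label") %in% names(records))) {
    stop_siam("`records` needs columns `id` and `class_label`.", "siam_input_error")
  }
  if (!"role" %in% names(records)) records$role <- "TEST"
  records$id <- as.character(records$id)
  records$class_label <- as.character(records$class_label)
  fingerprints <- as.matrix(fingerprints)
  storage.mode(fingerprints) <- "integer"
  if (nrow(fingerprints) != nrow(records)) {
    stop_siam("One fingerprint row per record is required.", "siam_shape_error")
  }
  if (anyDuplicated(records$id)) {
    stop_siam(
      sprintf("Duplicate molecule id '%s'.", records$id[duplicated(records$id)][1]),
      "siam_integrity_error"
    )
  }
  if (any(fingerprints < 0)) {
    stop_siam("Fingerprint counts must be non-negative.", "siam_integrity_error")
  }
  if (any(rowSums(fingerprints) == 0)) {
    bad <- records$id[rowSums(fingerprints) == 0][1]
    stop_siam(
      sprintf("Molecule '%s' has an all-zero fingerprint.", bad),
      "siam_integrity_error"
    )
  }
  if (!all(records$role %in% c("TEST", "QUERY"))) {
    stop_siam("Roles must be 'TEST' or 'QUERY'.", "siam_input_error")
  }
  if (any(records$role == "QUERY" & records$class_label == "DECOY")) {
    stop_siam("Query molecules must be actives, not decoys.", "siam_integrity_error")
  }
  rownames(fingerprints) <- records$id
  lib <- structure(
    list(
      records = records,
      fingerprints = fingerprints,
      classes = NULL,
      dim = ncol(fingerprints)
    ),
    class = "screening_library"
  )
  lib$classes <- if (is.null(classes)) compute_class_table(lib) else tibble::as_tibble(classes)
  lib
}

#' @rdname screening_library
#' @param x Object to test.
#' @export
is_screening_library <- function(x) inherits(x, "screening_library")

compute_class_table <- function(lib) {
  labels <- setdiff(sort(unique(lib$records$class_label)), "DECOY")
  tibble::tibble(
    class_label = labels,
    n_actives = vapply(labels, function(cl) sum(lib$records$class_label == cl),
                       integer(1), USE.NAMES = FALSE),
    diversity = vapply(labels, function(cl) {
      if (sum(lib$records$class_label == cl) < 2) return(NA_real_)
      mean_pairwise_similarity(lib, cl)
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' @export
print.screening_library <- function(x, ...) {
  n_dec <- sum(x$records$class_label == "DECOY")
  cat(sprintf(
    "<screening_library> %d molecules (%d actives in %d classes, %d decoys), dim = %d\n",
    nrow(x$records), nrow(x$records) - n_dec, nrow(x$classes), n_dec, x$dim
  ))
  print(x$classes, ...)
  invisible(x)
}

#' Tidy view of a screening library
#'
#' @param x A [screening_library].
#' @param ... Unused.
#' @return A tibble with one row per molecule: `id`, `class_label`, `role`
#'   and a `fingerprint` list-column of integer count vectors.
#' @export
as_tibble.screening_library <- function(x, ...) {
  out <- x$records
  out$fingerprint <- lapply(seq_len(nrow(x$fingerprints)), function(i) x$fingerprints[i, ])
  out
}

#' Read or write a screening library in CSV form
#'
#' Two plain-text dialects are supported. `dense`: one row per molecule,
#' `id,class,v1..v_dim` with a header. `sparse`: three columns
#' `id,class,fp`, where `fp` holds space-separated `index:count` tokens
#' with 0-based indices. Both round-trip bit-exactly through
#' `write_library()` / `read_library()`.
#'
#' @param path File path.
#' @param format `"dense"` or `"sparse"`.
#' @param dim Fingerprint length; required for `sparse` (dense infers it
#'   from the header).
#' @return `read_library()` returns a [screening_library]; `write_library()`
#'   returns `path` invisibly.
#' @export
read_library <- function(path, format = c("dense", "sparse"), dim = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_siam(sprintf("File not found: %s", path), "siam_input_error")
  }
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop_siam("Library file has no data rows.", "siam_parse_error")
  }
  body <- lines[-1]
  parts <- strsplit(body, ",", fixed = TRUE)
  if (format == "dense") {
    n_field <- lengths(parts)
    dim <- dim %||% (n_field[1] - 2L)
    bad <- which(n_field != dim + 2L)
    if (length(bad)) {
      stop_siam(
        sprintf("Line %d: expected %d fields, found %d.", bad[1] + 1L, dim + 2L, n_field[bad[1]]),
        if (n_field[bad[1]] > 2L) "siam_dimension_error" else "siam_parse_error"
      )
    }
    ids <- vapply(parts, `[[`, character(1), 1L)
    cls <- vapply(parts, `[[`, character(1), 2L)
    fp <- do.call(rbind, lapply(seq_along(parts), function(i) {
      v <- suppressWarnings(as.integer(parts[[i]][-(1:2)]))
      if (anyNA(v)) {
        stop_siam(sprintf("Line %d: non-integer fingerprint value.", i + 1L), "siam_parse_error")
      }
      v
    }))
  } else {
    if (is.null(dim)) {
      stop_siam("`dim` is required for the sparse dialect.", "siam_input_error")
    }
    bad <- which(lengths(parts) != 3L)
    if (length(bad)) {
      stop_siam(sprintf("Line %d: expected `id,class,tokens`.", bad[1] + 1L), "siam_parse_error")
    }
    ids <- vapply(parts, `[[`, character(1), 1L)
    cls <- vapply(parts, `[[`, character(1), 2L)
    fp <- do.call(rbind, lapply(seq_along(parts), function(i) {
      tokens <- strsplit(trimws(parts[[i]][3]), " +")[[1]]
      tokens <- tokens[nzchar(tokens)]
      v <- integer(dim)
      if (length(tokens)) {
        kv <- strsplit(tokens, ":", fixed = TRUE)
        if (any(lengths(kv) != 2L)) {
          stop_siam(sprintf("Line %d: malformed `index:count` token.", i + 1L), "siam_parse_error")
        }
        idx <- suppressWarnings(as.integer(vapply(kv, `[[`, character(1), 1L)))
        cnt <- suppressWarnings(as.integer(vapply(kv, `[[`, character(1), 2L)))
        if (anyNA(idx) || anyNA(cnt)) {
          stop_siam(sprintf("Line %d: non-integer token.", i + 1L), "siam_parse_error")
        }
        if (any(idx < 0L | idx >= dim)) {
          stop_siam(
            sprintf("Line %d: index out of range for dim %d (indices are 0-based).", i + 1L, dim),
            "siam_dimension_error"
          )
        }
        v[idx + 1L] <- cnt
      }
      v
    }))
  }
  screening_library(tibble::tibble(id = ids, class_label = cls), fp)
}

#' @rdname read_library
#' @param library A [screening_library] to write.
#' @export
write_library <- function(library, path, format = c("dense", "sparse")) {
  stopifnot(is_screening_library(library))
  format <- match.arg(format)
  fp <- library$fingerprints
  if (format == "dense") {
    header <- paste(c("id", "class", paste0("v", seq_len(ncol(fp)))), collapse = ",")
    rows <- paste(
      library$records$id, library$records$class_label,
      apply(fp, 1L, paste, collapse = ","),
      sep = ","
    )
  } else {
    header <- "id,class,fp"
    rows <- vapply(seq_len(nrow(fp)), function(i) {
      nz <- which(fp[i, ] != 0L)
      paste(
        library$records$id[i], library$records$class_label[i],
        paste(sprintf("%d:%d", nz - 1L, fp[i, nz]), collapse = " "),
        sep = ","
      )
    }, character(1))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
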