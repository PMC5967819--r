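#' Construct a time-series dataset
#'
#' A `ts_dataset` is a tibble with one row per series and three columns:
#' `id` (integer, `1..N` in row order), `label` (character, `NA` when the
#' dataset is unlabelled) and `values` (list-column of numeric vectors).
#' Series may have unequal lengths; no padding is ever applied. Missing or
#' non-finite observations are rejected.
#'
#' @param values A list of numeric vectors, one per series, each of length
#'   at least 1 with all values finite.
#' @param labels Optional character (or coercible) vector of class labels,
#'   one per series. Labels are kept as opaque strings; class identity is
#'   string equality.
#' @return A `ts_dataset` tibble with columns `id`, `label`, `values`.
#' @examples
#' d <- ts_dataset(list(c(0, 1, 2), c(3, 4)), labels = c("a", "b"))
#' d
#' @export
ts_dataset <- function(values, labels = NULL) {
  if (!is.list(values) || length(values) == 0) {
    abort("`values` must be a non-empty list of numeric vectors.")
  }
  values <- lapply(values, as.numeric)
  lens <- lengths(values)
  if (any(lens < 1)) abort("every series must have length >= 1.")
  bad <- which(!vapply(values, function(v) all(is.finite(v)), logical(1)))
  if (length(bad) > 0) {
    abort(sprintf("series %d contains non-finite values.", bad[1]))
  }
  n <- length(values)
  if (is.null(labels)) {
    labels <- rep(NA_character_, n)
  } else {
    if (length(labels) != n) abort("`labels` must have one entry per series.")
    labels <- as.character(labels)
  }
  out <- tibble(id = seq_len(n), label = labels, values = values)
  class(out) <- c("ts_dataset", class(out))
  out
}

#' @rdname ts_dataset
#' @param x Object to test.
#' @export
is_ts_dataset <- function(x) inherits(x, "ts_dataset")

# Coerce a tibble/data.frame with the right columns back to ts_dataset
# (dplyr verbs strip custom classes).
as_ts_dataset <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "label", "values") %in% names(x)))
  x <- as_tibble(x)
  class(x) <- c("ts_dataset", class(x)[!class(x) %in% "ts_dataset"])
  x
}

#' Does every series in a dataset have a label?
#' @param data A `ts_dataset`.
#' @return Logical scalar.
#' @export
has_labels <- function(data) {
  all(!is.na(data$label))
}

#' Read a UCR-archive style delimited time-series file
#'
#' One record per line: an optional leading class label followed by the
#' observations, separated by a comma or tab (auto-detected from the first
#' data line, overridable). Lines starting with `#` are treated as comments
#' and skipped. Ragged (unequal-length) records are permitted.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects `,` vs
#'   tab from the first non-comment line.
#' @param label_first If `TRUE` (default) the first field of each line is a
#'   class label kept as a string; otherwise every field is an observation.
#' @return A [ts_dataset()] tibble.
#' @export
read_ucr <- function(path, delimiter = NULL, label_first = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) abort(sprintf("no records in file: %s", path))
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  min_fields <- if (label_first) 2L else 1L
  values <- vector("list", length(fields))
  labels <- character(length(fields))
  for (k in seq_along(fields)) {
    f <- trimws(fields[[k]])
    if (length(f) < min_fields) {
      abort(sprintf("line %d: expected at least %d fields, found %d.",
                    line_no[k], min_fields, length(f)))
    }
    if (label_first) {
      labels[k] <- f[1]
      f <- f[-1]
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v) || any(!is.finite(v))) {
      abort(sprintf("line %d: unparseable or non-finite numeric field.",
                    line_no[k]))
    }
    values[[k]] <- v
  }
  ts_dataset(values, labels = if (label_first) labels else NULL)
}

#' Write a dataset as a UCR-archive style delimited file
#'
#' Values are printed with 17 significant digits so that
#' `read_ucr(write_ucr(d, path))` reproduces `d` bit-exactly.
#'
#' @param data A [ts_dataset()].
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @param header Optional character vector written first as `#`-prefixed
#'   comment lines (used by the CLI to echo the generating configuration).
#' @return `path`, invisibly.
#' @export
write_ucr <- function(data, path, delimiter = ",", header = NULL) {
  stopifnot(is_ts_dataset(data) || is.data.frame(data))
  if (nrow(data) == 0) abort("cannot write an empty dataset.")
  labelled <- has_labels(data)
  lines <- vapply(seq_len(nrow(data)), function(k) {
    vals <- formatC(data$values[[k]], format = "g", digits = 17)
    if (labelled) {
      paste(c(data$label[[k]], vals), collapse = delimiter)
    } else {
      paste(vals, collapse = delimiter)
    }
  }, character(1))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("cannot write to %s: %s",
                                             path, conditionMessage(e))))
  invisible(path)
}

#' Split a dataset into ordered chunks
#'
#' Chunks are contiguous slices in dataset (file) order — the arrival
#' sequence assumed by the incremental drivers. Every object lands in
#' exactly one chunk; the last chunk may be smaller. Each chunk carries a
#' `weight` column initialised to 1 (ordinary objects); the single-pass
#' driver later merges carried medoids with larger weights.
#'
#' @param data A [ts_dataset()].
#' @param chunk_size Number of series per chunk (the last may be smaller).
#' @param shuffle If `TRUE`, permute the dataset order first (requires
#'   `seed`). Chunking itself is by order, never shuffled silently.
#' @param seed Integer seed used only when `shuffle = TRUE`.
#' @return A list of chunk tibbles (class `ts_chunks`); each chunk has
#'   columns `id`, `label`, `values`, `weight`.
#' @examples
#' d <- simulate_warped_series(k = 2, n_per_cluster = 5, seed = 1)
#' length(make_chunks(d, 4))
#' @export
make_chunks <- function(data, chunk_size, shuffle = FALSE, seed = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1) abort("`chunk_size` must be >= 1.")
  n <- nrow(data)
  ord <- seq_len(n)
  if (isTRUE(shuffle)) {
    if (is.null(seed)) abort("`shuffle = TRUE` requires an explicit `seed`.")
    ord <- withr::with_seed(as.integer(seed), sample.int(n))
  }
  grp <- ceiling(seq_len(n) / chunk_size)
  chunks <- lapply(split(ord, grp), function(idx) {
    ch <- as_tibble(data[idx, c("id", "label", "values")])
    ch$weight <- rep(1, length(idx))
    ch
  })
  names(chunks) <- NULL
  class(chunks) <- c("ts_chunks", "list")
  chunks
}

#' @export
print.ts_dataset <- function(x, ...) {
  lens <- lengths(x$values)
  cat(sprintf("# A ts_dataset: %d series, lengths %d..%d%s\n",
              nrow(x), min(lens), max(lens),
              if (has_labels(x)) sprintf(", %d classes",
                                         length(unique(x$label))) else ""))
  NextMethod()
}

#' Plot the series of a dataset
#'
#' Draws every series (or a subsample) as a line, coloured by class label
#' and facetted by label when present.
#'
#' @param object A [ts_dataset()].
#' @param max_series Upper bound on the number of series drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ts_dataset <- function(object, max_series = 60, ...) {
  keep <- object[seq_len(min(nrow(object), max_series)), ]
  long <- tidyr::unnest(
    mutate(as_tibble(keep), t = map(.data$values, seq_along)),
    c("t", "values")
  )
  p <- ggplot(long, aes(x = .data$t, y = .data$values,
                        group = .data$id, colour = .data$label)) +
    geom_line(alpha = 0.7) +
    labs(x = "time index", y = "value", colour = "class")
  if (has_labels(keep)) p <- p + facet_wrap(~label)
  p
}
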