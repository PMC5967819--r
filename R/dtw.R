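#' Dynamic time warping alignment of two series
#'
#' Computes the accumulated DTW cost matrix by the classic dynamic
#' programme: the first row and column are cumulative sums of the local
#' cost, and every interior cell adds the local cost to the minimum of its
#' left, upper and diagonal neighbours. The DTW distance is the final cell
#' `cost[S, T]`, un-normalised (no path-length division). The optimal
#' warping path is recovered by backtracking; predecessor ties prefer the
#' diagonal step, then `(i, j-1)`, then `(i-1, j)`, which keeps the result
#' deterministic and the path as short as possible.
#'
#' The local cost between coordinates is `|a_i - b_j|` by default
#' (distance stays in signal units); squared differences are available via
#' `step_cost = "squared"`. No warping window is applied: the alignment is
#' unconstrained, so series of unequal length are handled naturally.
#'
#' All indices are 1-based: the path runs from `(1, 1)` to `(S, T)` with
#' steps in `{(+1,0), (0,+1), (+1,+1)}`.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param step_cost Local cost between coordinates: `"abs"` (default) or
#'   `"squared"`.
#' @return An object of class `dtw_alignment`: a list with `distance`
#'   (scalar), `cost` (S x T accumulated cost matrix), `path` (two-column
#'   integer matrix of aligned index pairs) and `step_cost`.
#' @examples
#' al <- dtw_distance(c(1, 2, 3), c(2, 3, 4))
#' al$distance
#' al$path
#' @export
dtw_distance <- function(a, b, step_cost = c("abs", "squared")) {
  step_cost <- match.arg(step_cost)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("series must be non-empty.")
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("series must be finite.")
  sc <- if (step_cost == "squared") 1L else 0L
  cost <- .dtw_cost_matrix(a, b, sc)
  path <- .dtw_backtrack(cost)
  colnames(path) <- c("i", "j")
  structure(
    list(distance = cost[length(a), length(b)],
         cost = cost, path = path, step_cost = step_cost),
    class = "dtw_alignment"
  )
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("DTW alignment (%s local cost): %d x %d, distance %.6g, path length %d\n",
              x$step_cost, nrow(x$cost), ncol(x$cost), x$distance, nrow(x$path)))
  invisible(x)
}

#' Plot a DTW alignment
#'
#' Heatmap of the accumulated cost matrix with the optimal warping path
#' overlaid.
#'
#' @param object A [dtw_distance()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dtw_alignment <- function(object, ...) {
  cm <- object$cost
  grid <- tidyr::expand_grid(i = seq_len(nrow(cm)), j = seq_len(ncol(cm)))
  grid$cost <- cm[as.matrix(grid[, c("i", "j")])]
  pathdf <- as_tibble(object$path)
  ggplot(grid, aes(x = .data$j, y = .data$i)) +
    geom_tile(aes(fill = .data$cost)) +
    geom_path(data = pathdf, colour = "white", linewidth = 1) +
    labs(x = "series b index", y = "series a index", fill = "accumulated\ncost")
}

#' Euclidean distance between two equal-length series
#'
#' The ordinary L2 distance. Unlike DTW it is undefined for series of
#' unequal length, and it cannot absorb time shifts — the reason DTW is
#' preferred for warped time series.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    abort("Euclidean distance requires equal-length series; use DTW for ragged pairs.")
  }
  sqrt(sum((a - b)^2))
}

#' Pairwise distance matrix over a dataset
#'
#' Computes the symmetric N x N matrix of pairwise distances under the
#' chosen metric, exploiting symmetry (each pair computed once). The
#' matrix is tagged with the metric that produced it.
#'
#' @param data A [ts_dataset()] (or any data frame with a `values`
#'   list-column), or a plain list of numeric vectors.
#' @param metric `"dtw"` (default, handles ragged series) or
#'   `"euclidean"` (equal lengths required).
#' @param step_cost Local cost for DTW, see [dtw_distance()].
#' @return An N x N numeric matrix of class `ts_distmat` with attribute
#'   `metric_tag` (e.g. `"dtw_abs"`, `"euclidean"`).
#' @examples
#' d <- simulate_warped_series(k = 2, n_per_cluster = 3, seed = 1)
#' D <- ts_distances(d)
#' attr(D, "metric_tag")
#' @export
ts_distances <- function(data, metric = c("dtw", "euclidean"),
                         step_cost = c("abs", "squared")) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  series <- extract_series(data)
  n <- length(series)
  if (n == 0) abort("dataset is empty.")
  if (metric == "euclidean") {
    lens <- lengths(series)
    if (length(unique(lens)) > 1) {
      abort("Euclidean metric requires equal-length series; use metric = \"dtw\".")
    }
    X <- do.call(rbind, series)
    D <- as.matrix(stats::dist(X, method = "euclidean"))
    dimnames(D) <- NULL
    tag <- "euclidean"
  } else {
    sc <- if (step_cost == "squared") 1L else 0L
    D <- .dtw_pairwise_cpp(series, sc)
    tag <- paste0("dtw_", step_cost)
  }
  structure(D, metric_tag = tag, class = c("ts_distmat", class(D)))
}

#' Distances from every series to a set of reference series
#'
#' Rectangular companion to [ts_distances()]: rows are the dataset's
#' series, columns the references (typically medoids).
#'
#' @inheritParams ts_distances
#' @param refs A list of numeric vectors, or a `ts_dataset`.
#' @return An N x length(refs) matrix.
#' @export
ts_cross_distances <- function(data, refs, metric = c("dtw", "euclidean"),
                               step_cost = c("abs", "squared")) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  series <- extract_series(data)
  refs <- extract_series(refs)
  if (metric == "euclidean") {
    lens <- unique(c(lengths(series), lengths(refs)))
    if (length(lens) > 1) {
      abort("Euclidean metric requires equal-length series; use metric = \"dtw\".")
    }
    out <- vapply(refs, function(r) {
      vapply(series, function(s) sqrt(sum((s - r)^2)), numeric(1))
    }, numeric(length(series)))
    matrix(out, nrow = length(series))
  } else {
    sc <- if (step_cost == "squared") 1L else 0L
    .dtw_cross_cpp(series, refs, sc)
  }
}

# Accept a ts_dataset, a data frame with a `values` list-column, or a bare
# list of numeric vectors.
extract_series <- function(data) {
  if (is.data.frame(data)) {
    if (!"values" %in% names(data)) abort("data frame must have a `values` list-column.")
    data$values
  } else if (is.list(data)) {
    lapply(data, as.numeric)
  } else {
    abort("expected a ts_dataset, data frame, or list of numeric vectors.")
  }
}

#' Write a distance matrix as a delimited square matrix
#'
#' One `#` comment line names the metric tag, then the N x N matrix.
#'
#' @param D A [ts_distances()] result.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_distmat <- function(D, path, delimiter = ",") {
  tag <- attr(D, "metric_tag") %||% "unknown"
  lines <- c(sprintf("# metric: %s", tag),
             apply(unclass(D), 1, function(r) {
               paste(formatC(r, format = "g", digits = 17), collapse = delimiter)
             }))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
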