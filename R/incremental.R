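#' Per-cluster medoid weights from a fuzzy partition
#'
#' After clustering a chunk, each of its C medoids is carried forward with
#' weight \eqn{w_c = \sum_i u_{ci} w_i}, the membership-weighted mass of
#' the objects it represents. Because membership columns sum to 1 the
#' total is conserved: \eqn{\sum_c w_c = \sum_i w_i}. The same formula
#' serves both drivers; they differ only in the object pool it is applied
#' to (single-pass: the chunk's objects merged with the carried medoids;
#' online: the chunk's own objects only).
#'
#' @param U C x N membership matrix over the pool.
#' @param weights Positive per-object weights over the same pool.
#' @return Numeric vector of C positive cluster weights.
#' @examples
#' U <- matrix(c(1, 0, 0, 1, 0.5, 0.5), nrow = 2)
#' medoid_weights(U, weights = c(1, 1, 1))
#' @export
medoid_weights <- function(U, weights) {
  if (ncol(U) != length(weights)) {
    abort("`weights` must have one entry per membership column.")
  }
  as.numeric(U %*% weights)
}

#' Single-pass incremental fuzzy c-medoids (spFDTW)
#'
#' Processes the dataset chunk by chunk. The first chunk is clustered with
#' all weights 1; its C medoids, carrying their [medoid_weights()], are
#' merged as ordinary (but heavier) objects into the next chunk, which is
#' clustered again — and so on until the last chunk. Carried medoids are
#' eligible for reselection; when reselected their weight is recomputed
#' from the merged pool (the carried weight already enters through
#' \eqn{w_i}). After the last chunk, fuzzy memberships of *all* N series
#' are recomputed against the final C medoids in a streaming second pass,
#' so the whole dataset never needs to be clustered at once. With a single
#' chunk the algorithm reduces exactly to the batch fit [fcmdd()].
#'
#' @param data A labelled or unlabelled [ts_dataset()]; ignored when
#'   `chunks` is supplied.
#' @param k Number of clusters.
#' @param chunk_size Objects per chunk (see [make_chunks()]); required
#'   unless `chunks` is given.
#' @param chunks Optional pre-built [make_chunks()] list.
#' @inheritParams fcmdd
#' @return A `fcmdd_incremental` object (subclass of `fcmdd_fit`) whose
#'   `membership` spans all N objects in dataset order, with a `history`
#'   tibble of per-chunk pool sizes, objectives, iteration counts and
#'   medoid ids, and `medoid_weights` of the final carried medoids.
#' @examples
#' d <- simulate_warped_series(k = 2, n_per_cluster = 8, seed = 3)
#' fit <- fcmdd_single_pass(d, k = 2, chunk_size = 8)
#' fit$history
#' @export
fcmdd_single_pass <- function(data = NULL, k, chunk_size = NULL, chunks = NULL,
                              fuzzifier = 2.3, metric = c("dtw", "euclidean"),
                              step_cost = c("abs", "squared"),
                              candidates = NULL, max_iter = 100) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  chunks <- resolve_chunks(data, chunk_size, chunks)
  k <- as.integer(k)

  carried_series <- list()
  carried_weights <- numeric(0)
  carried_ids <- integer(0)
  history <- vector("list", length(chunks))

  for (p in seq_along(chunks)) {
    ch <- chunks[[p]]
    pool_series <- c(carried_series, ch$values)
    pool_weights <- c(carried_weights, ch$weight)
    pool_ids <- c(carried_ids, ch$id)
    if (length(pool_series) < k) {
      abort(sprintf("chunk %d: pool of %d object(s) is smaller than k = %d.",
                    p, length(pool_series), k))
    }
    D <- ts_distances(pool_series, metric = metric, step_cost = step_cost)
    fit <- fcmdd(D, k = k, fuzzifier = fuzzifier, candidates = candidates,
                 max_iter = max_iter, weights = pool_weights)
    w_c <- medoid_weights(fit$membership, pool_weights)

    carried_series <- pool_series[fit$medoids]
    carried_weights <- w_c
    carried_ids <- pool_ids[fit$medoids]
    history[[p]] <- tibble(
      chunk = p, pool_size = length(pool_series), carried = length(carried_ids),
      objective = fit$objective, iterations = fit$iterations,
      converged = fit$converged, medoid_ids = list(carried_ids)
    )
  }

  finalize_incremental(chunks, carried_series, carried_ids, carried_weights,
                       k, fuzzifier, metric, step_cost, candidates, max_iter,
                       algorithm = "single_pass",
                       history = bind_rows(history))
}

#' Online incremental fuzzy c-medoids (oFDTW)
#'
#' Every chunk is clustered independently with unit weights; the C medoids
#' of each chunk, carrying their [medoid_weights()], are appended to a
#' medoid pool. After all chunks are processed, the pooled M*C weighted
#' medoids are clustered once more, and the final memberships of all N
#' series are recomputed against the resulting C medoids. Because the
#' chunk stage touches each chunk in isolation, it is order-independent —
#' permuting the chunks permutes only the pool, not the result (up to
#' cluster relabelling) — and could run in parallel.
#'
#' @inheritParams fcmdd_single_pass
#' @return A `fcmdd_incremental` object; see [fcmdd_single_pass()].
#' @export
fcmdd_online <- function(data = NULL, k, chunk_size = NULL, chunks = NULL,
                         fuzzifier = 2.3, metric = c("dtw", "euclidean"),
                         step_cost = c("abs", "squared"),
                         candidates = NULL, max_iter = 100) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  chunks <- resolve_chunks(data, chunk_size, chunks)
  k <- as.integer(k)

  pool_series <- list()
  pool_weights <- numeric(0)
  pool_ids <- integer(0)
  history <- vector("list", length(chunks))

  for (p in seq_along(chunks)) {
    ch <- chunks[[p]]
    if (nrow(ch) < k) {
      abort(sprintf("chunk %d: %d object(s) is smaller than k = %d.",
                    p, nrow(ch), k))
    }
    D <- ts_distances(ch$values, metric = metric, step_cost = step_cost)
    fit <- fcmdd(D, k = k, fuzzifier = fuzzifier, candidates = candidates,
                 max_iter = max_iter, weights = ch$weight)
    w_c <- medoid_weights(fit$membership, ch$weight)

    pool_series <- c(pool_series, ch$values[fit$medoids])
    pool_weights <- c(pool_weights, w_c)
    pool_ids <- c(pool_ids, ch$id[fit$medoids])
    history[[p]] <- tibble(
      chunk = p, pool_size = nrow(ch), carried = k,
      objective = fit$objective, iterations = fit$iterations,
      converged = fit$converged, medoid_ids = list(ch$id[fit$medoids])
    )
  }

  # final stage: weighted clustering of the pooled medoids
  Dp <- ts_distances(pool_series, metric = metric, step_cost = step_cost)
  final <- fcmdd(Dp, k = k, fuzzifier = fuzzifier, candidates = candidates,
                 max_iter = max_iter, weights = pool_weights)
  w_final <- medoid_weights(final$membership, pool_weights)
  history <- c(history, list(tibble(
    chunk = NA_integer_, pool_size = length(pool_series), carried = k,
    objective = final$objective, iterations = final$iterations,
    converged = final$converged, medoid_ids = list(pool_ids[final$medoids])
  )))

  finalize_incremental(chunks, pool_series[final$medoids],
                       pool_ids[final$medoids], w_final,
                       k, fuzzifier, metric, step_cost, candidates, max_iter,
                       algorithm = "online",
                       history = bind_rows(history))
}

resolve_chunks <- function(data, chunk_size, chunks) {
  if (is.null(chunks)) {
    if (is.null(data) || is.null(chunk_size)) {
      abort("supply either `chunks` or both `data` and `chunk_size`.")
    }
    chunks <- make_chunks(data, chunk_size)
  }
  if (!inherits(chunks, "ts_chunks") && !is.list(chunks)) {
    abort("`chunks` must be a make_chunks() list.")
  }
  chunks
}

# Second pass: memberships of every object against the final medoids,
# streamed chunk by chunk, then the driver result object.
finalize_incremental <- function(chunks, medoid_series, medoid_ids,
                                 medoid_w, k, fuzzifier, metric, step_cost,
                                 candidates, max_iter, algorithm, history) {
  U <- finalize_memberships(chunks, medoid_series, fuzzifier = fuzzifier,
                            metric = metric, step_cost = step_cost)
  ids <- unlist(lapply(chunks, `[[`, "id"))
  ord <- order(ids)
  U <- U[, ord, drop = FALSE]
  labels <- unlist(lapply(chunks, `[[`, "label"))[ord]
  n <- ncol(U)

  dmed <- ts_cross_distances(unlist(lapply(chunks, `[[`, "values"),
                                    recursive = FALSE)[ord],
                             medoid_series, metric = metric,
                             step_cost = step_cost)
  J <- objective_cross(dmed, U, rep(1, n), fuzzifier)

  new_fcmdd_fit(
    medoids = medoid_ids, membership = U, weights = rep(1, n),
    objective = J,
    objective_trace = history$objective,
    iterations = sum(history$iterations), converged = all(history$converged),
    medoid_series = medoid_series, medoid_weights = medoid_w,
    labels = if (all(!is.na(labels))) labels else NULL,
    history = history,
    config = list(k = k, fuzzifier = fuzzifier,
                  metric = if (metric == "dtw") paste0("dtw_", step_cost) else metric,
                  candidates = candidates, max_iter = max_iter,
                  algorithm = algorithm),
    class = "fcmdd_incremental"
  )
}

#' Recompute fuzzy memberships of every series against fixed medoids
#'
#' The final step of both incremental drivers: the membership formula is
#' applied to each object against the final medoid series, streaming over
#' chunks so the full dataset need not be resident at once. Weights play
#' no role here (the membership formula is weight-free).
#'
#' @param data A [ts_dataset()], data frame with a `values` list-column,
#'   or a [make_chunks()] list.
#' @param medoid_series List of C numeric vectors (the final medoids).
#' @inheritParams fcmdd
#' @return C x N membership matrix in the order the objects appear.
#' @export
finalize_memberships <- function(data, medoid_series, fuzzifier = 2.3,
                                 metric = c("dtw", "euclidean"),
                                 step_cost = c("abs", "squared")) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  chunk_list <- if (inherits(data, "ts_chunks")) {
    lapply(data, `[[`, "values")
  } else if (is.data.frame(data)) {
    list(data$values)
  } else if (is.list(data) && all(vapply(data, is.data.frame, logical(1)))) {
    lapply(data, `[[`, "values")
  } else {
    list(extract_series(data))
  }
  parts <- lapply(chunk_list, function(series) {
    dmed <- ts_cross_distances(series, medoid_series, metric = metric,
                               step_cost = step_cost)
    memberships_from_dist(dmed, fuzzifier)
  })
  do.call(cbind, parts)
}
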