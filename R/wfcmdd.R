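#' Weighted fuzzy c-medoids objective
#'
#' The objective minimised by the weighted fuzzy c-medoids algorithm:
#' \deqn{J = \sum_{c=1}^{C} \sum_{i=1}^{N} w_i \, u_{ci}^m \, d(x_i, v_c)}
#' where \eqn{d} is the clustering metric (DTW by default), \eqn{w_i} the
#' per-object weights, \eqn{u_{ci}} the fuzzy memberships and \eqn{v_c} the
#' medoid of cluster \eqn{c}. Always non-negative.
#'
#' @param D N x N distance matrix (e.g. from [ts_distances()]).
#' @param U C x N membership matrix, columns summing to 1.
#' @param weights Positive per-object weights (length N).
#' @param medoids Integer vector of C distinct medoid row indices into `D`.
#' @param fuzzifier Fuzzifier m > 1.
#' @return Non-negative scalar.
#' @export
wfcmdd_objective <- function(D, U, weights, medoids, fuzzifier) {
  check_model_shapes(D, U, weights, medoids)
  objective_cross(unclass(D)[, medoids, drop = FALSE], U, weights, fuzzifier)
}

# dmed is N x C: distances from every object to each medoid.
objective_cross <- function(dmed, U, weights, fuzzifier) {
  sum((weights * t(U^fuzzifier)) * dmed)
}

check_model_shapes <- function(D, U, weights, medoids) {
  n <- ncol(D)
  if (nrow(D) != n) abort("`D` must be square.")
  if (ncol(U) != n) abort("`U` must have one column per object.")
  if (length(weights) != n) abort("`weights` must have one entry per object.")
  if (anyDuplicated(medoids)) abort("medoid indices must be distinct.")
  if (any(medoids < 1 | medoids > n)) abort("medoid indices out of range.")
  invisible(TRUE)
}

#' Fuzzy membership update
#'
#' Given the current medoids, each object's membership in cluster c is
#' \deqn{u_{ci} = \left[\sum_{l=1}^{C}
#'   \big(d(x_i,v_c)/d(x_i,v_l)\big)^{1/(m-1)}\right]^{-1},}
#' so every column of U sums to 1. If an object is at distance zero from
#' one or more medoids the formula divides by zero; the standard fuzzy
#' c-means convention is applied: membership 1/(number of zero-distance
#' medoids) for each such cluster, 0 elsewhere. Weights never enter the
#' membership formula — they act only in the objective and medoid update.
#'
#' @inheritParams wfcmdd_objective
#' @param medoids Integer vector of C distinct medoid indices.
#' @return C x N membership matrix with unit column sums.
#' @examples
#' D <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3)
#' update_memberships(D, medoids = c(1, 3), fuzzifier = 2)
#' @export
update_memberships <- function(D, medoids, fuzzifier) {
  if (fuzzifier <= 1) abort("`fuzzifier` must be > 1.")
  dmed <- unclass(D)[, medoids, drop = FALSE]
  memberships_from_dist(dmed, fuzzifier)
}

# dmed: N x C distances to medoids -> C x N membership matrix.
memberships_from_dist <- function(dmed, fuzzifier) {
  n <- nrow(dmed); C <- ncol(dmed)
  U <- matrix(0, nrow = C, ncol = n)
  expo <- -1 / (fuzzifier - 1)
  for (i in seq_len(n)) {
    d <- dmed[i, ]
    zero <- d == 0
    if (any(zero)) {
      U[zero, i] <- 1 / sum(zero)
    } else {
      r <- d^expo
      U[, i] <- r / sum(r)
    }
  }
  U
}

#' Deterministic farthest-sum medoid initialisation
#'
#' The first medoid is the object minimising the sum of its distances to
#' all other objects (the most central object). Each subsequent medoid is
#' the unchosen object maximising the sum of its distances to the medoids
#' already chosen, so the initial medoids are mutually far apart. All ties
#' break to the lowest object index, making initialisation — and hence the
#' whole fit — fully deterministic.
#'
#' @inheritParams wfcmdd_objective
#' @param k Number of medoids (clusters) to select.
#' @return Integer vector of k distinct indices.
#' @export
initialize_medoids <- function(D, k) {
  D <- unclass(D)
  n <- ncol(D)
  k <- as.integer(k)
  if (k < 1 || k > n) abort(sprintf("`k` must be in 1..%d.", n))
  sums <- rowSums(D)
  medoids <- integer(k)
  medoids[1] <- which.min(sums)       # which.min breaks ties low
  if (k > 1) {
    for (c in 2:k) {
      chosen <- medoids[seq_len(c - 1)]
      far <- rowSums(D[, chosen, drop = FALSE])
      far[chosen] <- -Inf
      medoids[c] <- which.max(far)
    }
  }
  medoids
}

#' Medoid update with candidate restriction
#'
#' For each cluster the new medoid minimises the weighted fuzzy cost
#' \eqn{\sum_i w_i u_{ci}^m d(x_i, x)} over a candidate set: the q objects
#' with largest membership in the cluster, plus the cluster's current
#' medoid (keeping the incumbent eligible guarantees the update can never
#' increase the objective). Clusters are processed in index order; if a
#' cluster's best candidate is already taken by an earlier cluster, its
#' next-best candidate is used, extending the candidate set to all objects
#' if necessary, so the returned medoids are always pairwise distinct.
#' Cost ties break to the lowest object index.
#'
#' @inheritParams wfcmdd_objective
#' @param q Candidate-set size per cluster (default `min(5, N)`).
#' @param current Optional current medoid indices (length C), appended to
#'   each cluster's candidate set.
#' @return Integer vector of C distinct medoid indices.
#' @export
select_medoids <- function(D, U, weights, fuzzifier, q = NULL, current = NULL) {
  D <- unclass(D)
  n <- ncol(D)
  C <- nrow(U)
  if (is.null(q)) q <- min(5L, n)
  q <- max(1L, min(as.integer(q), n))
  taken <- integer(0)
  medoids <- integer(C)
  for (c in seq_len(C)) {
    rank_c <- order(-U[c, ], seq_len(n))   # by membership desc, index asc
    cand <- rank_c[seq_len(q)]
    if (!is.null(current)) cand <- unique(c(cand, current[c]))
    coef <- weights * U[c, ]^fuzzifier
    pick <- best_untaken(D, coef, cand, taken)
    if (is.na(pick)) {
      # candidate set exhausted by earlier clusters: extend to all objects
      pick <- best_untaken(D, coef, seq_len(n), taken)
    }
    medoids[c] <- pick
    taken <- c(taken, pick)
  }
  medoids
}

# argmin of sum_i coef[i] * D[i, x] over x in cand \ taken; ties -> lowest
# index; NA if every candidate is taken.
best_untaken <- function(D, coef, cand, taken) {
  cand <- setdiff(cand, taken)
  if (length(cand) == 0) return(NA_integer_)
  costs <- as.numeric(coef %*% D[, cand, drop = FALSE])
  cand <- cand[order(costs, cand)]
  cand[1]
}

#' Fit weighted fuzzy c-medoids to time series
#'
#' The clustering core: alternating (Picard) iteration of the membership
#' update and the candidate-restricted medoid update, started from the
#' deterministic farthest-sum initialisation, until the medoid set of an
#' iteration equals the previous one (or `max_iter` is hit, in which case
#' the returned model is flagged unconverged). With `metric = "dtw"` this
#' clusters warped series by shape; with `metric = "euclidean"` the same
#' loop is the classic weighted fuzzy c-medoids. The objective value is
#' recorded after every iteration; the trace is non-increasing and
#' bounded below by 0, which is what guarantees convergence. There is no
#' randomness anywhere: refitting the same input reproduces the model
#' bit-exactly.
#'
#' @param data A [ts_dataset()] (or data frame with a `values`
#'   list-column), or a precomputed square distance matrix from
#'   [ts_distances()].
#' @param k Number of clusters C (>= 2 for a meaningful partition).
#' @param fuzzifier Fuzzifier m > 1 (default 2.3).
#' @param metric,step_cost Passed to [ts_distances()] when `data` is not
#'   already a distance matrix.
#' @param candidates Medoid-candidate count q (default `min(5, N)`).
#' @param max_iter Iteration cap (default 100).
#' @param weights Optional positive per-object weights (default all 1).
#' @return An object of class `fcmdd_fit`: list with `medoids` (indices
#'   into the input order), `membership` (C x N), `weights`, `objective`,
#'   `objective_trace`, `iterations`, `converged`, `cluster` (hardened
#'   assignment) and the resolved configuration.
#' @examples
#' d <- simulate_warped_series(k = 3, n_per_cluster = 6, seed = 7)
#' fit <- fcmdd(d, k = 3)
#' glance(fit)
#' @export
fcmdd <- function(data, k, fuzzifier = 2.3,
                  metric = c("dtw", "euclidean"),
                  step_cost = c("abs", "squared"),
                  candidates = NULL, max_iter = 100, weights = NULL) {
  metric <- match.arg(metric)
  step_cost <- match.arg(step_cost)
  if (is.matrix(data)) {
    D <- data
    metric_tag <- attr(D, "metric_tag") %||% "precomputed"
    series <- NULL
  } else {
    series <- extract_series(data)
    D <- ts_distances(data, metric = metric, step_cost = step_cost)
    metric_tag <- attr(D, "metric_tag")
  }
  D <- unclass(D)
  n <- ncol(D)
  k <- as.integer(k)
  if (n < k) abort(sprintf("need at least k = %d objects, have %d.", k, n))
  if (fuzzifier <= 1) abort("`fuzzifier` must be > 1.")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    abort("`weights` must be positive, one per object.")
  }
  if (is.null(candidates)) candidates <- min(5L, n)

  medoids <- initialize_medoids(D, k)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    U <- memberships_from_dist(D[, medoids, drop = FALSE], fuzzifier)
    new_medoids <- select_medoids(D, U, weights, fuzzifier,
                                  q = candidates, current = medoids)
    trace <- c(trace,
               objective_cross(D[, new_medoids, drop = FALSE], U,
                               weights, fuzzifier))
    if (identical(new_medoids, medoids)) {
      converged <- TRUE
      break
    }
    medoids <- new_medoids
  }
  U <- memberships_from_dist(D[, medoids, drop = FALSE], fuzzifier)
  J <- objective_cross(D[, medoids, drop = FALSE], U, weights, fuzzifier)

  new_fcmdd_fit(
    medoids = medoids, membership = U, weights = weights, objective = J,
    objective_trace = trace, iterations = iter, converged = converged,
    medoid_series = if (!is.null(series)) series[medoids] else NULL,
    labels = if (is.data.frame(data) && "label" %in% names(data)) data$label else NULL,
    config = list(k = k, fuzzifier = fuzzifier, metric = metric_tag,
                  candidates = candidates, max_iter = max_iter,
                  algorithm = "wfcmdd")
  )
}

new_fcmdd_fit <- function(..., class = character()) {
  fit <- list(...)
  fit$cluster <- harden(fit$membership)
  structure(fit, class = c(class, "fcmdd_fit"))
}

#' @export
print.fcmdd_fit <- function(x, ...) {
  cat(sprintf("%s fit: %d clusters, %d objects, metric %s\n",
              x$config$algorithm, x$config$k, ncol(x$membership),
              x$config$metric))
  cat(sprintf("  objective %.6g after %d iteration(s)%s\n", x$objective,
              x$iterations, if (x$converged) "" else " (NOT converged)"))
  cat("  medoid ids:", paste(x$medoids, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname fcmdd
#' @param x,object A `fcmdd_fit`.
#' @param ... Unused.
#' @export
glance.fcmdd_fit <- function(x, ...) {
  tibble(
    k = x$config$k,
    n = ncol(x$membership),
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged,
    metric = x$config$metric,
    algorithm = x$config$algorithm
  )
}

#' @rdname fcmdd
#' @export
tidy.fcmdd_fit <- function(x, ...) {
  sizes <- tabulate(x$cluster, nbins = x$config$k)
  tibble(
    cluster = seq_len(x$config$k),
    medoid_id = x$medoids,
    size = sizes,
    total_membership = rowSums(x$membership)
  )
}

#' @rdname fcmdd
#' @param data The dataset the model was fitted to (first argument by
#'   convention so calls pipe).
#' @export
augment.fcmdd_fit <- function(x, data = NULL, ...) {
  n <- ncol(x$membership)
  base <- if (is.null(data)) tibble(id = seq_len(n)) else as_tibble(data)
  if (nrow(base) != n) abort("`data` does not match the fitted model size.")
  base$.cluster <- factor(x$cluster, levels = seq_len(x$config$k))
  base$.membership <- x$membership[cbind(x$cluster, seq_len(n))]
  base
}

#' Membership heatmap for a fitted clustering
#'
#' Objects (columns) are ordered by hardened cluster then by membership
#' strength, so block structure is visible when the partition is crisp.
#'
#' @param object A `fcmdd_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcmdd_fit <- function(object, ...) {
  U <- object$membership
  ord <- order(object$cluster, -U[cbind(object$cluster, seq_len(ncol(U)))])
  long <- tidyr::expand_grid(cluster = seq_len(nrow(U)),
                             position = seq_len(ncol(U)))
  long$membership <- U[cbind(long$cluster, ord[long$position])]
  ggplot(long, aes(x = .data$position, y = factor(.data$cluster),
                   fill = .data$membership)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "steelblue4", limits = c(0, 1)) +
    labs(x = "object (ordered by cluster)", y = "cluster", fill = "membership")
}

#' Plot medoid series of a fitted clustering
#'
#' @param fit A `fcmdd_fit` carrying medoid series (fitted from a dataset,
#'   not a bare distance matrix).
#' @return A ggplot object with one facet per cluster medoid.
#' @export
plot_medoids <- function(fit) {
  if (is.null(fit$medoid_series)) {
    abort("fit carries no medoid series (fitted from a distance matrix); refit from a dataset.")
  }
  long <- tibble(
    cluster = rep(seq_along(fit$medoid_series), lengths(fit$medoid_series)),
    t = unlist(lapply(fit$medoid_series, seq_along)),
    value = unlist(fit$medoid_series)
  )
  ggplot(long, aes(x = .data$t, y = .data$value)) +
    geom_line(colour = "steelblue4") +
    facet_wrap(~cluster, labeller = label_both) +
    labs(x = "time index", y = "value")
}
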