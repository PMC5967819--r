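#' Harden a fuzzy membership matrix
#'
#' Assigns each object to its maximum-membership cluster; ties break to
#' the lowest cluster index. This is the bridge from a fuzzy partition to
#' the crisp assignment all external validity statistics operate on.
#'
#' @param U C x N membership matrix with unit column sums.
#' @return Integer vector of N cluster indices in 1..C.
#' @export
harden <- function(U) {
  if (!is.matrix(U)) abort("`U` must be a matrix.")
  max.col(t(U), ties.method = "first")
}

#' Class-by-cluster contingency table
#'
#' @param truth Character/factor vector of true class labels.
#' @param cluster Integer (or factor) vector of cluster assignments.
#' @return A classes x clusters integer matrix of counts `n_ij`.
#' @export
cluster_contingency <- function(truth, cluster) {
  if (length(truth) != length(cluster)) {
    abort("`truth` and `cluster` must cover the same objects.")
  }
  if (anyNA(truth) || anyNA(cluster)) abort("labels and clusters must be complete.")
  unclass(table(class = as.character(truth), cluster = as.character(cluster)))
}

as_contingency <- function(truth, cluster = NULL) {
  if (is.matrix(truth) && is.null(cluster)) {
    storage.mode(truth) <- "double"
    if (any(truth < 0)) abort("contingency counts must be non-negative.")
    truth
  } else {
    cluster_contingency(truth, cluster)
  }
}

#' F-Measure of a clustering against true classes
#'
#' For class i and cluster j, recall is `n_ij / n_i`, precision is
#' `n_ij / n_j`, and `F(i, j)` their harmonic mean. Each class scores its
#' best-matching cluster, and classes are weighted by size:
#' \deqn{F_c = \sum_i (n_i / N) \max_j F(i, j).}
#' 1 means the hardened partition reproduces the classes exactly (up to
#' relabelling); higher is better.
#'
#' @param truth True class labels, or a classes x clusters contingency
#'   matrix (then `cluster` is omitted).
#' @param cluster Cluster assignments (e.g. from [harden()]).
#' @return Scalar in \[0, 1\].
#' @examples
#' f_measure(c("a", "a", "b", "b"), c(1, 1, 2, 2))
#' @export
f_measure <- function(truth, cluster = NULL) {
  tab <- as_contingency(truth, cluster)
  N <- sum(tab)
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  best <- vapply(seq_len(nrow(tab)), function(i) {
    f_ij <- vapply(seq_len(ncol(tab)), function(j) {
      if (n_j[j] == 0 || tab[i, j] == 0) return(0)
      r <- tab[i, j] / n_i[i]
      p <- tab[i, j] / n_j[j]
      2 * p * r / (p + r)
    }, numeric(1))
    max(f_ij)
  }, numeric(1))
  sum(n_i / N * best)
}

#' Entropy of a clustering against true classes
#'
#' Per-cluster class-distribution entropy
#' \eqn{E_j = -\sum_i p_{ij} \log p_{ij}} with `p_ij = n_ij / n_j` (and
#' `0 log 0 := 0`), averaged over clusters weighted by size:
#' \eqn{E_{cs} = \sum_j (n_j / N) E_j}. 0 means every cluster is pure;
#' lower is better.
#'
#' @inheritParams f_measure
#' @param base Logarithm base; natural log by default, 10 selectable.
#' @return Non-negative scalar.
#' @export
cluster_entropy <- function(truth, cluster = NULL, base = exp(1)) {
  tab <- as_contingency(truth, cluster)
  N <- sum(tab)
  n_j <- colSums(tab)
  e_j <- vapply(seq_len(ncol(tab)), function(j) {
    if (n_j[j] == 0) return(0)
    p <- tab[, j] / n_j[j]
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }, numeric(1))
  sum(n_j / N * e_j)
}

#' Hypergeometric enrichment p-value of a cluster
#'
#' The probability of observing `m` or more members of a class of size `M`
#' in a draw of `n` objects from a dataset of `N`:
#' \deqn{p = \sum_{i=m}^{n} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n},}
#' i.e. the upper tail of the hypergeometric distribution (computed in
#' log space via [stats::phyper()], stable for N up to at least 1e4).
#' A smaller p-value marks a more significantly class-enriched cluster.
#'
#' @param N Dataset size.
#' @param M Class ("annotation") size, `M <= N`.
#' @param n Cluster size, `n <= N`.
#' @param m Number of class members observed in the cluster,
#'   `0 <= m <= min(n, M)`.
#' @return p-value in \[0, 1\].
#' @examples
#' cluster_pvalue(10, 5, 4, 3)  # 55/210
#' @export
cluster_pvalue <- function(N, M, n, m) {
  if (any(c(N, M, n, m) < 0) || M > N || n > N || m > min(n, M)) {
    abort("require 0 <= m <= min(n, M) and M, n <= N.")
  }
  if (m == 0) return(1)
  phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Clustering Score from per-cluster enrichment p-values
#'
#' Each cluster is scored by its minimum hypergeometric enrichment
#' p-value over all classes ([cluster_pvalue()] with the class as the
#' annotation). A cluster is significant when that p-value falls below
#' `cutoff` (the alpha level, default 0.05). The Clustering Score is
#' \deqn{CS = \big(\sum_{\mathrm{significant}} \min(p_i) +
#'   n_l \cdot cutoff\big) / (n_s + n_l),}
#' where `ns`/`nl` count significant/insignificant clusters. Lower is
#' better; `-log10(CS)` is reported as a higher-is-better transform.
#'
#' @inheritParams f_measure
#' @param cutoff Significance level (default 0.05).
#' @return An object of class `clustering_score`: list with `clusters`
#'   (a tibble of per-cluster size, best class, minimum p-value and
#'   significance flag), `ns`, `nl`, `cs` and `neg_log10_cs`.
#' @export
clustering_score <- function(truth, cluster = NULL, cutoff = 0.05) {
  tab <- as_contingency(truth, cluster)
  N <- sum(tab)
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  rows <- lapply(seq_len(ncol(tab)), function(j) {
    p_ij <- vapply(seq_len(nrow(tab)), function(i) {
      cluster_pvalue(N, n_i[i], n_j[j], tab[i, j])
    }, numeric(1))
    best <- which.min(p_ij)
    tibble(cluster = colnames(tab)[j] %||% as.character(j),
           size = n_j[j],
           best_class = rownames(tab)[best] %||% as.character(best),
           min_p = p_ij[best],
           significant = p_ij[best] < cutoff)
  })
  clusters <- bind_rows(rows)
  ns <- sum(clusters$significant)
  nl <- sum(!clusters$significant)
  cs <- (sum(clusters$min_p[clusters$significant]) + nl * cutoff) / (ns + nl)
  structure(
    list(clusters = clusters, ns = ns, nl = nl, cutoff = cutoff,
         cs = cs, neg_log10_cs = -log10(cs)),
    class = "clustering_score"
  )
}

#' @export
print.clustering_score <- function(x, ...) {
  cat(sprintf("Clustering Score: CS = %.4g (-log10 = %.3f), %d significant / %d insignificant at alpha = %g\n",
              x$cs, x$neg_log10_cs, x$ns, x$nl, x$cutoff))
  print(x$clusters)
  invisible(x)
}

#' @rdname clustering_score
#' @param x A `clustering_score`.
#' @param ... Unused.
#' @export
tidy.clustering_score <- function(x, ...) x$clusters

#' @rdname clustering_score
#' @export
glance.clustering_score <- function(x, ...) {
  tibble(cs = x$cs, neg_log10_cs = x$neg_log10_cs, ns = x$ns, nl = x$nl,
         cutoff = x$cutoff)
}

#' Evaluate a fitted clustering against true class labels
#'
#' Hardens the fitted memberships and computes all four external validity
#' statistics in one tidy row: F-Measure, entropy, Clustering Score and
#' its -log10 transform, plus the significant-cluster count.
#'
#' @param fit A `fcmdd_fit` (or a C x N membership matrix, or a crisp
#'   assignment vector).
#' @param truth True class labels; defaults to the labels stored in the
#'   fit when it was trained on a labelled dataset.
#' @param base Entropy log base.
#' @param cutoff Significance level for the Clustering Score.
#' @return A one-row tibble.
#' @examples
#' d <- simulate_warped_series(k = 2, n_per_cluster = 8, seed = 5)
#' evaluate_clustering(fcmdd(d, k = 2), d$label)
#' @export
evaluate_clustering <- function(fit, truth = NULL, base = exp(1), cutoff = 0.05) {
  assignment <- if (inherits(fit, "fcmdd_fit")) {
    if (is.null(truth)) truth <- fit$labels
    fit$cluster
  } else if (is.matrix(fit)) {
    harden(fit)
  } else {
    fit
  }
  if (is.null(truth)) abort("true class labels are required.")
  score <- clustering_score(truth, assignment, cutoff = cutoff)
  tibble(
    f_measure = f_measure(truth, assignment),
    entropy = cluster_entropy(truth, assignment, base = base),
    cs = score$cs,
    neg_log10_cs = score$neg_log10_cs,
    n_significant = score$ns,
    n_clusters = nrow(score$clusters)
  )
}
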