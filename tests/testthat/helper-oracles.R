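# Independent oracles used across tests. Each deliberately avoids the code
# path it checks: exhaustive enumeration instead of dynamic programming,
# explicit loops instead of matrix algebra.

# All monotone warping paths from (1,1) to (S,T) with steps
# {(+1,0),(0,+1),(+1,+1)}; feasible only for tiny S, T.
enumerate_paths <- function(S, T) {
  if (S == 1 && T == 1) return(list(matrix(c(1, 1), ncol = 2)))
  out <- list()
  if (S > 1) out <- c(out, lapply(enumerate_paths(S - 1, T),
                                  function(p) rbind(p, c(S, T))))
  if (T > 1) out <- c(out, lapply(enumerate_paths(S, T - 1),
                                  function(p) rbind(p, c(S, T))))
  if (S > 1 && T > 1) out <- c(out, lapply(enumerate_paths(S - 1, T - 1),
                                           function(p) rbind(p, c(S, T))))
  out
}

# DTW distance by exhaustive path enumeration.
dtw_oracle <- function(a, b, delta = function(x, y) abs(x - y)) {
  paths <- enumerate_paths(length(a), length(b))
  min(vapply(paths, function(p) {
    sum(vapply(seq_len(nrow(p)),
               function(r) delta(a[p[r, 1]], b[p[r, 2]]), numeric(1)))
  }, numeric(1)))
}

# Triple-loop objective recomputation.
objective_oracle <- function(D, U, w, medoids, m) {
  total <- 0
  for (c in seq_along(medoids)) {
    for (i in seq_len(ncol(U))) {
      total <- total + w[i] * U[c, i]^m * D[i, medoids[c]]
    }
  }
  total
}

# Hypergeometric upper tail by enumerating all draws of n objects out of N,
# with objects 1..M carrying the annotation.
pvalue_oracle <- function(N, M, n, m) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= M) >= m)
}

# Loop-based F-Measure over a contingency table.
f_measure_oracle <- function(tab) {
  N <- sum(tab)
  total <- 0
  for (i in seq_len(nrow(tab))) {
    best <- 0
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) {
        r <- tab[i, j] / sum(tab[i, ])
        p <- tab[i, j] / sum(tab[, j])
        best <- max(best, 2 * p * r / (p + r))
      }
    }
    total <- total + sum(tab[i, ]) / N * best
  }
  total
}

# Loop-based entropy over a contingency table.
entropy_oracle <- function(tab, base = exp(1)) {
  N <- sum(tab)
  total <- 0
  for (j in seq_len(ncol(tab))) {
    nj <- sum(tab[, j])
    ej <- 0
    for (i in seq_len(nrow(tab))) {
      pij <- tab[i, j] / nj
      if (pij > 0) ej <- ej - pij * log(pij, base = base)
    }
    total <- total + nj / N * ej
  }
  total
}

# Random symmetric non-negative distance matrix with zero diagonal.
random_distmat <- function(n, zero_pairs = 0) {
  D <- matrix(runif(n * n, 0.1, 5), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  if (zero_pairs > 0) {
    for (k in seq_len(zero_pairs)) {
      ij <- sample(n, 2)
      D[ij[1], ij[2]] <- 0
      D[ij[2], ij[1]] <- 0
    }
  }
  D
}

# A small random ragged dataset of integer-valued series.
random_tiny_dataset <- function(n, max_len = 5) {
  ts_dataset(lapply(seq_len(n), function(i) {
    sample(-5:5, sample(max_len, 1) + 0L, replace = TRUE)
  }))
}
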