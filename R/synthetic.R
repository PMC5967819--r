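#' Deterministic prototype shapes
#'
#' A fixed family of mutually dissimilar unit-amplitude shapes sampled on
#' a regular grid, used as cluster prototypes by the generator, in this
#' order: sine, square, ramp, Gaussian bump, chirp, damped oscillation.
#'
#' @param k Number of prototypes (at most 6, the family size).
#' @param base_length Number of samples per prototype.
#' @return A [ts_dataset()] of k prototypes labelled `"1"..."k"`.
#' @examples
#' ts_prototypes(3, base_length = 40)
#' @export
ts_prototypes <- function(k, base_length = 60) {
  k <- as.integer(k)
  if (k < 1 || k > 6) abort("`k` must be between 1 and 6 (shape family size).")
  if (base_length < 4) abort("`base_length` must be at least 4.")
  t <- seq(0, 1, length.out = base_length)
  family <- list(
    sine    = sin(2 * pi * 2 * t),
    square  = ifelse(sin(2 * pi * 2 * t) >= 0, 1, -1),
    ramp    = 2 * t - 1,
    bump    = exp(-((t - 0.5) / 0.15)^2),
    chirp   = sin(2 * pi * (1 + 3 * t) * t),
    damped  = exp(-3 * t) * sin(2 * pi * 3 * t)
  )
  ts_dataset(unname(family[seq_len(k)]), labels = as.character(seq_len(k)))
}

#' Randomly time-warp a series
#'
#' Resamples a series along a random monotone non-decreasing time map: a
#' piecewise-linear map with `knots` interior knots whose displacement
#' from the identity scales with `warp_strength`. Displacements are
#' bounded below half the knot gap, so the map is strictly monotone by
#' construction — segments of the series are stretched or compressed but
#' never reordered. `warp_strength = 0` returns the series unchanged.
#' Draws from the current RNG stream (seed it, or use
#' [simulate_warped_series()] which seeds one stream per call).
#'
#' @param values Numeric vector.
#' @param warp_strength In \[0, 1\]: 0 = identity, 1 = knots may move
#'   almost half a knot gap.
#' @param knots Number of interior knots of the time map (default 4).
#' @param out_length Length of the resampled output (default: input
#'   length).
#' @return Numeric vector of length `out_length`.
#' @export
warp_series <- function(values, warp_strength, knots = 4, out_length = length(values)) {
  if (warp_strength < 0 || warp_strength > 1) {
    abort("`warp_strength` must be in [0, 1].")
  }
  n <- length(values)
  if (warp_strength == 0 && out_length == n) return(values)
  gap <- 1 / (knots + 1)
  u <- seq(0, 1, length.out = knots + 2)           # target knots
  disp <- runif(knots, -1, 1) * warp_strength * 0.45 * gap
  v <- u
  v[2:(knots + 1)] <- u[2:(knots + 1)] + disp      # source knots, monotone
  t_out <- seq(0, 1, length.out = out_length)
  src <- approx(u, v, xout = t_out)$y              # time map target -> source
  approx(seq(0, 1, length.out = n), values, xout = src)$y
}

#' Generate a labelled synthetic warped time-series dataset
#'
#' Emulates the structure DTW is designed for and the Euclidean distance
#' is not: each cluster is a set of copies of one prototype shape, each
#' copy independently time-warped by a random monotone map
#' ([warp_series()]) and perturbed by additive i.i.d. Gaussian noise.
#' Optional length jitter makes the dataset ragged, and an optional
#' outlier fraction replaces series with value-shuffled (structureless)
#' copies to exercise the medoid algorithm's noise resistance. Series are
#' interleaved across clusters (1, 2, ..., k, 1, 2, ...) so that
#' contiguous chunks mix classes. The whole draw consumes one RNG stream
#' seeded once from `seed`: generation is a pure function of its
#' arguments.
#'
#' @param k Number of clusters/prototypes (<= 6).
#' @param n_per_cluster Series per cluster.
#' @param base_length Samples per series before jitter (default 60).
#' @param warp_strength Monotone warp intensity in \[0, 1\] (default 0.3).
#' @param noise_sd Additive Gaussian noise standard deviation, in signal
#'   units of the unit-amplitude prototypes (default 0.05).
#' @param length_jitter Maximum +/- variation of series length (default
#'   0, i.e. equal lengths so the Euclidean metric stays applicable).
#' @param outlier_fraction Fraction of series replaced by value-shuffled
#'   outliers (default 0).
#' @param seed Integer seed (required; generation is deterministic).
#' @return A labelled [ts_dataset()] of `k * n_per_cluster` series whose
#'   labels are the prototype indices `"1"..."k"`.
#' @examples
#' d <- simulate_warped_series(k = 3, n_per_cluster = 5, seed = 42)
#' table(d$label)
#' @export
simulate_warped_series <- function(k = 3, n_per_cluster = 20, base_length = 60,
                                   warp_strength = 0.3, noise_sd = 0.05,
                                   length_jitter = 0, outlier_fraction = 0,
                                   seed = 1) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length_jitter < 0 || length_jitter >= base_length) {
    abort("`length_jitter` must be in [0, base_length).")
  }
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    abort("`outlier_fraction` must be in [0, 1].")
  }
  protos <- ts_prototypes(k, base_length)$values
  withr::local_seed(as.integer(seed))
  n_total <- k * as.integer(n_per_cluster)
  # interleaved labels: 1, 2, ..., k, 1, 2, ...
  lab <- rep(seq_len(k), times = n_per_cluster)
  values <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    len <- base_length
    if (length_jitter > 0) {
      len <- base_length + sample.int(2 * length_jitter + 1, 1) - length_jitter - 1
    }
    s <- warp_series(protos[[lab[i]]], warp_strength, out_length = len)
    values[[i]] <- s + rnorm(len, 0, noise_sd)
  }
  if (outlier_fraction > 0) {
    n_out <- floor(outlier_fraction * n_total)
    if (n_out > 0) {
      idx <- sample.int(n_total, n_out)
      for (i in idx) values[[i]] <- sample(values[[i]])
    }
  }
  ts_dataset(values, labels = as.character(lab))
}
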