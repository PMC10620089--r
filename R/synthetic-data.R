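#' Configuration for the two-cluster 2D pair sequence
#'
#' Consecutive input pairs are drawn from two Gaussian clusters centred at
#' `centers` on the x axis with standard deviations `sigma_x` and `sigma_y`.
#' With probability `crossover_prob` a pair spans the two clusters
#' (an unpredictable transition); otherwise both members share a cluster, so
#' cluster identity is the temporally contiguous feature of the sequence.
#'
#' @param sigma_x Standard deviation along x (default 0.1).
#' @param sigma_y Standard deviation along y.
#' @param centers Cluster centres on the x axis (default `c(-1, 1)`).
#' @param crossover_prob Probability `P` that a pair spans clusters.
#' @param n_pairs Number of consecutive pairs to draw.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `cluster_sequence_config`.
#' @export
cluster_sequence_config <- function(sigma_x = 0.1, sigma_y = 1,
                                    centers = c(-1, 1), crossover_prob = 0,
                                    n_pairs = 1000L, seed = NULL) {
  stopifnot(sigma_x > 0, sigma_y >= 0,
            crossover_prob >= 0, crossover_prob <= 1,
            length(centers) == 2)
  if (n_pairs < 1) stop("'n_pairs' must be positive")
  structure(list(sigma_x = sigma_x, sigma_y = sigma_y, centers = centers,
                 crossover_prob = crossover_prob, n_pairs = as.integer(n_pairs),
                 seed = seed),
            class = "cluster_sequence_config")
}

#' Generate paired consecutive inputs from the two-cluster 2D task
#'
#' Draws `n_pairs` pairs `(x(t - dt), x(t))` of 2D points. Each member is
#' sampled independently from a Gaussian centred on its cluster. Crossover
#' pairs (members in different clusters) are included as a fixed per-batch
#' fraction `round(P * n_pairs)` rather than Bernoulli draws, so small
#' batches carry exactly the configured contamination.
#'
#' @param config A [cluster_sequence_config()].
#' @return A `paired_batch`: list with `x_prev` and `x_curr`, each an
#'   `n_pairs` x 2 matrix (columns x, y), plus the cluster index of each
#'   member (`cluster_prev`, `cluster_curr`, values 1 or 2 indexing
#'   `config$centers`).
#' @export
gen_cluster_pairs <- function(config) {
  stopifnot(inherits(config, "cluster_sequence_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_pairs
  n_cross <- round(config$crossover_prob * n)
  cl_prev <- sample(c(1L, 2L), n, replace = TRUE)
  cl_curr <- cl_prev
  if (n_cross > 0) {
    idx <- sample.int(n, n_cross)
    cl_curr[idx] <- 3L - cl_prev[idx]
  }
  draw <- function(cl) {
    cbind(x = config$centers[cl] + rnorm(n, 0, config$sigma_x),
          y = rnorm(n, 0, config$sigma_y))
  }
  batch <- paired_batch(draw(cl_prev), draw(cl_curr))
  batch$cluster_prev <- cl_prev
  batch$cluster_curr <- cl_curr
  batch
}

#' Construct a batch of paired consecutive inputs
#'
#' @param x_prev,x_curr Matrices (B x N) holding the inputs at `t - dt` and
#'   `t` respectively.
#' @return A `paired_batch` object.
#' @export
paired_batch <- function(x_prev, x_curr) {
  x_prev <- as.matrix(x_prev); x_curr <- as.matrix(x_curr)
  if (!identical(dim(x_prev), dim(x_curr)))
    stop("'x_prev' and 'x_curr' must have identical dimensions")
  structure(list(x_prev = x_prev, x_curr = x_curr), class = "paired_batch")
}

#' Configuration for slow Fourier rate signals
#'
#' Periodic rate templates built from a Fourier basis
#' \deqn{x(t) = \sum_{k=1}^{K} (\theta_k / \alpha^k) \sin(2\pi k t / T + \phi_k)}
#' with coefficients \eqn{\theta_k, \phi_k \sim U[0, 1)}. The spectral decay
#' `alpha` > 1 biases the signal toward slow frequencies. The trace is then
#' centred on `base_rate`, variance-normalised and clipped below at
#' `clip_floor`. Note the harmonic index multiplies the frequency here
#' (`k * 2 * pi / T`), the standard Fourier-basis reading.
#'
#' @param period Signal period T in seconds.
#' @param alpha Spectral decay constant (default 1.1).
#' @param n_harmonics Number of Fourier components K (default 20).
#' @param sample_interval Sampling interval in seconds (default 0.010).
#' @param base_rate Centre rate in Hz (default 5).
#' @param clip_floor Lower rate clip in Hz (default 0.1).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `slow_signal_config`.
#' @export
slow_signal_config <- function(period = 3, alpha = 1.1, n_harmonics = 20L,
                               sample_interval = 0.010, base_rate = 5,
                               clip_floor = 0.1, seed = NULL) {
  stopifnot(period > 0, alpha > 1, clip_floor >= 0, sample_interval > 0)
  if (n_harmonics < 1) stop("'n_harmonics' must be at least 1")
  structure(list(period = period, alpha = alpha,
                 n_harmonics = as.integer(n_harmonics),
                 sample_interval = sample_interval, base_rate = base_rate,
                 clip_floor = clip_floor, seed = seed),
            class = "slow_signal_config")
}

#' Generate one period of a slow Fourier rate signal
#'
#' @param config A [slow_signal_config()].
#' @param raw If `TRUE`, return the centred variance-normalised trace before
#'   adding the base rate and clipping (used by tests).
#' @return A numeric rate trace (Hz) sampled at `config$sample_interval`
#'   covering exactly one period, with attributes `dt` and `period`.
#' @export
gen_slow_signal <- function(config, raw = FALSE) {
  stopifnot(inherits(config, "slow_signal_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  K <- config$n_harmonics
  theta <- runif(K); phi <- runif(K)
  tt <- seq(0, config$period - config$sample_interval,
            by = config$sample_interval)
  x <- rep(0, length(tt))
  for (k in seq_len(K))
    x <- x + theta[k] / config$alpha^k * sin(2 * pi * k * tt / config$period + phi[k])
  x <- (x - mean(x)) / sd(x)
  if (!raw) x <- pmax(config$base_rate + x, config$clip_floor)
  structure(x, dt = config$sample_interval, period = config$period)
}

#' Temporally shuffled control of a rate trace
#'
#' Repeats the one-period template `n_periods` times and permutes the
#' repeated trace on a fixed time grid, destroying its slow temporal
#' structure while preserving the multiset (and thus mean) of rate values.
#'
#' @param trace Rate trace from [gen_slow_signal()] (or any numeric vector
#'   with a `dt` attribute).
#' @param n_periods Number of repetitions before shuffling (default 13).
#' @param grid Shuffling grid in seconds (default 0.010); must be a multiple
#'   of the trace sampling interval.
#' @return The shuffled trace with the same `dt` attribute.
#' @export
make_shuffled_control <- function(trace, n_periods = 13L, grid = 0.010) {
  dt <- attr(trace, "dt")
  if (is.null(dt)) stop("'trace' must carry a 'dt' attribute")
  k <- grid / dt
  if (abs(k - round(k)) > 1e-9)
    stop("'grid' must be an integer multiple of the trace sampling interval")
  k <- as.integer(round(k))
  rep_trace <- rep(as.numeric(trace), n_periods)
  n_bins <- length(rep_trace) %/% k
  bins <- matrix(rep_trace[seq_len(n_bins * k)], nrow = k)
  shuffled <- as.numeric(bins[, sample.int(n_bins)])
  structure(shuffled, dt = dt)
}

#' Generate an inhomogeneous Poisson spike raster
#'
#' Every neuron in a population shares its population's instantaneous rate
#' trace; spikes are realised independently per neuron by per-step Bernoulli
#' thinning with probability `rate * dt` on a fixed simulation grid
#' (`rate * dt` must stay well below 1).
#'
#' @param group_rates A list of rate traces (Hz), one per population, each
#'   sampled on a common grid of width `rate_dt`. Traces are recycled
#'   periodically if shorter than `duration`.
#' @param group_sizes Integer vector of population sizes (same length as
#'   `group_rates`).
#' @param duration Raster duration in seconds.
#' @param dt Simulation step in seconds (default 1e-4).
#' @param rate_dt Sampling interval of the rate traces (default taken from
#'   the first trace's `dt` attribute, else 0.010).
#' @param group_names Optional population names.
#' @return A [spike_raster()] whose `population_slices` give the 1-based
#'   neuron index range of each population.
#' @export
gen_poisson_raster <- function(group_rates, group_sizes, duration, dt = 1e-4,
                               rate_dt = NULL, group_names = NULL) {
  stopifnot(length(group_rates) == length(group_sizes), duration > 0, dt > 0)
  if (is.null(rate_dt))
    rate_dt <- attr(group_rates[[1]], "dt") %||% 0.010
  if (dt > rate_dt)
    stop("'dt' must not exceed the rate sample interval")
  n_bins <- as.integer(ceiling(duration / rate_dt))
  rate_mat <- t(vapply(group_rates, function(tr) {
    tr <- as.numeric(tr)
    if (any(tr < 0)) stop("rates must be nonnegative")
    rep_len(tr, n_bins)
  }, numeric(n_bins)))
  if (n_bins == 1L) rate_mat <- matrix(rate_mat, nrow = length(group_rates))
  group_of <- rep.int(seq_along(group_sizes) - 1L, group_sizes)
  ev <- cpp_gen_poisson_raster(rate_mat, group_of, rate_dt, dt, duration)
  ends <- cumsum(group_sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (is.null(group_names))
    group_names <- paste0("P", seq_along(group_sizes) - 1L)
  slices <- stats::setNames(Map(c, starts, ends), group_names)
  spike_raster(ev$time, ev$id, duration = duration, dt = dt,
               population_slices = slices)
}

#' Construct a spike raster
#'
#' Timestamped spike events with named population index ranges.
#'
#' @param time Spike times in seconds, in `[0, duration)`.
#' @param id 1-based neuron ids.
#' @param duration Raster duration in seconds.
#' @param dt Simulation step used to generate the raster.
#' @param population_slices Named list of `c(first, last)` id ranges.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(time, id, duration, dt = 1e-4,
                         population_slices = list()) {
  time <- as.numeric(time); id <- as.integer(id)
  stopifnot(length(time) == length(id))
  if (length(time) && (min(time) < 0 || max(time) >= duration))
    stop("spike times must lie in [0, duration)")
  if (is.unsorted(time)) {
    o <- order(time, id)
    time <- time[o]; id <- id[o]
  }
  for (sl in population_slices)
    if (length(id) && any(id < 1L))
      stop("neuron ids must be positive")
  structure(list(time = time, id = id, duration = duration, dt = dt,
                 population_slices = population_slices),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d events, %.3g s, %d population(s)\n",
              length(x$time), x$duration, length(x$population_slices)))
  invisible(x)
}

#' Mean firing rate of a spike raster
#'
#' @param raster A [spike_raster()].
#' @param population Optional population name; default: all neurons.
#' @param n_neurons Number of neurons to average over when the raster carries
#'   no population slices.
#' @return Mean rate in Hz.
#' @export
raster_mean_rate <- function(raster, population = NULL, n_neurons = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (!is.null(population)) {
    sl <- raster$population_slices[[population]]
    if (is.null(sl)) stop("unknown population: ", population)
    n <- sl[2] - sl[1] + 1
    k <- sum(raster$id >= sl[1] & raster$id <= sl[2])
  } else {
    n <- n_neurons %||%
      (if (length(raster$population_slices))
         max(vapply(raster$population_slices, `[`, numeric(1), 2))
       else max(raster$id, 1L))
    k <- length(raster$time)
  }
  k / (n * raster$duration)
}

#' Bin a spike raster into per-neuron rate estimates
#'
#' @param raster A [spike_raster()].
#' @param bin_width Bin width in seconds (default 0.025).
#' @param neurons Integer ids to include (default: all up to the largest
#'   declared population index).
#' @return Matrix of rates (Hz), bins x neurons.
#' @export
bin_raster <- function(raster, bin_width = 0.025, neurons = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(neurons)) {
    n_max <- if (length(raster$population_slices))
      max(vapply(raster$population_slices, `[`, numeric(1), 2))
    else max(raster$id, 1L)
    neurons <- seq_len(n_max)
  }
  n_bins <- as.integer(floor(raster$duration / bin_width))
  keep <- raster$id %in% neurons & raster$time < n_bins * bin_width
  bin_of <- floor(raster$time[keep] / bin_width) + 1L
  id_idx <- match(raster$id[keep], neurons)
  counts <- matrix(0, n_bins, length(neurons))
  if (any(keep)) {
    tab <- table(factor(bin_of, levels = seq_len(n_bins)),
                 factor(id_idx, levels = seq_along(neurons)))
    counts <- matrix(as.numeric(tab), n_bins, length(neurons))
  }
  counts / bin_width
}

`%||%` <- function(a, b) if (is.null(a)) b else a
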