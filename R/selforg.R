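# The self-organizing two-layer network: Gaussian-tuned input layer,
# leaky-integrator output layer with percentile competition, Hebbian learning
# with post-update weight renormalization.

#' Input layer of the self-organizing network
#'
#' A mixture of two modalities of input neurons: eye-position units, each
#' firing maximally at a unique preferred eye position, and retinal units,
#' each firing maximally at a unique preferred retinal stimulus location.
#' Under the default ranges (eye \eqn{[-35, 35]} deg, retinal \eqn{[-10, 10]}
#' deg, 1 deg steps) the layer has 71 + 21 = 92 units. Input rates are
#' instantaneous functions of the current stimulus and eye position (no input
#' dynamics).
#'
#' Units are ordered eye-position units first, then retinal units.
#'
#' @param eye_range,retinal_range Length-2 numeric, degrees.
#' @param step Grid step for preferred values, degrees.
#' @param eye_width Eye-position tuning width \eqn{\rho}, degrees (default 15).
#' @param retinal_width Retinal tuning width \eqn{\sigma}, degrees (default 6).
#' @param eye_peak,retinal_peak Maximum activations (default 2).
#' @param sigmoid A [sigmoid_spec()] shared by all input units (default slope
#'   4.5, threshold 0).
#'
#' @return An object of class `"input_layer"`.
#' @export
#' @examples
#' layer <- input_layer()
#' layer$n_units # 92
input_layer <- function(eye_range = c(-35, 35), retinal_range = c(-10, 10),
                        step = 1, eye_width = 15, retinal_width = 6,
                        eye_peak = 2, retinal_peak = 2,
                        sigmoid = sigmoid_spec(4.5, 0)) {
  if (!is_sigmoid_spec(sigmoid)) stop("`sigmoid` must be a sigmoid_spec", call. = FALSE)
  eye_pref <- seq(eye_range[1], eye_range[2], by = step)
  ret_pref <- seq(retinal_range[1], retinal_range[2], by = step)
  structure(
    list(eye_pref = eye_pref, ret_pref = ret_pref,
         eye_width = eye_width, retinal_width = retinal_width,
         eye_peak = eye_peak, retinal_peak = retinal_peak,
         sigmoid = sigmoid,
         n_eye = length(eye_pref), n_retinal = length(ret_pref),
         n_units = length(eye_pref) + length(ret_pref)),
    class = "input_layer"
  )
}

#' @export
print.input_layer <- function(x, ...) {
  cat(sprintf("<input_layer> %d units (%d eye-position + %d retinal); rho = %g deg, sigma = %g deg\n",
              x$n_units, x$n_eye, x$n_retinal, x$eye_width, x$retinal_width))
  invisible(x)
}

#' Instantaneous input-layer rates
#'
#' Evaluates every input unit for a stimulus at retinal location `x` with the
#' eye at position `y`: eye-position units see `y`, retinal units see `x`,
#' and each Gaussian activation passes through the layer sigmoid.
#'
#' @param layer An [input_layer()].
#' @param x Retinal stimulus location, degrees (scalar).
#' @param y Eye position, degrees (scalar).
#'
#' @return Rate vector of length `layer$n_units` (eye units first).
#' @export
input_rates <- function(layer, x, y) {
  stopifnot(inherits(layer, "input_layer"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      !is.numeric(y) || length(y) != 1L || !is.finite(y)) {
    stop("`x` and `y` must be single finite numbers (degrees)", call. = FALSE)
  }
  h_eye <- layer$eye_peak * exp(-(y - layer$eye_pref)^2 / (2 * layer$eye_width^2))
  h_ret <- layer$retinal_peak * exp(-(x - layer$ret_pref)^2 / (2 * layer$retinal_width^2))
  sigmoid_rate(c(h_eye, h_ret), layer$sigmoid)
}

#' Initialize a self-organizing network
#'
#' Creates the output layer and its feedforward synapses. Each output neuron
#' receives afferents from a unique randomly drawn subset of
#' `floor(connectivity/100 * n_inputs)` input units (drawn without
#' replacement). Weights on existing synapses are initialized uniformly on
#' `[0, 1]` and each output's weight vector is renormalized to unit Euclidean
#' norm, so the unit-norm invariant maintained by [hebbian_update()] holds
#' from the start. Masked-out weights are exactly zero at all times.
#'
#' @param seed Integer seed; the network is fully reproducible from it.
#' @param layer An [input_layer()].
#' @param n_outputs Number of output neurons (default 100).
#' @param connectivity Percentage of the input population each output receives
#'   afferents from (default 10).
#' @param learning_rate Hebbian learning rate, per second (default 0.05).
#' @param tau Activation time constant, seconds (default 0.1, i.e. 100 ms).
#' @param dt Forward-Euler step, seconds (default `tau / 10`).
#' @param sparseness Sparseness percentile \eqn{\pi} for output competition
#'   (default 90: the competition threshold is the 90th-percentile activation,
#'   so about 10 percent of outputs fire above half-maximum at any time).
#' @param sigmoid Output [sigmoid_spec()] (default slope 4.5, threshold 0).
#'
#' @return An object of class `"gain_network"` with fields `weights`
#'   (`n_outputs` x `n_inputs`), `mask` (logical), `h` (activations), the
#'   dynamics and learning parameters and the seed.
#' @export
#' @examples
#' net <- init_network(1, input_layer())
#' rowSums(net$mask)[1] # 9 afferents per output under defaults
init_network <- function(seed, layer, n_outputs = 100, connectivity = 10,
                         learning_rate = 0.05, tau = 0.1, dt = NULL,
                         sparseness = 90, sigmoid = sigmoid_spec(4.5, 0)) {
  stopifnot(inherits(layer, "input_layer"))
  if (!is.numeric(connectivity) || connectivity <= 0 || connectivity > 100) {
    stop("`connectivity` must be in (0, 100]", call. = FALSE)
  }
  if (!is.numeric(n_outputs) || n_outputs < 1) stop("`n_outputs` must be >= 1", call. = FALSE)
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be positive (seconds)", call. = FALSE)
  if (is.null(dt)) dt <- tau / 10
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive (seconds)", call. = FALSE)
  if (!is.numeric(sparseness) || sparseness < 0 || sparseness >= 100) {
    stop("`sparseness` must be in [0, 100)", call. = FALSE)
  }
  if (!is_sigmoid_spec(sigmoid)) stop("`sigmoid` must be a sigmoid_spec", call. = FALSE)

  n_in <- layer$n_units
  n_aff <- floor(connectivity / 100 * n_in)
  if (n_aff < 1) stop("connectivity too low: each output needs at least one afferent", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  mask <- matrix(FALSE, nrow = n_outputs, ncol = n_in)
  for (i in seq_len(n_outputs)) {
    mask[i, sample.int(n_in, n_aff)] <- TRUE
  }
  weights <- matrix(0, nrow = n_outputs, ncol = n_in)
  weights[mask] <- stats::runif(sum(mask))
  weights <- weights / sqrt(rowSums(weights^2))

  structure(
    list(weights = weights, mask = mask, h = numeric(n_outputs),
         tau = tau, dt = dt, learning_rate = learning_rate,
         sparseness = sparseness, connectivity = connectivity,
         sigmoid = sigmoid, n_outputs = as.integer(n_outputs),
         n_inputs = n_in, n_afferents = n_aff, seed = as.integer(seed)),
    class = "gain_network"
  )
}

# Save/restore the global RNG state so seeded constructors do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.gain_network <- function(x, ...) {
  cat(sprintf("<gain_network> %d outputs x %d inputs; %d afferents each (connectivity %g%%)\n",
              x$n_outputs, x$n_inputs, x$n_afferents, x$connectivity))
  cat(sprintf("  tau = %g s, dt = %g s, learning rate = %g /s, sparseness percentile = %g, seed = %d\n",
              x$tau, x$dt, x$learning_rate, x$sparseness, x$seed))
  invisible(x)
}

#' One Forward-Euler step of the output dynamics
#'
#' Integrates the leaky-integrator activation equation
#' \eqn{\tau_h \, dh_i/dt = -h_i + \sum_j w_{ij} v_j} for all outputs
#' simultaneously: `h <- h + (dt/tau) * (-h + W v_in)`.
#'
#' @param net A [init_network()] network.
#' @param v_in Input rate vector (length `net$n_inputs`).
#'
#' @return The network with updated `h`.
#' @export
step_dynamics <- function(net, v_in) {
  stopifnot(inherits(net, "gain_network"))
  if (length(v_in) != net$n_inputs) stop("`v_in` has wrong length", call. = FALSE)
  drive <- drop(net$weights %*% v_in)
  net$h <- net$h + (net$dt / net$tau) * (-net$h + drive)
  if (any(!is.finite(net$h))) {
    stop("non-finite output activation: dynamics diverged", call. = FALSE)
  }
  net
}

#' Nearest-rank percentile
#'
#' The p-th percentile of `x` under the nearest-rank definition: the
#' `ceiling(p/100 * n)`-th smallest value (the minimum when `p = 0`).
#'
#' @param x Numeric vector.
#' @param p Percentile in `[0, 100)`.
#' @return A single value of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  n <- length(x)
  k <- max(1L, as.integer(ceiling(p / 100 * n)))
  sort(x, partial = k)[k]
}

#' Competitive output rates
#'
#' Implements soft winner-take-all competition among output neurons: the
#' competition threshold \eqn{p_\pi} is the current \eqn{\pi}-th percentile
#' (nearest-rank) of the activations, and each output fires at
#' \eqn{v_i = 1 / (1 + \exp(-2\varphi(h_i - p_\pi - \theta)))}. With
#' \eqn{\theta = 0}, a neuron whose activation equals the percentile value
#' fires at exactly 0.5, and roughly \eqn{(100-\pi)} percent of the
#' population fires above 0.5.
#'
#' @param net A [init_network()] network.
#' @return Rate vector of length `net$n_outputs`.
#' @export
competitive_rates <- function(net) {
  stopifnot(inherits(net, "gain_network"))
  p <- nearest_rank_percentile(net$h, net$sparseness)
  sigmoid_rate(net$h - p, net$sigmoid)
}

#' Hebbian weight update with renormalization
#'
#' Strengthens each existing synapse in proportion to the product of its
#' pre- and postsynaptic rates, `dw_ij = dt * learning_rate * v_i * v_j`
#' (masked-out synapses stay exactly zero), then renormalizes each output's
#' weight vector to unit Euclidean norm to prevent unbounded growth. Since
#' rates and initial weights are non-negative, weights stay non-negative:
#' the update cannot violate Dale's law.
#'
#' @param net A [init_network()] network.
#' @param v_in Presynaptic (input) rate vector.
#' @param v_out Postsynaptic (output) rate vector.
#'
#' @return The network with updated `weights`.
#' @export
hebbian_update <- function(net, v_in, v_out) {
  stopifnot(inherits(net, "gain_network"))
  if (length(v_in) != net$n_inputs || length(v_out) != net$n_outputs) {
    stop("rate vector of wrong length", call. = FALSE)
  }
  # a zero learning rate is an exact no-op: nothing to renormalize
  if (net$learning_rate == 0) return(net)
  dw <- (net$dt * net$learning_rate) * tcrossprod(v_out, v_in)
  dw[!net$mask] <- 0
  w <- net$weights + dw
  norms <- sqrt(rowSums(w^2))
  if (any(norms < 1e-12)) stop("zero-norm weight row after update", call. = FALSE)
  net$weights <- w / norms
  net
}

#' Steady-state output rates for a fixed stimulus
#'
#' For response measurement (as opposed to training), the output activations
#' are taken at the fixed point of the leaky-integrator dynamics under a
#' constant input, \eqn{h_i = \sum_j w_{ij} v_j}, and the competitive sigmoid
#' is applied across the population.
#'
#' @param net A [init_network()] (possibly trained) network.
#' @param layer The [input_layer()] driving the network.
#' @param x Retinal stimulus location, degrees.
#' @param y Eye position, degrees.
#'
#' @return Rate vector of length `net$n_outputs`.
#' @export
output_rates <- function(net, layer, x, y) {
  v_in <- input_rates(layer, x, y)
  h <- drop(net$weights %*% v_in)
  p <- nearest_rank_percentile(h, net$sparseness)
  sigmoid_rate(h - p, net$sigmoid)
}

#' Eye-position sweep of a trained output neuron
#'
#' Analogue of [eye_sweep()] for the self-organizing model: the stimulus is
#' held at retinal location `stimulus_at` while the eye visits each position;
#' steady-state competitive rates are recorded for output `unit`.
#'
#' @param net A [init_network()] (possibly trained) network.
#' @param layer The [input_layer()].
#' @param unit Output neuron index.
#' @param eye_positions Eye positions, degrees (default: the layer's eye
#'   preferred-value grid).
#' @param stimulus_at Retinal stimulus location, degrees.
#'
#' @return A [response_curve()] over eye position.
#' @export
output_eye_sweep <- function(net, layer, unit, eye_positions = NULL,
                             stimulus_at = 0) {
  if (is.null(eye_positions)) eye_positions <- layer$eye_pref
  rates <- vapply(eye_positions, function(yy) {
    output_rates(net, layer, stimulus_at, yy)[unit]
  }, numeric(1))
  response_curve(eye_positions, rates,
                 context = list(swept = "eye_position", retinal_x = stimulus_at,
                                unit = unit))
}

#' Retinal sweeps of a trained output neuron across fixations
#'
#' Analogue of [retinal_sweep_family()] for the self-organizing model.
#'
#' @inheritParams output_eye_sweep
#' @param fixations Eye positions of the fixations, degrees (must include the
#'   reference).
#' @param retinal_positions Retinal locations, degrees (default: the layer's
#'   retinal preferred-value grid).
#' @param reference_fixation Reference eye position (default 0).
#'
#' @return A [fixation_family()].
#' @export
output_retinal_family <- function(net, layer, unit, fixations,
                                  retinal_positions = NULL,
                                  reference_fixation = 0) {
  if (is.null(retinal_positions)) retinal_positions <- layer$ret_pref
  curves <- lapply(fixations, function(e) {
    rates <- vapply(retinal_positions, function(xx) {
      output_rates(net, layer, xx, e)[unit]
    }, numeric(1))
    response_curve(retinal_positions, rates,
                   context = list(swept = "retinal_location", eye_y = e, unit = unit))
  })
  fixation_family(fixations, curves, reference_fixation)
}

#' Eye-sweep linearity of every trained output neuron
#'
#' Evaluates the trained network over the full (retinal location, eye
#' position) grid, picks for each output neuron the retinal location at which
#' it responds most strongly (its "best" retinal location), and computes the
#' linearity of its eye sweep there, with the activity gate applied.
#'
#' @param net A trained [init_network()] network.
#' @param layer The [input_layer()].
#' @param retinal_positions,eye_positions Evaluation grids, degrees (defaults:
#'   the layer's preferred-value grids).
#' @param activity_min,range_min Activity gate, as in [linearity_r2()].
#'
#' @return Data frame with one row per output: `unit`, `best_retinal_x`,
#'   `r_squared`, `active`, `profile` (see [classify_profile()]).
#' @export
trained_population_linearity <- function(net, layer,
                                         retinal_positions = NULL,
                                         eye_positions = NULL,
                                         activity_min = 0.1, range_min = 0.05) {
  if (is.null(retinal_positions)) retinal_positions <- layer$ret_pref
  if (is.null(eye_positions)) eye_positions <- layer$eye_pref
  nx <- length(retinal_positions); ny <- length(eye_positions)

  # rates for all outputs over the full condition grid, competition applied
  # per condition
  R <- array(0, dim = c(net$n_outputs, nx, ny))
  for (ix in seq_len(nx)) {
    for (iy in seq_len(ny)) {
      R[, ix, iy] <- output_rates(net, layer, retinal_positions[ix], eye_positions[iy])
    }
  }

  rows <- lapply(seq_len(net$n_outputs), function(i) {
    surf <- R[i, , , drop = TRUE]          # nx x ny
    best_ix <- which.max(apply(surf, 1, max))
    curve <- surf[best_ix, ]
    lr <- linearity_r2(curve, abscissa = eye_positions,
                       activity_min = activity_min, range_min = range_min)
    data.frame(unit = i,
               best_retinal_x = retinal_positions[best_ix],
               r_squared = if (lr$active) lr$r_squared else NA_real_,
               active = lr$active,
               profile = classify_profile(curve, abscissa = eye_positions,
                                          activity_min = activity_min,
                                          range_min = range_min))
  })
  do.call(rbind, rows)
}
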