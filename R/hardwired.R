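# The hardwired gain-field model: a complete (alpha, beta) lattice of visual
# output neurons, each tuned to one combination of preferred retinal location
# and preferred eye position.

#' A single hardwired visual neuron
#'
#' Identified by its preferred retinal location `alpha` and preferred eye
#' position `beta` (both in degrees). Tuning widths, peaks and the sigmoid are
#' shared across the population and live on the [build_population()] grid.
#'
#' @param alpha Preferred retinal location, degrees.
#' @param beta Preferred eye position, degrees.
#' @return An object of class `"hardwired_neuron"`.
#' @export
hardwired_neuron <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "hardwired_neuron")
}

#' Build the hardwired population grid
#'
#' Constructs the full lattice of visual output neurons covering every
#' combination of preferred retinal location and preferred eye position in
#' integer-like steps. Under the default ranges (\eqn{[-10, 10]} degrees
#' retinal, \eqn{[-35, 35]} degrees eye position, 1 degree steps) this yields
#' 71 x 21 = 1491 neurons.
#'
#' Neurons are stored eye-major (beta varies slowest, alpha fastest); this
#' ordering is a storage convention only and all analyses identify neurons by
#' their `(alpha, beta)` pair.
#'
#' @param retinal_range Length-2 numeric, degrees; range of preferred retinal
#'   locations.
#' @param eye_range Length-2 numeric, degrees; range of preferred eye
#'   positions.
#' @param step Grid step in degrees; must divide both range widths.
#' @param retinal_width,eye_width Gaussian tuning widths \eqn{\sigma} and
#'   \eqn{\rho}, degrees.
#' @param retinal_peak,eye_peak Maximum activations of the two components.
#' @param sigmoid A [sigmoid_spec()]; defaults to slope 1.9, threshold 0.99.
#'
#' @return An object of class `"population_grid"` with elements `neurons`
#'   (data frame with columns `alpha`, `beta`), the ranges and step, the two
#'   tuning templates and the sigmoid.
#' @export
#' @examples
#' grid <- build_population()
#' nrow(grid$neurons) # 1491
build_population <- function(retinal_range = c(-10, 10),
                             eye_range = c(-35, 35),
                             step = 1,
                             retinal_width = 6,
                             eye_width = 20,
                             retinal_peak = 0.485,
                             eye_peak = 0.485,
                             sigmoid = sigmoid_spec(1.9, 0.99)) {
  check_range <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a finite length-2 numeric with min <= max", name),
           call. = FALSE)
    }
  }
  check_range(retinal_range, "retinal_range")
  check_range(eye_range, "eye_range")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) || step <= 0) {
    stop("`step` must be a single positive number (degrees)", call. = FALSE)
  }
  divides <- function(width) abs(width / step - round(width / step)) < 1e-9
  if (!divides(diff(retinal_range)) || !divides(diff(eye_range))) {
    stop("`step` must divide both range widths", call. = FALSE)
  }
  if (!is_sigmoid_spec(sigmoid)) stop("`sigmoid` must be a sigmoid_spec", call. = FALSE)

  alphas <- seq(retinal_range[1], retinal_range[2], by = step)
  betas <- seq(eye_range[1], eye_range[2], by = step)
  neurons <- expand.grid(alpha = alphas, beta = betas,
                         KEEP.OUT.ATTRS = FALSE)

  structure(
    list(
      neurons = neurons,
      retinal_range = retinal_range,
      eye_range = eye_range,
      step = step,
      retinal_width = retinal_width,
      eye_width = eye_width,
      retinal_peak = retinal_peak,
      eye_peak = eye_peak,
      sigmoid = sigmoid
    ),
    class = "population_grid"
  )
}

#' @export
print.population_grid <- function(x, ...) {
  cat(sprintf(
    "<population_grid> %d neurons; alpha in [%g, %g] deg, beta in [%g, %g] deg, step %g deg\n",
    nrow(x$neurons), x$retinal_range[1], x$retinal_range[2],
    x$eye_range[1], x$eye_range[2], x$step))
  cat(sprintf("  sigma = %g deg, rho = %g deg, peaks = (%g, %g), sigmoid slope %g threshold %g\n",
              x$retinal_width, x$eye_width, x$retinal_peak, x$eye_peak,
              x$sigmoid$slope, x$sigmoid$threshold))
  invisible(x)
}

neuron_specs <- function(neuron, grid) {
  list(
    retinal = tuning_spec(neuron$alpha, grid$retinal_width, grid$retinal_peak),
    eye = tuning_spec(neuron$beta, grid$eye_width, grid$eye_peak)
  )
}

as_neuron <- function(neuron) {
  if (inherits(neuron, "hardwired_neuron")) return(neuron)
  if (is.numeric(neuron) && length(neuron) == 2L) {
    return(hardwired_neuron(neuron[1], neuron[2]))
  }
  stop("`neuron` must be a hardwired_neuron or a numeric (alpha, beta) pair",
       call. = FALSE)
}

#' Firing rate of a hardwired neuron
#'
#' Composes the Gaussian retinal and eye-position components with the
#' population sigmoid: `sigmoid_rate(combined_activation(x, y, ...))`.
#' Vectorized over `x` and `y`.
#'
#' @param neuron A [hardwired_neuron()] or numeric `c(alpha, beta)`.
#' @param x Retinal stimulus location(s), degrees.
#' @param y Eye position(s), degrees.
#' @param grid A [build_population()] grid supplying widths, peaks and sigmoid.
#'
#' @return Firing rate(s) in (0, 1).
#' @export
neuron_rate <- function(neuron, x, y, grid) {
  neuron <- as_neuron(neuron)
  specs <- neuron_specs(neuron, grid)
  sigmoid_rate(combined_activation(x, y, specs$retinal, specs$eye), grid$sigmoid)
}

#' Tuning curve container
#'
#' Firing rate as a function of one swept variable (eye position or retinal
#' location) with everything else held fixed.
#'
#' @param abscissa Strictly increasing numeric vector, degrees.
#' @param rates Numeric vector of rates in `[0, 1]`, same length as `abscissa`.
#' @param context Named list recording what was swept and what was held fixed.
#' @return An object of class `"response_curve"`.
#' @export
response_curve <- function(abscissa, rates, context = list()) {
  if (!is.numeric(abscissa) || length(abscissa) == 0L || any(!is.finite(abscissa))) {
    stop("`abscissa` must be finite numeric", call. = FALSE)
  }
  if (any(diff(abscissa) <= 0)) {
    stop("`abscissa` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(rates) || length(rates) != length(abscissa) || any(!is.finite(rates))) {
    stop("`rates` must be finite numeric, same length as `abscissa`", call. = FALSE)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("`rates` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(abscissa = as.numeric(abscissa), rates = as.numeric(rates),
                 context = context),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve> %d points over [%g, %g] deg; rate range [%.4f, %.4f]\n",
              length(x$abscissa), min(x$abscissa), max(x$abscissa),
              min(x$rates), max(x$rates)))
  invisible(x)
}

#' @export
as.data.frame.response_curve <- function(x, ...) {
  data.frame(abscissa_deg = x$abscissa, rate = x$rates)
}

#' Eye-position sweep of a hardwired neuron
#'
#' Holds the visual stimulus fixed on the retina (by default at the neuron's
#' preferred retinal location) while the eye visits each position in
#' `eye_positions`, returning the resulting tuning curve.
#'
#' @inheritParams neuron_rate
#' @param eye_positions Eye positions to visit, degrees; defaults to the grid's
#'   full eye range in grid steps.
#' @param stimulus_at Retinal stimulus location, degrees; defaults to the
#'   neuron's `alpha`.
#'
#' @return A [response_curve()] over eye position.
#' @export
#' @examples
#' grid <- build_population()
#' curve <- eye_sweep(hardwired_neuron(-10, -34), grid)
#' round(curve$rates[curve$abscissa == 35], 3)
eye_sweep <- function(neuron, grid, eye_positions = NULL, stimulus_at = NULL) {
  neuron <- as_neuron(neuron)
  if (is.null(eye_positions)) {
    eye_positions <- seq(grid$eye_range[1], grid$eye_range[2], by = grid$step)
  }
  if (length(eye_positions) == 0L) stop("`eye_positions` must be non-empty", call. = FALSE)
  if (is.null(stimulus_at)) stimulus_at <- neuron$alpha
  rates <- neuron_rate(neuron, stimulus_at, eye_positions, grid)
  response_curve(eye_positions, rates,
                 context = list(swept = "eye_position", retinal_x = stimulus_at,
                                alpha = neuron$alpha, beta = neuron$beta))
}

#' Family of retinal sweeps across fixations
#'
#' For each fixation (eye position) in `fixations`, records the neuron's rate
#' at every retinal stimulus location in `retinal_positions`. The straight
#' ahead fixation (0 degrees) must be included: it is the reference curve for
#' [multiplicativity_test()].
#'
#' @inheritParams neuron_rate
#' @param fixations Eye positions of the fixations, degrees; must contain
#'   `reference_fixation`.
#' @param retinal_positions Retinal locations to sweep, degrees; defaults to
#'   the grid's full retinal range in grid steps.
#' @param reference_fixation Reference eye position, degrees (default 0,
#'   straight ahead).
#'
#' @return An object of class `"fixation_family"`: list with `fixations`,
#'   `curves` (one [response_curve()] per fixation, shared abscissa) and
#'   `reference_fixation`.
#' @export
retinal_sweep_family <- function(neuron, grid, fixations,
                                 retinal_positions = NULL,
                                 reference_fixation = 0) {
  neuron <- as_neuron(neuron)
  if (length(fixations) == 0L) stop("`fixations` must be non-empty", call. = FALSE)
  if (!any(abs(fixations - reference_fixation) < 1e-9)) {
    stop("`fixations` must include the reference fixation", call. = FALSE)
  }
  if (is.null(retinal_positions)) {
    retinal_positions <- seq(grid$retinal_range[1], grid$retinal_range[2],
                             by = grid$step)
  }
  curves <- lapply(fixations, function(e) {
    rates <- neuron_rate(neuron, retinal_positions, e, grid)
    response_curve(retinal_positions, rates,
                   context = list(swept = "retinal_location", eye_y = e,
                                  alpha = neuron$alpha, beta = neuron$beta))
  })
  fixation_family(fixations, curves, reference_fixation)
}

#' Construct a fixation family from curves
#'
#' @param fixations Eye positions, degrees.
#' @param curves List of [response_curve()] objects, one per fixation, all
#'   sharing the same abscissa.
#' @param reference_fixation Which fixation is the reference (default 0).
#' @return An object of class `"fixation_family"`.
#' @export
fixation_family <- function(fixations, curves, reference_fixation = 0) {
  if (length(curves) != length(fixations)) {
    stop("`curves` must have one entry per fixation", call. = FALSE)
  }
  absc <- curves[[1]]$abscissa
  for (cv in curves) {
    if (!inherits(cv, "response_curve")) stop("curves must be response_curve objects", call. = FALSE)
    if (!isTRUE(all.equal(cv$abscissa, absc))) {
      stop("all curves must share the same abscissa", call. = FALSE)
    }
  }
  if (!any(abs(fixations - reference_fixation) < 1e-9)) {
    stop("`fixations` must include the reference fixation", call. = FALSE)
  }
  structure(list(fixations = as.numeric(fixations), curves = curves,
                 reference_fixation = reference_fixation),
            class = "fixation_family")
}

#' @export
as.data.frame.fixation_family <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$fixations), function(i) {
    data.frame(fixation_deg = x$fixations[i],
               abscissa_deg = x$curves[[i]]$abscissa,
               rate = x$curves[[i]]$rates)
  }))
}

#' Tidy response surface of the population
#'
#' Evaluates every neuron's rate over a grid of stimulus locations and eye
#' positions and returns a long data frame suitable for CSV export.
#'
#' @param grid A [build_population()] grid.
#' @param retinal_x Retinal stimulus locations, degrees (default: grid steps).
#' @param eye_y Eye positions, degrees (default: grid steps).
#' @param neurons Optional data frame with columns `alpha`, `beta` selecting a
#'   subset; defaults to all neurons.
#'
#' @return Data frame with columns `alpha`, `beta`, `retinal_x`, `eye_y`,
#'   `rate`.
#' @export
population_responses <- function(grid, retinal_x = NULL, eye_y = NULL,
                                 neurons = NULL) {
  if (is.null(retinal_x)) {
    retinal_x <- seq(grid$retinal_range[1], grid$retinal_range[2], by = grid$step)
  }
  if (is.null(eye_y)) {
    eye_y <- seq(grid$eye_range[1], grid$eye_range[2], by = grid$step)
  }
  if (is.null(neurons)) neurons <- grid$neurons
  out <- vector("list", nrow(neurons))
  cells <- expand.grid(retinal_x = retinal_x, eye_y = eye_y,
                       KEEP.OUT.ATTRS = FALSE)
  for (i in seq_len(nrow(neurons))) {
    n <- hardwired_neuron(neurons$alpha[i], neurons$beta[i])
    out[[i]] <- data.frame(alpha = n$alpha, beta = n$beta,
                           retinal_x = cells$retinal_x, eye_y = cells$eye_y,
                           rate = neuron_rate(n, cells$retinal_x, cells$eye_y, grid))
  }
  do.call(rbind, out)
}
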