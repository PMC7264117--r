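# Gaussian tuning components and sigmoid rate transfer shared by both models.

#' Gaussian tuning component specification
#'
#' A single Gaussian tuning component describes how a neuron's internal
#' activation depends on one variable: either the retinal location of a visual
#' stimulus (preferred location \eqn{\alpha}, width \eqn{\sigma}) or the
#' position of the eye in the orbit (preferred position \eqn{\beta}, width
#' \eqn{\rho}). Activation peaks at `peak` when the variable equals
#' `preferred` and falls off as a Gaussian of the difference.
#'
#' @param preferred Preferred value, in degrees.
#' @param width Gaussian tuning width, in degrees; strictly positive.
#' @param peak Maximum activation (dimensionless); non-negative.
#'
#' @return An object of class `"tuning_spec"`.
#' @seealso [gaussian_activation()], [combined_activation()]
#' @export
#' @examples
#' spec <- tuning_spec(preferred = -10, width = 6, peak = 0.485)
#' gaussian_activation(-10, spec) # = 0.485, the peak
tuning_spec <- function(preferred, width, peak = 1) {
  if (!is.numeric(preferred) || length(preferred) != 1L || !is.finite(preferred)) {
    stop("`preferred` must be a single finite number (degrees)", call. = FALSE)
  }
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0) {
    stop("`width` must be a single strictly positive number (degrees)", call. = FALSE)
  }
  if (!is.numeric(peak) || length(peak) != 1L || !is.finite(peak) || peak < 0) {
    stop("`peak` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(preferred = as.numeric(preferred), width = as.numeric(width),
         peak = as.numeric(peak)),
    class = "tuning_spec"
  )
}

#' @export
print.tuning_spec <- function(x, ...) {
  cat(sprintf("<tuning_spec> preferred = %g deg, width = %g deg, peak = %g\n",
              x$preferred, x$width, x$peak))
  invisible(x)
}

#' Sigmoid transfer function specification
#'
#' The firing rate of every neuron in both models is obtained from its internal
#' activation \eqn{h} through the sigmoid
#' \eqn{v = 1 / (1 + \exp(-2\varphi(h - \theta)))}, with slope \eqn{\varphi}
#' and threshold \eqn{\theta}. Rates are therefore bounded in (0, 1) and equal
#' exactly 0.5 at \eqn{h = \theta}.
#'
#' @param slope Sigmoid slope \eqn{\varphi} (dimensionless); strictly positive.
#' @param threshold Sigmoid threshold \eqn{\theta} (dimensionless).
#'
#' @return An object of class `"sigmoid_spec"`.
#' @seealso [sigmoid_rate()]
#' @export
sigmoid_spec <- function(slope, threshold = 0) {
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) || slope <= 0) {
    stop("`slope` must be a single strictly positive number", call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("`threshold` must be a single finite number", call. = FALSE)
  }
  structure(list(slope = as.numeric(slope), threshold = as.numeric(threshold)),
            class = "sigmoid_spec")
}

#' @export
print.sigmoid_spec <- function(x, ...) {
  cat(sprintf("<sigmoid_spec> slope = %g, threshold = %g\n", x$slope, x$threshold))
  invisible(x)
}

is_tuning_spec <- function(x) inherits(x, "tuning_spec")
is_sigmoid_spec <- function(x) inherits(x, "sigmoid_spec")

# Exponent arguments are clamped to +-700 before exponentiation so extreme
# activations saturate to 0 or 1 instead of producing non-finite rates.
EXP_CLAMP <- 700

#' Gaussian activation of a tuning component
#'
#' Evaluates \eqn{peak \cdot \exp(-(value - preferred)^2 / (2\,width^2))}.
#' Vectorized over `value`.
#'
#' @param value Evaluation point(s), in degrees.
#' @param spec A [tuning_spec()].
#'
#' @return Activation value(s) in `[0, spec$peak]`.
#' @export
#' @examples
#' spec <- tuning_spec(0, 6, 0.485)
#' gaussian_activation(6, spec) / 0.485 # exp(-1/2)
gaussian_activation <- function(value, spec) {
  if (!is_tuning_spec(spec)) stop("`spec` must be a tuning_spec", call. = FALSE)
  if (!is.numeric(value) || length(value) == 0L || any(!is.finite(value))) {
    stop("`value` must be finite numeric (degrees)", call. = FALSE)
  }
  z <- (value - spec$preferred)^2 / (2 * spec$width^2)
  spec$peak * exp(-pmin(z, EXP_CLAMP))
}

#' Combined retinal and eye-position activation
#'
#' The internal activation of a visual neuron is the sum of a retinal component
#' evaluated at the stimulus location `x` and an eye-position component
#' evaluated at the eye position `y`:
#' \eqn{h(x, y) = h_r(x) + h_e(y)}.
#'
#' @param x Retinal stimulus location(s), degrees.
#' @param y Eye position(s), degrees.
#' @param retinal A [tuning_spec()] for the retinal component.
#' @param eye A [tuning_spec()] for the eye-position component.
#'
#' @return Activation in `[0, retinal$peak + eye$peak]`. `x` and `y` recycle
#'   as usual.
#' @export
combined_activation <- function(x, y, retinal, eye) {
  gaussian_activation(x, retinal) + gaussian_activation(y, eye)
}

#' Sigmoid firing rate
#'
#' Maps internal activation to an instantaneous firing rate through
#' \eqn{v = 1 / (1 + \exp(-2\varphi(h - \theta)))}. Strictly increasing in
#' `h`; `h = threshold` maps to exactly 0.5. Vectorized over `h`.
#'
#' @param h Internal activation(s); finite numeric.
#' @param spec A [sigmoid_spec()].
#'
#' @return Rate(s) in (0, 1) (saturating to 0 or 1 within floating tolerance).
#' @export
#' @examples
#' sigmoid_rate(0.99, sigmoid_spec(1.9, 0.99)) # exactly 0.5
sigmoid_rate <- function(h, spec) {
  if (!is_sigmoid_spec(spec)) stop("`spec` must be a sigmoid_spec", call. = FALSE)
  if (!is.numeric(h) || length(h) == 0L || any(!is.finite(h))) {
    stop("`h` must be finite numeric", call. = FALSE)
  }
  z <- -2 * spec$slope * (h - spec$threshold)
  1 / (1 + exp(pmin(pmax(z, -EXP_CLAMP), EXP_CLAMP)))
}
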