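# Quantitative analyses of tuning curves: linearity (R-squared of a linear
# fit), population histograms, multiplicative-modulation testing and
# response-profile classification.

curve_parts <- function(curve, abscissa = NULL) {
  if (inherits(curve, "response_curve")) {
    list(x = curve$abscissa, v = curve$rates)
  } else if (is.numeric(curve) && !is.null(abscissa)) {
    list(x = as.numeric(abscissa), v = as.numeric(curve))
  } else {
    stop("supply a response_curve, or rates plus `abscissa`", call. = FALSE)
  }
}

#' Linearity of a tuning curve
#'
#' Fits an ordinary least-squares line (with intercept) of firing rate against
#' the swept variable and reports the coefficient of determination
#' \eqn{R^2 = 1 - SSE/SST}, a standard measure of how linear an eye-position
#' modulation profile is. \eqn{R^2 = 1} means a perfectly linear response;
#' \eqn{R^2 = 0} means none of the response is captured by a line (e.g. a
#' profile symmetric about the sweep midpoint, whose best-fit slope is zero).
#'
#' Degenerate curves (total sum of squares below `1e-12`, i.e. essentially
#' constant) are flagged and assigned \eqn{R^2 = 0} by convention rather than
#' an undefined value.
#'
#' An activity gate marks curves with too little response to interpret:
#' `active` is `TRUE` iff the maximum rate is at least `activity_min` and the
#' rate range (max - min) is at least `range_min`.
#'
#' @param curve A [response_curve()], or a numeric rate vector with `abscissa`
#'   supplied.
#' @param abscissa Abscissa values when `curve` is a bare numeric vector.
#' @param activity_min Minimum peak rate for the activity gate (default 0.1).
#' @param range_min Minimum rate range for the activity gate (default 0.05).
#'
#' @return An object of class `"linearity_result"`: list with `r_squared`,
#'   `slope`, `intercept`, `active`, `degenerate`, `n`.
#' @export
#' @examples
#' grid <- build_population()
#' res <- linearity_r2(eye_sweep(hardwired_neuron(-10, -34), grid))
#' round(res$r_squared, 2)
linearity_r2 <- function(curve, abscissa = NULL,
                         activity_min = 0.1, range_min = 0.05) {
  p <- curve_parts(curve, abscissa)
  if (length(p$v) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(p$x)) || any(!is.finite(p$v))) {
    stop("curve contains non-finite values", call. = FALSE)
  }
  active <- max(p$v) >= activity_min && (max(p$v) - min(p$v)) >= range_min
  sst <- sum((p$v - mean(p$v))^2)
  if (sst < 1e-12) {
    res <- list(r_squared = 0, slope = 0, intercept = mean(p$v),
                active = active, degenerate = TRUE, n = length(p$v))
  } else {
    fit <- stats::lm(v ~ x, data = data.frame(x = p$x, v = p$v))
    sse <- sum(stats::residuals(fit)^2)
    r2 <- 1 - sse / sst
    res <- list(r_squared = min(max(r2, 0), 1),
                slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                active = active, degenerate = FALSE, n = length(p$v))
  }
  structure(res, class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("<linearity_result> R^2 = %.4f%s (slope %.4g, intercept %.4g, n = %d)%s\n",
              x$r_squared, if (x$degenerate) " [degenerate]" else "",
              x$slope, x$intercept, x$n,
              if (x$active) "" else " [inactive]"))
  invisible(x)
}

#' Eye-sweep linearity of every neuron in a hardwired population
#'
#' For each neuron, sweeps the eye over `eye_positions` with the stimulus at
#' the neuron's preferred retinal location and computes [linearity_r2()].
#' Vectorized over the population (all curves are evaluated as one matrix and
#' the least-squares fit is done in closed form; equivalence with
#' [linearity_r2()] is exact to numerical precision).
#'
#' @param grid A [build_population()] grid.
#' @param eye_positions Eye positions of the sweep (default: full grid range
#'   in grid steps).
#' @param activity_min,range_min Activity gate, as in [linearity_r2()].
#'
#' @return Data frame with columns `alpha`, `beta`, `r_squared`, `slope`,
#'   `intercept`, `active`, `degenerate`.
#' @export
population_linearity <- function(grid, eye_positions = NULL,
                                 activity_min = 0.1, range_min = 0.05) {
  if (is.null(eye_positions)) {
    eye_positions <- seq(grid$eye_range[1], grid$eye_range[2], by = grid$step)
  }
  y <- as.numeric(eye_positions)
  n <- nrow(grid$neurons)
  # stimulus at alpha => retinal component contributes its peak for all neurons
  he <- outer(y, grid$neurons$beta, function(yy, bb) {
    grid$eye_peak * exp(-(yy - bb)^2 / (2 * grid$eye_width^2))
  })
  V <- sigmoid_rate(grid$retinal_peak + he, grid$sigmoid)  # |y| x n

  m <- length(y)
  ybar <- mean(y)
  yc <- y - ybar
  syy <- sum(yc^2)
  vbar <- colMeans(V)
  sxy <- drop(crossprod(yc, V))            # per-neuron covariance numerator
  sst <- colSums(V^2) - m * vbar^2
  slope <- sxy / syy
  ssr <- slope * sxy
  r2 <- ifelse(sst < 1e-12, 0, pmin(pmax(ssr / sst, 0), 1))
  vmax <- apply(V, 2, max)
  vmin <- apply(V, 2, min)

  data.frame(
    alpha = grid$neurons$alpha,
    beta = grid$neurons$beta,
    r_squared = r2,
    slope = ifelse(sst < 1e-12, 0, slope),
    intercept = ifelse(sst < 1e-12, vbar, vbar - slope * ybar),
    active = vmax >= activity_min & (vmax - vmin) >= range_min,
    degenerate = sst < 1e-12
  )
}

#' Histogram of R-squared values across a population
#'
#' Bins R-squared values into equal-width bins over `[0, 1]` (default width
#' 0.2) and reports the percentage of the population per bin. Bins are
#' half-open `[lo, hi)` except the last, which is closed so that a value of
#' exactly 1 is counted once.
#'
#' @param values Numeric vector of R-squared values in `[0, 1]`.
#' @param bin_width Bin width (must divide 1 evenly; default 0.2).
#'
#' @return An object of class `"r2_histogram"`: list with `bin_edges`,
#'   `proportions` (percentages summing to 100) and `n`.
#' @export
#' @examples
#' r2_histogram(c(0.1, 0.3, 0.5, 0.9))$proportions
r2_histogram <- function(values, bin_width = 0.2) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("`values` must lie in [0, 1]", call. = FALSE)
  }
  nb <- round(1 / bin_width)
  if (abs(nb * bin_width - 1) > 1e-9 || nb < 1) {
    stop("`bin_width` must divide 1 evenly", call. = FALSE)
  }
  edges <- seq(0, 1, length.out = nb + 1L)
  idx <- pmin(findInterval(values, edges), nb)  # top edge closed
  counts <- tabulate(idx, nbins = nb)
  structure(list(bin_edges = edges,
                 proportions = 100 * counts / length(values),
                 n = length(values)),
            class = "r2_histogram")
}

#' @export
print.r2_histogram <- function(x, ...) {
  nb <- length(x$proportions)
  lab <- sprintf("[%.1f,%.1f%s", x$bin_edges[-(nb + 1)], x$bin_edges[-1],
                 c(rep(")", nb - 1), "]"))
  cat(sprintf("<r2_histogram> n = %d\n", x$n))
  print(stats::setNames(round(x$proportions, 2), lab))
  invisible(x)
}

#' @export
as.data.frame.r2_histogram <- function(x, ...) {
  nb <- length(x$proportions)
  data.frame(bin_lo = x$bin_edges[-(nb + 1)], bin_hi = x$bin_edges[-1],
             percent = x$proportions)
}

#' Test for multiplicative gain modulation
#'
#' A family of retinal tuning curves recorded at different fixations is
#' multiplicatively gain modulated when every curve is a scalar multiple of
#' the straight-ahead (reference) curve. For each non-reference fixation the
#' best scale constant is the least-squares solution
#' \eqn{c_e = \langle r_0, r_e\rangle / \langle r_0, r_0\rangle}; the family
#' passes when the worst relative residual
#' \eqn{\max_e \lVert c_e r_0 - r_e\rVert / \lVert r_e\rVert} does not exceed
#' `tolerance`.
#'
#' @param family A [fixation_family()].
#' @param tolerance Maximum relative residual to pass (default 0.05).
#'
#' @return An object of class `"multiplicativity_result"`: list with
#'   `fixations` (non-reference), `scale_constants`, `relative_residuals`,
#'   `max_relative_residual`, `passes`, `tolerance`.
#' @export
multiplicativity_test <- function(family, tolerance = 0.05) {
  if (!inherits(family, "fixation_family")) {
    stop("`family` must be a fixation_family", call. = FALSE)
  }
  ref_i <- which(abs(family$fixations - family$reference_fixation) < 1e-9)[1]
  r0 <- family$curves[[ref_i]]$rates
  if (sum(r0^2) < 1e-24) stop("reference curve has zero norm", call. = FALSE)
  others <- setdiff(seq_along(family$fixations), ref_i)
  consts <- numeric(length(others))
  resid <- numeric(length(others))
  for (k in seq_along(others)) {
    re <- family$curves[[others[k]]]$rates
    ce <- sum(r0 * re) / sum(r0^2)
    consts[k] <- ce
    resid[k] <- sqrt(sum((ce * r0 - re)^2)) / sqrt(sum(re^2))
  }
  mx <- if (length(resid)) max(resid) else 0
  structure(
    list(fixations = family$fixations[others],
         scale_constants = consts,
         relative_residuals = resid,
         max_relative_residual = mx,
         passes = mx <= tolerance,
         tolerance = tolerance),
    class = "multiplicativity_result"
  )
}

#' @export
print.multiplicativity_result <- function(x, ...) {
  cat(sprintf("<multiplicativity_result> max relative residual %.4f (tolerance %.3f): %s\n",
              x$max_relative_residual, x$tolerance,
              if (x$passes) "PASS" else "FAIL"))
  df <- data.frame(fixation_deg = x$fixations,
                   scale_constant = round(x$scale_constants, 4),
                   relative_residual = round(x$relative_residuals, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Classify a tuning-curve profile
#'
#' Coarse classification of an eye-position tuning curve into `"unresponsive"`
#' (fails the activity gate), `"monotonic"` (rate rises or falls across the
#' sweep, peaking at or near a boundary) or `"peaked"` (an interior maximum
#' with the rate falling off on both sides). The thresholds are heuristics,
#' all configurable.
#'
#' @inheritParams linearity_r2
#' @param edge_window Grid steps from a boundary within which the argmax
#'   counts as "at the edge" (default 2).
#' @param interior_min_deg Minimum distance (degrees) of the argmax from both
#'   boundaries for a peak to count as interior (default 5).
#' @param drop_frac Fraction of the rate range by which the curve must fall on
#'   both sides of an interior peak (default 0.2).
#' @param tv_slack Allowed ratio of total variation to rate range for a
#'   monotonic call (default 1.1; a strictly monotone curve has ratio 1).
#'
#' @return One of `"monotonic"`, `"peaked"`, `"unresponsive"`.
#' @export
classify_profile <- function(curve, abscissa = NULL,
                             activity_min = 0.1, range_min = 0.05,
                             edge_window = 2, interior_min_deg = 5,
                             drop_frac = 0.2, tv_slack = 1.1) {
  p <- curve_parts(curve, abscissa)
  if (length(p$v) < 3L) stop("need at least 3 points", call. = FALSE)
  vmax <- max(p$v); vmin <- min(p$v); rng <- vmax - vmin
  if (!(vmax >= activity_min && rng >= range_min)) return("unresponsive")

  i <- which.max(p$v)
  n <- length(p$v)
  tv <- sum(abs(diff(p$v)))
  near_edge <- i <= 1L + edge_window || i >= n - edge_window
  if (near_edge && tv <= tv_slack * rng) return("monotonic")

  dist_lo <- p$x[i] - p$x[1]
  dist_hi <- p$x[n] - p$x[i]
  if (dist_lo >= interior_min_deg && dist_hi >= interior_min_deg) {
    drop_left <- p$v[i] - min(p$v[1:i])
    drop_right <- p$v[i] - min(p$v[i:n])
    if (drop_left >= drop_frac * rng && drop_right >= drop_frac * rng) {
      return("peaked")
    }
  }
  "monotonic"
}

#' Read tuning curves from a tidy CSV
#'
#' Accepts user-supplied tuning-curve tables with columns `unit_id`,
#' `abscissa_deg`, `rate` (one row per sampled point) and returns a named list
#' of [response_curve()] objects.
#'
#' @param path Path to a CSV file.
#' @return Named list of [response_curve()]s, one per unit.
#' @export
read_tuning_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "abscissa_deg", "rate")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns unit_id, abscissa_deg, rate", call. = FALSE)
  }
  split_df <- split(df, df$unit_id)
  lapply(split_df, function(d) {
    d <- d[order(d$abscissa_deg), ]
    response_curve(d$abscissa_deg, d$rate, context = list(unit_id = d$unit_id[1]))
  })
}

#' Per-unit linearity and profile classification
#'
#' Applies [linearity_r2()] and [classify_profile()] to a collection of
#' tuning curves (from internal simulations or [read_tuning_curves()]).
#'
#' @param curves Named list of [response_curve()]s.
#' @param activity_min,range_min Activity gate, as in [linearity_r2()].
#' @return Data frame with columns `unit_id`, `r_squared`, `slope`,
#'   `intercept`, `active`, `profile`.
#' @export
analyze_tuning_curves <- function(curves, activity_min = 0.1, range_min = 0.05) {
  if (length(curves) == 0L) stop("`curves` must be non-empty", call. = FALSE)
  ids <- names(curves)
  if (is.null(ids)) ids <- as.character(seq_along(curves))
  rows <- lapply(seq_along(curves), function(i) {
    lr <- linearity_r2(curves[[i]], activity_min = activity_min,
                       range_min = range_min)
    data.frame(unit_id = ids[i], r_squared = lr$r_squared, slope = lr$slope,
               intercept = lr$intercept, active = lr$active,
               profile = classify_profile(curves[[i]], activity_min = activity_min,
                                          range_min = range_min))
  })
  do.call(rbind, rows)
}
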