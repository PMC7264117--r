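# Training-schedule generation and the training driver.

#' Generate a randomized fixation/saccade training schedule
#'
#' One schedule consists of `epochs` epochs; each epoch contains one period
#' per retinal stimulus location (the stimulus is clamped to that retinal
#' location for the whole period). Within a period the eye makes
#' `fixations_per_period` fixations at uniform random integer eye positions,
#' joined by constant-velocity saccades (so under the defaults each period has
#' 15 fixations and 14 counted saccades). The first fixation of a period is
#' reached from the previous period's final eye position by an un-counted
#' transition saccade, keeping the 15/14 accounting intact.
#'
#' Two timing modes are provided because fixation-based timing (15 x 300 ms
#' plus saccade time, about 5.3 s per period) and nominal presentation timing
#' (2 s per retinal location) are both natural readings of the protocol:
#' `"fixation_defined"` (default) uses `fixation_duration` per fixation;
#' `"nominal_2s"` rescales fixation durations so each period lasts exactly
#' `presentation_s` including saccade time.
#'
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @param epochs Number of epochs (default 10).
#' @param retinal_locations Retinal stimulus locations, degrees (default
#'   integer steps over \eqn{[-10, 10]}).
#' @param fixations_per_period Fixations per period (default 15).
#' @param fixation_duration Duration of one fixation, seconds (default 0.3).
#' @param saccade_speed Constant saccade velocity, degrees/second (default
#'   400).
#' @param eye_range Range of fixation targets, degrees (default
#'   \eqn{[-35, 35]}); targets are integers in this range.
#' @param schedule_mode `"fixation_defined"` or `"nominal_2s"`.
#' @param presentation_s Nominal presentation time per retinal location,
#'   seconds, used by `"nominal_2s"` (default 2).
#' @param shuffle_periods Shuffle the order of retinal locations within each
#'   epoch (default `FALSE`: sequential order).
#' @param initial_eye Eye position before the first period, degrees.
#'
#' @return An object of class `"training_schedule"`: a list with `events`
#'   (data frame: `epoch`, `period`, `retinal_x`, `kind`, `counted`,
#'   `t_start`, `t_end`, `eye_start`, `eye_end`) and the configuration.
#' @export
#' @examples
#' sched <- make_schedule(1, epochs = 1)
#' table(sched$events$kind[sched$events$counted])
make_schedule <- function(seed,
                          epochs = 10,
                          retinal_locations = seq(-10, 10, by = 1),
                          fixations_per_period = 15,
                          fixation_duration = 0.3,
                          saccade_speed = 400,
                          eye_range = c(-35, 35),
                          schedule_mode = c("fixation_defined", "nominal_2s"),
                          presentation_s = 2,
                          shuffle_periods = FALSE,
                          initial_eye = 0) {
  schedule_mode <- match.arg(schedule_mode)
  if (fixations_per_period < 1) stop("`fixations_per_period` must be >= 1", call. = FALSE)
  if (epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (saccade_speed <= 0) stop("`saccade_speed` must be positive", call. = FALSE)
  if (fixation_duration <= 0) stop("`fixation_duration` must be positive", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  targets_pool <- seq(ceiling(eye_range[1]), floor(eye_range[2]), by = 1)
  nfix <- as.integer(fixations_per_period)

  # column accumulators (one slot per event) assembled into a single data
  # frame at the end
  acc <- list(epoch = integer(0), period = integer(0), retinal_x = numeric(0),
              kind = character(0), counted = logical(0),
              duration = numeric(0), eye_start = numeric(0),
              eye_end = numeric(0))
  push <- function(ep, pd, rx, kind, counted, duration, eye_start, eye_end) {
    n <- length(kind)
    acc$epoch <<- c(acc$epoch, rep(ep, n))
    acc$period <<- c(acc$period, rep(pd, n))
    acc$retinal_x <<- c(acc$retinal_x, rep(rx, n))
    acc$kind <<- c(acc$kind, kind)
    acc$counted <<- c(acc$counted, counted)
    acc$duration <<- c(acc$duration, duration)
    acc$eye_start <<- c(acc$eye_start, eye_start)
    acc$eye_end <<- c(acc$eye_end, eye_end)
  }

  prev_eye <- initial_eye
  period_counter <- 0L
  for (ep in seq_len(epochs)) {
    locs <- if (shuffle_periods) sample(retinal_locations) else retinal_locations
    for (rx in locs) {
      period_counter <- period_counter + 1L
      targets <- sample(targets_pool, nfix, replace = TRUE)

      sacc_durations <- abs(diff(targets)) / saccade_speed
      fix_dur <- fixation_duration
      if (schedule_mode == "nominal_2s") {
        fix_dur <- (presentation_s - sum(sacc_durations)) / nfix
        if (fix_dur <= 0) {
          stop("nominal_2s mode: saccade time exceeds the presentation time",
               call. = FALSE)
        }
      }

      # un-counted transition saccade into the period's first fixation target
      trans_dur <- abs(targets[1] - prev_eye) / saccade_speed
      if (trans_dur > 0) {
        push(ep, period_counter, rx, "saccade", FALSE, trans_dur,
             prev_eye, targets[1])
      }

      # interleaved fixation/saccade sequence: f1 s1 f2 s2 ... f_nfix
      n_ev <- 2L * nfix - 1L
      kind <- rep(c("fixation", "saccade"), length.out = n_ev)
      dur <- numeric(n_ev)
      dur[kind == "fixation"] <- fix_dur
      dur[kind == "saccade"] <- sacc_durations
      eye_start <- numeric(n_ev)
      eye_end <- numeric(n_ev)
      eye_start[kind == "fixation"] <- targets
      eye_end[kind == "fixation"] <- targets
      eye_start[kind == "saccade"] <- targets[-nfix]
      eye_end[kind == "saccade"] <- targets[-1]
      push(ep, period_counter, rx, kind, rep(TRUE, n_ev), dur,
           eye_start, eye_end)
      prev_eye <- targets[nfix]
    }
  }

  t_end <- cumsum(acc$duration)
  events <- data.frame(epoch = acc$epoch, period = acc$period,
                       retinal_x = acc$retinal_x, kind = acc$kind,
                       counted = acc$counted,
                       t_start = t_end - acc$duration, t_end = t_end,
                       eye_start = acc$eye_start, eye_end = acc$eye_end)

  structure(
    list(events = events,
         config = list(seed = as.integer(seed), epochs = epochs,
                       retinal_locations = retinal_locations,
                       fixations_per_period = nfix,
                       fixation_duration = fixation_duration,
                       saccade_speed = saccade_speed, eye_range = eye_range,
                       schedule_mode = schedule_mode,
                       presentation_s = presentation_s,
                       shuffle_periods = shuffle_periods,
                       initial_eye = initial_eye)),
    class = "training_schedule"
  )
}

#' @export
print.training_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<training_schedule> %d epochs x %d periods; %d events; %.1f s total (mode %s, seed %d)\n",
              x$config$epochs, length(x$config$retinal_locations),
              nrow(ev), max(ev$t_end), x$config$schedule_mode, x$config$seed))
  invisible(x)
}

#' @export
as.data.frame.training_schedule <- function(x, ...) x$events

#' Nominal training duration
#'
#' The protocol's nominal arithmetic: number of retinal locations times the
#' nominal presentation seconds per location times the number of epochs
#' (21 x 2 s x 10 = 420 s under the defaults). This is the stated duration of
#' training regardless of the schedule's actual timing mode.
#'
#' @param n_locations Number of retinal stimulus locations (default 21).
#' @param presentation_s Nominal seconds per location (default 2).
#' @param epochs Number of epochs (default 10).
#' @return Duration in seconds.
#' @export
nominal_training_duration <- function(n_locations = 21, presentation_s = 2,
                                      epochs = 10) {
  n_locations * presentation_s * epochs
}

#' Discretize a schedule into integration steps
#'
#' Expands schedule events into one row per Forward-Euler step of size `dt`:
#' the retinal stimulus location `x` (clamped for the whole period), the eye
#' position `y` (linearly interpolated during saccades, with the endpoint
#' exact), the period index and whether the step belongs to a fixation.
#' Saccade durations are rounded up to whole steps; fixation durations to the
#' nearest step.
#'
#' @param schedule A [make_schedule()] schedule.
#' @param dt Step size, seconds.
#' @return Data frame with columns `x`, `y`, `period`, `fixating`.
#' @export
schedule_trajectory <- function(schedule, dt) {
  stopifnot(inherits(schedule, "training_schedule"))
  ev <- schedule$events
  dur <- ev$t_end - ev$t_start
  is_fix <- ev$kind == "fixation"
  n_steps <- ifelse(is_fix,
                    pmax(1L, as.integer(round(dur / dt))),
                    as.integer(ceiling(dur / dt - 1e-9)))
  ys <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    n <- n_steps[i]
    if (n == 0L) next
    ys[[i]] <- if (is_fix[i]) rep(ev$eye_start[i], n)
               else ev$eye_start[i] + (ev$eye_end[i] - ev$eye_start[i]) * seq_len(n) / n
  }
  data.frame(x = rep(ev$retinal_x, n_steps),
             y = unlist(ys, use.names = FALSE),
             period = rep(ev$period, n_steps),
             fixating = rep(is_fix, n_steps))
}

#' Train a self-organizing network on a schedule
#'
#' Drives the network through the schedule at `net$dt` resolution. At every
#' step the input rates are evaluated for the current stimulus/eye condition,
#' the output activations take one Forward-Euler step, competitive rates are
#' computed, and (when learning is enabled for that step) the Hebbian update
#' plus renormalization is applied. By default learning is active during
#' saccades as well as fixations; set `learn_during_saccades = FALSE` to
#' restrict learning to fixation steps.
#'
#' Two interchangeable engines are provided: `"compiled"` (the fast path) and
#' `"reference"` (a plain-R loop over the exported single-step functions, kept
#' as an executable specification and cross-checked in the test suite).
#'
#' @param net A [init_network()] network.
#' @param layer The [input_layer()] driving the network.
#' @param schedule A [make_schedule()] schedule.
#' @param learn_during_saccades Apply the Hebbian update during saccade steps
#'   (default `TRUE`).
#' @param engine `"compiled"` or `"reference"`.
#'
#' @return A list with `network` (the trained network) and `log` (data frame,
#'   one row per period: `epoch`, `period`, `retinal_x`, `mean_sparseness` —
#'   the mean fraction of outputs firing above 0.5 across the period's steps —
#'   and `mean_abs_dw`, the mean absolute net weight change over the period,
#'   averaged over existing synapses).
#' @export
run_training <- function(net, layer, schedule, learn_during_saccades = TRUE,
                         engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(net, "gain_network"), inherits(layer, "input_layer"),
            inherits(schedule, "training_schedule"))
  if (layer$n_units != net$n_inputs) {
    stop("network and input layer sizes disagree", call. = FALSE)
  }
  traj <- schedule_trajectory(schedule, net$dt)
  learn <- if (learn_during_saccades) rep(TRUE, nrow(traj)) else traj$fixating
  if (net$learning_rate == 0) learn <- rep(FALSE, nrow(traj))

  if (engine == "compiled") {
    res <- cpp_train_loop(
      net$weights, net$mask * 1.0, net$h,
      layer$eye_pref, layer$ret_pref,
      layer$eye_peak, layer$eye_width, layer$retinal_peak, layer$retinal_width,
      layer$sigmoid$slope, layer$sigmoid$threshold,
      net$sigmoid$slope, net$sigmoid$threshold, net$sparseness,
      net$tau, net$dt, net$learning_rate,
      traj$x, traj$y, as.integer(traj$period), as.integer(learn))
    net$weights <- res$weights
    net$h <- drop(res$h)
    sparseness <- drop(res$sparseness)
    mean_abs_dw <- drop(res$mean_abs_dw)
  } else {
    n_periods <- max(traj$period)
    sp_sum <- numeric(n_periods); mean_abs_dw <- numeric(n_periods)
    n_steps <- integer(n_periods)
    w_period <- net$weights
    current <- traj$period[1]
    for (s in seq_len(nrow(traj))) {
      pd <- traj$period[s]
      if (pd != current) {
        mean_abs_dw[current] <- mean(abs(net$weights - w_period)[net$mask])
        w_period <- net$weights
        current <- pd
      }
      v_in <- input_rates(layer, traj$x[s], traj$y[s])
      net <- step_dynamics(net, v_in)
      v_out <- competitive_rates(net)
      sp_sum[pd] <- sp_sum[pd] + mean(v_out > 0.5)
      if (learn[s]) net <- hebbian_update(net, v_in, v_out)
      n_steps[pd] <- n_steps[pd] + 1L
    }
    mean_abs_dw[current] <- mean(abs(net$weights - w_period)[net$mask])
    sparseness <- sp_sum / n_steps
  }

  per <- unique(schedule$events[, c("epoch", "period", "retinal_x")])
  per <- per[order(per$period), ]
  log <- data.frame(epoch = per$epoch, period = per$period,
                    retinal_x = per$retinal_x,
                    mean_sparseness = sparseness,
                    mean_abs_dw = mean_abs_dw)
  rownames(log) <- NULL
  list(network = net, log = log)
}

#' Save a network checkpoint
#'
#' Writes a checkpoint as two flat text files under `path`: `network.json`
#' (all scalar parameters, the seed, and the afferent index lists) and
#' `weights.csv` (one row per existing synapse: `output`, `input`, `weight`).
#'
#' @param net A [init_network()] network.
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  header <- list(
    n_outputs = net$n_outputs, n_inputs = net$n_inputs,
    n_afferents = net$n_afferents, connectivity = net$connectivity,
    tau = net$tau, dt = net$dt, learning_rate = net$learning_rate,
    sparseness = net$sparseness,
    sigmoid = list(slope = net$sigmoid$slope, threshold = net$sigmoid$threshold),
    seed = net$seed, h = net$h,
    afferents = apply(net$mask, 1, which, simplify = FALSE)
  )
  jsonlite::write_json(header, file.path(path, "network.json"),
                       auto_unbox = TRUE, digits = NA)
  idx <- which(net$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.csv(
    data.frame(output = idx[, 1], input = idx[, 2],
               weight = net$weights[idx]),
    file.path(path, "weights.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Directory written by [save_network()].
#' @return A `"gain_network"` object.
#' @export
load_network <- function(path) {
  header <- jsonlite::read_json(file.path(path, "network.json"),
                                simplifyVector = TRUE)
  wtab <- utils::read.csv(file.path(path, "weights.csv"))
  mask <- matrix(FALSE, header$n_outputs, header$n_inputs)
  weights <- matrix(0, header$n_outputs, header$n_inputs)
  mask[cbind(wtab$output, wtab$input)] <- TRUE
  weights[cbind(wtab$output, wtab$input)] <- wtab$weight
  structure(
    list(weights = weights, mask = mask, h = as.numeric(header$h),
         tau = header$tau, dt = header$dt,
         learning_rate = header$learning_rate,
         sparseness = header$sparseness,
         connectivity = header$connectivity,
         sigmoid = sigmoid_spec(header$sigmoid$slope, header$sigmoid$threshold),
         n_outputs = as.integer(header$n_outputs),
         n_inputs = as.integer(header$n_inputs),
         n_afferents = as.integer(header$n_afferents),
         seed = as.integer(header$seed)),
    class = "gain_network"
  )
}
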