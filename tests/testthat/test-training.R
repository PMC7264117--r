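test_that("schedules have the documented event accounting", {
  sched <- make_schedule(1)
  ev <- sched$events
  counted <- ev[ev$counted, ]

  expect_equal(max(ev$period), 10 * 21)
  expect_equal(sum(counted$kind == "fixation"), 10 * 21 * 15)
  expect_equal(sum(counted$kind == "saccade"), 10 * 21 * 14)

  # per period: exactly 15 fixations totalling 15 x 300 ms, saccade time
  # = sum |delta eye| / speed
  for (pd in c(1, 57, 210)) {
    pe <- counted[counted$period == pd, ]
    fix <- pe[pe$kind == "fixation", ]
    sac <- pe[pe$kind == "saccade", ]
    expect_equal(nrow(fix), 15)
    expect_equal(sum(fix$t_end - fix$t_start), 15 * 0.3, tolerance = 1e-9)
    expect_equal(sum(sac$t_end - sac$t_start),
                 sum(abs(sac$eye_end - sac$eye_start)) / 400, tolerance = 1e-9)
    # events alternate and are contiguous in time
    expect_true(all(diff(match(pe$kind, c("fixation", "saccade"))) != 0))
    expect_equal(pe$t_start[-1], pe$t_end[-nrow(pe)], tolerance = 1e-9)
  }

  # fixation targets are integers inside the eye range
  expect_true(all(ev$eye_end == round(ev$eye_end)))
  expect_true(all(ev$eye_end >= -35 & ev$eye_end <= 35))

  # a 40 degree saccade at 400 deg/s lasts 100 ms
  d <- abs(ev$eye_end - ev$eye_start)[ev$kind == "saccade"]
  t <- (ev$t_end - ev$t_start)[ev$kind == "saccade"]
  expect_equal(t, d / 400, tolerance = 1e-12)

  expect_identical(make_schedule(1), sched)
  expect_false(identical(make_schedule(2)$events$eye_end, ev$eye_end))
})

test_that("every retinal location is visited once per epoch", {
  sched <- make_schedule(4, epochs = 3)
  per <- unique(sched$events[, c("epoch", "period", "retinal_x")])
  visits <- table(per$retinal_x)
  expect_true(all(visits == 3))
  expect_equal(length(visits), 21)

  shuf <- make_schedule(4, epochs = 3, shuffle_periods = TRUE)
  pers <- unique(shuf$events[, c("epoch", "period", "retinal_x")])
  expect_true(all(table(pers$retinal_x) == 3))
})

test_that("the nominal-presentation mode makes each period last 2 seconds", {
  sched <- make_schedule(5, epochs = 1, schedule_mode = "nominal_2s")
  counted <- sched$events[sched$events$counted, ]
  for (pd in unique(counted$period)) {
    pe <- counted[counted$period == pd, ]
    expect_equal(sum(pe$t_end - pe$t_start), 2, tolerance = 1e-9)
  }
})

test_that("nominal training duration follows the protocol arithmetic", {
  expect_equal(nominal_training_duration(), 420)
  expect_equal(nominal_training_duration(1, 1, 1), 1)
  expect_equal(nominal_training_duration(21, 2, 1), 42)
})

test_that("trajectories discretize events with exact saccade endpoints", {
  sched <- tiny_schedule()
  traj <- schedule_trajectory(sched, dt = 0.01)
  expect_named(traj, c("x", "y", "period", "fixating"))
  # each fixation contributes round(0.3 / 0.01) = 30 steps
  expect_equal(sum(traj$fixating),
               sum(sched$events$kind == "fixation") * 30)
  # saccade endpoints are hit exactly
  ev <- sched$events
  for (i in which(ev$kind == "saccade")) {
    expect_true(any(abs(traj$y - ev$eye_end[i]) < 1e-12))
  }
  # periods are contiguous and non-decreasing
  expect_true(all(diff(traj$period) %in% c(0L, 1L)))
})

test_that("training with zero learning rate leaves the weights untouched", {
  layer <- std_layer()
  net <- init_network(2, layer, learning_rate = 0)
  fit <- run_training(net, layer, tiny_schedule())
  expect_identical(fit$network$weights, net$weights)
  expect_equal(fit$log$mean_abs_dw, rep(0, 3))
})

test_that("compiled and reference training engines agree", {
  layer <- std_layer()
  net <- init_network(6, layer)
  sched <- tiny_schedule(seed = 7, locations = c(-10, 5), nfix = 3)

  fast <- run_training(net, layer, sched, engine = "compiled")
  slow <- run_training(net, layer, sched, engine = "reference")
  expect_equal(fast$network$weights, slow$network$weights, tolerance = 1e-12)
  expect_equal(fast$network$h, slow$network$h, tolerance = 1e-12)
  expect_equal(fast$log$mean_sparseness, slow$log$mean_sparseness,
               tolerance = 1e-12)
  expect_equal(fast$log$mean_abs_dw, slow$log$mean_abs_dw, tolerance = 1e-12)

  # saccade-gated learning is also equivalent across engines
  fg <- run_training(net, layer, sched, learn_during_saccades = FALSE)
  sg <- run_training(net, layer, sched, learn_during_saccades = FALSE,
                     engine = "reference")
  expect_equal(fg$network$weights, sg$network$weights, tolerance = 1e-12)
  expect_false(identical(fg$network$weights, fast$network$weights))
})

test_that("training is deterministic and keeps rows unit-norm", {
  layer <- std_layer()
  sched <- tiny_schedule(seed = 8)
  a <- run_training(init_network(9, layer), layer, sched)
  b <- run_training(init_network(9, layer), layer, sched)
  expect_identical(a$network$weights, b$network$weights)
  expect_equal(sqrt(rowSums(a$network$weights^2)), rep(1, 100),
               tolerance = 1e-12)
  expect_true(all(a$network$weights >= 0))
})

test_that("per-epoch weight change settles as self-organization proceeds", {
  layer <- std_layer()
  # 3-seed median of the per-epoch mean weight-change magnitude
  per_epoch <- sapply(1:3, function(s) {
    fit <- run_training(init_network(100 + s, layer), layer,
                        make_schedule(200 + s))
    agg <- stats::aggregate(mean_abs_dw ~ epoch, fit$log, mean)
    agg$mean_abs_dw
  })
  med <- apply(per_epoch, 1, stats::median)
  expect_equal(which.max(med), 1L)          # the first epoch moves most
  expect_lt(med[length(med)], 0.5 * med[1]) # and the trend settles
  expect_lt(stats::cor(seq_along(med), med, method = "kendall"), 0)
})

test_that("network checkpoints round-trip through the flat text format", {
  layer <- std_layer()
  net <- init_network(10, layer)
  fit <- run_training(net, layer, tiny_schedule())
  dir <- withr::local_tempdir()
  save_network(fit$network, dir)
  expect_true(file.exists(file.path(dir, "network.json")))
  expect_true(file.exists(file.path(dir, "weights.csv")))
  back <- load_network(dir)
  expect_equal(back$weights, fit$network$weights, tolerance = 1e-12)
  expect_identical(back$mask, fit$network$mask)
  expect_equal(back$h, fit$network$h, tolerance = 1e-12)
  expect_equal(back$sparseness, fit$network$sparseness)
  expect_equal(back$seed, fit$network$seed)
})
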