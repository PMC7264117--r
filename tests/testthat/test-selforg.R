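test_that("input layer mixes 71 eye-position and 21 retinal units", {
  layer <- std_layer()
  expect_equal(layer$n_eye, 71)
  expect_equal(layer$n_retinal, 21)
  expect_equal(layer$n_units, 92)

  v <- input_rates(layer, x = 0, y = -7)
  expect_length(v, 92)
  expect_true(all(v > 0 & v < 1))

  # a unit probed at its own preferred value fires at sigmoid(peak) = ~1
  j <- which(layer$eye_pref == -7)
  expect_equal(v[j], 1 / (1 + exp(-2 * 4.5 * 2.0)), tolerance = 1e-15)
  expect_equal(v[j], 1, tolerance = 2e-8)
  jr <- layer$n_eye + which(layer$ret_pref == 0)
  expect_equal(v[jr], 1, tolerance = 2e-8)

  expect_error(input_rates(layer, NA, 0), "finite")
})

test_that("network initialization is seeded, masked and unit-norm", {
  layer <- std_layer()
  net <- init_network(7, layer)
  expect_equal(net$n_afferents, 9)             # floor(10% of 92)
  expect_true(all(rowSums(net$mask) == 9))
  expect_true(all(net$weights[!net$mask] == 0))
  expect_true(all(net$weights >= 0))
  expect_equal(sqrt(rowSums(net$weights^2)), rep(1, 100), tolerance = 1e-12)

  # reproducibility and seed sensitivity
  expect_identical(init_network(7, layer), net)
  expect_false(identical(init_network(8, layer)$mask, net$mask))

  # full connectivity
  full <- init_network(1, layer, n_outputs = 5, connectivity = 100)
  expect_true(all(full$mask))

  expect_error(init_network(1, layer, connectivity = 0.5), "afferent")
  expect_error(init_network(1, layer, connectivity = 0), "\\(0, 100\\]")
})

test_that("leaky-integrator dynamics relax to the drive", {
  layer <- std_layer()
  net <- init_network(3, layer, n_outputs = 4, connectivity = 100)

  # single Euler step with dt = tau lands exactly on W v
  net1 <- net; net1$dt <- net1$tau
  v_in <- input_rates(layer, 0, 0)
  expect_equal(step_dynamics(net1, v_in)$h, drop(net$weights %*% v_in),
               tolerance = 1e-14)

  # constant unit drive: one default step from rest gives dt/tau = 0.1
  net2 <- net
  net2$weights <- matrix(0, 4, 92); net2$weights[, 1] <- 1
  net2$mask <- net2$weights > 0
  v_unit <- c(1, rep(0, 91))
  net2 <- step_dynamics(net2, v_unit)
  expect_equal(net2$h, rep(0.1, 4))

  # after 10 time constants the state reaches the fixed point
  for (s in 1:100) net2 <- step_dynamics(net2, v_unit)
  expect_equal(net2$h, rep(1, 4), tolerance = 1e-4)

  expect_error(step_dynamics(net, c(1, 2)), "length")
})

test_that("percentile competition admits the expected fraction of winners", {
  expect_equal(nearest_rank_percentile(1:100, 90), 90)
  expect_equal(nearest_rank_percentile(1:100, 0), 1)
  expect_equal(nearest_rank_percentile(c(5, 1, 9), 50), 5)

  layer <- std_layer()
  net <- init_network(5, layer)

  # all activations equal: every neuron sits at the threshold, rate 0.5
  net$h <- rep(0.7, 100)
  expect_equal(competitive_rates(net), rep(0.5, 100))

  # h = 1..100 at the 90th percentile: exactly 10 neurons above half-maximum
  net$h <- as.numeric(1:100)
  expect_equal(sum(competitive_rates(net) > 0.5), 10)

  # percentile 0: threshold at the minimum, every rate >= 0.5
  net$sparseness <- 0
  expect_true(all(competitive_rates(net) >= 0.5))
})

test_that("Hebbian updates strengthen coactive synapses then renormalize", {
  layer <- std_layer()
  net <- init_network(9, layer, n_outputs = 2, connectivity = 100)
  net$dt <- 1; net$learning_rate <- 0.05     # dt * rate = 0.05 for hand case

  w <- matrix(0, 2, 92)
  w[1, 1] <- 0.6; w[1, 2] <- 0.8
  w[2, 3] <- 1
  net$weights <- w; net$mask <- matrix(TRUE, 2, 92)

  v_in <- c(1, rep(0, 91))
  v_out <- c(1, 0)
  upd <- hebbian_update(net, v_in, v_out)
  # hand arithmetic: (0.65, 0.8) / sqrt(1.0625)
  expect_equal(upd$weights[1, 1:2], c(0.63059, 0.77611), tolerance = 1e-5)
  # silent output neuron: row untouched
  expect_equal(upd$weights[2, ], w[2, ])
  expect_equal(sqrt(rowSums(upd$weights^2)), c(1, 1), tolerance = 1e-12)
})

test_that("weights stay non-negative and masked across random updates", {
  layer <- std_layer()
  net <- init_network(13, layer)
  set.seed(13)
  for (s in 1:30) {
    v_in <- input_rates(layer, sample(-10:10, 1), sample(-35:35, 1))
    net <- step_dynamics(net, v_in)
    net <- hebbian_update(net, v_in, competitive_rates(net))
    expect_true(all(net$weights >= 0))
    expect_true(all(net$weights[!net$mask] == 0))
    expect_equal(sqrt(rowSums(net$weights^2)), rep(1, 100), tolerance = 1e-12)
  }
})

test_that("steady-state output sweeps have the documented shape", {
  layer <- std_layer()
  net <- init_network(17, layer)
  curve <- output_eye_sweep(net, layer, unit = 1, stimulus_at = -10)
  expect_length(curve$rates, 71)
  expect_true(all(curve$rates > 0 & curve$rates < 1))

  fam <- output_retinal_family(net, layer, 1, fixations = c(-12, 0, 12))
  expect_length(fam$curves, 3)
  expect_equal(fam$curves[[1]]$abscissa, -10:10)

  lin <- trained_population_linearity(net, layer)
  expect_equal(nrow(lin), 100)
  expect_true(all(lin$profile %in% c("monotonic", "peaked", "unresponsive")))
  expect_true(all(is.na(lin$r_squared) | (lin$r_squared >= 0 & lin$r_squared <= 1)))
})
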