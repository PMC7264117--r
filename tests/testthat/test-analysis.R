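test_that("linearity R-squared recovers exact lines and flags degenerate curves", {
  x <- -35:35
  line <- 0.2 + 0.004 * x
  res <- linearity_r2(line, abscissa = x)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 0.004, tolerance = 1e-12)
  expect_equal(res$intercept, 0.2, tolerance = 1e-12)
  expect_false(res$degenerate)

  # constant curve: degenerate convention R^2 = 0
  res0 <- linearity_r2(rep(0.3, 71), abscissa = x)
  expect_identical(res0$r_squared, 0)
  expect_true(res0$degenerate)

  # symmetric curve about the midpoint: zero slope, R^2 = 0
  sym <- 0.1 + 0.5 * exp(-x^2 / 200)
  ress <- linearity_r2(sym, abscissa = x)
  expect_equal(ress$r_squared, 0, tolerance = 1e-12)
  expect_equal(ress$slope, 0, tolerance = 1e-12)

  expect_error(linearity_r2(c(0.1, 0.2), abscissa = c(1, 2)), "3 points")
})

test_that("linearity matches an independent normal-equations fit", {
  set.seed(31)
  for (rep in 1:25) {
    x <- sort(runif(sample(10:80, 1), -35, 35))
    v <- pmin(pmax(runif(1) + runif(1, -0.01, 0.01) * x +
                     rnorm(length(x), sd = 0.05), 0), 1)
    if (max(v) - min(v) < 1e-6) next
    got <- linearity_r2(v, abscissa = x)
    want <- normal_equations_r2(x, v)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  }
})

test_that("R-squared is invariant to affine rescaling of either axis", {
  set.seed(32)
  x <- -35:35
  v <- 0.3 + 0.005 * x + 0.2 * exp(-(x - 5)^2 / 150)
  base <- linearity_r2(v, abscissa = x)$r_squared
  expect_equal(linearity_r2(v, abscissa = 3 * x + 11)$r_squared, base,
               tolerance = 1e-10)
  expect_equal(linearity_r2(0.5 * v + 0.1, abscissa = x)$r_squared, base,
               tolerance = 1e-10)
})

test_that("the activity gate marks weak or flat curves inactive", {
  x <- -35:35
  weak <- rep(0.02, 71) + 0.03 * exp(-x^2 / 100)       # max < 0.1
  expect_false(linearity_r2(weak, abscissa = x)$active)
  flat <- rep(0.5, 71) + 0.01 * exp(-x^2 / 100)        # range < 0.05
  expect_false(linearity_r2(flat, abscissa = x)$active)
  strong <- 0.1 + 0.5 * exp(-x^2 / 400)
  expect_true(linearity_r2(strong, abscissa = x)$active)
})

test_that("vectorized population linearity agrees with the per-neuron path", {
  grid <- std_grid(rho = 10)
  lin <- population_linearity(grid)
  expect_equal(nrow(lin), 1491)
  set.seed(33)
  for (i in sample(nrow(lin), 12)) {
    single <- linearity_r2(eye_sweep(hardwired_neuron(lin$alpha[i], lin$beta[i]),
                                     grid))
    expect_equal(lin$r_squared[i], single$r_squared, tolerance = 1e-10)
    expect_equal(lin$slope[i], single$slope, tolerance = 1e-10)
  }
})

test_that("R-squared histograms bin half-open with a closed top bin", {
  h <- r2_histogram(c(0.1, 0.3, 0.5, 0.9))
  expect_equal(h$proportions, c(25, 25, 25, 0, 25))
  expect_equal(h$bin_edges, c(0, 0.2, 0.4, 0.6, 0.8, 1.0))

  # exact 1.0 lands in (and only in) the last bin
  expect_equal(r2_histogram(rep(1, 5))$proportions, c(0, 0, 0, 0, 100))
  # bin boundaries belong to the upper bin
  expect_equal(r2_histogram(c(0.2))$proportions, c(0, 100, 0, 0, 0))

  set.seed(34)
  expect_equal(sum(r2_histogram(runif(137))$proportions), 100, tolerance = 1e-9)

  expect_error(r2_histogram(numeric(0)), "non-empty")
  expect_error(r2_histogram(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(r2_histogram(0.5, bin_width = 0.3), "divide")
})

test_that("multiplicativity is exact for scalar-multiple families", {
  x <- -10:10
  base <- 0.1 + 0.3 * exp(-x^2 / 30)
  fam <- fixation_family(
    c(-12, 0, 12),
    list(response_curve(x, 2 * base), response_curve(x, base),
         response_curve(x, 0.5 * base)))
  res <- multiplicativity_test(fam)
  expect_equal(res$scale_constants, c(2, 0.5), tolerance = 1e-12)
  expect_equal(res$max_relative_residual, 0, tolerance = 1e-12)
  expect_true(res$passes)

  # identical curves: constants one, residual zero
  fam2 <- fixation_family(c(0, 20), list(response_curve(x, base),
                                         response_curve(x, base)))
  res2 <- multiplicativity_test(fam2)
  expect_equal(res2$scale_constants, 1, tolerance = 1e-12)
  expect_equal(res2$max_relative_residual, 0, tolerance = 1e-12)

  # a genuinely non-multiplicative family fails
  fam3 <- fixation_family(
    c(0, 20),
    list(response_curve(x, base), response_curve(x, rev(base) + 0.2)))
  expect_false(multiplicativity_test(fam3, tolerance = 0.01)$passes)

  zero <- fixation_family(c(0, 5), list(response_curve(x, rep(0, 21)),
                                        response_curve(x, base)))
  expect_error(multiplicativity_test(zero), "zero norm")
})

test_that("profile classification separates monotonic, peaked and unresponsive", {
  x <- -35:35
  expect_equal(classify_profile(seq(0.1, 0.9, length.out = 71), abscissa = x),
               "monotonic")
  expect_equal(classify_profile(seq(0.9, 0.1, length.out = 71), abscissa = x),
               "monotonic")
  expect_equal(classify_profile(0.1 + 0.6 * exp(-x^2 / 200), abscissa = x),
               "peaked")
  expect_equal(classify_profile(rep(0.01, 71) + 0.02 * exp(-x^2 / 200),
                                abscissa = x),
               "unresponsive")
  # sigmoidal curve saturating at both ends still reads monotonic
  sig <- 1 / (1 + exp(-0.2 * x))
  expect_equal(classify_profile(sig, abscissa = x), "monotonic")
})

test_that("user tuning-curve CSVs round-trip through the analysis", {
  x <- -35:35
  df <- rbind(
    data.frame(unit_id = "a", abscissa_deg = x,
               rate = seq(0.1, 0.9, length.out = 71)),
    data.frame(unit_id = "b", abscissa_deg = x,
               rate = 0.1 + 0.6 * exp(-x^2 / 200)))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)

  curves <- read_tuning_curves(path)
  expect_named(curves, c("a", "b"))
  res <- analyze_tuning_curves(curves)
  expect_equal(res$profile, c("monotonic", "peaked"))
  expect_gt(res$r_squared[res$unit_id == "a"], 0.99)
  expect_lt(res$r_squared[res$unit_id == "b"], 0.1)
})
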