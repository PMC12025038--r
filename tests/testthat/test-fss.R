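# Firefly Sigma Seeker: dispersion statistic, adaptive stopping rules,
# attractiveness decay, swarm dynamics and the threshold update.

test_that("loss dispersion is the population standard deviation", {
  expect_identical(loss_stddev(c(0.5, 0.5, 0.5)), 0)
  expect_identical(loss_stddev(c(0, 2)), 1)
  set.seed(10)
  v <- rnorm(40)
  expect_equal(loss_stddev(v), pop_sd_oracle(v), tolerance = 1e-12)
  expect_equal(loss_stddev(v, 7), pop_sd_oracle(tail(v, 7)), tolerance = 1e-12)
  expect_error(loss_stddev(numeric(0)), "empty")
  expect_error(loss_stddev(v, 0), "between 1")
  expect_error(loss_stddev(v, 41), "between 1")
})

test_that("the stopping threshold is the sensitivity-dispersion product", {
  st <- early_stop_state(sigma_mult = 2)
  expect_identical(compute_threshold(st, 0.05), 0.1)
  expect_identical(compute_threshold(st, 0), 0)
  set.seed(2)
  for (i in 1:10) {
    s <- runif(1, 0.1, 5); d <- runif(1, 0, 2)
    expect_identical(compute_threshold(early_stop_state(sigma_mult = s), d),
                     s * d)
  }
  expect_error(compute_threshold(st, -0.1), ">= 0")
})

test_that("a strongly improving trace never stops", {
  st <- early_stop_state(sigma_mult = 0.01, patience = 10, min_delta = 0.01)
  trace <- seq(2, 1, by = -0.05)
  expect_false(should_stop(st, trace)$stop)
})

test_that("a constant trace stops after exactly `patience` flat epochs", {
  st <- early_stop_state(patience = 10, min_delta = 0.01)
  expect_false(should_stop(st, rep(1, 10))$stop)   # never before patience
  dec <- should_stop(st, rep(1, 11))
  expect_true(dec$stop)
  expect_identical(dec$reason, "patience")
  expect_identical(dec$epochs_without_improvement, 10L)
})

test_that("the dispersion rule fires at its constructed boundary and flips
           when the trace is truncated", {
  st <- early_stop_state(sigma_mult = 2, patience = 3, min_delta = 0,
                         window = 3)
  trace <- c(3, 3, 3, 3, 3 - 5e-4 * (1:4))
  dec <- should_stop(st, trace)
  expect_true(dec$stop)
  expect_identical(dec$reason, "fss_threshold")
  expect_identical(dec$consecutive_below, 3L)
  # one epoch shorter: only 2 consecutive below-threshold epochs
  dec2 <- should_stop(st, trace[-length(trace)])
  expect_false(dec2$stop)
  expect_identical(dec2$consecutive_below, 2L)
})

test_that("raising the sensitivity multiplier never un-stops a dispersion stop", {
  set.seed(12)
  for (i in 1:20) {
    trace <- cumsum(c(2, rnorm(14, -0.01, 0.05)))
    s <- runif(1, 0.2, 2)
    st1 <- early_stop_state(sigma_mult = s, patience = 3, min_delta = 0,
                            window = 5)
    st2 <- early_stop_state(sigma_mult = 2 * s, patience = 3, min_delta = 0,
                            window = 5)
    d1 <- should_stop(st1, trace)
    if (d1$reason == "fss_threshold")
      expect_true(should_stop(st2, trace)$stop)
  }
})

test_that("attractiveness decays exponentially with distance", {
  expect_identical(update_attractiveness(0.8, 1.5, 0), 0.8)
  expect_identical(update_attractiveness(0.8, 0, 3), 0.8)
  expect_equal(update_attractiveness(1, 1, log(2)), 0.5, tolerance = 1e-12)
  expect_error(update_attractiveness(1, 1, -1), ">= 0")
  # monotone non-increasing in distance, bounded by the previous value
  d <- seq(0, 5, by = 0.5)
  a <- vapply(d, function(dd) update_attractiveness(2, 0.7, dd), numeric(1))
  expect_true(all(diff(a) < 0))
  expect_true(all(a <= 2))
})

test_that("firefly steps move dimmer fireflies toward brighter ones", {
  cfg <- swarm_config(n = 2, beta = 0.5, gamma_abs = 0, gamma_rand = 0,
                      bounds = c(-10, 10), seed = 1)
  obj <- function(x) x^2
  swarm <- list(pos = matrix(c(0, 1), 2, 1),
                brightness = c(0, 1), attract = c(1, 1))
  out <- firefly_step(swarm, obj, cfg)
  expect_identical(out$pos[1, 1], 0)      # brightest does not move
  expect_identical(out$pos[2, 1], 0.5)    # 1 + 0.5 * 1 * (0 - 1)

  same <- list(pos = matrix(c(2, 2), 2, 1), brightness = c(4, 4),
               attract = c(1, 1))
  out2 <- firefly_step(same, obj, cfg)
  expect_identical(out2$pos, same$pos)    # identical positions: no movement
})

test_that("the swarm minimizes a convex toy objective", {
  cfg <- swarm_config(bounds = c(0, 10), seed = 42)
  res <- firefly_optimize(function(x) (x - 3)^2, cfg)
  expect_lt(abs(res$best_x - 3), 0.1)
  expect_true(all(diff(res$trace$best_value) <= 0))

  # determinism under a fixed seed
  res2 <- firefly_optimize(function(x) (x - 3)^2, cfg)
  expect_identical(res$trace, res2$trace)

  const <- firefly_optimize(function(x) 7, swarm_config(n = 5, iterations = 5,
                                                        bounds = c(0, 1),
                                                        seed = 1))
  expect_identical(const$best_value, 7)

  # non-finite objective values are penalized, not fatal
  spiky <- function(x) if (x > 5) NaN else (x - 3)^2
  res3 <- firefly_optimize(spiky, swarm_config(n = 6, iterations = 10,
                                               bounds = c(0, 10), seed = 3))
  expect_true(is.finite(res3$best_value))
})

test_that("swarm configuration rejects invalid settings", {
  expect_error(swarm_config(n = 1, bounds = c(0, 1)), ">= 2")
  expect_error(swarm_config(bounds = c(1, 1)), "lower < upper")
  expect_error(swarm_config(beta = -1, bounds = c(0, 1)), ">= 0")
})

test_that("the surrogate-gradient threshold update is a clamped step", {
  st <- early_stop_state(eta_theta = 0.5)
  st$theta <- 0.1
  expect_identical(update_threshold(st, 0)$theta, 0.1)
  expect_identical(update_threshold(st, 0.1)$theta, 0.05)
  expect_identical(update_threshold(st, 100)$theta, 0)   # clamps at zero
  st$theta_max <- 0.2
  expect_identical(update_threshold(st, -10)$theta, 0.2) # clamps at max
})
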