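# Firefly Sigma Seeker (FSS): loss-dispersion statistic, adaptive
# early-stopping threshold, the firefly-swarm optimizer used to tune the
# FSS/MWR sensitivity hyperparameters, and the surrogate-gradient threshold
# update.

#' Dispersion of recent validation losses
#'
#' Population standard deviation `sqrt((1/N) * sum (loss_i - mean)^2)` over
#' the last `window` entries of a loss history. Zero iff the window is
#' constant.
#'
#' @param history Numeric vector of per-epoch losses (chronological).
#' @param window Number of trailing entries to use (`1 <= window <=
#'   length(history)`).
#' @return Non-negative dispersion value.
#' @export
loss_stddev <- function(history, window = length(history)) {
  if (length(history) == 0) stop("loss history is empty")
  if (window < 1 || window > length(history))
    stop("`window` must be between 1 and the history length")
  v <- utils::tail(history, window)
  if (any(!is.finite(v))) stop("loss history must be finite")
  sqrt(mean((v - mean(v))^2))
}

#' Early-stopping state
#'
#' Holds the FSS sensitivity multiplier and the patience bookkeeping of the
#' fixed-improvement rule.
#'
#' @param sigma_mult Sensitivity multiplier applied to the loss dispersion
#'   to form the stopping threshold `theta` (the quantity the firefly
#'   search tunes). Default 1.
#' @param patience Epochs a rule must hold before stopping (default 10).
#' @param min_delta Minimum improvement of the best validation loss that
#'   resets patience (default 0.01).
#' @param window Trailing window for the dispersion statistic (default =
#'   `patience`).
#' @param eta_theta Learning rate for the surrogate-gradient threshold
#'   update (default 0.1).
#' @param theta_max Upper clamp for the updated threshold (default `Inf`).
#' @return An `early_stop_state`.
#' @export
early_stop_state <- function(sigma_mult = 1, patience = 10L, min_delta = 0.01,
                             window = patience, eta_theta = 0.1,
                             theta_max = Inf) {
  if (patience < 1) stop("`patience` must be >= 1")
  if (min_delta < 0) stop("`min_delta` must be >= 0")
  if (eta_theta < 0) stop("`eta_theta` must be >= 0")
  structure(list(sigma_mult = sigma_mult, patience = as.integer(patience),
                 min_delta = min_delta, window = as.integer(window),
                 eta_theta = eta_theta, theta_max = theta_max, theta = 0),
            class = "early_stop_state")
}

#' Adaptive stopping threshold
#'
#' `theta = sigma_mult * dispersion`: the early-stopping threshold scales
#' with the recent variability of the validation loss, so noisy phases
#' demand larger improvements than quiet ones.
#'
#' @param state An [early_stop_state()].
#' @param dispersion Non-negative loss dispersion (from [loss_stddev()]).
#' @return Threshold `theta >= 0`.
#' @export
compute_threshold <- function(state, dispersion) {
  if (!is.finite(dispersion) || dispersion < 0)
    stop("`dispersion` must be finite and >= 0")
  state$sigma_mult * dispersion
}

#' Early-stopping decision
#'
#' Stops when EITHER (a) the epoch-over-epoch loss decrease has stayed
#' below the adaptive threshold `theta` (recomputed each epoch from the
#' trailing dispersion window) for `patience` consecutive epochs
#' (`"fss_threshold"`), OR (b) the best loss has not improved by at least
#' `min_delta` for `patience` epochs (`"patience"`). Neither rule can fire
#' before `patience + 1` epochs of history exist.
#'
#' @param state An [early_stop_state()].
#' @param history Numeric vector of per-epoch validation losses.
#' @return List: `stop` (logical), `reason` (`"fss_threshold"`,
#'   `"patience"` or `"none"`), `theta`, `dispersion`,
#'   `consecutive_below`, `epochs_without_improvement`.
#' @export
should_stop <- function(state, history) {
  stopifnot(inherits(state, "early_stop_state"))
  n <- length(history)
  if (n == 0) stop("loss history is empty")
  # rule (b): fixed minimum improvement of the best loss
  best <- history[1]
  ewi <- 0L
  if (n > 1) for (t in 2:n) {
    if (best - history[t] >= state$min_delta) {
      best <- history[t]
      ewi <- 0L
    } else ewi <- ewi + 1L
  }
  # rule (a): decrease below the adaptive dispersion threshold
  below <- logical(0)
  theta_t <- 0
  disp_t <- 0
  if (n > 1) {
    below <- logical(n - 1L)
    for (t in 2:n) {
      disp_t <- loss_stddev(history[seq_len(t)], min(state$window, t))
      theta_t <- compute_threshold(state, disp_t)
      below[t - 1L] <- (history[t - 1L] - history[t]) < theta_t
    }
  }
  consec <- 0L
  for (b in rev(below)) {
    if (!b) break
    consec <- consec + 1L
  }
  stop_a <- consec >= state$patience
  stop_b <- ewi >= state$patience
  list(stop = stop_a || stop_b,
       reason = if (stop_a) "fss_threshold" else if (stop_b) "patience" else "none",
       theta = theta_t, dispersion = disp_t,
       consecutive_below = consec, epochs_without_improvement = ewi)
}

#' Exponential attractiveness decay
#'
#' `A * exp(-gamma_abs * distance)`: a firefly's pull decays exponentially
#' with distance; it never exceeds the current attractiveness and equals it
#' at distance 0.
#'
#' @param A Current attractiveness, `> 0`.
#' @param gamma_abs Non-negative decay rate.
#' @param distance Non-negative distance.
#' @return Updated attractiveness.
#' @export
update_attractiveness <- function(A, gamma_abs, distance) {
  if (!is.finite(distance) || distance < 0) stop("`distance` must be >= 0")
  if (A <= 0) stop("`A` must be positive")
  if (gamma_abs < 0) stop("`gamma_abs` must be >= 0")
  A * exp(-gamma_abs * distance)
}

#' Firefly swarm configuration
#'
#' @param n Population size (>= 2), default 15.
#' @param iterations Number of swarm iterations, default 50.
#' @param beta Movement scale toward brighter fireflies, default 1.
#' @param gamma_abs Attractiveness decay rate (exponential in distance),
#'   default 1.
#' @param gamma_rand Randomness scale; each pairwise move adds
#'   `gamma_rand * u` with `u` uniform per dimension in `[-0.5, 0.5]`.
#'   Default 0.2.
#' @param bounds 2-row matrix (or 2-vector for 1-D): lower/upper bound per
#'   dimension, all finite with lower < upper.
#' @param seed RNG seed for the swarm run.
#' @return A `swarm_config`.
#' @export
swarm_config <- function(n = 15L, iterations = 50L, beta = 1, gamma_abs = 1,
                         gamma_rand = 0.2, bounds, seed = 1L) {
  if (n < 2) stop("population size must be >= 2")
  if (any(c(beta, gamma_abs, gamma_rand) < 0))
    stop("beta, gamma_abs, gamma_rand must be >= 0")
  if (is.vector(bounds) && length(bounds) == 2L) bounds <- matrix(bounds, 2L, 1L)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds[1, ] >= bounds[2, ]))
    stop("`bounds` must be a 2 x D matrix of finite lower < upper bounds")
  structure(list(n = as.integer(n), iterations = as.integer(iterations),
                 beta = beta, gamma_abs = gamma_abs, gamma_rand = gamma_rand,
                 bounds = bounds, seed = as.integer(seed)),
            class = "swarm_config")
}

eval_objective <- function(objective, x) {
  v <- tryCatch(objective(x), error = function(e) Inf)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) Inf else v
}

# Brighter = lower objective; ties broken by firefly index (lower wins).
is_brighter <- function(brightness, j, i) {
  brightness[j] < brightness[i] || (brightness[j] == brightness[i] && j < i)
}

#' One firefly-swarm step
#'
#' Each firefly moves toward every brighter one by
#' `beta * A_ij * (x_j - x_i) + gamma_rand * u` where `A_ij` is its
#' distance-decayed attractiveness ([update_attractiveness()]) and `u` is
#' uniform in `[-0.5, 0.5]` per dimension; positions are clamped to the
#' bounds. Stored attractiveness then decays with each firefly's Euclidean
#' distance to the current brightest, and brightness is re-evaluated.
#' Consumes the current RNG stream, so trajectories are reproducible under
#' an outer seed.
#'
#' @param swarm List with `pos` (`n x D` matrix), `brightness` (numeric),
#'   `attract` (positive numeric).
#' @param objective Function mapping a position vector to a finite scalar
#'   (lower is better); non-finite values are penalized with `Inf`.
#' @param config A [swarm_config()].
#' @return Updated swarm list.
#' @export
firefly_step <- function(swarm, objective, config) {
  n <- nrow(swarm$pos)
  if (is.null(n) || n == 0) stop("swarm is empty")
  D <- ncol(swarm$pos)
  lo <- config$bounds[1, ]; hi <- config$bounds[2, ]
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i || !is_brighter(swarm$brightness, j, i)) next
      d <- sqrt(sum((swarm$pos[j, ] - swarm$pos[i, ])^2))
      a_ij <- update_attractiveness(swarm$attract[i], config$gamma_abs, d)
      u <- stats::runif(D, -0.5, 0.5)
      swarm$pos[i, ] <- clamp(swarm$pos[i, ] +
                                config$beta * a_ij * (swarm$pos[j, ] - swarm$pos[i, ]) +
                                config$gamma_rand * u, lo, hi)
    }
  }
  b_idx <- order(swarm$brightness, seq_len(n))[1]
  for (i in seq_len(n)) {
    d_best <- sqrt(sum((swarm$pos[i, ] - swarm$pos[b_idx, ])^2))
    swarm$attract[i] <- update_attractiveness(swarm$attract[i],
                                              config$gamma_abs, d_best)
  }
  swarm$brightness <- vapply(seq_len(n),
                             function(i) eval_objective(objective, swarm$pos[i, ]),
                             numeric(1))
  swarm
}

#' Firefly-swarm minimization
#'
#' Runs [firefly_step()] for `config$iterations` iterations from a uniform
#' random initial population, with elitist best-so-far bookkeeping (the
#' recorded best value is monotone non-increasing).
#'
#' @param objective Scalar objective to minimize over the bounded box.
#' @param config A [swarm_config()].
#' @return A `firefly_result`: `best_x`, `best_value`, `trace` (tibble:
#'   iteration, best_value, best position), final `swarm`.
#' @export
firefly_optimize <- function(objective, config) {
  with_rng(config$seed, {
    D <- ncol(config$bounds)
    pos <- sapply(seq_len(D), function(d)
      stats::runif(config$n, config$bounds[1, d], config$bounds[2, d]))
    pos <- matrix(pos, config$n, D)
    swarm <- list(pos = pos,
                  brightness = vapply(seq_len(config$n),
                                      function(i) eval_objective(objective, pos[i, ]),
                                      numeric(1)),
                  attract = rep(1, config$n))
    bi <- order(swarm$brightness, seq_len(config$n))[1]
    best_x <- swarm$pos[bi, ]
    best_v <- swarm$brightness[bi]
    trace <- vector("list", config$iterations + 1L)
    trace[[1]] <- c(iteration = 0, best_value = best_v, best_x)
    for (it in seq_len(config$iterations)) {
      swarm <- firefly_step(swarm, objective, config)
      bi <- order(swarm$brightness, seq_len(config$n))[1]
      if (swarm$brightness[bi] < best_v) {
        best_v <- swarm$brightness[bi]
        best_x <- swarm$pos[bi, ]
      }
      trace[[it + 1L]] <- c(iteration = it, best_value = best_v, best_x)
    }
    tr <- do.call(rbind, trace)
    colnames(tr) <- c("iteration", "best_value", paste0("x", seq_len(D)))
    structure(list(best_x = best_x, best_value = best_v,
                   trace = tibble::as_tibble(as.data.frame(tr)),
                   swarm = swarm, config = config),
              class = "firefly_result")
  })
}

#' @export
print.firefly_result <- function(x, ...) {
  cat(sprintf("<firefly_result> best value %.6g at (%s) after %d iteration(s)\n",
              x$best_value, paste(signif(x$best_x, 6), collapse = ", "),
              x$config$iterations))
  invisible(x)
}

#' Surrogate-gradient threshold update
#'
#' `theta <- clamp(theta - eta_theta * gradient, 0, theta_max)`. A hard
#' pruning threshold has no exact loss gradient, so the caller supplies a
#' surrogate (the training loop uses a central finite difference of the
#' validation loss under masks built at the threshold scaled by 1 +/- 0.1).
#'
#' @param state An [early_stop_state()] carrying `theta`, `eta_theta`,
#'   `theta_max`.
#' @param gradient Surrogate gradient of the total loss w.r.t. the
#'   threshold.
#' @return The state with updated `theta`.
#' @export
update_threshold <- function(state, gradient) {
  stopifnot(inherits(state, "early_stop_state"))
  state$theta <- threshold_step(state$theta, gradient, state$eta_theta,
                                state$theta_max)
  state
}

# Pure clamped gradient step shared by update_threshold and the alpha
# update inside the training loop.
threshold_step <- function(theta, gradient, eta, theta_max = Inf) {
  if (!is.finite(gradient)) return(theta)
  clamp(theta - eta * gradient, 0, theta_max)
}
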