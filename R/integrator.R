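#' Simulation configuration
#'
#' @param dt Time step of the Euler-Maruyama scheme (default 0.01).
#' @param n_steps Total number of steps (default 1.8e6).
#' @param transient_fraction Fraction of initial steps discarded when forming
#'   long-time averages (default 0.30).
#' @param record_stride Steps between stored coupling frames (default chosen so
#'   that about 200 frames are kept).
#' @param seed RNG seed attached to runs started from this configuration.
#' @param store_couplings Keep strided coupling frames (default TRUE).
#' @param store_phases Keep the full-resolution phase matrix. Needed by
#'   switch-event detection; off by default to save memory.
#' @param store_velocities Keep the full-resolution deterministic phase
#'   velocities (needed by the escape predictor).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.01,
                       n_steps = 1.8e6,
                       transient_fraction = 0.30,
                       record_stride = NULL,
                       seed = 1L,
                       store_couplings = TRUE,
                       store_phases = FALSE,
                       store_velocities = FALSE) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (transient_fraction < 0 || transient_fraction >= 1) {
    stop("`transient_fraction` must be in [0, 1)", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("`n_steps` must be >= 1", call. = FALSE)
  if (is.null(record_stride)) record_stride <- max(1L, n_steps %/% 200L)
  record_stride <- as.integer(record_stride)
  if (record_stride < 1L) stop("`record_stride` must be >= 1", call. = FALSE)
  structure(
    list(dt = dt, n_steps = n_steps, transient_fraction = transient_fraction,
         record_stride = record_stride, seed = as.integer(seed),
         store_couplings = isTRUE(store_couplings),
         store_phases = isTRUE(store_phases),
         store_velocities = isTRUE(store_velocities)),
    class = "sim_config"
  )
}

variant_code <- function(variant) {
  match(variant, c("dense", "sparse", "freq_adaptive")) - 1L
}

#' Single Euler-Maruyama step
#'
#' Advances the state by one step: `theta <- (theta + dt * rhs_phases +
#' sigma * sqrt(dt) * noise_draw) mod 2*pi` and `k <- k + dt * rhs_couplings`.
#' This R-level step is the reference path; long runs go through the compiled
#' loop in [simulate_kuramoto()], which must agree with iterating this step.
#'
#' @param state A [kuramoto_state()].
#' @param params A [kuramoto_params()].
#' @param dt Positive time step.
#' @param noise_draw Length-`N` vector of standard-normal draws (default all
#'   zero, i.e. the deterministic step).
#' @return The advanced [kuramoto_state()].
#' @export
em_step <- function(state, params, dt, noise_draw = NULL) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (is.null(noise_draw)) noise_draw <- numeric(params$n)
  th <- state$theta + dt * rhs_phases(state, params) +
    params$sigma * sqrt(dt) * noise_draw
  if (any(!is.finite(th))) {
    stop("non-finite phase after step at t = ", state$t, call. = FALSE)
  }
  k <- state$k + dt * rhs_couplings(state, params)
  kuramoto_state(th, k, t = state$t + dt)
}

#' Integrate the coupled phase/coupling dynamics
#'
#' Runs the Euler-Maruyama scheme for `config$n_steps` steps from `initial`,
#' recording the two Kuramoto order parameters every step and coupling frames
#' every `config$record_stride` steps. Deterministic given
#' `(config$seed, params, config, initial)`; the seed only matters when
#' `params$sigma > 0`.
#'
#' @param params A [kuramoto_params()].
#' @param config A [sim_config()].
#' @param initial A [kuramoto_state()]; typically from
#'   [sample_initial_condition()].
#' @return A `kuramoto_trajectory`: list with `series` (tibble of `step`, `t`,
#'   `R`, `R2`), optional `theta` / `vel` full-resolution matrices
#'   (`N x (n_steps+1)`, one column per step), optional `k_frames` array
#'   (`N x N x n_frames`) with
#'   `frame_steps`, the final `state`, and the `params`/`config` snapshot.
#' @examples
#' p <- kuramoto_params(n = 4)
#' init <- sample_initial_condition(4, seed = 1)
#' traj <- simulate_kuramoto(p, sim_config(n_steps = 1000), init)
#' head(traj$series)
#' @export
simulate_kuramoto <- function(params, config, initial) {
  check_state_params(initial, params)
  if (params$variant == "sparse" && !graph_is_connected(params$adjacency)) {
    stop("adjacency must be connected", call. = FALSE)
  }
  set.seed(config$seed)
  res <- simulate_cpp(
    theta0 = initial$theta, k0 = initial$k, omega = params$omega,
    eps1 = params$eps1, eps2 = params$eps2,
    beta1 = params$beta1, beta2 = params$beta2,
    sigma = params$sigma, variant = variant_code(params$variant),
    gamma0 = params$gamma0, alpha = params$alpha,
    adjacency = params$adjacency,
    dt = config$dt, n_steps = config$n_steps,
    record_stride = config$record_stride,
    store_phases = config$store_phases,
    store_velocities = config$store_velocities,
    store_couplings = config$store_couplings
  )
  steps <- 0:config$n_steps
  traj <- list(
    series = tibble::tibble(step = steps, t = steps * config$dt,
                            R = res$R, R2 = res$R2),
    theta = if (config$store_phases) res$theta_full else NULL,
    vel = if (config$store_velocities) res$vel_full else NULL,
    k_frames = if (config$store_couplings) {
      array(res$k_frames, dim = c(params$n, params$n,
                                  length(res$frame_steps)))
    } else NULL,
    frame_steps = if (config$store_couplings) res$frame_steps else NULL,
    state = kuramoto_state(res$theta_final, res$k_final,
                           t = config$n_steps * config$dt),
    params = params,
    config = config,
    seed = config$seed
  )
  class(traj) <- "kuramoto_trajectory"
  traj
}

#' @export
print.kuramoto_trajectory <- function(x, ...) {
  cat("<kuramoto_trajectory> N =", x$params$n, " steps =", x$config$n_steps,
      " dt =", x$config$dt, " seed =", x$seed, "\n")
  s <- transient_slice(x)
  cat("  post-transient <R> =", round(mean(x$series$R[s]), 4),
      " <R2> =", round(mean(x$series$R2[s]), 4), "\n")
  invisible(x)
}

# indices of the post-transient part of the per-step series
transient_slice <- function(traj, transient_fraction = NULL) {
  tf <- transient_fraction %||% traj$config$transient_fraction
  first <- floor(tf * traj$config$n_steps) + 1L
  seq.int(first + 1L, nrow(traj$series))
}

#' Long-time averaged order parameters of a trajectory
#'
#' @param x A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return One-row tibble with `n`, `n_steps`, `mean_R`, `mean_R2`, `label`
#'   (from [classify_state()]) and the RNG `seed`.
#' @method glance kuramoto_trajectory
#' @export
glance.kuramoto_trajectory <- function(x, ...) {
  s <- transient_slice(x)
  m_r <- mean(x$series$R[s])
  m_r2 <- mean(x$series$R2[s])
  tibble::tibble(
    n = x$params$n, n_steps = x$config$n_steps,
    mean_R = m_r, mean_R2 = m_r2,
    label = classify_state(m_r, m_r2),
    seed = x$seed
  )
}

#' Per-step order-parameter series of a trajectory
#'
#' @param x A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `step`, `t`, `R`, `R2`.
#' @method tidy kuramoto_trajectory
#' @export
tidy.kuramoto_trajectory <- function(x, ...) {
  x$series
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the order-parameter time series of a run
#'
#' @param object A `kuramoto_trajectory`.
#' @param ... Unused.
#' @return A ggplot object showing `R(t)` and `R2(t)`.
#' @method autoplot kuramoto_trajectory
#' @export
autoplot.kuramoto_trajectory <- function(object, ...) {
  df <- tidyr::pivot_longer(object$series, c("R", "R2"),
                            names_to = "order_parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$order_parameter)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time", y = NULL, colour = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||% .data
NULL
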