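#' Estimated time of escape (ETE) from a single snapshot
#'
#' For each oscillator, the number of simulation steps needed to reach the
#' cluster boundary — the point anti-podal to its current cluster centre —
#' assuming the distance closes linearly at the snapshot velocity:
#' `eta_i = (distance to boundary) / (|theta_dot_i| * dt)`. Distances are
#' measured in the co-moving cluster frame (reference direction `psi2/2`), so
#' the rule reduces to "distance of theta_i from the boundary at pi" when the
#' clusters sit at 0 and pi. Oscillators with `eta > eta_max` are excluded
#' (too slow for the linear extrapolation to be trusted). An optional
#' direction filter additionally excludes oscillators whose velocity points
#' away from the boundary; it is off by default because near the saddle the
#' snapshot velocity of an almost-arrived switcher is at round-off scale and
#' its sign is uninformative, while the magnitude ratio remains meaningful.
#'
#' @param theta Length-`N` snapshot phase vector.
#' @param theta_dot Length-`N` deterministic phase velocities at the snapshot.
#' @param dt Simulation time step.
#' @param theta_b Distance of the boundary from the cluster centre (default
#'   `pi`, the anti-podal point).
#' @param eta_max Exclusion cutoff in steps (default 500); exclusion is strict
#'   (`eta > eta_max`), so `eta = eta_max` is kept.
#' @param direction_filter Exclude oscillators moving away from the boundary
#'   (default FALSE, the pure-magnitude rule).
#' @param rel_disp Optional length-`N` signed displacement of each oscillator
#'   from its own cluster centre, in `[-pi, pi]`. When supplied (as
#'   [forecast_events()] does, from the crossing tracker, which knows each
#'   oscillator's membership history) it overrides the snapshot-only
#'   inference, which has to assign each oscillator to the nearest centre and
#'   therefore cannot place anyone beyond the halfway point.
#' @return Tibble with one row per oscillator: `id`, `distance` (radians to
#'   the boundary), `speed` (radians/step), `eta` (steps; `Inf` for zero
#'   speed) and `excluded`.
#' @examples
#' # tight cluster at 0 / pi; oscillator 4 is 0.4 rad short of the boundary
#' th <- c(0, 0.01, pi, pi - 0.4)
#' estimate_escape_times(th, c(0, 0, 0, 0.2), dt = 0.01,
#'                       rel_disp = c(0, 0.01, 0, pi - 0.4))
#' @export
estimate_escape_times <- function(theta, theta_dot, dt, theta_b = pi,
                                  eta_max = 500, direction_filter = FALSE,
                                  rel_disp = NULL) {
  if (length(theta) != length(theta_dot)) {
    stop("`theta` and `theta_dot` must have equal length", call. = FALSE)
  }
  if (is.null(rel_disp)) {
    op <- order_parameters(theta)
    ref <- op$psi2 / 2
    # displacement from the nearest cluster centre, in (-pi/2, pi/2]
    r <- (theta - ref + pi) %% (2 * pi) - pi
    r <- ifelse(abs(r) > pi / 2, r - sign(r) * pi, r)
  } else {
    if (length(rel_disp) != length(theta)) {
      stop("`rel_disp` must match `theta` in length", call. = FALSE)
    }
    r <- rel_disp
  }
  distance <- pmax(theta_b - abs(r), 0)
  step_disp <- abs(theta_dot) * dt
  eta <- ifelse(step_disp > 0, distance / step_disp, Inf)
  eta[distance <= 0] <- 0
  away <- direction_filter & distance > 0 & r != 0 &
    sign(theta_dot) != sign(r)
  excluded <- eta > eta_max | away
  tibble::tibble(id = seq_along(theta), distance = distance,
                 speed = step_disp, eta = eta, excluded = excluded)
}

#' Predicted switcher set from ETE values
#'
#' The leader is the non-excluded oscillator with minimal ETE; the predicted
#' set contains every non-excluded oscillator within `delta_eta` steps of the
#' leader's ETE.
#'
#' @param eta Tibble from [estimate_escape_times()], or a numeric ETE vector
#'   (then `Inf`/`NA` mark exclusions).
#' @param delta_eta Temporal margin in steps (default 150).
#' @return List with `leader` (integer, `NA` if all excluded) and `predicted`
#'   (integer vector of oscillator ids, possibly empty).
#' @examples
#' predict_switcher_set(c(100, 240, 260, NA)) # leader 1, set {1, 2}
#' @export
predict_switcher_set <- function(eta, delta_eta = 150) {
  if (is.data.frame(eta)) {
    vals <- ifelse(eta$excluded, Inf, eta$eta)
    ids <- eta$id
  } else {
    vals <- ifelse(is.na(eta), Inf, eta)
    ids <- seq_along(eta)
  }
  if (all(!is.finite(vals))) {
    return(list(leader = NA_integer_, predicted = integer(0)))
  }
  leader <- ids[which.min(vals)]
  predicted <- ids[is.finite(vals) & vals <= min(vals) + delta_eta]
  list(leader = leader, predicted = sort(predicted))
}

#' Score a prediction against the actual switcher set
#'
#' * `Perfect`: predicted set equals the actual set.
#' * `Good`: every actual switcher predicted, plus extras (proper superset).
#' * `Partial`: some but not all actual switchers predicted.
#' * `Missed`: no overlap.
#'
#' @param predicted Integer vector of predicted oscillator ids (may be empty).
#' @param actual Non-empty integer vector of oscillators that actually
#'   switched.
#' @return One of `"Perfect"`, `"Good"`, `"Partial"`, `"Missed"`.
#' @examples
#' score_prediction(c(3, 7), 3) # "Good"
#' @export
score_prediction <- function(predicted, actual) {
  if (length(actual) == 0) stop("`actual` must be non-empty", call. = FALSE)
  p <- unique(as.integer(predicted))
  a <- unique(as.integer(actual))
  if (setequal(p, a)) return("Perfect")
  if (all(a %in% p)) return("Good")
  if (any(a %in% p)) return("Partial")
  "Missed"
}

#' Forecast every detected switching event of a trajectory
#'
#' Takes the snapshot `tau_win` steps before each event's first crossing,
#' computes ETEs from the stored deterministic velocities, forms the predicted
#' set and scores it against the event's actual switchers.
#'
#' @param trajectory A `kuramoto_trajectory` run with `store_phases = TRUE`
#'   and `store_velocities = TRUE`.
#' @param events Tibble from [detect_switch_events()]; detected on demand if
#'   `NULL`.
#' @param tau_win Snapshot lead time in steps (default 200).
#' @param eta_max,delta_eta,direction_filter Passed to the ETE machinery.
#' @param grouping_window Used when `events` is `NULL`.
#' @param boundary_tol Arrival tolerance of the crossing tracker (see
#'   [detect_switch_events()]); the ETE boundary is placed consistently at
#'   `pi - boundary_tol`, the same line whose crossing defines the event.
#' @return Tibble with one row per scorable event: `event`, `t_step`,
#'   `t_snap`, `actual` and `predicted` (list-columns), `leader`, `category`.
#'   Events whose snapshot would fall before step 0 are dropped.
#' @export
forecast_events <- function(trajectory, events = NULL, tau_win = 200,
                            eta_max = 500, delta_eta = 150,
                            direction_filter = FALSE, grouping_window = 50,
                            boundary_tol = 0.1) {
  if (is.null(trajectory$vel)) {
    stop("trajectory lacks stored velocities; rerun with store_velocities = TRUE",
         call. = FALSE)
  }
  if (is.null(trajectory$theta)) {
    stop("trajectory lacks full-resolution phases; rerun with store_phases = TRUE",
         call. = FALSE)
  }
  ac <- all_crossings(trajectory$theta, boundary_tol)
  if (is.null(events)) {
    t_min <- floor(trajectory$config$transient_fraction *
                     trajectory$config$n_steps)
    events <- events_from_crossings(ac, grouping_window, t_min)
  }
  dt <- trajectory$config$dt
  out <- lapply(seq_len(nrow(events)), function(e) {
    t_event <- events$t_step[e]
    t_snap <- t_event - tau_win
    if (t_snap < 0) return(NULL)
    col <- t_snap + 1L # theta column c holds step c - 1
    # signed displacement from each oscillator's own cluster centre, from the
    # crossing tracker (membership history, not nearest-centre inference)
    rel <- rel_disp_at(ac, trajectory$theta, t_snap)
    eta <- estimate_escape_times(trajectory$theta[, col],
                                 trajectory$vel[, col], dt,
                                 theta_b = pi - boundary_tol,
                                 eta_max = eta_max,
                                 direction_filter = direction_filter,
                                 rel_disp = rel)
    pred <- predict_switcher_set(eta, delta_eta = delta_eta)
    actual <- events$ids[[e]]
    category <- score_prediction(pred$predicted, actual)
    tibble::tibble(event = events$event[e], t_step = t_event, t_snap = t_snap,
                   actual = list(actual), predicted = list(pred$predicted),
                   leader = pred$leader, category = category)
  })
  dplyr::bind_rows(out)
}

#' Snapshot-prediction experiment over many realizations
#'
#' For each realization: draw a random initial condition, integrate, detect
#' switching events after the transient, forecast each event from the snapshot
#' `tau_win` steps earlier, and score it. Realization seeds are derived from
#' `seed` by one `sample.int()` draw, so the sweep is reproducible and
#' order-independent.
#'
#' @param params A [kuramoto_params()].
#' @param config A [sim_config()]; phase and velocity storage is forced on.
#' @param n_realizations Number of independent runs.
#' @param tau_win,eta_max,delta_eta,grouping_window,direction_filter,boundary_tol
#'   Predictor settings, see [forecast_events()].
#' @param seed Master seed.
#' @return List of class `prediction_summary` with `events` (per-event tibble
#'   across realizations), `summary` (per-category counts and percentages),
#'   `success_rate` (Perfect + Good, percent), `n_events`, `n_realizations`.
#' @export
run_prediction_experiment <- function(params, config, n_realizations,
                                      tau_win = 200, eta_max = 500,
                                      delta_eta = 150, grouping_window = 50,
                                      direction_filter = FALSE,
                                      boundary_tol = 0.1, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_realizations)
  config$store_phases <- TRUE
  config$store_velocities <- TRUE
  config$store_couplings <- FALSE
  all_events <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    cfg <- config
    cfg$seed <- seeds[r]
    init <- sample_initial_condition(params$n, seed = seeds[r])
    traj <- simulate_kuramoto(params, cfg, init)
    fc <- forecast_events(traj, tau_win = tau_win, eta_max = eta_max,
                          delta_eta = delta_eta,
                          direction_filter = direction_filter,
                          grouping_window = grouping_window,
                          boundary_tol = boundary_tol)
    if (nrow(fc) > 0) {
      fc$realization <- r
      all_events[[r]] <- fc
    }
  }
  events <- dplyr::bind_rows(all_events)
  cats <- c("Perfect", "Good", "Partial", "Missed")
  counts <- vapply(cats, function(cc) sum(events$category == cc), integer(1))
  n_events <- sum(counts)
  pct <- if (n_events > 0) 100 * counts / n_events else rep(NA_real_, 4)
  structure(
    list(events = events,
         summary = tibble::tibble(category = cats, count = unname(counts),
                                  percent = unname(pct)),
         success_rate = unname(pct[1] + pct[2]),
         n_events = n_events,
         n_realizations = n_realizations,
         tau_win = tau_win, eta_max = eta_max, delta_eta = delta_eta,
         seed = seed),
    class = "prediction_summary"
  )
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat("<prediction_summary>", x$n_events, "events over", x$n_realizations,
      "realizations\n")
  print(x$summary)
  cat("success rate (Perfect + Good):", round(x$success_rate, 2), "%\n")
  invisible(x)
}

#' Per-category counts of a prediction experiment
#'
#' @param x A `prediction_summary`.
#' @param ... Unused.
#' @return Tibble with `category`, `count`, `percent`.
#' @method tidy prediction_summary
#' @export
tidy.prediction_summary <- function(x, ...) x$summary

#' One-row overview of a prediction experiment
#'
#' @param x A `prediction_summary`.
#' @param ... Unused.
#' @return One-row tibble with event counts and the success rate.
#' @method glance prediction_summary
#' @export
glance.prediction_summary <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, n_realizations = x$n_realizations,
                 success_rate = x$success_rate,
                 perfect_pct = x$summary$percent[x$summary$category == "Perfect"],
                 missed_pct = x$summary$percent[x$summary$category == "Missed"])
}

#' Bar chart of prediction outcome categories
#'
#' @param object A `prediction_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prediction_summary
#' @export
autoplot.prediction_summary <- function(object, ...) {
  df <- object$summary
  df$category <- factor(df$category,
                        levels = c("Perfect", "Good", "Partial", "Missed"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$percent)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "switching events") +
    ggplot2::theme_minimal()
}
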