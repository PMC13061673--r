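#' Adaptation-rate phase diagram
#'
#' Simulates each `(eps1, eps2)` grid point for `n_realizations` independent
#' runs, averages `R` and `R2` over the final `average_window` steps of each
#' run and over realizations, then classifies the pixel with
#' [classify_state()]. The full-resolution study uses `eps1` on `[0, 0.01]`
#' and `eps2` on `[0, 0.003]` in steps of 1e-4 with 200 realizations of 4e4
#' steps; the default here is a coarser grid sized for interactive use, with
#' every knob exposed.
#'
#' @param eps1_values,eps2_values Grid axes (positive adaptation rates).
#' @param n Number of oscillators (default 10).
#' @param n_realizations Runs per pixel (default 10).
#' @param n_steps Steps per run (default 2e4).
#' @param average_window Final steps averaged (default 1000).
#' @param dt Time step.
#' @param seed Master seed; per-(pixel, realization) seeds derive from it, so
#'   the sweep is reproducible regardless of execution order.
#' @return Object of class `kuramoto_phase_diagram`: a list with `pixels`
#'   (tibble: `eps1`, `eps2`, `mean_R`, `mean_R2`, `label`) and the sweep
#'   settings.
#' @export
sweep_epsilon_grid <- function(eps1_values = seq(0.001, 0.01, by = 0.001),
                               eps2_values = seq(1e-4, 3e-3, by = 5e-4),
                               n = 10, n_realizations = 10, n_steps = 2e4,
                               average_window = 1000, dt = 0.01, seed = 1L) {
  grid <- tidyr::expand_grid(eps1 = eps1_values, eps2 = eps2_values)
  set.seed(seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max,
                                nrow(grid) * n_realizations),
                     nrow(grid), n_realizations)
  avg <- purrr::map(seq_len(nrow(grid)), function(px) {
    rs <- vapply(seq_len(n_realizations), function(r) {
      s <- seed_mat[px, r]
      params <- kuramoto_params(n = n, eps1 = grid$eps1[px],
                                eps2 = grid$eps2[px])
      cfg <- sim_config(dt = dt, n_steps = n_steps, seed = s,
                        store_couplings = FALSE)
      traj <- simulate_kuramoto(params, cfg,
                                sample_initial_condition(n, seed = s))
      idx <- seq.int(nrow(traj$series) - average_window + 1L,
                     nrow(traj$series))
      c(mean(traj$series$R[idx]), mean(traj$series$R2[idx]))
    }, numeric(2))
    c(mean_R = mean(rs[1, ]), mean_R2 = mean(rs[2, ]))
  })
  pixels <- dplyr::bind_cols(grid, dplyr::bind_rows(lapply(avg, as.list)))
  pixels$label <- classify_state(pixels$mean_R, pixels$mean_R2)
  structure(
    list(pixels = pixels, n = n, n_realizations = n_realizations,
         n_steps = n_steps, average_window = average_window, seed = seed),
    class = "kuramoto_phase_diagram"
  )
}

#' @export
print.kuramoto_phase_diagram <- function(x, ...) {
  cat("<kuramoto_phase_diagram>", nrow(x$pixels), "pixels, N =", x$n,
      ",", x$n_realizations, "realizations/pixel\n")
  print(table(x$pixels$label))
  invisible(x)
}

#' Pixel table of a phase diagram
#'
#' @param x A `kuramoto_phase_diagram`.
#' @param ... Unused.
#' @return The `pixels` tibble.
#' @method tidy kuramoto_phase_diagram
#' @export
tidy.kuramoto_phase_diagram <- function(x, ...) x$pixels

#' Categorical heatmap of a phase diagram
#'
#' @param object A `kuramoto_phase_diagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kuramoto_phase_diagram
#' @export
autoplot.kuramoto_phase_diagram <- function(object, ...) {
  ggplot2::ggplot(object$pixels,
                  ggplot2::aes(x = .data$eps1, y = .data$eps2,
                               fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      anti_phase_clusters = "darkorange", incoherent = "grey60",
      in_phase = "steelblue")) +
    ggplot2::labs(x = expression(epsilon[1]), y = expression(epsilon[2]),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Quadratic fit of the coherence-incoherence boundary
#'
#' For each `eps1` column of the diagram the boundary point is the smallest
#' `eps2` labelled incoherent (columns without one are skipped); a quadratic
#' `eps2 = a * eps1^2 + b * eps1 + c` is then least-squares fitted through
#' those points.
#'
#' @param diagram A `kuramoto_phase_diagram`.
#' @return List of class `boundary_fit` with `coefficients` (named `a`, `b`,
#'   `c`), `points` (tibble of boundary points), `residuals`, and
#'   `available` — FALSE (with empty fields) when fewer than 3 boundary
#'   points exist.
#' @export
fit_transition_boundary <- function(diagram) {
  inc <- dplyr::filter(diagram$pixels, .data$label == "incoherent")
  pts <- if (nrow(inc) == 0) {
    tibble::tibble(eps1 = numeric(0), eps2 = numeric(0))
  } else {
    inc |>
      dplyr::group_by(.data$eps1) |>
      dplyr::summarise(eps2 = min(.data$eps2), .groups = "drop")
  }
  if (nrow(pts) < 3) {
    return(structure(list(available = FALSE, points = pts,
                          coefficients = NULL, residuals = NULL),
                     class = "boundary_fit"))
  }
  fit <- stats::lm(eps2 ~ I(eps1^2) + eps1, data = pts)
  co <- stats::coef(fit)
  structure(
    list(available = TRUE,
         coefficients = c(a = unname(co["I(eps1^2)"]),
                          b = unname(co["eps1"]),
                          c = unname(co["(Intercept)"])),
         points = pts,
         residuals = stats::residuals(fit)),
    class = "boundary_fit"
  )
}

#' @export
print.boundary_fit <- function(x, ...) {
  if (!x$available) {
    cat("<boundary_fit> unavailable (fewer than 3 boundary points)\n")
  } else {
    cat("<boundary_fit> eps2 =", format(x$coefficients["a"], digits = 4),
        "* eps1^2 +", format(x$coefficients["b"], digits = 4), "* eps1 +",
        format(x$coefficients["c"], digits = 4), "\n")
    cat("  rms residual:", format(sqrt(mean(x$residuals^2)), digits = 3), "\n")
  }
  invisible(x)
}

#' Noise sweep at fixed initial conditions
#'
#' Reruns the same initial condition under each noise intensity and reports
#' the resulting classification (and event counts when phases are stored), to
#' probe how disorder erodes the metastable two-cluster state.
#'
#' @param sigmas Noise intensities to scan.
#' @param params Baseline [kuramoto_params()] (its `sigma` is overridden).
#' @param config A [sim_config()]; set `store_phases = TRUE` to count events.
#' @param seed Seed for the shared initial condition and the noise streams.
#' @return Tibble with one row per sigma: `sigma`, `mean_R`, `mean_R2`,
#'   `label`, `n_events` (NA unless phases stored), and a list-column
#'   `trajectory`.
#' @export
noise_sweep <- function(sigmas, params, config, seed = 1L) {
  init <- sample_initial_condition(params$n, seed = seed)
  rows <- purrr::map(sigmas, function(sg) {
    p <- params
    p$sigma <- sg
    cfg <- config
    cfg$seed <- seed
    traj <- simulate_kuramoto(p, cfg, init)
    g <- glance(traj)
    n_ev <- if (cfg$store_phases) nrow(detect_switch_events(traj)) else NA_integer_
    tibble::tibble(sigma = sg, mean_R = g$mean_R, mean_R2 = g$mean_R2,
                   label = g$label, n_events = n_ev, trajectory = list(traj))
  })
  dplyr::bind_rows(rows)
}

#' Dwell time versus network connectivity
#'
#' For each target mean degree, samples connected Erdos-Renyi graphs, runs the
#' sparse-variant dynamics and pools the anti-phase dwell intervals over
#' realizations.
#'
#' @param n Number of oscillators (default 10).
#' @param mean_degrees Average degrees to scan; `n - 1` is the complete graph.
#' @param n_realizations Runs per degree (default 20).
#' @param config A [sim_config()].
#' @param eps1,eps2 Adaptation rates (defaults 0.01 / 1e-4).
#' @param r_th Dwell threshold (default 0.8).
#' @param min_duration Dwell intervals shorter than this many steps are
#'   treated as threshold chatter and dropped (default 50, the same scale
#'   used to group individual boundary crossings into one switching event).
#' @param seed Master seed.
#' @return Tibble with one row per degree: `mean_degree`,
#'   `realized_mean_degree` (averaged over samples), `mean_dwell`, `sd_dwell`
#'   (steps), `n_intervals`, `n_resampled` (disconnected draws rejected inside
#'   the graph generator are not counted here; this counts realizations that
#'   needed a fresh graph seed).
#' @export
connectivity_sweep <- function(n = 10, mean_degrees = c(3, 5, 7, 9),
                               n_realizations = 20, config = sim_config(),
                               eps1 = 0.01, eps2 = 1e-4, r_th = 0.8,
                               min_duration = 50, seed = 1L) {
  set.seed(seed)
  seed_mat <- matrix(sample.int(.Machine$integer.max,
                                length(mean_degrees) * n_realizations),
                     length(mean_degrees), n_realizations)
  rows <- purrr::map(seq_along(mean_degrees), function(d) {
    deg <- mean_degrees[d]
    durations <- integer(0)
    realized <- numeric(n_realizations)
    for (r in seq_len(n_realizations)) {
      s <- seed_mat[d, r]
      a <- generate_connected_graph(n, deg, seed = s)
      realized[r] <- attr(a, "realized_mean_degree")
      params <- kuramoto_params(n = n, eps1 = eps1, eps2 = eps2,
                                adjacency = a, variant = "sparse")
      cfg <- config
      cfg$seed <- s
      cfg$store_couplings <- FALSE
      traj <- simulate_kuramoto(params, cfg,
                                sample_initial_condition(n, seed = s))
      sl <- transient_slice(traj)
      dw <- dwell_intervals(traj$series$R[sl], traj$series$R2[sl], r_th,
                            min_duration = min_duration)
      durations <- c(durations, dw$duration)
    }
    tibble::tibble(mean_degree = deg,
                   realized_mean_degree = mean(realized),
                   mean_dwell = if (length(durations)) mean(durations) else 0,
                   sd_dwell = if (length(durations) > 1) stats::sd(durations) else NA_real_,
                   n_intervals = length(durations))
  })
  dplyr::bind_rows(rows)
}

#' Regime scan of the coupling-dependent-frequency variant
#'
#' Classifies the long-run state for each `(gamma0, alpha)` pair of the
#' `"freq_adaptive"` variant and measures the phase separation between the two
#' clusters (the circular distance between the cluster mean phases at the
#' final state).
#'
#' @param gamma0_values,alpha_values Scan axes.
#' @param n Number of oscillators (default 10).
#' @param config A [sim_config()].
#' @param eps1,eps2 Adaptation rates.
#' @param seed Master seed.
#' @return Tibble with `gamma0`, `alpha`, `mean_R`, `mean_R2`, `label`,
#'   `cluster_phase_diff` (radians; NA when no two-cluster structure).
#' @export
gamma_alpha_scan <- function(gamma0_values, alpha_values = 0, n = 10,
                             config = sim_config(), eps1 = 0.01, eps2 = 1e-4,
                             seed = 1L) {
  grid <- tidyr::expand_grid(gamma0 = gamma0_values, alpha = alpha_values)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(g) {
    params <- kuramoto_params(n = n, eps1 = eps1, eps2 = eps2,
                              gamma0 = grid$gamma0[g], alpha = grid$alpha[g],
                              variant = "freq_adaptive")
    cfg <- config
    cfg$seed <- seeds[g]
    traj <- simulate_kuramoto(params, cfg,
                              sample_initial_condition(n, seed = seeds[g]))
    gl <- glance(traj)
    part <- assign_clusters(traj$state$theta)
    pd <- if (isTRUE(attr(part, "no_two_cluster_structure")) ||
              any(part$sizes == 0)) {
      NA_real_
    } else {
      m0 <- Arg(mean(exp(1i * traj$state$theta[part$labels == part$labels[1]])))
      m1 <- Arg(mean(exp(1i * traj$state$theta[part$labels != part$labels[1]])))
      d <- abs(m0 - m1) %% (2 * pi)
      min(d, 2 * pi - d)
    }
    tibble::tibble(gamma0 = grid$gamma0[g], alpha = grid$alpha[g],
                   mean_R = gl$mean_R, mean_R2 = gl$mean_R2,
                   label = gl$label, cluster_phase_diff = pd)
  })
  dplyr::bind_rows(rows)
}
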