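#' Write / read a trajectory
#'
#' The per-step series goes to a plain CSV (`step`, `t`, `R`, `R2`, full
#' double precision); parameters, configuration and seed go to a JSON sidecar
#' (`<path>.json`). Full-resolution phase/velocity matrices and coupling
#' frames are not persisted — regenerate them from the seed.
#'
#' @param trajectory A `kuramoto_trajectory`.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   a `kuramoto_trajectory` (series, params, config, seed; no frames).
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory$series)
  for (cc in c("t", "R", "R2")) df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    format_version = 1L,
    n_rows = nrow(trajectory$series),
    seed = trajectory$seed,
    params = params_to_list(trajectory$params),
    config = unclass(trajectory$config)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) {
    stop("missing sidecar ", meta_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$format_version) || meta$format_version != 1L) {
    stop("unsupported trajectory format version", call. = FALSE)
  }
  df <- utils::read.csv(path)
  if (nrow(df) != meta$n_rows) {
    stop("trajectory file is corrupted: expected ", meta$n_rows,
         " rows, found ", nrow(df), call. = FALSE)
  }
  cfg <- meta$config
  config <- sim_config(dt = cfg$dt, n_steps = cfg$n_steps,
                       transient_fraction = cfg$transient_fraction,
                       record_stride = cfg$record_stride, seed = cfg$seed,
                       store_couplings = cfg$store_couplings,
                       store_phases = cfg$store_phases,
                       store_velocities = cfg$store_velocities)
  traj <- list(series = tibble::as_tibble(df), theta = NULL, vel = NULL,
               k_frames = NULL, frame_steps = NULL, state = NULL,
               params = params_from_list(meta$params), config = config,
               seed = meta$seed)
  class(traj) <- "kuramoto_trajectory"
  traj
}

params_to_list <- function(p) {
  out <- unclass(p)
  out$adjacency <- if (is.null(p$adjacency)) NULL else unclass(p$adjacency)
  out
}

params_from_list <- function(x) {
  kuramoto_params(
    n = x$n, eps1 = x$eps1, eps2 = x$eps2, beta1 = x$beta1, beta2 = x$beta2,
    sigma = x$sigma, omega = x$omega, gamma0 = x$gamma0, alpha = x$alpha,
    adjacency = if (is.null(x$adjacency)) NULL else matrix(unlist(x$adjacency),
                                                           x$n, x$n),
    variant = x$variant
  )
}

#' Run an experiment from a JSON configuration file
#'
#' The configuration names the experiment and its settings:
#'
#' ```json
#' {"experiment": "simulate",
#'  "params": {"n": 10, "eps1": 0.01, "eps2": 1e-4},
#'  "config": {"n_steps": 20000, "seed": 7},
#'  "scale": 1.0}
#' ```
#'
#' `params` accepts every [kuramoto_params()] argument, plus
#' `omega = "normal(mean,std)"` to sample heterogeneous frequencies, and
#' `adjacency_file` pointing at an edge-list text file. `scale` multiplies
#' step counts and realization counts (a value below 1 gives a desk-scale
#' run). Experiments: `simulate`, `stability`, `predict`, `sweep`,
#' `connectivity`, `noise`, `gamma_scan`, `fixtures`.
#'
#' Outputs land in `out_dir`: a trajectory CSV and/or a summary JSON plus a
#' `manifest.json` recording the config hash, seed, and package version, so
#' every artifact is traceable. Rerunning an identical config overwrites with
#' identical content.
#'
#' @param path JSON configuration file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the parsed config and the output file
#'   paths.
#' @export
run_from_config <- function(path, out_dir = dirname(path)) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment <- cfg$experiment %||% "simulate"
  scale <- cfg$scale %||% 1
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  pl <- cfg$params %||% list()
  seed <- cfg$config$seed %||% 1L
  if (!is.null(pl$omega) && is.character(pl$omega)) {
    m <- regmatches(pl$omega,
                    regexec("normal\\(([-0-9.eE+]+),\\s*([-0-9.eE+]+)\\)",
                            pl$omega))[[1]]
    if (length(m) != 3) stop("cannot parse omega spec: ", pl$omega,
                             call. = FALSE)
    set.seed(seed)
    pl$omega <- stats::rnorm(pl$n, as.numeric(m[2]), as.numeric(m[3]))
  }
  if (!is.null(pl$adjacency_file)) {
    pl$adjacency <- read_edge_list(file.path(dirname(path),
                                             pl$adjacency_file), pl$n)
    pl$adjacency_file <- NULL
  }
  params <- do.call(kuramoto_params, pl)

  sc <- cfg$config %||% list()
  n_steps <- max(100L, as.integer((sc$n_steps %||% 2e4) * scale))
  config <- sim_config(dt = sc$dt %||% 0.01, n_steps = n_steps,
                       transient_fraction = sc$transient_fraction %||% 0.30,
                       record_stride = sc$record_stride,
                       seed = seed,
                       store_couplings = sc$store_couplings %||% FALSE,
                       store_phases = sc$store_phases %||% FALSE,
                       store_velocities = sc$store_velocities %||% FALSE)

  outputs <- character(0)
  summary_out <- NULL
  if (experiment == "simulate") {
    traj <- simulate_kuramoto(params, config,
                              sample_initial_condition(params$n, seed = seed))
    traj_path <- file.path(out_dir, "trajectory.csv")
    write_trajectory(traj, traj_path)
    summary_out <- as.list(glance(traj))
    outputs <- c(traj_path, paste0(traj_path, ".json"))
  } else if (experiment == "stability") {
    rep <- spectrum_report(n = params$n)
    summary_out <- list(eigenvalues = rep$eigenvalues,
                        n_positive = rep$n_positive, n_zero = rep$n_zero,
                        n_negative = rep$n_negative,
                        max_deviation = rep$max_deviation)
  } else if (experiment == "predict") {
    ps <- run_prediction_experiment(
      params, config,
      n_realizations = max(1L, as.integer((cfg$n_realizations %||% 10) * scale)),
      tau_win = cfg$tau_win %||% 200, eta_max = cfg$eta_max %||% 500,
      delta_eta = cfg$delta_eta %||% 150,
      grouping_window = cfg$group_window %||% 50, seed = seed)
    ev_path <- file.path(out_dir, "events.csv")
    ev <- ps$events
    if (nrow(ev) > 0) {
      ev$actual <- vapply(ev$actual, paste, "", collapse = ";")
      ev$predicted <- vapply(ev$predicted, paste, "", collapse = ";")
      utils::write.csv(ev, ev_path, row.names = FALSE)
      outputs <- ev_path
    }
    summary_out <- list(summary = ps$summary, success_rate = ps$success_rate,
                        n_events = ps$n_events)
  } else if (experiment == "sweep") {
    pd <- sweep_epsilon_grid(
      n = params$n,
      n_realizations = max(1L, as.integer((cfg$n_realizations %||% 5) * scale)),
      n_steps = n_steps, seed = seed)
    px_path <- file.path(out_dir, "pixels.csv")
    utils::write.csv(pd$pixels, px_path, row.names = FALSE)
    fit <- fit_transition_boundary(pd)
    summary_out <- list(labels = table(pd$pixels$label),
                        boundary_available = fit$available,
                        boundary_coefficients = fit$coefficients)
    outputs <- px_path
  } else if (experiment == "connectivity") {
    tb <- connectivity_sweep(
      n = params$n,
      mean_degrees = cfg$mean_degrees %||% c(3, 5, 7, 9),
      n_realizations = max(1L, as.integer((cfg$n_realizations %||% 10) * scale)),
      config = config, eps1 = params$eps1, eps2 = params$eps2, seed = seed)
    dw_path <- file.path(out_dir, "dwell.csv")
    utils::write.csv(tb, dw_path, row.names = FALSE)
    summary_out <- list(dwell = tb)
    outputs <- dw_path
  } else if (experiment == "noise") {
    tb <- noise_sweep(cfg$sigmas %||% c(0, 1e-5, 1e-3, 0.1), params, config,
                      seed = seed)
    summary_out <- list(
      noise = tb[, c("sigma", "mean_R", "mean_R2", "label", "n_events")])
  } else if (experiment == "gamma_scan") {
    tb <- gamma_alpha_scan(cfg$gamma0_values %||% c(0.1, 0.4, 0.8),
                           cfg$alpha_values %||% 0, n = params$n,
                           config = config, eps1 = params$eps1,
                           eps2 = params$eps2, seed = seed)
    summary_out <- list(gamma_scan = tb)
  } else if (experiment == "fixtures") {
    a <- generate_connected_graph(params$n, cfg$mean_degree %||% (params$n - 1),
                                  seed = seed)
    gpath <- file.path(out_dir, "graph.edges")
    write_edge_list(a, gpath)
    summary_out <- list(realized_mean_degree = attr(a, "realized_mean_degree"))
    outputs <- gpath
  } else {
    stop("unknown experiment: ", experiment, call. = FALSE)
  }

  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_out, summary_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  manifest <- list(
    experiment = experiment, seed = seed, scale = scale,
    config_sha = unname(cli_digest(path)),
    package_version = as.character(utils::packageVersion("adaptkuramoto")),
    outputs = basename(c(outputs, summary_path))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(config = cfg,
                 outputs = c(outputs, summary_path,
                             file.path(out_dir, "manifest.json"))))
}

# content hash of a file without extra dependencies: sum of a simple rolling
# polynomial over bytes, hex-encoded (traceability, not cryptography)
cli_digest <- function(path) {
  bytes <- as.integer(readBin(path, "raw", file.info(path)$size))
  h <- 0
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    h <- (h * 31 + sum(chunk * seq_along(chunk))) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
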