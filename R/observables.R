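#' Kuramoto order parameters of a phase configuration
#'
#' `R e^{i psi} = mean(e^{i theta})` measures global synchrony;
#' `R2 e^{i psi2} = mean(e^{2 i theta})` is large whenever the phases
#' concentrate on two anti-podal points, so `R ~ 0` with `R2 ~ 1` signals two
#' anti-phase clusters.
#'
#' @param theta Numeric phase vector (radians), length >= 1.
#' @return One-row tibble with columns `R`, `psi`, `R2`, `psi2`.
#' @examples
#' order_parameters(c(0, 0, pi, pi)) # R = 0, R2 = 1
#' @export
order_parameters <- function(theta) {
  if (length(theta) < 1L) stop("`theta` must be non-empty", call. = FALSE)
  z1 <- mean(exp(1i * theta))
  z2 <- mean(exp(2i * theta))
  tibble::tibble(R = Mod(z1), psi = Arg(z1), R2 = Mod(z2), psi2 = Arg(z2))
}

#' Classify a collective state from long-time averaged order parameters
#'
#' Both above the threshold: in-phase synchronization. First at or below the
#' threshold while the second exceeds it: two anti-phase clusters. Anything
#' else: incoherent.
#'
#' @param mean_R,mean_R2 Long-time averages in `[0, 1]`; vectorized.
#' @param r_th Classification threshold (default 0.8).
#' @return Character vector with values `"in_phase"`, `"anti_phase_clusters"`
#'   or `"incoherent"`.
#' @examples
#' classify_state(0.3, 0.95)
#' classify_state(0.8, 0.95) # boundary counts as anti-phase clusters
#' @export
classify_state <- function(mean_R, mean_R2, r_th = 0.8) {
  eps <- 1e-9 # round-off margin: |mean(e^{i theta})| can exceed 1 by ulps
  if (any(mean_R < -eps | mean_R > 1 + eps |
            mean_R2 < -eps | mean_R2 > 1 + eps, na.rm = TRUE)) {
    stop("order parameters must lie in [0, 1]", call. = FALSE)
  }
  mean_R <- pmin(pmax(mean_R, 0), 1)
  mean_R2 <- pmin(pmax(mean_R2, 0), 1)
  dplyr::case_when(
    mean_R > r_th & mean_R2 > r_th ~ "in_phase",
    mean_R <= r_th & mean_R2 > r_th ~ "anti_phase_clusters",
    TRUE ~ "incoherent"
  )
}

#' Assign oscillators to the two anti-phase clusters
#'
#' Uses half the angle of the second-order mean field, `psi2 / 2`, as the
#' instantaneous reference direction: oscillator `i` joins cluster 0 if
#' `cos(theta_i - psi2/2) > 0` (ties to cluster 0), else cluster 1. Sizes are
#' reported with `n_a` the cluster containing oscillator 1. The rule is
#' drift-proof: it follows the clusters if the whole configuration rotates.
#'
#' @param theta Numeric phase vector, length >= 2.
#' @param r2_floor Minimum `R2` for a two-cluster structure to be meaningful
#'   (default 0.2); below it the partition is flagged rather than trusted.
#' @return A [cluster_partition()] (reference phase `psi2/2`), with attribute
#'   `no_two_cluster_structure = TRUE` when `R2 < r2_floor`.
#' @examples
#' assign_clusters(c(0, 0, 0, pi))$sizes
#' @export
assign_clusters <- function(theta, r2_floor = 0.2) {
  if (length(theta) < 2L) stop("need at least 2 phases", call. = FALSE)
  op <- order_parameters(theta)
  ref <- op$psi2 / 2
  labels <- ifelse(cos(theta - ref) >= 0, 0L, 1L)
  part <- cluster_partition(labels, reference_phase = ref)
  if (op$R2 < r2_floor) attr(part, "no_two_cluster_structure") <- TRUE
  part
}

# --- trajectory frame machinery ---------------------------------------------

# Unwrap an angle series: remove 2*pi jumps so the series is continuous.
unwrap_angles <- function(x) {
  d <- diff(x)
  d <- (d + pi) %% (2 * pi) - pi
  x[1] + c(0, cumsum(d))
}

# Crossing records for all oscillators of a full-resolution phase matrix
# (n x (S + 1), one column per step). Wraps the compiled tracker: returns the
# unwrapped psi2/2 reference series, the initial anchors (integer multiples
# of pi locating each oscillator's cluster centre in the reference frame),
# and the crossing table with 0-based step indices.
all_crossings <- function(theta_mat, boundary_tol = 0.1) {
  res <- detect_crossings_cpp(theta_mat, boundary_tol)
  n <- nrow(theta_mat)
  tbl <- tibble::tibble(id = res$id, step = res$row - 1L,
                        anchor_after = res$anchor_after)
  list(ref = res$ref, anchor0 = res$anchor0, tbl = tbl,
       by_osc = split(seq_len(nrow(tbl)), factor(tbl$id, levels = seq_len(n))))
}

# absolute anchor (in units of pi) of oscillator i at a 0-based step
anchor_at <- function(ac, i, step) {
  rows <- ac$by_osc[[i]]
  if (length(rows) == 0) return(ac$anchor0[i])
  before <- rows[ac$tbl$step[rows] <= step]
  if (length(before) == 0) ac$anchor0[i] else
    ac$tbl$anchor_after[before[length(before)]]
}

# signed displacement of every oscillator from its own cluster centre at a
# 0-based step, in (-pi, pi]
rel_disp_at <- function(ac, theta_mat, step) {
  n <- nrow(theta_mat)
  a <- vapply(seq_len(n), function(i) anchor_at(ac, i, step), integer(1))
  raw <- theta_mat[, step + 1L] - ac$ref[step + 1L] - pi * (a %% 2L)
  (raw + pi) %% (2 * pi) - pi
}

# Grouped switching events from crossing records. Crossings closer than
# grouping_window steps chain into one collective event; events at or before
# t_min_steps are dropped.
events_from_crossings <- function(ac, grouping_window, t_min_steps) {
  n <- length(ac$anchor0)
  cross_tbl <- ac$tbl[, c("id", "step")]
  empty <- tibble::tibble(event = integer(0), t_step = integer(0),
                          n_switchers = integer(0), ids = list(),
                          pre_labels = list(), post_labels = list())
  if (nrow(cross_tbl) == 0) return(empty)
  cross_tbl <- dplyr::arrange(cross_tbl, .data$step)
  gap <- c(0, diff(cross_tbl$step))
  cross_tbl$event <- cumsum(gap > grouping_window) + 1L
  events <- cross_tbl |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(t_step = min(.data$step),
                     t_last = max(.data$step),
                     ids = list(sort(unique(.data$id))),
                     .groups = "drop") |>
    dplyr::filter(.data$t_step > t_min_steps)
  if (nrow(events) == 0) return(empty)
  labels_at <- function(step) {
    a <- vapply(seq_len(n), function(i) anchor_at(ac, i, step), integer(1))
    as.integer(a %% 2L)
  }
  events$pre_labels <- lapply(events$t_step - 1L, labels_at)
  events$post_labels <- lapply(events$t_last, labels_at)
  events$event <- seq_len(nrow(events))
  events$n_switchers <- lengths(events$ids)
  events[, c("event", "t_step", "n_switchers", "ids",
             "pre_labels", "post_labels")]
}

#' Detect cluster-switching events in a trajectory
#'
#' An oscillator switches when its displacement in the co-moving cluster frame
#' (reference direction `psi2/2`) accumulates a full `pi` from the centre of
#' its current cluster, i.e. it reaches the anti-podal boundary and lands in
#' the opposite cluster. Individual crossings less than `grouping_window`
#' steps apart are merged into one collective event; events at or before
#' `t_min_steps` are discarded.
#'
#' @param trajectory A `kuramoto_trajectory` run with `store_phases = TRUE`.
#' @param grouping_window Merge window in simulation steps (default 50).
#' @param t_min_steps Earliest step counted (default
#'   `transient_fraction * n_steps`).
#' @param boundary_tol Numerical arrival tolerance (radians, default 0.1):
#'   a crossing fires when the displacement reaches `pi - boundary_tol`.
#'   The anti-podal point is the attracting destination of the switch and is
#'   only reached asymptotically, so an exact-`pi` trigger would time-stamp
#'   events thousands of steps into the round-off creep of the arrival.
#' @return Tibble with one row per event: `event` index, `t_step` (0-based
#'   step of the first crossing in the group), `n_switchers`, `ids`
#'   (list-column of oscillator ids), and list-columns `pre_labels` /
#'   `post_labels` of 0/1 cluster labels.
#' @export
detect_switch_events <- function(trajectory, grouping_window = 50,
                                 t_min_steps = NULL, boundary_tol = 0.1) {
  if (is.null(trajectory$theta)) {
    stop("trajectory lacks full-resolution phases; rerun with store_phases = TRUE",
         call. = FALSE)
  }
  t_min_steps <- t_min_steps %||%
    floor(trajectory$config$transient_fraction * trajectory$config$n_steps)
  ac <- all_crossings(trajectory$theta, boundary_tol)
  events_from_crossings(ac, grouping_window, t_min_steps)
}

#' Dwell intervals of the two-cluster anti-phase state
#'
#' Maximal runs of steps with `R < r_th` and `R2 > r_th` — periods spent in
#' (the vicinity of) a two-cluster anti-phase configuration.
#'
#' @param R_series,R2_series Equal-length per-step order-parameter series.
#' @param r_th Threshold (default 0.8).
#' @param min_duration Shortest run (steps) counted as a dwell interval
#'   (default 1, i.e. no filter). Configurations sitting almost exactly on
#'   the threshold — e.g. a near 9:1 cluster split, whose `R` equals the
#'   threshold up to noise — produce runs of a few steps that are threshold
#'   chatter, not lifetimes; sweeps that average lifetimes filter them out.
#' @return Tibble with columns `start`, `end` (1-based indices into the
#'   series) and `duration` (steps, `end - start + 1`).
#' @examples
#' dwell_intervals(rep(0.3, 100), rep(0.95, 100))
#' @export
dwell_intervals <- function(R_series, R2_series, r_th = 0.8,
                            min_duration = 1) {
  if (length(R_series) != length(R2_series)) {
    stop("series must have equal length", call. = FALSE)
  }
  inside <- R_series < r_th & R2_series > r_th
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration
  tibble::tibble(start = starts[keep], end = ends[keep],
                 duration = r$lengths[keep])
}
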