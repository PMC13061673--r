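#' Deterministic phase velocities
#'
#' Right-hand side of the phase equation (noise excluded; the integrator adds
#' the stochastic increment separately).
#'
#' * dense: `dtheta_i/dt = omega_i + (1/N) sum_j k_ij sin(theta_j - theta_i)`
#' * sparse: the sum runs over network neighbours only and is normalised by the
#'   node degree `sum_j A_ij`
#' * freq_adaptive: `dtheta_i/dt = omega_i + (1/N) sum_j k_ij (gamma0 -
#'   sin(theta_i - theta_j + alpha))`
#'
#' @param state A [kuramoto_state()].
#' @param params A [kuramoto_params()].
#' @return Length-`N` numeric vector of phase velocities (radians/time).
#' @examples
#' p <- kuramoto_params(n = 2)
#' st <- kuramoto_state(c(0, pi / 2), matrix(c(0, 1, 1, 0), 2, 2))
#' rhs_phases(st, p) # c(0.5, -0.5)
#' @export
rhs_phases <- function(state, params) {
  check_state_params(state, params)
  th <- state$theta
  n <- params$n
  # diff[i, j] = theta_j - theta_i
  diff <- outer(th, th, function(a, b) b - a)
  if (params$variant == "freq_adaptive") {
    inter <- params$gamma0 - sin(-diff + params$alpha)
    drop(params$omega + (state$k * inter) %*% rep(1, n) / n)
  } else if (params$variant == "sparse") {
    a <- params$adjacency
    deg <- rowSums(a)
    if (any(deg < 1)) stop("sparse variant requires degree >= 1", call. = FALSE)
    drop(params$omega + ((a * state$k * sin(diff)) %*% rep(1, n)) / deg)
  } else {
    drop(params$omega + (state$k * sin(diff)) %*% rep(1, n) / n)
  }
}

#' Deterministic coupling velocities
#'
#' Each directed coupling relaxes at its triangle's rate towards a target set
#' by the instantaneous phase difference:
#' `dk_ij/dt = -eps1 [k_ij + sin(theta_i - theta_j + beta1)]` above the
#' diagonal, `-eps2 [k_ij + sin(theta_i - theta_j + beta2)]` below it, and 0 on
#' the diagonal. In the `"sparse"` variant the whole bracket is multiplied by
#' `A_ij`, so couplings of absent links are frozen at their initial values.
#'
#' @inheritParams rhs_phases
#' @return `N x N` numeric matrix of coupling velocities; zero diagonal.
#' @examples
#' p <- kuramoto_params(n = 2, eps1 = 0.01)
#' st <- kuramoto_state(c(0, 0), matrix(0, 2, 2))
#' rhs_couplings(st, p)[1, 2] # -eps1 * (0 - 1) = 0.01
#' @export
rhs_couplings <- function(state, params) {
  check_state_params(state, params)
  th <- state$theta
  n <- params$n
  # diff_ij[i, j] = theta_i - theta_j (note: opposite sign to rhs_phases)
  dth <- outer(th, th, "-")
  upper <- upper.tri(state$k)
  rate <- matrix(params$eps2, n, n)
  rate[upper] <- params$eps1
  beta <- matrix(params$beta2, n, n)
  beta[upper] <- params$beta1
  dk <- -rate * (state$k + sin(dth + beta))
  if (params$variant == "sparse") dk <- dk * params$adjacency
  diag(dk) <- 0
  dk
}

#' Coupling-dependent effective frequencies
#'
#' In the `"freq_adaptive"` variant each oscillator carries an effective
#' natural frequency `omega_i + (gamma0/N) sum_j k_ij`, which drifts with the
#' adapting couplings even when all bare frequencies are zero.
#'
#' @inheritParams rhs_phases
#' @return Length-`N` numeric vector; equals `params$omega` when `gamma0 = 0`.
#' @export
effective_frequencies <- function(state, params) {
  check_state_params(state, params)
  params$omega + params$gamma0 * rowSums(state$k) / params$n
}

#' Two-cluster anti-phase partition
#'
#' A labelling of the `N` oscillators into cluster 0 (at a reference phase) and
#' cluster 1 (at reference + pi).
#'
#' @param labels Length-`N` vector of 0/1 cluster labels.
#' @param reference_phase Phase of cluster 0 (radians), default 0.
#' @return An object of class `cluster_partition` with fields `labels`,
#'   `sizes` (`n_a` = size of the cluster containing oscillator 1) and
#'   `reference_phase`.
#' @examples
#' cluster_partition(c(0, 0, 1, 1))
#' @export
cluster_partition <- function(labels, reference_phase = 0) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (length(labels) < 2L) stop("need at least 2 oscillators", call. = FALSE)
  n_a <- sum(labels == labels[1])
  structure(
    list(labels = labels, sizes = c(n_a = n_a, n_b = length(labels) - n_a),
         reference_phase = as.numeric(reference_phase)),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> sizes", x$sizes[1], "/", x$sizes[2],
      " ref phase", round(x$reference_phase, 3), "\n")
  invisible(x)
}

#' Exact two-cluster saddle equilibrium
#'
#' Constructs the anti-phase two-cluster fixed point of the dense model with
#' orthogonal phase shifts (`beta1 = -pi/2`, `beta2 = +pi/2`): phases sit at
#' the partition's reference phase or at reference + pi, and every coupling at
#' the unique root of its relaxation ODE — upper couplings +1 within a cluster
#' and -1 across, lower couplings -1 within and +1 across. At this state both
#' right-hand sides vanish identically.
#'
#' @param partition A [cluster_partition()].
#' @param params A [kuramoto_params()] with `variant = "dense"` and orthogonal
#'   `beta1`, `beta2`.
#' @return A [kuramoto_state()] with `rhs_phases()` and `rhs_couplings()` zero
#'   to machine precision.
#' @examples
#' p <- kuramoto_params(n = 4)
#' eq <- equilibrium_two_cluster(cluster_partition(c(0, 0, 1, 1)), p)
#' max(abs(rhs_phases(eq, p)))
#' @export
equilibrium_two_cluster <- function(partition, params) {
  if (params$variant != "dense") {
    stop("two-cluster equilibrium is defined for the dense variant", call. = FALSE)
  }
  if (!isTRUE(all.equal(params$beta1, -pi / 2)) ||
      !isTRUE(all.equal(params$beta2, pi / 2))) {
    stop("equilibrium construction requires beta1 = -pi/2, beta2 = +pi/2",
         call. = FALSE)
  }
  lab <- partition$labels
  if (length(lab) != params$n) {
    stop("partition size does not match params$n", call. = FALSE)
  }
  theta <- partition$reference_phase + pi * lab
  same <- outer(lab, lab, "==")
  k <- matrix(0, params$n, params$n)
  k[upper.tri(k)] <- ifelse(same[upper.tri(same)], 1, -1)
  k[lower.tri(k)] <- ifelse(same[lower.tri(same)], -1, 1)
  kuramoto_state(theta, k, t = 0)
}
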