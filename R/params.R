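#' Model parameters for the non-reciprocal adaptive Kuramoto system
#'
#' Bundles every constant of the coupled phase/coupling dynamics. Phases evolve
#' as `dtheta_i/dt = omega_i + (1/N) sum_j k_ij sin(theta_j - theta_i) + noise`,
#' while each directed coupling relaxes towards a phase-difference-dependent
#' target, `dk_ij/dt = -eps [k_ij + sin(theta_i - theta_j + beta)]`, with the
#' Hebbian rate/shift (`eps1`, `beta1`) on upper-triangle couplings (`i < j`)
#' and the anti-Hebbian pair (`eps2`, `beta2`) on lower-triangle couplings
#' (`i > j`). Non-reciprocity — different rule and time scale per link
#' direction — is what makes the anti-phase two-cluster state metastable.
#'
#' @param n Number of oscillators, `N >= 2`.
#' @param eps1 Adaptation rate of upper (Hebbian) couplings, `> 0` (1/time).
#' @param eps2 Adaptation rate of lower (anti-Hebbian) couplings, `> 0`.
#' @param beta1 Phase shift of the upper adaptation rule (radians). Default
#'   `-pi/2`, the Hebbian choice: co-phased pairs strengthen towards +1.
#' @param beta2 Phase shift of the lower rule (radians). Default `+pi/2`
#'   (anti-Hebbian).
#' @param sigma Intensity of additive Gaussian white phase noise, `>= 0`.
#' @param omega Natural frequencies: a scalar (recycled) or length-`n` vector
#'   (radians/time). Default 0 for all oscillators.
#' @param gamma0 Gain of the coupling-dependent frequency term in the
#'   `"freq_adaptive"` variant, in `[0, 1]`. 0 disables the mechanism.
#' @param alpha Phase lag of the interaction in the `"freq_adaptive"` variant
#'   (radians).
#' @param adjacency Optional symmetric 0/1 matrix with zero diagonal giving the
#'   network for the `"sparse"` variant; must be connected. `NULL` means
#'   all-to-all.
#' @param variant One of `"dense"`, `"sparse"`, `"freq_adaptive"`.
#'
#' @return An object of class `kuramoto_params` (a validated list).
#' @examples
#' p <- kuramoto_params(n = 10, eps1 = 0.01, eps2 = 1e-4)
#' p$beta1
#' @export
kuramoto_params <- function(n,
                            eps1 = 0.01,
                            eps2 = 1e-4,
                            beta1 = -pi / 2,
                            beta2 = pi / 2,
                            sigma = 0,
                            omega = 0,
                            gamma0 = 0,
                            alpha = 0,
                            adjacency = NULL,
                            variant = c("dense", "sparse", "freq_adaptive")) {
  variant <- match.arg(variant)
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.numeric(eps1) || length(eps1) != 1L || eps1 <= 0) {
    stop("`eps1` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(eps2) || length(eps2) != 1L || eps2 <= 0) {
    stop("`eps2` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(gamma0) || length(gamma0) != 1L || gamma0 < 0 || gamma0 > 1) {
    stop("`gamma0` must lie in [0, 1]", call. = FALSE)
  }
  if (length(omega) == 1L) omega <- rep(as.numeric(omega), n)
  if (length(omega) != n) {
    stop("`omega` must be scalar or length `n`", call. = FALSE)
  }
  if (!is.null(adjacency)) {
    adjacency <- validate_adjacency(adjacency, n)
  }
  if (variant == "sparse") {
    if (is.null(adjacency)) {
      # all-to-all network: sparse dynamics on the complete graph
      adjacency <- matrix(1, n, n)
      diag(adjacency) <- 0
    }
    if (any(rowSums(adjacency) < 1)) {
      stop("sparse variant requires every node to have degree >= 1",
           call. = FALSE)
    }
  }
  structure(
    list(n = n, eps1 = eps1, eps2 = eps2, beta1 = beta1, beta2 = beta2,
         sigma = sigma, omega = as.numeric(omega), gamma0 = gamma0,
         alpha = alpha, adjacency = adjacency, variant = variant),
    class = "kuramoto_params"
  )
}

validate_adjacency <- function(a, n) {
  a <- as.matrix(a)
  if (!all(dim(a) == c(n, n))) {
    stop("`adjacency` must be an n x n matrix", call. = FALSE)
  }
  if (!all(a %in% c(0, 1))) stop("`adjacency` must be 0/1", call. = FALSE)
  if (any(diag(a) != 0)) stop("`adjacency` must have zero diagonal", call. = FALSE)
  if (!isTRUE(all.equal(a, t(a)))) stop("`adjacency` must be symmetric", call. = FALSE)
  if (!graph_is_connected(a)) stop("`adjacency` must be connected", call. = FALSE)
  storage.mode(a) <- "double"
  attributes(a) <- list(dim = dim(a)) # drop generator metadata
  a
}

# breadth-first reachability from node 1
graph_is_connected <- function(a) {
  n <- nrow(a)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0) {
    nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.kuramoto_params <- function(x, ...) {
  cat("<kuramoto_params> N =", x$n, " variant =", x$variant, "\n")
  cat("  eps1 =", x$eps1, " eps2 =", x$eps2,
      " beta1 =", round(x$beta1, 4), " beta2 =", round(x$beta2, 4), "\n")
  cat("  sigma =", x$sigma, " gamma0 =", x$gamma0, " alpha =", x$alpha, "\n")
  om <- unique(x$omega)
  if (length(om) == 1L) cat("  omega =", om, "(homogeneous)\n")
  else cat("  omega = heterogeneous, mean", round(mean(x$omega), 4), "\n")
  if (!is.null(x$adjacency)) {
    cat("  adjacency: mean degree", round(mean(rowSums(x$adjacency)), 2), "\n")
  }
  invisible(x)
}

#' Instantaneous system state
#'
#' Phases are stored wrapped to `[0, 2*pi)`; the coupling matrix is directed
#' with an exactly zero diagonal (no self-coupling).
#'
#' @param theta Length-`N` phase vector (radians).
#' @param k `N x N` coupling matrix, diagonal zero.
#' @param t Time attached to the state (default 0).
#' @return An object of class `kuramoto_state`.
#' @examples
#' st <- kuramoto_state(c(0, pi), matrix(c(0, 1, 1, 0), 2, 2))
#' @export
kuramoto_state <- function(theta, k, t = 0) {
  theta <- as.numeric(theta)
  k <- as.matrix(k)
  n <- length(theta)
  if (!all(dim(k) == c(n, n))) {
    stop("`k` must be a square matrix matching length(theta)", call. = FALSE)
  }
  if (any(diag(k) != 0)) stop("diag(k) must be exactly zero", call. = FALSE)
  structure(list(theta = theta %% (2 * pi), k = k, t = as.numeric(t)),
            class = "kuramoto_state")
}

#' @export
print.kuramoto_state <- function(x, ...) {
  cat("<kuramoto_state> N =", length(x$theta), " t =", x$t, "\n")
  cat("  theta:", paste(round(utils::head(x$theta, 6), 3), collapse = " "),
      if (length(x$theta) > 6) "...\n" else "\n")
  invisible(x)
}

check_state_params <- function(state, params) {
  if (length(state$theta) != params$n) {
    stop("state dimension does not match params$n", call. = FALSE)
  }
  invisible(TRUE)
}
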