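#' Jacobian blocks of the coupled dynamics
#'
#' Exact partial derivatives of the phase and coupling right-hand sides with
#' respect to the state `(theta, k)` of the dense model, arranged in four
#' blocks. Coupling coordinates are indexed row-major over `(i, j)` with the
#' frozen diagonal entries kept in place, so the coupling sub-space has
#' dimension `N^2` and the `k`-`k` block is diagonal with entries `-eps1`
#' (upper-triangle coordinates), `-eps2` (lower-triangle), and 0 (diagonal
#' coordinates).
#'
#' At the two-cluster equilibrium the phase-coupling block `J_theta_k`
#' vanishes identically (all pairwise `sin` terms are 0), so the spectrum of
#' the full Jacobian is the union of the spectra of `J_theta_theta` and
#' `J_k_k`; the latter is entirely negative, which reduces the stability
#' question to the phase block.
#'
#' @param state A [kuramoto_state()], typically from
#'   [equilibrium_two_cluster()].
#' @param params A [kuramoto_params()] with `variant = "dense"`.
#' @return List of class `jacobian_blocks` with `j_theta_theta` (`N x N`),
#'   `j_theta_k` (`N x N^2`), `j_k_theta` (`N^2 x N`), `j_k_k_diag` (length
#'   `N^2` diagonal of the coupling-coupling block) and `evaluated_at`.
#' @export
jacobian_blocks <- function(state, params) {
  if (params$variant != "dense") {
    stop("jacobian_blocks supports the dense variant", call. = FALSE)
  }
  check_state_params(state, params)
  n <- params$n
  th <- state$theta
  k <- state$k

  # d(theta_i)/d(theta_j): (1/N) k_ij cos(theta_j - theta_i), diagonal
  # compensates so rows of the block sum to zero contributions
  cosd <- outer(th, th, function(a, b) cos(b - a))
  jtt <- k * cosd / n
  diag(jtt) <- 0
  diag(jtt) <- -rowSums(jtt)

  # coupling coordinate index, row-major over (i, j): idx = (i - 1) * N + j
  cidx <- function(i, j) (i - 1L) * n + j

  # d(theta_i)/d(k_pq): nonzero only for p = i, equals (1/N) sin(theta_q -
  # theta_i)
  jtk <- matrix(0, n, n * n)
  for (i in seq_len(n)) {
    for (q in seq_len(n)) {
      if (q == i) next
      jtk[i, cidx(i, q)] <- sin(th[q] - th[i]) / n
    }
  }

  # d(k_ij)/d(theta): -eps * cos(theta_i - theta_j + beta) * (d/dtheta of the
  # difference): +1 for theta_i, -1 for theta_j
  jkt <- matrix(0, n * n, n)
  jkk <- numeric(n * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      eps <- if (i < j) params$eps1 else params$eps2
      beta <- if (i < j) params$beta1 else params$beta2
      cc <- cos(th[i] - th[j] + beta)
      jkt[cidx(i, j), i] <- -eps * cc
      jkt[cidx(i, j), j] <- eps * cc
      jkk[cidx(i, j)] <- -eps
    }
  }

  structure(
    list(j_theta_theta = jtt, j_theta_k = jtk, j_k_theta = jkt,
         j_k_k_diag = jkk, evaluated_at = state, params = params),
    class = "jacobian_blocks"
  )
}

#' Closed-form phase block at the two-cluster equilibrium
#'
#' With equilibrium couplings at their fixed-point values, every product
#' `k_ij cos(theta_j - theta_i)` equals +1 above the diagonal and -1 below it
#' regardless of the partition, giving off-diagonal entries `+1/N` (upper) and
#' `-1/N` (lower) and a compensating diagonal `-(N - 2 i + 1)/N`. Rows sum to
#' zero (the marginal global phase shift) and the matrix anticommutes with the
#' index-reversal flip: `chi %*% J %*% chi = -J`, which forces the spectrum
#' into plus/minus pairs.
#'
#' @param n System size, `N >= 2`.
#' @return `N x N` numeric matrix.
#' @examples
#' phase_block_at_equilibrium(2) # [[-1/2, 1/2], [-1/2, 1/2]]
#' @export
phase_block_at_equilibrium <- function(n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  m <- matrix(-1 / n, n, n)
  m[upper.tri(m)] <- 1 / n
  diag(m) <- -(n - 2 * seq_len(n) + 1) / n
  m
}

#' Analytic saddle spectrum of the phase block
#'
#' For even `N = 2m` the eigenvalues are the pairs `+-(1 - 2k/N)` for
#' `k = 1, ..., m - 1` plus a double zero; for odd `N = 2m + 1` the pairs run
#' to `k = m` with a single zero. The positive half counts the unstable
#' directions of the two-cluster saddle, so instability grows with system
#' size.
#'
#' @param n System size, `N >= 2`.
#' @return Sorted (decreasing) numeric vector of `N` eigenvalues.
#' @examples
#' analytic_spectrum(4) # 0.5, 0, 0, -0.5
#' @export
analytic_spectrum <- function(n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  m <- n %/% 2
  if (n %% 2 == 0) {
    ks <- seq_len(m - 1)           # empty for N = 2
    pos <- 1 - 2 * ks / n
    sort(c(pos, -pos, 0, 0), decreasing = TRUE)
  } else {
    ks <- seq_len(m)
    pos <- 1 - 2 * ks / n
    sort(c(pos, -pos, 0), decreasing = TRUE)
  }
}

#' Number of unstable directions of the two-cluster saddle
#'
#' @param n System size, `N >= 2`.
#' @return Integer: `m - 1` for `N = 2m`, `m` for `N = 2m + 1`. Non-decreasing
#'   in `N`.
#' @examples
#' count_unstable_directions(10) # 4
#' @export
count_unstable_directions <- function(n) {
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  m <- as.integer(n %/% 2)
  if (n %% 2 == 0) m - 1L else m
}

#' Numerical spectrum versus the analytic prediction
#'
#' Eigendecomposes the phase block at a two-cluster equilibrium (either the
#' closed form for a given `n`, or the `j_theta_theta` block of supplied
#' [jacobian_blocks()]) and compares against [analytic_spectrum()].
#'
#' @param n System size (used when `blocks` is `NULL`).
#' @param blocks Optional [jacobian_blocks()] evaluated at an equilibrium.
#' @param zero_tol Absolute tolerance classifying an eigenvalue as zero
#'   (default 1e-9).
#' @return List of class `spectrum_report`: `eigenvalues` (sorted
#'   decreasing), `predicted`, `max_deviation`, and counts `n_positive`,
#'   `n_negative`, `n_zero`, `n_unstable_predicted`.
#' @export
spectrum_report <- function(n = NULL, blocks = NULL, zero_tol = 1e-9) {
  if (is.null(blocks)) {
    if (is.null(n)) stop("supply `n` or `blocks`", call. = FALSE)
    jtt <- phase_block_at_equilibrium(n)
  } else {
    jtt <- blocks$j_theta_theta
    n <- nrow(jtt)
  }
  ev <- eigen(jtt, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8) {
    warning("non-negligible imaginary parts in the phase-block spectrum")
  }
  ev <- sort(Re(ev), decreasing = TRUE)
  structure(
    list(eigenvalues = ev,
         predicted = analytic_spectrum(n),
         max_deviation = max(abs(ev - analytic_spectrum(n))),
         n_positive = sum(ev > zero_tol),
         n_negative = sum(ev < -zero_tol),
         n_zero = sum(abs(ev) <= zero_tol),
         n_unstable_predicted = count_unstable_directions(n),
         n = n, zero_tol = zero_tol),
    class = "spectrum_report"
  )
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat("<spectrum_report> N =", x$n, "\n")
  cat("  unstable:", x$n_positive, "(predicted", x$n_unstable_predicted, ")",
      " zero:", x$n_zero, " stable:", x$n_negative, "\n")
  cat("  max |numeric - analytic| =", format(x$max_deviation, digits = 3), "\n")
  invisible(x)
}

#' Eigenvalues of a spectrum report, one row each
#'
#' @param x A `spectrum_report`.
#' @param ... Unused.
#' @return Tibble with `index`, `eigenvalue`, `predicted`, `sign_class`.
#' @method tidy spectrum_report
#' @export
tidy.spectrum_report <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$eigenvalues),
    eigenvalue = x$eigenvalues,
    predicted = x$predicted,
    sign_class = dplyr::case_when(
      x$eigenvalues > x$zero_tol ~ "unstable",
      x$eigenvalues < -x$zero_tol ~ "stable",
      TRUE ~ "zero"
    )
  )
}

#' One-row summary of a spectrum report
#'
#' @param x A `spectrum_report`.
#' @param ... Unused.
#' @return One-row tibble with the signed counts and maximal deviation.
#' @method glance spectrum_report
#' @export
glance.spectrum_report <- function(x, ...) {
  tibble::tibble(n = x$n, n_positive = x$n_positive, n_zero = x$n_zero,
                 n_negative = x$n_negative,
                 n_unstable_predicted = x$n_unstable_predicted,
                 max_deviation = x$max_deviation)
}

#' Spectrum plot: numerical eigenvalues against the analytic ladder
#'
#' @param object A `spectrum_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spectrum_report
#' @export
autoplot.spectrum_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$eigenvalue,
                                     colour = .data$sign_class)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "rank", y = "eigenvalue", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Index-reversal flip matrix
#'
#' The anti-diagonal permutation under which the equilibrium phase block
#' anticommutes.
#'
#' @param n Matrix size.
#' @return `n x n` permutation matrix.
#' @export
flip_matrix <- function(n) {
  m <- matrix(0, n, n)
  m[cbind(seq_len(n), rev(seq_len(n)))] <- 1
  m
}
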