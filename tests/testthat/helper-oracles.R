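# Independent reference implementations used to cross-check the production
# (vectorized / compiled) code paths. These are deliberately naive: double
# loops, no shared code with R/.

# phase velocities by literal summation
naive_rhs_phases <- function(theta, k, omega, variant = "dense",
                             adjacency = NULL, gamma0 = 0, alpha = 0) {
  n <- length(theta)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (variant == "dense") {
        acc <- acc + k[i, j] * sin(theta[j] - theta[i])
      } else if (variant == "sparse") {
        acc <- acc + adjacency[i, j] * k[i, j] * sin(theta[j] - theta[i])
      } else {
        if (j != i) {
          acc <- acc + k[i, j] * (gamma0 - sin(theta[i] - theta[j] + alpha))
        }
      }
    }
    denom <- if (variant == "sparse") sum(adjacency[i, ]) else n
    out[i] <- omega[i] + acc / denom
  }
  out
}

# coupling velocities by literal case analysis
naive_rhs_couplings <- function(theta, k, eps1, eps2, beta1, beta2,
                                variant = "dense", adjacency = NULL) {
  n <- length(theta)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (i < j) {
        val <- -eps1 * (k[i, j] + sin(theta[i] - theta[j] + beta1))
      } else {
        val <- -eps2 * (k[i, j] + sin(theta[i] - theta[j] + beta2))
      }
      if (variant == "sparse") val <- val * adjacency[i, j]
      out[i, j] <- val
    }
  }
  out
}

# central finite differences of a vector-valued function
fd_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  jac <- matrix(0, length(f0), length(x))
  for (c in seq_along(x)) {
    xp <- x
    xm <- x
    xp[c] <- xp[c] + h
    xm[c] <- xm[c] - h
    jac[, c] <- (f(xp) - f(xm)) / (2 * h)
  }
  jac
}

# four-category scoring by explicit set relations, for cross-checking
naive_score <- function(p, a) {
  p <- unique(p)
  a <- unique(a)
  inter <- intersect(p, a)
  if (length(p) == length(a) && length(inter) == length(a)) return("Perfect")
  if (length(inter) == length(a)) return("Good")
  if (length(inter) > 0) return("Partial")
  "Missed"
}

# minimal metastable run shared by several tests (cached per session)
metastable_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- kuramoto_params(n = 10, eps1 = 0.01, eps2 = 1e-4)
      cfg <- sim_config(n_steps = 1.2e6, seed = 3, store_phases = TRUE,
                        store_velocities = TRUE, store_couplings = FALSE)
      cache <<- simulate_kuramoto(p, cfg, sample_initial_condition(10, seed = 3))
    }
    cache
  }
})

# smallest lag (in frames) at which a series repeats within tol, or NA;
# a constant series repeats at every lag
periodic_lag <- function(x, tol = 1e-6, min_lag = 1) {
  n <- length(x)
  for (lag in seq.int(min_lag, floor(n / 2))) {
    if (max(abs(x[seq_len(n - lag) + lag] - x[seq_len(n - lag)])) <= tol) {
      return(lag)
    }
  }
  NA_integer_
}
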