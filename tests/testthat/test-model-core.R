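test_that("parameter validation rejects ill-formed inputs", {
  expect_error(kuramoto_params(n = 1), "n")
  expect_error(kuramoto_params(n = 4, eps1 = 0), "eps1")
  expect_error(kuramoto_params(n = 4, eps2 = -1e-4), "eps2")
  expect_error(kuramoto_params(n = 4, sigma = -0.1), "sigma")
  expect_error(kuramoto_params(n = 4, gamma0 = 1.5), "gamma0")
  expect_error(kuramoto_params(n = 4, omega = c(1, 2)), "omega")
  bad <- matrix(1, 4, 4) # nonzero diagonal
  expect_error(kuramoto_params(n = 4, adjacency = bad), "diagonal")
  disconnected <- matrix(0, 4, 4)
  disconnected[1, 2] <- disconnected[2, 1] <- 1
  disconnected[3, 4] <- disconnected[4, 3] <- 1
  expect_error(kuramoto_params(n = 4, adjacency = disconnected), "connected")
})

test_that("phase velocities match hand-evaluated cases", {
  p <- kuramoto_params(n = 2)
  st0 <- kuramoto_state(c(0, 0), matrix(c(0, 0.3, -0.2, 0), 2, 2))
  expect_equal(rhs_phases(st0, p), c(0, 0))

  st <- kuramoto_state(c(0, pi / 2), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(rhs_phases(st, p), c(0.5, -0.5))

  # state dimension mismatch rejected
  expect_error(rhs_phases(st, kuramoto_params(n = 3)), "dimension")
})

test_that("coupling velocities follow the in/cross-cluster slope analysis", {
  p <- kuramoto_params(n = 3, eps1 = 0.01, eps2 = 1e-4)
  # co-phased pair, upper coupling: dk = -eps1 (k - 1), pulled to +1
  k <- matrix(0.25, 3, 3)
  diag(k) <- 0
  st <- kuramoto_state(c(1, 1, 1 + pi), k)
  dk <- rhs_couplings(st, p)
  expect_equal(dk[1, 2], -p$eps1 * (0.25 - 1))
  # anti-phase pair, lower coupling: dk = -eps2 (k - 1)
  expect_equal(dk[3, 1], -p$eps2 * (0.25 - 1))
  # anti-phase pair, upper coupling: pulled to -1
  expect_equal(dk[1, 3], -p$eps1 * (0.25 + 1))
  expect_equal(diag(dk), rep(0, 3))
})

test_that("effective frequencies reduce to omega and to row-sum gain", {
  p0 <- kuramoto_params(n = 10, omega = 0.7, gamma0 = 0,
                        variant = "freq_adaptive")
  k1 <- matrix(1, 10, 10)
  diag(k1) <- 0
  st <- kuramoto_state(runif(10, 0, 2 * pi), k1)
  expect_equal(effective_frequencies(st, p0), rep(0.7, 10))

  p <- kuramoto_params(n = 10, gamma0 = 0.1, variant = "freq_adaptive")
  expect_equal(effective_frequencies(st, p), rep(0.1 * 9 / 10, 10))

  # balanced +-1 rows cancel exactly
  kb <- matrix(0, 4, 4)
  kb[upper.tri(kb)] <- 1
  kb[lower.tri(kb)] <- -1
  kb[1, ] <- -kb[, 1] # make row sums 0: row i has mix summing to 0
  kb2 <- rbind(c(0, 1, -1, 0), c(-1, 0, 1, 0), c(1, -1, 0, 0), c(1, -1, 0, 0))
  pb <- kuramoto_params(n = 4, gamma0 = 0.5, variant = "freq_adaptive")
  stb <- kuramoto_state(rep(0, 4), kb2)
  expect_equal(effective_frequencies(stb, pb), rep(0, 4))
})

test_that("two-cluster equilibrium annihilates both right-hand sides", {
  for (labels in list(c(0, 0, 1, 1), c(0, 1, 0, 1, 1), c(0, rep(1, 9)))) {
    n <- length(labels)
    p <- kuramoto_params(n = n, eps1 = 0.01, eps2 = 1e-4)
    eq <- equilibrium_two_cluster(cluster_partition(labels), p)
    expect_equal(max(abs(rhs_phases(eq, p))), 0)
    expect_lt(max(abs(rhs_couplings(eq, p))), 1e-15)
  }
})

test_that("equilibrium couplings take the signed block pattern", {
  p <- kuramoto_params(n = 4)
  eq <- equilibrium_two_cluster(cluster_partition(c(0, 0, 1, 1)), p)
  expect_equal(eq$k[1, 2], 1)   # same cluster, upper
  expect_equal(eq$k[1, 3], -1)  # opposite cluster, upper
  expect_equal(eq$k[2, 1], -1)  # same cluster, lower
  expect_equal(eq$k[3, 1], 1)   # opposite cluster, lower
  # non-orthogonal shifts rejected
  p2 <- kuramoto_params(n = 4, beta1 = -1.2)
  expect_error(equilibrium_two_cluster(cluster_partition(c(0, 0, 1, 1)), p2),
               "beta")
})

test_that("right-hand sides are invariant under a global phase shift", {
  set.seed(42)
  for (variant in c("dense", "sparse", "freq_adaptive")) {
    n <- 7
    adj <- if (variant == "sparse") generate_connected_graph(n, 4, seed = 5)
           else NULL
    p <- kuramoto_params(n = n, eps1 = 0.02, eps2 = 3e-4, gamma0 = 0.1,
                         alpha = 0.02, adjacency = adj, variant = variant)
    k <- matrix(runif(n * n, -1, 1), n, n)
    diag(k) <- 0
    th <- runif(n, 0, 2 * pi)
    st <- kuramoto_state(th, k)
    st_shift <- kuramoto_state(th + 1.234, k)
    expect_equal(rhs_phases(st_shift, p), rhs_phases(st, p), tolerance = 1e-12)
    expect_equal(rhs_couplings(st_shift, p), rhs_couplings(st, p),
                 tolerance = 1e-12)
  }
})

test_that("sparse variant on the complete graph reproduces dense dynamics", {
  # coupling adaptation is identical on the complete graph; the phase
  # equation differs only in its normalization (node degree N - 1 versus
  # system size N), so velocities match after that rescaling
  set.seed(7)
  n <- 6
  complete <- matrix(1, n, n)
  diag(complete) <- 0
  omega <- rnorm(n, 0, 0.3)
  pd <- kuramoto_params(n = n, omega = omega)
  ps <- kuramoto_params(n = n, omega = omega, adjacency = complete,
                        variant = "sparse")
  for (rep in 1:5) {
    k <- matrix(runif(n * n, -1, 1), n, n)
    diag(k) <- 0
    st <- kuramoto_state(runif(n, 0, 2 * pi), k)
    expect_equal((rhs_phases(st, ps) - omega) * (n - 1) / n,
                 rhs_phases(st, pd) - omega, tolerance = 1e-12)
    expect_equal(rhs_couplings(st, ps), rhs_couplings(st, pd))
  }
})

test_that("frequency-adaptive variant with gamma0 = 0, alpha = 0 equals dense", {
  set.seed(8)
  n <- 5
  pf <- kuramoto_params(n = n, gamma0 = 0, alpha = 0, variant = "freq_adaptive")
  pd <- kuramoto_params(n = n)
  for (rep in 1:5) {
    k <- matrix(runif(n * n, -1, 1), n, n)
    diag(k) <- 0
    st <- kuramoto_state(runif(n, 0, 2 * pi), k)
    expect_equal(rhs_phases(st, pf), rhs_phases(st, pd), tolerance = 1e-14)
  }
})

test_that("vectorized right-hand sides agree with the naive double loop", {
  set.seed(11)
  for (n in c(2, 3, 5, 8, 13, 20)) {
    adj <- generate_connected_graph(n, max(1, n - 2), seed = n)
    for (variant in c("dense", "sparse", "freq_adaptive")) {
      p <- kuramoto_params(n = n, eps1 = 0.013, eps2 = 2e-4, gamma0 = 0.15,
                           alpha = 0.03, omega = rnorm(n, 0, 0.5),
                           adjacency = if (variant == "sparse") adj else NULL,
                           variant = variant)
      k <- matrix(runif(n * n, -1, 1), n, n)
      diag(k) <- 0
      st <- kuramoto_state(runif(n, 0, 2 * pi), k)
      expect_equal(rhs_phases(st, p),
                   naive_rhs_phases(st$theta, k, p$omega, variant,
                                    p$adjacency, p$gamma0, p$alpha),
                   tolerance = 1e-12)
      expect_equal(rhs_couplings(st, p),
                   naive_rhs_couplings(st$theta, k, p$eps1, p$eps2,
                                       p$beta1, p$beta2, variant,
                                       p$adjacency),
                   tolerance = 1e-12)
    }
  }
})

test_that("coupling fixed-point targets stay within [-1, 1]", {
  set.seed(3)
  p <- kuramoto_params(n = 6)
  for (rep in 1:20) {
    st <- kuramoto_state(runif(6, 0, 2 * pi), matrix(0, 6, 6))
    dk <- rhs_couplings(st, p)
    # with k = 0, dk/eps = -sin(...) is the fixed-point target itself
    targets <- dk / ifelse(upper.tri(dk), p$eps1, p$eps2)
    expect_true(all(abs(targets[row(dk) != col(dk)]) <= 1 + 1e-12))
  }
})
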