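test_that("escape-time arithmetic and exclusions follow the definitions", {
  th <- c(0, 0.01, pi, pi - 0.4)
  # oscillator 4 closes 0.002 rad per step towards the boundary
  eta <- estimate_escape_times(th, c(0, 0, 0, 0.2), dt = 0.01,
                               rel_disp = c(0, 0.01, 0, pi - 0.4))
  expect_equal(eta$eta[4], 0.4 / 0.002)
  expect_false(eta$excluded[4])
  # zero-velocity oscillators get infinite ETE and are excluded, not errors
  expect_true(all(is.infinite(eta$eta[c(1, 3)])))
  expect_true(all(eta$excluded[c(1, 3)]))

  # distance pi at displacement 5e-5 per step: eta ~ 62832 > 500 -> excluded
  eta2 <- estimate_escape_times(c(0, pi), c(5e-3, 5e-3), dt = 0.01,
                                rel_disp = c(0, 0))
  expect_gt(eta2$eta[1], 500)
  expect_true(eta2$excluded[1])

  # exactly at the boundary: eta = 0, always the leader
  eta3 <- estimate_escape_times(c(0, 0, pi), c(0.1, 0.01, 0.01), dt = 0.01,
                                rel_disp = c(pi, 0, 0))
  expect_equal(eta3$eta[1], 0)
  expect_equal(predict_switcher_set(eta3)$leader, 1L)

  # eta exactly at the cutoff is kept (exclusion is strict)
  eta4 <- estimate_escape_times(0, 0.2, dt = 0.01, eta_max = 500,
                                rel_disp = pi - 500 * 0.2 * 0.01)
  expect_equal(eta4$eta, 500)
  expect_false(eta4$excluded)
})

test_that("direction filter excludes only movement away from the boundary", {
  th <- c(0.3, -0.3)
  eta_off <- estimate_escape_times(th, c(-1.5, -1.5), dt = 0.01,
                                   rel_disp = th)
  expect_false(any(eta_off$excluded))
  eta_on <- estimate_escape_times(th, c(-1.5, -1.5), dt = 0.01,
                                  rel_disp = th, direction_filter = TRUE)
  expect_true(eta_on$excluded[1])   # moving towards own centre
  expect_false(eta_on$excluded[2])  # moving towards the boundary
})

test_that("predicted set collects everyone within the margin of the leader", {
  pr <- predict_switcher_set(c(100, 240, 260, NA), delta_eta = 150)
  expect_equal(pr$leader, 1L)
  expect_equal(pr$predicted, c(1L, 2L)) # 260 > 250 stays out

  expect_equal(predict_switcher_set(c(NA, 300, NA))$predicted, 2L)
  # ties at the minimum both enter
  expect_equal(predict_switcher_set(c(100, 100, 500))$predicted, c(1L, 2L))
  # all excluded: empty forecast
  empty <- predict_switcher_set(c(NA, NA))
  expect_true(is.na(empty$leader))
  expect_length(empty$predicted, 0)
})

test_that("scoring matches the four set relations on all small subset pairs", {
  expect_equal(score_prediction(3, 3), "Perfect")
  expect_equal(score_prediction(c(3, 7), 3), "Good")
  expect_equal(score_prediction(3, c(3, 7)), "Partial")
  expect_equal(score_prediction(5, 3), "Missed")
  expect_error(score_prediction(1, integer(0)), "non-empty")

  # exhaustive cross-check against the naive implementation, N = 4
  universe <- 1:4
  subsets <- unlist(lapply(0:4, function(k)
    combn(universe, k, simplify = FALSE)), recursive = FALSE)
  for (p in subsets) {
    for (a in subsets) {
      if (length(a) == 0) next
      expect_equal(score_prediction(p, a), naive_score(p, a))
    }
  }
})

test_that("growing the margin can only improve the category", {
  rank_of <- c(Missed = 1, Partial = 2, Good = 3, Perfect = 3)
  set.seed(10)
  for (rep in 1:50) {
    eta <- sample(c(1:600, NA), 8, replace = TRUE)
    a <- sample(1:8, sample(1:3, 1))
    small <- score_prediction(predict_switcher_set(eta, 50)$predicted, a)
    large <- score_prediction(predict_switcher_set(eta, 300)$predicted, a)
    if (all(is.na(eta))) next
    # enlarging delta_eta grows P monotonically
    expect_true(all(predict_switcher_set(eta, 50)$predicted %in%
                      predict_switcher_set(eta, 300)$predicted))
    # the category can only move up the Missed < Partial < Good/Perfect order
    expect_gte(rank_of[[large]], rank_of[[small]])
  }
})

test_that("forecasting a metastable run scores its events coherently", {
  traj <- metastable_trajectory()
  ev <- detect_switch_events(traj)
  fc <- forecast_events(traj, events = ev)
  expect_lte(nrow(fc), nrow(ev))
  expect_true(all(fc$category %in% c("Perfect", "Good", "Partial", "Missed")))
  # every scored event has a non-empty actual set and snapshot before it
  expect_true(all(lengths(fc$actual) >= 1))
  expect_true(all(fc$t_snap == fc$t_step - 200))
  # excluded oscillators never enter the predicted set: leaders are members
  nonempty <- lengths(fc$predicted) > 0
  expect_true(all(mapply(function(l, p) l %in% p,
                         fc$leader[nonempty], fc$predicted[nonempty])))
})

test_that("the prediction experiment is deterministic given its seed", {
  p <- kuramoto_params(n = 6, eps1 = 0.01, eps2 = 1e-4)
  cfg <- sim_config(n_steps = 8e5, store_couplings = FALSE)
  s1 <- run_prediction_experiment(p, cfg, n_realizations = 2, seed = 21)
  s2 <- run_prediction_experiment(p, cfg, n_realizations = 2, seed = 21)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$events$t_step, s2$events$t_step)
  expect_equal(sum(s1$summary$count), s1$n_events)
  if (s1$n_events > 0) {
    expect_equal(sum(s1$summary$percent), 100)
  }
})
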