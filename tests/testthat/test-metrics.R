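test_that("excitation detection on constructed pulses is exact", {
  flat <- data.frame(time = 0:100, x = rep(0.1, 101))
  expect_equal(nrow(detect_excitations(flat, 1)), 0L)

  # triangle crossing the threshold 1 between t = 5 and t = 15
  tri <- data.frame(time = seq(0, 20, by = 0.5),
                    x = 2 - abs(seq(0, 20, by = 0.5) - 10) / 5)
  ev <- detect_excitations(tri, 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset, 5, tolerance = 0.5)
  expect_equal(ev$duration, 10, tolerance = 0.5)
  expect_equal(ev$peak, 2)

  # events touching the trajectory edges are discarded, not mis-timed
  edge <- data.frame(time = 0:10, x = c(5, 5, 0.1, rep(0.1, 6), 5, 5))
  ev2 <- detect_excitations(edge, 1)
  expect_equal(nrow(ev2), 0L)
  expect_equal(attr(ev2, "edge_events"), 2L)
})

test_that("hysteresis groups noisy threshold chatter into one event", {
  t <- 0:12
  x <- c(0, 2, 0.8, 2, 0.8, 2, 0, 0, 2, 0, 2, 0, 0)
  # without hysteresis the dips below 1 split the first burst
  plain <- detect_excitations(data.frame(time = t, x = x), 1)
  expect_equal(nrow(plain), 5L)
  # with a lower bound 0.5 the 0.8-dips no longer end the event
  grouped <- detect_excitations(data.frame(time = t, x = x), 1,
                                lower = 0.5)
  expect_equal(nrow(grouped), 3L)
  # durations still measure time above the threshold only
  expect_lt(grouped$duration[1], diff(range(t[x > 0.5])))
  expect_error(detect_excitations(data.frame(time = t, x = x), 1,
                                  lower = 2), "lower")
})

test_that("detection is threshold-monotone and duration-bounded", {
  set.seed(42)
  for (rep in 1:5) {
    x <- abs(cumsum(rnorm(400, sd = 0.3)))
    traj <- data.frame(time = seq_along(x), x = x)
    thr <- stats::quantile(x, 0.6)
    lo <- detect_excitations(traj, thr)
    hi <- detect_excitations(traj, thr * 1.5)
    expect_lte(nrow(hi), nrow(lo))
    expect_lte(sum(lo$duration), max(traj$time) - min(traj$time))
    expect_true(all(lo$peak >= thr))
    if (nrow(hi) && nrow(lo)) {
      expect_lte(sum(hi$duration), sum(lo$duration))
    }
  }
})

test_that("the closed-form excitation estimate has the right structure", {
  np <- ref_norm(delta_a = 1.5, epsilon = 0.074)
  x0 <- 0.8; y0 <- 20
  tau <- seq(0, 200, by = 0.01)
  x <- analytic_excitation(x0, y0, np, tau)
  expect_equal(x[1], x0)
  expect_lt(x[length(x)], 1e-3)
  # derivative at 0 equals eps (delta_AT y0 - delta_c x0)
  d0 <- (x[2] - x[1]) / 0.01
  expect_equal(d0, np$epsilon * (np$delta_AT * y0 - np$delta_c * x0),
               tolerance = 1e-2)
  # without complexes: pure exponential dilution
  x_free <- analytic_excitation(x0, 0, np, tau)
  expect_equal(x_free, x0 * exp(-np$epsilon * np$delta_c * tau))
})

test_that("excursion comparison is zero against itself and aligns time bases", {
  np <- ref_norm(delta_a = 1.5, epsilon = 0.074)
  fp <- find_fixed_points(np)[[1]]
  tr <- ta_integrate(np, c(0.9 * np$kappa, fp$y), 50 / np$epsilon,
                     representation = "reduced", n_out = 2000L)
  self <- compare_excursion(tr, tr, np$kappa)
  expect_equal(self$max_rel_dev, 0)
  expect_equal(self$excitation_time_rel_diff, 0)
  # resampled copy on a coarser grid stays close
  coarse <- tr[seq(1, nrow(tr), by = 4), ]
  res <- compare_excursion(tr, coarse, np$kappa)
  expect_lt(res$excitation_time_rel_diff, 0.02)
  expect_lt(res$max_rel_dev, 0.2)  # linear interpolation on the steep rise
  # no overlap is flagged rather than silently zero
  low <- data.frame(time = tr$time, x = rep(1e-4, nrow(tr)))
  expect_false(compare_excursion(low, tr, np$kappa)$overlap)
})

test_that("oscillatory excitations recur at the limit-cycle period", {
  np <- ref_norm(delta_a = 3)
  m <- limit_cycle_metrics(np, tau_end = 300 / np$epsilon,
                           n_out = 12000L)
  traj <- m$trajectory
  ev <- detect_excitations(traj[traj$time > max(traj$time) / 2, ],
                           np$kappa)
  expect_gt(nrow(ev), 5L)
  spacing <- diff(ev$onset)
  expect_lt(max(abs(spacing - m$period)) / m$period, 0.02)
  expect_lt(max(abs(ev$duration - m$excitation_time)) /
              m$excitation_time, 0.05)
})
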