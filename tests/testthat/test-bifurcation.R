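# the delta_a branch at eps = 0.074 is reused across the blocks below
branch_da <- continue_branch(ref_norm(epsilon = 0.074), "delta_a",
                             c(1, 3), steps = 31L)

test_that("the fixed-point branch over delta_a has one stability change", {
  expect_equal(nrow(branch_da), 31L)
  expect_true(branch_da$stable[1])
  expect_false(branch_da$stable[nrow(branch_da)])
  flips <- sum(diff(branch_da$stable) != 0)
  expect_equal(flips, 1L)
  # branch is continuous: adjacent fixed points stay close
  expect_lt(max(abs(diff(branch_da$x))), 0.05)
  # delta_AT co-varies with delta_a at fixed F/eps
  np <- ref_norm(epsilon = 0.074)
  np_hi <- taexcite:::branch_params(np, "delta_a", 2.5)
  expect_equal(np_hi$delta_AT / np_hi$delta_a,
               np$delta_AT / np$delta_a, tolerance = 1e-12)
})

test_that("the stability loss is a supercritical Hopf with finite onset period", {
  h <- detect_hopf(branch_da, refine_tol = 1e-3)
  expect_equal(nrow(h), 1L)
  expect_true(h$hopf)
  expect_gt(h$value, 2)
  expect_lt(h$value, 3)
  expect_lt(abs(h$re_lambda), 0.05)
  expect_gt(h$im_lambda, 1)
  expect_equal(h$criticality, "supercritical")
  expect_true(is.finite(h$onset_period) && h$onset_period > 0)

  # just past onset the cycle is already an order of magnitude larger
  # than the fixed point (Canard explosion)
  np_past <- taexcite:::branch_params(ref_norm(epsilon = 0.074),
                                      "delta_a", h$value * 1.01)
  fp <- find_fixed_points(np_past)[[1]]
  m <- limit_cycle_metrics(np_past, tau_end = 600 / np_past$epsilon,
                           n_out = 12000L)
  expect_gt(m$amplitude / fp$x, 10)
})

test_that("sweeping the toxin translation rate also crosses a Hopf", {
  branch_eps <- continue_branch(ref_norm(delta_a = 2), "epsilon",
                                c(0.03, 0.15), steps = 25L)
  h <- detect_hopf(branch_eps, refine_tol = 1e-4)
  expect_equal(sum(h$hopf), 1L)
  expect_gt(h$value[h$hopf], 0.03)
  expect_lt(h$value[h$hopf], 0.15)
  expect_gt(h$im_lambda[h$hopf], 0)
})

test_that("limit-cycle metrics separate quiescent and oscillatory regimes", {
  quiet <- limit_cycle_metrics(ref_norm(delta_a = 1),
                               tau_end = 100 / 0.0738, n_out = 4000L)
  expect_equal(quiet$excitation_time, 0)
  expect_true(is.na(quiet$period))

  osc <- limit_cycle_metrics(ref_norm(delta_a = 3))
  expect_gt(osc$n_cycles, 10L)
  expect_gt(osc$amplitude, ref_norm()$kappa)
  expect_gt(osc$period, osc$excitation_time)
})

test_that("the oscillation period falls with increasing stress", {
  periods <- vapply(seq(2.4, 4, by = 0.4), function(da) {
    limit_cycle_metrics(ref_norm(delta_a = da),
                        tau_end = 300 / 0.0738,
                        n_out = 10000L)$period
  }, numeric(1))
  expect_true(all(diff(periods) < 0))
})

test_that("the excitation-time map is quiet at low stress and positive beyond", {
  np <- ref_norm()
  sw <- sweep_excitation_time(np, c(1, 3.5), c(0.05, 0.12),
                              resolution = 3L, engine = "ode",
                              tau_end = 200 / np$epsilon)
  expect_equal(nrow(sw), 9L)
  low_corner <- sw$excitation_time[sw$delta_a == 1 &
                                     sw$epsilon == 0.05]
  expect_equal(low_corner, 0)
  expect_gt(max(sw$excitation_time, na.rm = TRUE), 0)
})
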