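test_that("volume factor and rate conversions reproduce the reference values", {
  expect_equal(volume_factor(0.6e-18), 3.612e8)
  expect_equal(2 * volume_factor(0.6e-18), volume_factor(1.2e-18))
  expect_error(volume_factor(0), "positive")
  expect_error(volume_factor(-1e-18), "positive")

  a_T <- molar_rate_to_count_rate(1.32e5, 0.6e-18)
  expect_equal(signif(a_T, 3), 3.65e-4)
  expect_equal(molar_rate_to_count_rate(0, 0.6e-18), 0)
  expect_equal(molar_rate_to_count_rate(volume_factor(0.6e-18), 0.6e-18),
               1)
  expect_error(molar_rate_to_count_rate(-1, 0.6e-18), "non-negative")
})

test_that("half-life conversion gives the printed decay rates", {
  expect_equal(round(halflife_to_rate(5.7 * 60), 3), 0.002)
  expect_equal(halflife_to_rate(log(2)), 1)
  expect_equal(signif(halflife_to_rate(40 * 60), 3), 2.89e-4)
  expect_error(halflife_to_rate(0), "positive")
})

test_that("nondimensionalization reproduces the published normalized table", {
  np <- normalize_params(ref_params())
  expect_equal(report_3sf(np$gamma), 7.38)
  expect_equal(report_3sf(np$alpha), 6.74)
  expect_equal(report_3sf(np$epsilon), 0.0738)
  expect_equal(report_3sf(np$kappa), 0.407)
  expect_equal(report_3sf(np$beta), 100)
  expect_equal(report_3sf(np$delta_a), 1.16)
  expect_equal(report_3sf(np$delta_c), 1.96)
  expect_equal(np$n, 2)
  # the rounded-dilution preset preserves the printed dimensional rates
  printed <- ta_params_table1("printed")
  expect_equal(printed$d_c, 0.00028)
  expect_equal(printed$d_a, 0.00231)
})

test_that("normalize/denormalize round-trips to 1e-12 relative error", {
  np <- normalize_params(ref_params())
  back <- normalize_params(denormalize_params(np))
  expect_rel_equal(unlist(unclass(back)), unlist(unclass(np)), 1e-12)

  p <- ref_params()
  p2 <- denormalize_params(normalize_params(p), d_m = p$d_m,
                           b_1 = p$b_1, D = p$D, v_cell = p$v_cell)
  expect_rel_equal(unlist(unclass(p2)), unlist(unclass(p)), 1e-12)
})

test_that("time-unit invariance: pure-rate scalings leave ratio parameters fixed", {
  p <- ref_params()
  c_f <- 3.7
  p_scaled <- ta_params(r_F = p$r_F * c_f, d_m = p$d_m * c_f,
                        d_large = p$d_large * c_f, K_t = p$K_t, n = p$n,
                        b_1 = p$b_1 * c_f, b_2 = p$b_2 * c_f,
                        a_T = p$a_T * c_f, d_c = p$d_c * c_f,
                        d_a = p$d_a * c_f, F = p$F, D = p$D,
                        v_cell = p$v_cell)
  np <- normalize_params(p)
  nps <- normalize_params(p_scaled)
  for (f in c("epsilon", "beta", "delta_a", "delta_c", "delta_AT", "n")) {
    expect_equal(nps[[f]], np[[f]], tolerance = 1e-12)
  }
  # parameters carrying molecule-count scales do change
  expect_false(isTRUE(all.equal(nps$kappa, np$kappa)))
  expect_false(isTRUE(all.equal(nps$alpha, np$alpha)))
})

test_that("stress transformations act on the degradation/translation rates only", {
  p <- ta_params_table1("printed")
  stressed <- apply_stress(p, multiplier_da = 2)
  expect_equal(stressed$d_a, 0.00462)
  expect_equal(unclass(apply_stress(p, 1, 1)), unclass(p))
  other <- setdiff(names(unclass(p)), c("d_a", "b_2"))
  expect_equal(unclass(stressed)[other], unclass(p)[other])

  np <- ref_norm()
  np2 <- apply_stress(np, multiplier_da = 2)
  expect_equal(np2$delta_a, 2 * np$delta_a)
  expect_equal(np2$delta_AT, 2 * np$delta_AT)
  expect_equal(np2$epsilon, np$epsilon)
  # F = delta_AT * epsilon / delta_a is invariant under any stress
  F_of <- function(x) x$delta_AT * x$epsilon / x$delta_a
  np3 <- apply_stress(np, multiplier_da = 1.7, multiplier_eps = 2.3)
  expect_equal(F_of(np3), F_of(np), tolerance = 1e-12)
  expect_error(apply_stress(np, -1), "positive")
})

test_that("normalization commutes with stress application", {
  p <- ref_params()
  a <- normalize_params(apply_stress(p, 1.7, 2.3))
  b <- apply_stress(normalize_params(p), 1.7, 2.3)
  expect_rel_equal(unlist(unclass(a)), unlist(unclass(b)), 1e-12)
  # set_stress hits requested absolute values with delta_AT slaved
  np <- set_stress(normalize_params(p), delta_a = 3, epsilon = 0.1)
  expect_equal(np$delta_a, 3)
  expect_equal(np$epsilon, 0.1)
  expect_equal(np$delta_AT, 0.1 * 3 / 0.1, tolerance = 1e-12)
})

test_that("stress schedules validate their windows", {
  s <- stress_schedule(c(10, 50), c(20, 70), mult_da = 2)
  expect_s3_class(s, "ta_stress_schedule")
  expect_equal(nrow(s), 2L)
  expect_error(stress_schedule(10, 5), "t_end")
  expect_error(stress_schedule(c(0, 5), c(10, 15)), "overlap")
  expect_error(stress_schedule(0, 10, mult_da = 0), "positive")
})

test_that("parameter config files round-trip and the bundled table loads", {
  p <- ref_params()
  tmp <- tempfile(fileext = ".json")
  write_params(p, tmp)
  p2 <- read_params(tmp)
  expect_s3_class(p2, "ta_params")
  expect_rel_equal(unlist(unclass(p2)), unlist(unclass(p)), 1e-12)

  np <- normalize_params(p)
  write_params(np, tmp)
  np2 <- read_params(tmp)
  expect_s3_class(np2, "ta_norm_params")
  expect_rel_equal(unlist(unclass(np2)), unlist(unclass(np)), 1e-12)

  bundled <- read_params(system.file("extdata", "table1.json",
                                     package = "taexcite"))
  expect_s3_class(bundled, "ta_params")
  expect_equal(bundled$d_a, 0.00231)
  expect_equal(bundled$a_T, 0.000365)
  unlink(tmp)
})

test_that("parameter validation rejects unphysical sets", {
  expect_error(ta_params(b_2 = 0.2), "b_2")
  expect_error(ta_params(F = 0), "F")
  expect_error(ta_params(n = 1.5), "integer")
  expect_error(ta_params(d_m = -1), "positive")
  expect_error(ta_norm_params(delta_c = 2, delta_a = 1, beta = 100,
                              alpha = 7, gamma = 7, epsilon = 1.2,
                              kappa = 0.4), "epsilon")
})
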