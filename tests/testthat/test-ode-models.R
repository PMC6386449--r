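test_that("the cleavage Hill function behaves like a sigmoid switch", {
  expect_equal(hill_cleavage(0.407, 0.407, 2), 0.5)
  expect_equal(hill_cleavage(0, 0.407, 2), 0)
  expect_equal(hill_cleavage(2, 1, 2), 0.8)
  x <- seq(0, 5, length.out = 50)
  expect_true(all(diff(hill_cleavage(x, 0.4, 2)) > 0))
})

test_that("the dimensional right-hand side implements the four balance equations", {
  p <- ref_params()
  expect_equal(rhs_full(c(0, 0, 0, 0), p), c(p$r_F * p$D, 0, 0, 0))
  # at T = K_t the cleavage sink runs at half its maximal rate
  M <- 37
  d <- rhs_full(c(M, 0, p$K_t, 0), p)
  no_cleave <- rhs_full(c(M, 0, p$K_t, 0), p,
                        ta_variant(cleavage = FALSE))
  expect_equal(no_cleave[1] - d[1], p$d_large * M / 2)
  expect_error(rhs_full(c(-1, 0, 0, 0), p), "non-negative")
})

test_that("normalized and dimensional models are the same system under the variable scalings", {
  p <- ref_params()
  np <- normalize_params(p)
  eps <- p$b_2 / p$b_1
  # scalings: m = (d_m/(r_F D eps)) M, a/x/y = (d_m/eps) (A/T/AT),
  # tau = d_m t
  sx <- p$d_m / eps
  sm <- p$d_m / (p$r_F * p$D * eps)
  state0_n <- c(m = 20, a = 3, x = 1.2, y = 14)
  state0_d <- c(state0_n[1] / sm, state0_n[2:4] / sx)
  tau_end <- 30
  tr_n <- ta_integrate(np, state0_n, tau_end,
                       representation = "normalized", tol = 1e-10,
                       n_out = 300L)
  tr_d <- ta_integrate(p, state0_d, tau_end / p$d_m,
                       representation = "full", tol = 1e-10,
                       n_out = 300L)
  expect_rel_equal(tr_d$M * sm, tr_n$m, 1e-6)
  expect_rel_equal(tr_d$T * sx, tr_n$x, 1e-6)
  expect_rel_equal(tr_d$AT * sx, tr_n$y, 1e-6)
})

test_that("quasi-steady-state levels match their closed forms and limits", {
  np <- ref_norm()
  expect_equal(mrna_qss(0, np), 1 / np$epsilon)
  expect_equal(mrna_qss(1e9, np), 1 / (np$epsilon * np$beta),
               tolerance = 1e-6)
  expect_equal(mrna_qss(np$kappa, np),
               (1 / np$epsilon) / (1 + (np$beta - 1) / 2))
  expect_equal(antitoxin_qss(0, np),
               np$gamma * mrna_qss(0, np) / np$delta_a)
  # monotone decreasing in the toxin level
  x <- 10^seq(-3, 2, length.out = 120)
  expect_true(all(diff(antitoxin_qss(x, np)) < 0))
  # the mRNA equilibrium with no toxin is 1/eps in the 4-D model too
  d <- rhs_normalized(c(1 / np$epsilon, 5, 0, 0), np)
  expect_equal(d[1], 0)
})

test_that("the reduced model vanishes on its own fixed point and matches the 4-D equilibrium", {
  np <- ref_norm()
  fp <- find_fixed_points(np)[[1]]
  expect_lt(max(abs(rhs_reduced(fp$x, fp$y, np))), 1e-10)
  # the QSSA fixed point is an exact equilibrium of the normalized 4-D
  # system (m and a slaved to x)
  state4 <- c(mrna_qss(fp$x, np), antitoxin_qss(fp$x, np), fp$x, fp$y)
  expect_lt(max(abs(rhs_normalized(state4, np))), 1e-9)
})

test_that("with production and binding off the toxin follows the two-exponential solution", {
  np <- ref_norm()
  np$alpha <- 1e-12
  np$gamma <- 1e-12
  x0 <- 3; y0 <- 20
  tr <- ta_integrate(np, c(x0, y0), 40, representation = "reduced",
                     tol = 1e-10, n_out = 200L)
  expect_rel_equal(tr$x, analytic_excitation(x0, y0, np, tr$time), 1e-6)
})

test_that("the TAT extension conserves complexed toxin bookkeeping", {
  np <- ref_norm(delta_a = 3)
  v <- ta_variant(tat = TRUE)
  tr <- ta_integrate(np, c(1, 5, 1), 50, representation = "tat",
                     variant = v, n_out = 500L)
  # c = y + 2z must obey dc/dtau = alpha (a + y) x - eps (dc + dAT) c;
  # check the identity by comparing two independent finite differences
  dt <- diff(tr$time)
  c_tot <- tr$y + 2 * tr$z
  dc_num <- diff(c_tot) / dt
  mid <- function(v) (v[-1] + v[-length(v)]) / 2
  a_mid <- antitoxin_qss(mid(tr$x), np, v)
  dc_model <- np$alpha * (a_mid + mid(tr$y)) * mid(tr$x) -
    np$epsilon * (np$delta_c + np$delta_AT) * mid(c_tot)
  expect_lt(stats::median(abs(dc_num - dc_model) /
                            pmax(abs(dc_model), 1e-6)), 1e-2)
  # z = 0, y = 0 reduces exactly to the two-variable right-hand side
  expect_equal(rhs_tat(0.5, 0, 0, np)[1:2], rhs_reduced(0.5, 0, np))
})

test_that("inhibition factors reduce to the plain model when switched off", {
  np <- ref_norm()
  v0 <- ta_variant(growth_inhibition = TRUE, translation_inhibition = TRUE,
                   B_t = 0, B_m = 0, S_t = 1, S_m = 1)
  expect_equal(rhs_reduced(0.7, 8, np, v0), rhs_reduced(0.7, 8, np))
  # at extreme toxin levels translation and dilution shut down
  v1 <- ta_variant(growth_inhibition = TRUE,
                   translation_inhibition = TRUE)
  p <- ref_params()
  d_inf <- rhs_full(c(10, 0, 1e12, 0), p, v1)
  expect_lt(abs(d_inf[2]), 1e-6)  # translation suppressed
})

test_that("integration respects equilibria, positivity and stress windows", {
  np <- ref_norm()
  fp <- find_fixed_points(np)[[1]]
  tr <- ta_integrate(np, c(fp$x, fp$y), 100, representation = "reduced",
                     tol = 1e-10, n_out = 200L)
  expect_lt(max(abs(tr$x - fp$x)), 1e-7)
  expect_true(all(tr$x >= 0) && all(tr$y >= 0))

  # a stress window switches parameters exactly at its boundaries
  sched <- stress_schedule(20, 60, mult_da = 2)
  tr_s <- ta_integrate(np, c(fp$x, fp$y), 100,
                       representation = "reduced",
                       stress_schedule = sched, n_out = 500L)
  inside <- ta_integrate(apply_stress(np, 2), c(fp$x, fp$y), 40,
                         representation = "reduced", n_out = 200L)
  i_end <- which.min(abs(tr_s$time - 60))
  expect_equal(tr_s$x[i_end], inside$x[nrow(inside)], tolerance = 1e-5)
  expect_error(ta_integrate(np, c(1, 1), -5), "positive")
  expect_error(ta_integrate(np, c(-1, 1), 5), "non-negative")
})

test_that("halving the tolerance leaves the excitation time essentially unchanged", {
  np <- ref_norm(delta_a = 1.5, epsilon = 0.074)
  fp <- find_fixed_points(np)[[1]]
  et <- sapply(c(1e-8, 5e-9), function(tol) {
    tr <- ta_integrate(np, c(0.9 * np$kappa, fp$y), 60 / np$epsilon,
                       representation = "reduced", tol = tol,
                       n_out = 4000L)
    detect_excitations(tr, np$kappa)$duration[1]
  })
  expect_lt(abs(et[2] - et[1]) / et[1], 0.01)
})
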