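test_that("the sampler is exact on a linear birth-death network", {
  # stationary law of 0 -> X (rate b), X -> 0 (rate d per molecule) is
  # Poisson(b/d): mean = variance = 20
  rs <- birth_death(2, 0.1)
  finals <- vapply(1:500, function(s) {
    tr <- gillespie_run(rs, 0L, 80, seed = s, sample_dt = 20)
    tr$X[nrow(tr)]
  }, numeric(1))
  target <- 20
  se_mean <- sqrt(target / length(finals))
  expect_lt(abs(mean(finals) - target), 3 * se_mean)
  se_var <- target * sqrt(2 / (length(finals) - 1))  # approx for Poisson
  expect_lt(abs(stats::var(finals) - target), 4 * se_var)
})

test_that("pure-decay lifetimes match the exponential mean", {
  d <- 0.05
  rs <- reaction_system("X", list(
    list(change = -1L, rate = d, order = 1, s1 = "X")))
  # area under N(t)/N0 estimates the mean lifetime 1/d
  mean_life <- vapply(1:60, function(s) {
    tr <- gillespie_run(rs, 1000L, 200, seed = s, sample_dt = 0.25)
    sum(tr$X[-nrow(tr)] * diff(tr$time)) / 1000
  }, numeric(1))
  se <- stats::sd(mean_life) / sqrt(length(mean_life))
  expect_lt(abs(mean(mean_life) - 1 / d), 3 * se)
})

test_that("runs are seed-deterministic and absorb at zero propensity", {
  rs <- birth_death(2, 0.1)
  a <- gillespie_run(rs, 5L, 50, seed = 7, sample_dt = 1)
  b <- gillespie_run(rs, 5L, 50, seed = 7, sample_dt = 1)
  c <- gillespie_run(rs, 5L, 50, seed = 8, sample_dt = 1)
  expect_identical(a$X, b$X)
  expect_false(identical(a$X, c$X))

  dead <- reaction_system("X", list(
    list(change = -1L, rate = 0.2, order = 1, s1 = "X")))
  tr <- gillespie_run(dead, 3L, 1000, seed = 1, sample_dt = 10)
  expect_true(attr(tr, "absorbed"))
  expect_equal(tr$X[nrow(tr)], 0)
  expect_true(all(diff(tr$X) <= 0))
})

test_that("reaction channels reproduce the deterministic right-hand side for every variant", {
  p <- ref_params()
  np <- normalize_params(p)
  r_op <- dna_r_from_counts(4.9, np)
  variants <- list(
    minimal = ta_variant(),
    no_cleavage = ta_variant(cleavage = FALSE),
    tat = ta_variant(tat = TRUE),
    dna = ta_variant(dna_binding = TRUE, r = r_op),
    inhibited = ta_variant(growth_inhibition = TRUE,
                           translation_inhibition = TRUE),
    everything = ta_variant(tat = TRUE, dna_binding = TRUE, r = r_op,
                            growth_inhibition = TRUE,
                            translation_inhibition = TRUE))
  set.seed(99)
  for (nm in names(variants)) {
    v <- variants[[nm]]
    rs <- build_reactions(v, p)
    n_sp <- length(rs$species)
    for (k in 1:100) {
      state <- stats::runif(n_sp, 0, 200)
      expect_equal(unname(mean_field_rhs(rs, state)),
                   rhs_full(state, p, v),
                   tolerance = 1e-12, info = nm)
    }
  }
})

test_that("complex decay channels conserve total toxin", {
  rs <- build_reactions(ta_variant(tat = TRUE), ref_params())
  # total toxin = T + AT + 2 TAT; release channels must conserve it
  w <- c(M = 0, A = 0, T = 1, AT = 1, TAT = 2)
  release <- which(rs$class == "d_a" & rs$stoich["T", ] > 0)
  expect_length(release, 2L)
  for (j in release) {
    expect_equal(sum(w * rs$stoich[, j]), 0)
  }
})

test_that("stress windows modulate the stochastic rates in place", {
  # birth-death with the decay channel tagged as d_a: doubling it in a
  # window halves the mean level there
  rs <- reaction_system("X", list(
    list(change = 1L, rate = 5, order = 0),
    list(change = -1L, rate = 0.05, order = 1, s1 = "X",
         class = "d_a")))
  sched <- stress_schedule(1000, 2000, mult_da = 2)
  tr <- gillespie_run(rs, 100L, 3000, seed = 3, sample_dt = 2,
                      stress_schedule = sched)
  mean_in <- mean(tr$X[tr$time > 1400 & tr$time < 2000])
  mean_out <- mean(tr$X[tr$time > 400 & tr$time < 1000])
  expect_lt(abs(mean_out - 100) / 100, 0.15)
  expect_lt(abs(mean_in - 50) / 50, 0.25)
  # identical seeds with the same schedule bit-reproduce
  tr2 <- gillespie_run(rs, 100L, 3000, seed = 3, sample_dt = 2,
                       stress_schedule = sched)
  expect_identical(tr$X, tr2$X)
})

test_that("occupancy mass is conserved and concentrates at a stable fixed point", {
  np <- ref_norm(delta_a = 1)
  p <- denormalize_params(np)
  rs <- build_reactions(ta_variant(), p)
  ic <- initial_counts(np, p)
  tr <- gillespie_run(rs, ic, 5e4, seed = 2, sample_dt = 10)
  hm <- occupancy_heatmap(tr, np, d_m = p$d_m)
  expect_equal(hm$total_time, 5e4, tolerance = 1e-6)
  # monostable regime: most mass within a factor two of the fixed point
  fp <- find_fixed_points(np)[[1]]
  in_box <- outer(hm$x_mid >= fp$x / 2 & hm$x_mid <= fp$x * 2,
                  hm$y_mid >= fp$y / 2 & hm$y_mid <= fp$y * 2)
  expect_gt(sum(hm$counts[in_box]) / sum(hm$counts), 0.5)
})

test_that("stochastic excitations in the excitable regime follow the deterministic orbit", {
  np <- ref_norm(delta_a = 3)
  p <- denormalize_params(np)
  rs <- build_reactions(ta_variant(), p)
  ic <- initial_counts(np, p)
  trajs <- lapply(1:3, function(s) {
    gillespie_run(rs, ic, 1e5, seed = s, sample_dt = 20)
  })
  hm <- occupancy_heatmap(trajs, np, d_m = p$d_m)
  # deterministic limit cycle as reference orbit
  m <- limit_cycle_metrics(np, tau_end = 200 / np$epsilon,
                           n_out = 8000L)
  orbit <- m$trajectory[m$trajectory$time > 100 / np$epsilon, ]
  # super-threshold occupancy should hug the orbit: for bins with
  # x > kappa, the y of most occupancy lies within a factor 2 of the
  # orbit's y at the nearest x
  excited <- which(hm$x_mid > np$kappa)
  mass_near <- 0; mass_tot <- 0
  for (i in excited) {
    # the orbit's y is double-valued in x (rising and falling branch)
    ys <- orbit$y[abs(log(orbit$x / hm$x_mid[i])) < log(1.3)]
    if (!length(ys)) next
    w <- hm$counts[i, ]
    mass_tot <- mass_tot + sum(w)
    near <- hm$y_mid >= min(ys) / 2 & hm$y_mid <= max(ys) * 2
    mass_near <- mass_near + sum(w[near])
  }
  expect_gt(mass_tot, 0)
  expect_gt(mass_near / mass_tot, 0.8)
})
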