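# Exact stochastic simulation (direct-method Gillespie) of the model
# variants, plus occupancy heatmaps and stochastic excitation statistics.
# Propensities are encoded structurally (mass-action order plus an
# optional Hill / repression / saturation modifier) so that the C++ core
# can evaluate them and the mean-field right-hand side can be recovered
# exactly for consistency checks.

#' Build a reaction system
#'
#' Low-level constructor. Each reaction has a stoichiometric change
#' vector, a rate constant, a kinetic order (0 = zeroth, 1 = first order
#' in `s1`, 2 = second order in `s1` and `s2`) and an optional modifier
#' of the propensity evaluated on species `modsp`: `"hill"` multiplies by
#' `X^n/(X^n + K^n)` (`mp1 = K`, `mp2 = n`), `"repress"` by
#' `r/(r + X)` (`mp1 = r`), `"saturate"` by `S/(1 + B X)` (`mp1 = B`,
#' `mp2 = S`).
#'
#' @param species Character vector of species names.
#' @param reactions List of reactions, each a list with fields `change`
#'   (integer vector over species), `rate`, `order`, and optionally `s1`,
#'   `s2` (species names), `mod`, `modsp`, `mp1`, `mp2`, `class` (free
#'   label used to target stress multipliers).
#' @return An object of class `ta_reactions`.
#' @export
reaction_system <- function(species, reactions) {
  n_s <- length(species)
  n_r <- length(reactions)
  stoich <- matrix(0L, n_s, n_r, dimnames = list(species, NULL))
  rate <- numeric(n_r)
  order <- integer(n_r)
  s1 <- integer(n_r); s2 <- integer(n_r)
  mod <- integer(n_r); modsp <- integer(n_r)
  mp1 <- numeric(n_r); mp2 <- numeric(n_r)
  cls <- character(n_r)
  sp_idx <- function(nm) {
    i <- match(nm, species)
    if (is.na(i)) stop("unknown species `", nm, "`", call. = FALSE)
    i
  }
  mods <- c(none = 0L, hill = 1L, repress = 2L, saturate = 3L)
  for (j in seq_len(n_r)) {
    r <- reactions[[j]]
    stoich[, j] <- as.integer(r$change)
    rate[j] <- r$rate
    order[j] <- as.integer(r$order)
    s1[j] <- if (order[j] >= 1L) sp_idx(r$s1) else 1L
    s2[j] <- if (order[j] == 2L) sp_idx(r$s2) else 1L
    m <- if (is.null(r$mod)) "none" else r$mod
    mod[j] <- mods[[m]]
    modsp[j] <- if (mod[j] > 0L) sp_idx(r$modsp) else 1L
    mp1[j] <- if (is.null(r$mp1)) 0 else r$mp1
    mp2[j] <- if (is.null(r$mp2)) 0 else r$mp2
    cls[j] <- if (is.null(r$class)) "" else r$class
  }
  if (any(rate < 0)) stop("rates must be non-negative", call. = FALSE)
  structure(list(species = species, stoich = stoich, rate = rate,
                 order = order, s1 = s1, s2 = s2, mod = mod,
                 modsp = modsp, mp1 = mp1, mp2 = mp2, class = cls),
            class = "ta_reactions")
}

#' Reaction channels of a toxin-antitoxin model variant
#'
#' Builds the stochastic counterpart of the deterministic model, channel
#' by channel, so that the stoichiometry-weighted propensities reproduce
#' the ODE right-hand side exactly (see [mean_field_rhs()]). The minimal
#' variant comprises transcription, the two translations, complex
#' formation, basal and cleavage-induced mRNA decay, antitoxin decay,
#' in-complex antitoxin decay releasing the toxin, and dilution of toxin
#' and complex. The TAT variant adds `AT + T -> TAT`, `TAT -> 2T`
#' (antitoxin degraded in the secondary complex) and TAT dilution. DNA
#' binding multiplies the transcription propensity by `r_c/(r_c + AT)`;
#' inhibition scales translation propensities by `f_m(T)` and dilution
#' propensities by `f_t(T)`.
#'
#' @param variant A [ta_variant()].
#' @param p A [ta_params()] object (dimensional, per-molecule rates).
#' @return A [reaction_system()] with species
#'   `M, A, T, AT[, TAT]`.
#' @export
build_reactions <- function(variant, p) {
  stopifnot(inherits(variant, "ta_variant"), inherits(p, "ta_params"))
  eps <- p$b_2 / p$b_1
  species <- c("M", "A", "T", "AT", if (variant$tat) "TAT")
  ns <- length(species)
  ch <- function(...) {
    v <- integer(ns)
    args <- list(...)
    for (nm in names(args)) v[match(nm, species)] <- args[[nm]]
    v
  }
  d_a2 <- p$F * p$d_a
  # count-space constants of the inhibition / repression functions
  b_m <- variant$B_m * p$d_m / eps
  b_t <- variant$B_t * p$d_m / eps
  r_c <- if (variant$dna_binding) variant$r * eps / p$d_m else NA_real_

  trans_mod <- function() {
    if (variant$translation_inhibition) {
      list(mod = "saturate", modsp = "T", mp1 = b_m, mp2 = variant$S_m)
    } else list()
  }
  dil_mod <- function() {
    if (variant$growth_inhibition) {
      list(mod = "saturate", modsp = "T", mp1 = b_t, mp2 = variant$S_t)
    } else list()
  }
  rx <- list()
  add <- function(base, extra = list()) {
    rx[[length(rx) + 1L]] <<- c(base, extra)
  }
  # transcription (optionally repressed by operator-bound AT)
  add(list(change = ch(M = 1), rate = p$r_F * p$D, order = 0,
           class = "transcription"),
      if (variant$dna_binding) {
        list(mod = "repress", modsp = "AT", mp1 = r_c)
      } else list())
  # translation
  add(list(change = ch(A = 1), rate = p$b_1, order = 1, s1 = "M",
           class = "translation_A"), trans_mod())
  add(list(change = ch(T = 1), rate = p$b_2, order = 1, s1 = "M",
           class = "translation_T"), trans_mod())
  # complex formation
  add(list(change = ch(A = -1, T = -1, AT = 1), rate = p$a_T, order = 2,
           s1 = "A", s2 = "T", class = "binding"))
  # mRNA decay: basal + toxin-induced cleavage
  add(list(change = ch(M = -1), rate = p$d_m, order = 1, s1 = "M",
           class = "mrna_decay"))
  if (variant$cleavage) {
    add(list(change = ch(M = -1), rate = p$d_large, order = 1, s1 = "M",
             mod = "hill", modsp = "T", mp1 = p$K_t, mp2 = p$n,
             class = "cleavage"))
  }
  # antitoxin decay, free and in complex (the latter releases the toxin)
  add(list(change = ch(A = -1), rate = p$d_a, order = 1, s1 = "A",
           class = "d_a"))
  add(list(change = ch(AT = -1, T = 1), rate = d_a2, order = 1,
           s1 = "AT", class = "d_a"))
  # dilution by growth
  add(list(change = ch(T = -1), rate = p$d_c, order = 1, s1 = "T",
           class = "dilution"), dil_mod())
  add(list(change = ch(AT = -1), rate = p$d_c, order = 1, s1 = "AT",
           class = "dilution"), dil_mod())
  if (variant$tat) {
    add(list(change = ch(AT = -1, T = -1, TAT = 1), rate = p$a_T,
             order = 2, s1 = "AT", s2 = "T", class = "binding"))
    add(list(change = ch(TAT = -1, T = 2), rate = d_a2, order = 1,
             s1 = "TAT", class = "d_a"))
    add(list(change = ch(TAT = -1), rate = p$d_c, order = 1, s1 = "TAT",
             class = "dilution"), dil_mod())
  }
  rs <- reaction_system(species, rx)
  attr(rs, "params") <- p
  attr(rs, "variant") <- variant
  rs
}

#' Mean-field right-hand side of a reaction system
#'
#' Stoichiometry-weighted sum of the propensities evaluated at a (real
#' valued) state: the deterministic rate equations implied by the
#' stochastic model. For systems from [build_reactions()] this equals
#' [rhs_full()] at every state, which is the correspondence that lets
#' deterministic and Gillespie simulations be compared.
#'
#' @param rs A [reaction_system()].
#' @param state Numeric state vector (counts, may be non-integer).
#' @return Named numeric vector of time derivatives.
#' @export
mean_field_rhs <- function(rs, state) {
  a <- propensities(rs, state)
  drop(rs$stoich %*% a)
}

propensities <- function(rs, state, mult = NULL) {
  n_r <- length(rs$rate)
  if (is.null(mult)) mult <- rep(1, n_r)
  vapply(seq_len(n_r), function(j) {
    a <- rs$rate[j] * mult[j]
    if (rs$order[j] >= 1L) a <- a * state[rs$s1[j]]
    if (rs$order[j] == 2L) a <- a * state[rs$s2[j]]
    if (rs$mod[j] == 1L) {
      xm <- state[rs$modsp[j]]
      a <- a * xm^rs$mp2[j] / (xm^rs$mp2[j] + rs$mp1[j]^rs$mp2[j])
    } else if (rs$mod[j] == 2L) {
      a <- a * rs$mp1[j] / (rs$mp1[j] + state[rs$modsp[j]])
    } else if (rs$mod[j] == 3L) {
      a <- a * rs$mp2[j] / (1 + rs$mp1[j] * state[rs$modsp[j]])
    }
    max(a, 0)
  }, numeric(1))
}

#' Default initial counts for stochastic runs
#'
#' The deterministic fixed point of the reduced system, converted to
#' molecule counts through the normalization scalings and rounded to
#' integers; mRNA and free antitoxin start at their quasi-steady-state
#' levels. Falls back to a low-toxin state if no fixed point is found.
#'
#' @param np A [ta_norm_params()] object (the normalized counterpart of
#'   `p`).
#' @param p A [ta_params()] object.
#' @param variant A [ta_variant()].
#' @return Integer vector of initial counts matching
#'   [build_reactions()]'s species order.
#' @export
initial_counts <- function(np, p, variant = ta_variant()) {
  eps <- p$b_2 / p$b_1
  scale_x <- eps / p$d_m           # molecules per unit of x, a, y
  scale_m <- p$r_F * p$D * eps / p$d_m
  fps <- suppressWarnings(find_fixed_points(np, variant))
  if (length(fps)) {
    fp <- fps[[1L]]
    m <- mrna_qss(fp$x, np, variant, fp$y)
    a <- antitoxin_qss(fp$x, np, variant, fp$y)
    counts <- c(M = round(m * scale_m), A = round(a * scale_x),
                T = round(fp$x * scale_x), AT = round(fp$y * scale_x))
    if (variant$tat) {
      counts <- c(counts,
                  TAT = round(if (!is.null(fp$z)) fp$z * scale_x else 0))
    }
  } else {
    counts <- c(M = round(p$r_F * p$D / p$d_m),
                A = round(p$b_1 * p$r_F * p$D / (p$d_m * p$d_a)),
                T = 0, AT = 0)
    if (variant$tat) counts <- c(counts, TAT = 0)
  }
  pmax(as.integer(counts), 0L)
}

#' Run an exact stochastic simulation
#'
#' Direct-method Gillespie sampling of a reaction system. A stress
#' schedule is honored by piecewise-constant propensity multipliers:
#' channels whose class is `"d_a"` are scaled by the window's `mult_da`
#' and the toxin translation channel by `mult_eps`; at a window boundary
#' the exponential clock is advanced to the boundary and redrawn, which
#' is exact for piecewise-constant rates. The state is recorded on a
#' regular sampling grid.
#'
#' @param rs A [reaction_system()].
#' @param init_counts Non-negative integer initial counts.
#' @param t_end End time (seconds for dimensional systems).
#' @param seed Integer seed (via [set.seed()]); reproducible event
#'   sequences for equal seeds and inputs.
#' @param sample_dt Sampling interval; default `t_end/2000`.
#' @param stress_schedule Optional [stress_schedule()] in the same time
#'   units.
#' @param max_steps Guard on the number of reaction events.
#' @return A data frame of class `ta_ssa_trajectory` (`time` plus one
#'   column per species) with attributes `seed`, `n_events`, `absorbed`
#'   (all propensities hit zero before `t_end`).
#' @export
gillespie_run <- function(rs, init_counts, t_end, seed,
                          sample_dt = t_end / 2000,
                          stress_schedule = NULL,
                          max_steps = 5e8) {
  stopifnot(inherits(rs, "ta_reactions"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (any(init_counts < 0) || any(init_counts != round(init_counts))) {
    stop("`init_counts` must be non-negative integers", call. = FALSE)
  }
  if (length(init_counts) != length(rs$species)) {
    stop("`init_counts` must have one entry per species", call. = FALSE)
  }
  sample_times <- seq(0, t_end, by = sample_dt)
  if (sample_times[length(sample_times)] < t_end) {
    sample_times <- c(sample_times, t_end)
  }
  n_r <- length(rs$rate)
  if (is.null(stress_schedule)) {
    seg_start <- 0
    seg_mult <- matrix(1, 1L, n_r)
  } else {
    stopifnot(inherits(stress_schedule, "ta_stress_schedule"))
    bounds <- sort(unique(c(0, stress_schedule$t_start,
                            stress_schedule$t_end)))
    bounds <- bounds[bounds < t_end]
    seg_start <- bounds
    seg_mult <- matrix(1, length(bounds), n_r)
    for (k in seq_along(bounds)) {
      mid <- if (k < length(bounds)) {
        (bounds[k] + bounds[k + 1L]) / 2
      } else (bounds[k] + t_end) / 2
      hit <- which(stress_schedule$t_start <= mid &
                     mid < stress_schedule$t_end)
      if (length(hit)) {
        w <- hit[1L]
        seg_mult[k, rs$class == "d_a"] <- stress_schedule$mult_da[w]
        seg_mult[k, rs$class == "translation_T"] <-
          seg_mult[k, rs$class == "translation_T"] *
          stress_schedule$mult_eps[w]
      }
    }
  }
  set.seed(as.integer(seed))
  res <- .ssa_run(rs$stoich, rs$rate, rs$order, rs$s1 - 1L, rs$s2 - 1L,
                  rs$mod, rs$modsp - 1L, rs$mp1, rs$mp2,
                  as.numeric(init_counts), sample_times,
                  seg_start, seg_mult, max_steps)
  traj <- as.data.frame(cbind(sample_times, res$counts))
  names(traj) <- c("time", rs$species)
  structure(traj, class = c("ta_ssa_trajectory", "data.frame"),
            seed = as.integer(seed), n_events = res$n_events,
            absorbed = res$absorbed, source = "ssa",
            variant = attr(rs, "variant"),
            volume_factor = if (!is.null(attr(rs, "params"))) {
              volume_factor(attr(rs, "params")$v_cell)
            } else NULL)
}

#' Time-weighted occupancy of the (toxin, complex) plane
#'
#' Bins the visited `(T, AT)` counts of one or more stochastic
#' trajectories, weighting each visit by the time spent, after
#' converting counts to the normalized `(x, y)` coordinates. States with
#' zero toxin cannot be shown on logarithmic axes and are excluded when
#' `log_scale` is `TRUE`.
#'
#' @param trajs A `ta_ssa_trajectory` or list of them.
#' @param np The [ta_norm_params()] of the system (for the count-to-`x`
#'   conversion, which needs `epsilon` and the mRNA decay anchor).
#' @param d_m mRNA decay anchor (s^-1) used in the conversion.
#' @param x_bins,y_bins Bin edges in normalized units, or a single count
#'   for automatic log-spaced bins.
#' @param log_scale Exclude zero-toxin states (log axes)?
#' @return A list with `counts` (matrix of occupancy times), `x_mid`,
#'   `y_mid` (bin midpoints) and `total_time`.
#' @export
occupancy_heatmap <- function(trajs, np, d_m = 0.002, x_bins = 60L,
                              y_bins = 60L, log_scale = TRUE) {
  if (inherits(trajs, "data.frame")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  scale <- d_m / np$epsilon  # x per molecule
  pool_x <- numeric(0); pool_y <- numeric(0); pool_w <- numeric(0)
  for (tr in trajs) {
    t <- tr$time
    w <- c(diff(t), 0)
    pool_x <- c(pool_x, tr$T * scale)
    pool_y <- c(pool_y, tr$AT * scale)
    pool_w <- c(pool_w, w)
  }
  total_time <- sum(pool_w)
  if (log_scale) {
    keep <- pool_x > 0 & pool_y > 0
    pool_x <- pool_x[keep]; pool_y <- pool_y[keep]
    pool_w <- pool_w[keep]
  }
  edges <- function(v, bins) {
    if (length(bins) > 1L) return(bins)
    rng <- range(v[v > 0])
    10^seq(log10(rng[1L]) - 1e-9, log10(rng[2L]) + 1e-9,
           length.out = bins + 1L)
  }
  xe <- edges(pool_x, x_bins)
  ye <- edges(pool_y, y_bins)
  ix <- findInterval(pool_x, xe, rightmost.closed = TRUE)
  iy <- findInterval(pool_y, ye, rightmost.closed = TRUE)
  ok <- ix >= 1L & ix <= length(xe) - 1L & iy >= 1L & iy <= length(ye) - 1L
  counts <- matrix(0, length(xe) - 1L, length(ye) - 1L)
  for (k in which(ok)) {
    counts[ix[k], iy[k]] <- counts[ix[k], iy[k]] + pool_w[k]
  }
  list(counts = counts,
       x_mid = sqrt(xe[-1L] * xe[-length(xe)]),
       y_mid = sqrt(ye[-1L] * ye[-length(ye)]),
       total_time = total_time)
}

#' Excitation statistics over stochastic trajectories
#'
#' Pools the super-threshold events of one or more trajectories (free
#' toxin above `K_t`, edge events discarded) and reports the mean and
#' standard deviation of the excitation time, the mean spacing of event
#' onsets (period) and the mean peak level.
#'
#' @param trajs A `ta_ssa_trajectory` or list of them.
#' @param K_t Threshold in molecules.
#' @param lower Hysteresis bound passed to [detect_excitations()]; the
#'   default `K_t/2` keeps shot noise around the threshold from
#'   splitting one excitation into many brief events.
#' @return A list with `n_events`, `mean_excitation_time`,
#'   `sd_excitation_time`, `mean_period`, `mean_amplitude`. With no
#'   events the mean excitation time is 0 and the other metrics `NA`.
#' @export
excitation_stats <- function(trajs, K_t, lower = K_t / 2) {
  if (inherits(trajs, "data.frame")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1L)
  durations <- numeric(0)
  peaks <- numeric(0)
  periods <- numeric(0)
  for (tr in trajs) {
    ev <- detect_excitations(tr, K_t, species = "T", lower = lower)
    durations <- c(durations, ev$duration)
    peaks <- c(peaks, ev$peak)
    if (nrow(ev) > 1L) periods <- c(periods, diff(ev$onset))
  }
  if (!length(durations)) {
    return(list(n_events = 0L, mean_excitation_time = 0,
                sd_excitation_time = NA_real_, mean_period = NA_real_,
                mean_amplitude = NA_real_))
  }
  list(n_events = length(durations),
       mean_excitation_time = mean(durations),
       sd_excitation_time = stats::sd(durations),
       mean_period = if (length(periods)) mean(periods) else NA_real_,
       mean_amplitude = mean(peaks))
}
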