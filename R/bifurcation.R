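# Natural-parameter continuation of the reduced system's fixed point over
# the stress parameters, Hopf detection with empirical criticality, limit
# cycle metrics and two-parameter excitation-time sweeps.

#' Continue the fixed point over a stress parameter
#'
#' Tracks the reduced system's fixed point while `delta_a` or `epsilon`
#' varies, using the previous solution as the Newton seed
#' (natural-parameter continuation; the branch has no folds over the
#' scanned ranges). The in-complex degradation fraction
#' `F = delta_AT * epsilon / delta_a` is held fixed, so `delta_AT`
#' co-varies with the swept parameter.
#'
#' @param np Base [ta_norm_params()] object.
#' @param param `"delta_a"` or `"epsilon"`.
#' @param range Positive parameter range (length 2).
#' @param steps Number of branch points (>= 10).
#' @param variant A [ta_variant()].
#' @return A data frame of class `ta_branch` with columns `param`,
#'   `value`, `x`, `y`, `re_lambda` (largest real part), `im_lambda`
#'   (matching imaginary part magnitude), `stable`, `oscillatory`. If
#'   Newton diverges mid-branch the branch is truncated with a warning.
#' @export
continue_branch <- function(np, param = c("delta_a", "epsilon"), range,
                            steps = 40L, variant = ta_variant()) {
  param <- match.arg(param)
  stopifnot(length(range) == 2L, all(range > 0), steps >= 10L)
  values <- seq(range[1L], range[2L], length.out = steps)
  rows <- vector("list", length(values))
  seed <- NULL
  for (i in seq_along(values)) {
    np_i <- branch_params(np, param, values[i])
    rhs_fn <- function(s) rhs_reduced(s[1], s[2], np_i, variant)
    root <- if (!is.null(seed)) newton_solve(rhs_fn, seed) else NULL
    if (is.null(root)) {
      fps <- suppressWarnings(find_fixed_points(np_i, variant))
      if (length(fps) == 0L) {
        warning("continuation truncated at ", param, " = ", values[i],
                ": no fixed point found")
        rows <- rows[seq_len(i - 1L)]
        break
      }
      fp <- fps[[1L]]
      root <- c(fp$x, fp$y)
    }
    seed <- root
    fp <- new_fixed_point(root, np_i, variant, rhs_fn)
    lead <- which.max(Re(fp$eigenvalues))
    rows[[i]] <- data.frame(param = param, value = values[i],
                            x = fp$x, y = fp$y,
                            re_lambda = Re(fp$eigenvalues[lead]),
                            im_lambda = abs(Im(fp$eigenvalues[lead])),
                            stable = fp$stable,
                            oscillatory = fp$oscillatory)
  }
  branch <- do.call(rbind, rows)
  structure(branch, class = c("ta_branch", "data.frame"),
            np = np, variant = variant)
}

# normalized set at a branch point: swept parameter replaced, delta_AT
# slaved through the fixed fraction F
branch_params <- function(np, param, value) {
  if (param == "delta_a") set_stress(np, delta_a = value)
  else set_stress(np, epsilon = value)
}

#' Detect Hopf bifurcations along a branch
#'
#' Scans the branch for sign changes in the leading eigenvalue's real
#' part, refines each crossing by bisection on fresh fixed-point solves,
#' and classifies the crossing as a Hopf point when the eigenvalues are
#' complex there. Criticality is decided empirically by probing for a
#' coexisting large-amplitude attractor on the stable side of the
#' crossing: a subcritical Hopf comes with a fold of cycles, so a strong
#' kick just below onset keeps the system cycling, whereas near a
#' supercritical Hopf the kicked trajectory fires at most one excursion
#' and settles back to the fixed point. (The emerging cycle itself is
#' not usable here: a Canard explosion can inflate it to full size
#' within a parameter window narrower than the numerical precision of
#' the crossing.)
#'
#' @param branch A [continue_branch()] result.
#' @param refine_tol Bisection tolerance on the parameter.
#' @param side_offset Relative parameter offset of the coexistence probe
#'   on the stable side of the crossing.
#' @return A data frame with one row per crossing: `value`, `re_lambda`,
#'   `im_lambda`, `hopf` (imaginary part nonzero), `criticality`
#'   (`"supercritical"`, `"subcritical"` or `NA` for non-Hopf
#'   crossings), and `onset_period` (`2 pi / im_lambda`).
#' @export
detect_hopf <- function(branch, refine_tol = 1e-4,
                        side_offset = 5e-3) {
  stopifnot(inherits(branch, "ta_branch"))
  np <- attr(branch, "np")
  variant <- attr(branch, "variant")
  param <- branch$param[1L]
  re <- branch$re_lambda
  idx <- which(re[-1L] * re[-length(re)] < 0)
  if (!length(idx)) {
    return(data.frame(value = numeric(0), re_lambda = numeric(0),
                      im_lambda = numeric(0), hopf = logical(0),
                      criticality = character(0),
                      onset_period = numeric(0)))
  }
  eig_at <- function(value) {
    np_i <- branch_params(np, param, value)
    fps <- suppressWarnings(find_fixed_points(np_i, variant))
    if (!length(fps)) return(NULL)
    ev <- fps[[1L]]$eigenvalues
    lead <- which.max(Re(ev))
    list(re = Re(ev[lead]), im = abs(Im(ev[lead])), fp = fps[[1L]])
  }
  out <- lapply(idx, function(i) {
    lo <- branch$value[i]; hi <- branch$value[i + 1L]
    f_lo <- re[i]
    while (hi - lo > refine_tol) {
      mid <- (lo + hi) / 2
      e <- eig_at(mid)
      if (is.null(e)) break
      if (sign(e$re) == sign(f_lo)) lo <- mid else hi <- mid
    }
    value <- (lo + hi) / 2
    e <- eig_at(value)
    hopf <- !is.null(e) && e$im > 1e-9
    crit <- NA_character_
    if (hopf) {
      # probe the stable side with a strong kick: sustained cycling
      # there means a coexisting large cycle (subcritical)
      direction <- if (re[i + 1L] > 0) 1 else -1
      below <- value * (1 - direction * side_offset)
      np_below <- branch_params(np, param, below)
      fps <- suppressWarnings(find_fixed_points(np_below, variant))
      if (length(fps) == 1L) {
        fp <- fps[[1L]]
        traj <- ta_integrate(np_below, c(10 * np_below$kappa, fp$y),
                             400 / np_below$epsilon,
                             representation = "reduced",
                             variant = variant, n_out = 8000L)
        tail_x <- traj$x[traj$time > 0.7 * max(traj$time)]
        sustained <- any(tail_x > np_below$kappa)
        crit <- if (sustained) "subcritical" else "supercritical"
      }
    }
    data.frame(value = value,
               re_lambda = if (is.null(e)) NA_real_ else e$re,
               im_lambda = if (is.null(e)) NA_real_ else e$im,
               hopf = hopf,
               criticality = crit,
               onset_period = if (hopf) 2 * pi / e$im else NA_real_)
  })
  do.call(rbind, out)
}

#' Limit-cycle metrics of the reduced system
#'
#' Integrates a long run, discards the transient half, detects cycles by
#' successive upward crossings of the cleavage threshold `kappa`, and
#' reports the mean amplitude (maximum `x` per cycle), period (spacing of
#' upward crossings) and excitation time (time above `kappa` per cycle).
#' For an excitable (non-oscillatory) system supply a super-threshold
#' `kick` to measure the single resulting excitation; without crossings
#' the excitation time is zero and period/amplitude are `NA`.
#'
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()].
#' @param tau_end Run length in tau units (default `500/eps`).
#' @param transient Fraction of the run discarded as transient.
#' @param kick Optional initial toxin level (normalized); defaults to a
#'   small displacement off the fixed point.
#' @param n_out Output samples.
#' @return A list with `amplitude`, `period`, `excitation_time`,
#'   `n_cycles`, and the trajectory used (`trajectory`).
#' @export
limit_cycle_metrics <- function(np, variant = ta_variant(),
                                tau_end = 500 / np$epsilon,
                                transient = 0.5, kick = NULL,
                                n_out = 20000L) {
  fps <- suppressWarnings(find_fixed_points(np, variant))
  if (length(fps)) {
    fp <- fps[[1L]]
    state0 <- c(if (is.null(kick)) fp$x * 1.2 else kick, fp$y)
    if (variant$tat) state0 <- c(state0, if (!is.null(fp$z)) fp$z else 0)
  } else {
    state0 <- c(if (is.null(kick)) np$kappa else kick, 1)
    if (variant$tat) state0 <- c(state0, 0)
  }
  rep <- if (variant$tat) "tat" else "reduced"
  traj <- ta_integrate(np, state0, tau_end, representation = rep,
                       variant = variant, n_out = n_out)
  keep <- traj$time >= transient * tau_end
  t <- traj$time[keep]
  x <- traj$x[keep]
  up <- which(x[-1L] > np$kappa & x[-length(x)] <= np$kappa)
  if (length(up) < 2L) {
    ev <- detect_excitations(traj, np$kappa)
    return(list(amplitude = if (nrow(ev)) max(ev$peak) else NA_real_,
                period = NA_real_,
                excitation_time = if (nrow(ev)) mean(ev$duration) else 0,
                n_cycles = nrow(ev), trajectory = traj))
  }
  ev <- detect_excitations(data.frame(time = t, x = x), np$kappa)
  list(amplitude = mean(ev$peak),
       period = mean(diff(t[up])),
       excitation_time = mean(ev$duration),
       n_cycles = length(up), trajectory = traj)
}

#' Two-parameter excitation-time map
#'
#' Mean excitation time over a grid of the stress parameters `delta_a`
#' and `epsilon` (normalized space; `delta_AT` co-varies through the
#' fixed fraction `F`). Each cell is measured either from the reduced
#' ODE limit cycle ([limit_cycle_metrics()]) or from pooled Gillespie
#' runs ([excitation_stats()] over `seeds`). Cells without excitations
#' are 0; cells whose computation fails are recorded as `NA` and the
#' sweep continues.
#'
#' @param np Base [ta_norm_params()] object.
#' @param delta_a_range,eps_range Positive ranges.
#' @param resolution Grid points per axis (recycled to length 2).
#' @param engine `"ode"` or `"ssa"`.
#' @param variant A [ta_variant()].
#' @param seeds Integer seeds for the SSA engine.
#' @param t_end_ssa SSA run length in seconds.
#' @param tau_end ODE run length in tau units.
#' @return A data frame of class `ta_sweep` with columns `delta_a`,
#'   `epsilon`, `excitation_time` (tau units), `sd` (SSA only) and `n`.
#' @export
sweep_excitation_time <- function(np, delta_a_range, eps_range,
                                  resolution = 8L,
                                  engine = c("ode", "ssa"),
                                  variant = ta_variant(),
                                  seeds = 1:4,
                                  t_end_ssa = 2e5,
                                  tau_end = 300 / np$epsilon) {
  engine <- match.arg(engine)
  stopifnot(all(delta_a_range > 0), all(eps_range > 0))
  resolution <- rep_len(as.integer(resolution), 2L)
  das <- seq(delta_a_range[1L], delta_a_range[2L],
             length.out = resolution[1L])
  eps <- seq(eps_range[1L], eps_range[2L], length.out = resolution[2L])
  grid <- expand.grid(delta_a = das, epsilon = eps)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    np_i <- set_stress(np, delta_a = grid$delta_a[i],
                       epsilon = grid$epsilon[i])
    tryCatch({
      if (engine == "ode") {
        lab <- classify_regime(np_i, variant)
        if (identical(as.character(lab), "oscillatory")) {
          m <- limit_cycle_metrics(np_i, variant, tau_end = tau_end,
                                   n_out = 8000L)
          c(m$excitation_time, NA_real_, m$n_cycles)
        } else {
          c(0, NA_real_, 0)
        }
      } else {
        p_i <- denormalize_params(np_i)
        rs <- build_reactions(variant, p_i)
        trajs <- lapply(seeds, function(s) {
          gillespie_run(rs, initial_counts(np_i, p_i, variant), t_end_ssa,
                        seed = s, sample_dt = t_end_ssa / 4000)
        })
        st <- excitation_stats(trajs, p_i$K_t)
        # convert seconds to tau units for comparability with the ODE map
        c(st$mean_excitation_time * p_i$d_m, st$sd_excitation_time * p_i$d_m,
          st$n_events)
      }
    }, error = function(e) c(NA_real_, NA_real_, NA_real_))
  })
  res <- do.call(rbind, res)
  out <- cbind(grid, data.frame(excitation_time = res[, 1L],
                                sd = res[, 2L], n = res[, 3L]))
  structure(out, class = c("ta_sweep", "data.frame"), engine = engine)
}
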