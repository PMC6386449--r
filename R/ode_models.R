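# Right-hand sides for the deterministic model variants and their
# integration. Three representations are supported: the dimensional 4-ODE
# model (M, A, T, AT), its normalized form (m, a, x, y), and the 2-D
# quasi-steady-state reduction (x, y) with mRNA and antitoxin slaved to
# the toxin level. The secondary-complex (TAT) extension adds z, and the
# growth/translation inhibition extension scales translation terms by
# f_m(x) = S_m/(1 + B_m x) and dilution terms by f_t(x) = S_t/(1 + B_t x).

#' Hill-modulated mRNA cleavage fraction
#'
#' Fraction of the maximal cleavage-induced mRNA decay that is active at
#' toxin level `x`: `x^n / (x^n + K^n)`. Monotone increasing, 0 at `x = 0`
#' and 1/2 at the threshold `x = K`.
#'
#' @param x Toxin level (counts or normalized), non-negative.
#' @param K Cleavage threshold (same units as `x`), positive.
#' @param n Hill coefficient (>= 1).
#' @return Cleavage fraction in `[0, 1]`, vectorized over `x`.
#' @export
hill_cleavage <- function(x, K, n) {
  stopifnot(all(x >= 0), K > 0, n >= 1)
  xn <- x^n
  xn / (xn + K^n)
}

#' Model variant selection
#'
#' Flags selecting the interactions included in a model. The minimal
#' system has toxin-induced mRNA cleavage only; `tat` adds the secondary
#' complex TAT (one antitoxin neutralizing two toxins); `dna_binding` adds
#' transcriptional autoregulation, the complex AT binding the operator and
#' repressing transcription by a factor `r/(r + y)`; the inhibition flags
#' add growth-rate suppression (`f_t` scaling all dilution terms) and
#' translational inhibition (`f_m` scaling all translation terms) at high
#' free toxin.
#'
#' @param cleavage Include toxin-induced mRNA cleavage?
#' @param tat Include the secondary complex TAT?
#' @param dna_binding Include operator binding by AT?
#' @param r Dimensionless operator-binding parameter in normalized `y`
#'   units; required when `dna_binding` is on. The reference binding
#'   parameter is specified in molecule counts; use
#'   [dna_r_from_counts()] to convert.
#' @param growth_inhibition Scale dilution by `f_t(x) = S_t/(1 + B_t x)`?
#' @param translation_inhibition Scale translation by
#'   `f_m(x) = S_m/(1 + B_m x)`?
#' @param S_t,B_t,S_m,B_m Inhibition function constants (normalized toxin
#'   units for `B_t`, `B_m`).
#' @return An object of class `ta_variant`.
#' @export
ta_variant <- function(cleavage = TRUE,
                       tat = FALSE,
                       dna_binding = FALSE,
                       r = NULL,
                       growth_inhibition = FALSE,
                       translation_inhibition = FALSE,
                       S_t = 1, B_t = if (growth_inhibition) 1 else 0,
                       S_m = 1, B_m = if (translation_inhibition) 1 else 0) {
  if (dna_binding && (is.null(r) || r <= 0)) {
    stop("`r` must be positive when DNA binding is included",
         call. = FALSE)
  }
  if (any(c(S_t, B_t, S_m, B_m) < 0)) {
    stop("inhibition constants must be non-negative", call. = FALSE)
  }
  if (!dna_binding) r <- NULL
  structure(list(cleavage = isTRUE(cleavage),
                 tat = isTRUE(tat),
                 dna_binding = isTRUE(dna_binding),
                 r = r,
                 growth_inhibition = isTRUE(growth_inhibition),
                 translation_inhibition = isTRUE(translation_inhibition),
                 S_t = S_t, B_t = B_t, S_m = S_m, B_m = B_m),
            class = "ta_variant")
}

#' Convert an operator-binding parameter from molecule counts to
#' normalized units
#'
#' The transcription repression factor is `r/(r + y)` with `y` the
#' normalized complex level; the reference binding parameter (4.9) is
#' given in molecule counts of AT, which the normalization divides by
#' `epsilon/d_m` molecules per `y` unit.
#'
#' @param r_counts Binding parameter in molecules of AT.
#' @param np A [ta_norm_params()] object (supplies `epsilon`).
#' @param d_m mRNA decay anchor (s^-1).
#' @return `r` in normalized `y` units.
#' @export
dna_r_from_counts <- function(r_counts, np, d_m = 0.002) {
  stopifnot(r_counts > 0)
  r_counts * d_m / np$epsilon
}

# inhibition factors in normalized units
f_m <- function(x, variant) {
  if (variant$translation_inhibition) variant$S_m / (1 + variant$B_m * x)
  else rep(1, length(x))
}
f_t <- function(x, variant) {
  if (variant$growth_inhibition) variant$S_t / (1 + variant$B_t * x)
  else rep(1, length(x))
}

#' Dimensional right-hand side of the 4-ODE (or 5-ODE with TAT) model
#'
#' Time derivatives of `(M, A, T, AT)` (plus `TAT` when the variant
#' includes it) in molecules per second:
#' \deqn{dM/dt = r_F D - d_m M - d_{large} H(T) M}
#' \deqn{dA/dt = b_1 M - a_T A T - d_a A}
#' \deqn{dT/dt = b_2 M - a_T A T - d_c T + d_{a2} AT}
#' \deqn{dAT/dt = a_T A T - d_c AT - d_{a2} AT}
#' with `H(T)` the [hill_cleavage()] fraction and `d_a2 = F d_a`. With the
#' TAT variant, `AT + T -> TAT` at rate `a_T AT T`, TAT decays back to two
#' toxins at `d_a2 TAT` and is diluted at `d_c TAT`. DNA binding
#' multiplies transcription by `r_c/(r_c + AT)` where `r_c` is `r`
#' converted to counts; inhibition scales translation terms by `f_m(T)`
#' and dilution terms by `f_t(T)` (both in count units).
#'
#' @param state Named or positional numeric vector `(M, A, T, AT[, TAT])`,
#'   non-negative.
#' @param p A [ta_params()] object.
#' @param variant A [ta_variant()]; default minimal with cleavage.
#' @return Numeric vector of derivatives, same length as `state`.
#' @export
rhs_full <- function(state, p, variant = ta_variant()) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  M <- state[[1]]; A <- state[[2]]; T <- state[[3]]; AT <- state[[4]]
  TAT <- if (variant$tat) state[[5]] else 0
  d_a2 <- p$F * p$d_a
  eps <- p$b_2 / p$b_1
  H <- if (variant$cleavage) hill_cleavage(T, p$K_t, p$n) else 0
  # inhibition constants converted from normalized to count units
  fm <- if (variant$translation_inhibition)
    variant$S_m / (1 + variant$B_m * (p$d_m / eps) * T) else 1
  ft <- if (variant$growth_inhibition)
    variant$S_t / (1 + variant$B_t * (p$d_m / eps) * T) else 1
  transcription <- p$r_F * p$D
  if (variant$dna_binding) {
    r_c <- variant$r * eps / p$d_m
    transcription <- transcription * r_c / (r_c + AT)
  }
  bind1 <- p$a_T * A * T
  dM <- transcription - p$d_m * M - p$d_large * H * M
  dA <- fm * p$b_1 * M - bind1 - p$d_a * A
  dT <- fm * p$b_2 * M - bind1 - ft * p$d_c * T + d_a2 * AT
  dAT <- bind1 - ft * p$d_c * AT - d_a2 * AT
  if (variant$tat) {
    bind2 <- p$a_T * AT * T
    dT <- dT - bind2 + 2 * d_a2 * TAT
    dAT <- dAT - bind2
    dTAT <- bind2 - ft * p$d_c * TAT - d_a2 * TAT
    c(dM, dA, dT, dAT, dTAT)
  } else {
    c(dM, dA, dT, dAT)
  }
}

#' Normalized 4-ODE right-hand side
#'
#' Derivatives of `(m, a, x, y)` with respect to the scaled time
#' `tau = d_m t`:
#' \deqn{dm/d\tau = 1/\epsilon - m - (\beta - 1) H(x) m}
#' \deqn{da/d\tau = -\alpha a x + \gamma m - \delta_a a}
#' \deqn{dx/d\tau = -\alpha a x + \epsilon(\gamma m + \delta_{AT} y
#'   - \delta_c x)}
#' \deqn{dy/d\tau = \alpha a x - \epsilon(\delta_c + \delta_{AT}) y}
#'
#' @param state Numeric vector `(m, a, x, y)`, non-negative.
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()] (cleavage flag, DNA binding and
#'   inhibition are honored).
#' @return Numeric vector of derivatives.
#' @export
rhs_normalized <- function(state, np, variant = ta_variant()) {
  if (any(state < 0)) stop("state must be non-negative", call. = FALSE)
  m <- state[[1]]; a <- state[[2]]; x <- state[[3]]; y <- state[[4]]
  H <- if (variant$cleavage) hill_cleavage(x, np$kappa, np$n) else 0
  fm <- f_m(x, variant); ft <- f_t(x, variant)
  prod_m <- 1 / np$epsilon
  if (variant$dna_binding) prod_m <- prod_m * variant$r / (variant$r + y)
  bind <- np$alpha * a * x
  c(prod_m - m - (np$beta - 1) * H * m,
    fm * np$gamma * m - bind - np$delta_a * a,
    np$epsilon * (fm * np$gamma * m + np$delta_AT * y -
                    ft * np$delta_c * x) - bind,
    bind - np$epsilon * (ft * np$delta_c + np$delta_AT) * y)
}

#' Quasi-steady-state mRNA level
#'
#' Setting `dm/dtau = 0` gives
#' `m(x) = (1/eps) / (1 + (beta - 1) x^n/(x^n + kappa^n))`; with DNA
#' binding the transcription factor `r/(r + y)` multiplies the result.
#' Translational inhibition does not enter `m` (it scales translation,
#' not transcription).
#'
#' @param x Normalized toxin level (vectorized).
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()].
#' @param y Normalized complex level; only used with DNA binding.
#' @return Quasi-steady-state `m(x)`.
#' @export
mrna_qss <- function(x, np, variant = ta_variant(), y = 0) {
  H <- if (variant$cleavage) hill_cleavage(x, np$kappa, np$n) else 0
  m <- (1 / np$epsilon) / (1 + (np$beta - 1) * H)
  if (variant$dna_binding) m <- m * variant$r / (variant$r + y)
  m
}

#' Quasi-steady-state antitoxin level
#'
#' Setting `da/dtau = 0` gives `a(x) = gamma m(x) / (alpha x + delta_a)`;
#' with translational inhibition the numerator carries `f_m(x)`, and with
#' DNA binding `m` depends on the current `y`.
#'
#' @inheritParams mrna_qss
#' @return Quasi-steady-state `a(x)`.
#' @export
antitoxin_qss <- function(x, np, variant = ta_variant(), y = 0) {
  m <- mrna_qss(x, np, variant, y)
  f_m(x, variant) * np$gamma * m / (np$alpha * x + np$delta_a)
}

#' Reduced 2-D right-hand side
#'
#' The quasi-steady-state reduction of the normalized model:
#' \deqn{dx/d\tau = -\alpha a(x) x + \epsilon(\gamma m(x) + \delta_{AT} y
#'   - \delta_c x)}
#' \deqn{dy/d\tau = \alpha a(x) x - \epsilon(\delta_c + \delta_{AT}) y}
#' with [mrna_qss()] and [antitoxin_qss()] substituted. DNA binding makes
#' `m` and `a` depend on the instantaneous `y`; inhibition scales
#' translation by `f_m(x)` and dilution by `f_t(x)`.
#'
#' @param x,y Normalized toxin and complex levels.
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()].
#' @return Numeric vector `(dx/dtau, dy/dtau)`.
#' @export
rhs_reduced <- function(x, y, np, variant = ta_variant()) {
  m <- mrna_qss(x, np, variant, y)
  a <- f_m(x, variant) * np$gamma * m / (np$alpha * x + np$delta_a)
  fm <- f_m(x, variant); ft <- f_t(x, variant)
  bind <- np$alpha * a * x
  c(np$epsilon * (fm * np$gamma * m + np$delta_AT * y -
                    ft * np$delta_c * x) - bind,
    bind - np$epsilon * (ft * np$delta_c + np$delta_AT) * y)
}

#' Reduced 3-D right-hand side with the secondary complex TAT
#'
#' Quasi-steady-state model including the secondary complex `z` (one
#' antitoxin binding two toxins): complex `y` captures a second toxin at
#' rate `alpha x y`, and `z` releases two toxins when its antitoxin is
#' degraded (rate `delta_AT`):
#' \deqn{dx/d\tau = -\alpha (a(x) + y) x + \epsilon(\gamma m(x)
#'   + \delta_{AT}(y + 2z) - \delta_c x)}
#' \deqn{dy/d\tau = \alpha (a(x) - y) x - \epsilon(\delta_c
#'   + \delta_{AT}) y}
#' \deqn{dz/d\tau = \alpha x y - \epsilon(\delta_c + \delta_{AT}) z}
#' The total complexed toxin `c = y + 2z` obeys
#' `dc/dtau = alpha (a(x) + y) x - eps (delta_c + delta_AT) c`.
#'
#' @param x,y,z Normalized toxin, AT and TAT levels.
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()].
#' @return Numeric vector `(dx/dtau, dy/dtau, dz/dtau)`.
#' @export
rhs_tat <- function(x, y, z, np, variant = ta_variant(tat = TRUE)) {
  m <- mrna_qss(x, np, variant, y)
  a <- f_m(x, variant) * np$gamma * m / (np$alpha * x + np$delta_a)
  fm <- f_m(x, variant); ft <- f_t(x, variant)
  c(np$epsilon * (fm * np$gamma * m + np$delta_AT * (y + 2 * z) -
                    ft * np$delta_c * x) - np$alpha * (a + y) * x,
    np$alpha * (a - y) * x - np$epsilon * (ft * np$delta_c +
                                             np$delta_AT) * y,
    np$alpha * x * y - np$epsilon * (ft * np$delta_c + np$delta_AT) * z)
}

# dispatch a variant/representation to its rhs and state dimension
ta_rhs <- function(representation, params, variant) {
  switch(representation,
    full = list(
      fn = function(t, s, q) list(rhs_full(pmax(s, 0), params, variant)),
      dim = if (variant$tat) 5L else 4L,
      names = c("M", "A", "T", "AT", if (variant$tat) "TAT")),
    normalized = list(
      fn = function(t, s, q) list(rhs_normalized(pmax(s, 0), params,
                                                 variant)),
      dim = 4L,
      names = c("m", "a", "x", "y")),
    reduced = list(
      fn = function(t, s, q) {
        s <- pmax(s, 0)
        list(rhs_reduced(s[1], s[2], params, variant))
      },
      dim = 2L,
      names = c("x", "y")),
    tat = list(
      fn = function(t, s, q) {
        s <- pmax(s, 0)
        list(rhs_tat(s[1], s[2], s[3], params, variant))
      },
      dim = 3L,
      names = c("x", "y", "z")),
    stop("unknown representation `", representation, "`", call. = FALSE)
  )
}

#' Integrate a deterministic model variant
#'
#' Integrates the selected representation with a stiff-capable method
#' (`deSolve::lsoda`), honoring an optional stress schedule by
#' segment-wise integration with a parameter switch at each window
#' boundary. The system has three well-separated timescales (order
#' `eps`, 1 and `1/eps`), so tight tolerances are the default. States are
#' clipped to zero when an accepted step undershoots within solver
#' tolerance; larger undershoot raises an error.
#'
#' @param params A `ta_params` (for `representation = "full"`) or
#'   `ta_norm_params` (otherwise) object.
#' @param state0 Initial state, non-negative, in the representation's
#'   variables (`(M, A, T, AT[, TAT])`, `(m, a, x, y)`, `(x, y)` or
#'   `(x, y, z)`).
#' @param t_end End time (seconds for `"full"`, tau units otherwise).
#' @param representation One of `"reduced"`, `"full"`, `"normalized"`,
#'   `"tat"`.
#' @param variant A [ta_variant()].
#' @param stress_schedule Optional [stress_schedule()] in the same time
#'   units.
#' @param tol Relative tolerance (absolute tolerance is `tol * 1e-2`).
#' @param n_out Number of equally spaced output times.
#' @return A data frame of class `ta_trajectory` with a `time` column and
#'   one column per state variable; attributes record the representation,
#'   variant and solver settings.
#' @export
ta_integrate <- function(params, state0, t_end,
                         representation = c("reduced", "full",
                                            "normalized", "tat"),
                         variant = ta_variant(),
                         stress_schedule = NULL,
                         tol = 1e-8,
                         n_out = 2000L) {
  representation <- match.arg(representation)
  if (representation == "full") {
    stopifnot(inherits(params, "ta_params"))
  } else {
    stopifnot(inherits(params, "ta_norm_params"))
  }
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  if (any(state0 < 0)) stop("initial state must be non-negative",
                            call. = FALSE)
  model <- ta_rhs(representation, params, variant)
  if (length(state0) != model$dim) {
    stop("`state0` must have length ", model$dim, " for representation `",
         representation, "`", call. = FALSE)
  }
  times <- seq(0, t_end, length.out = n_out)

  # break [0, t_end] into segments of constant parameters
  breaks <- 0
  segs <- list()
  if (!is.null(stress_schedule)) {
    stopifnot(inherits(stress_schedule, "ta_stress_schedule"))
    bounds <- sort(unique(pmin(pmax(
      c(stress_schedule$t_start, stress_schedule$t_end), 0), t_end)))
    breaks <- unique(c(0, bounds, t_end))
  } else {
    breaks <- c(0, t_end)
  }
  breaks <- breaks[breaks <= t_end]
  if (breaks[length(breaks)] < t_end) breaks <- c(breaks, t_end)

  seg_params <- function(t_mid) {
    if (is.null(stress_schedule)) return(params)
    hit <- stress_schedule$t_start <= t_mid & t_mid < stress_schedule$t_end
    if (!any(hit)) return(params)
    w <- which(hit)[1L]
    apply_stress(params, stress_schedule$mult_da[w],
                 stress_schedule$mult_eps[w])
  }

  out <- NULL
  state <- state0
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    p_i <- seg_params((t0 + t1) / 2)
    model_i <- ta_rhs(representation, p_i, variant)
    seg_times <- unique(c(t0, times[times > t0 & times < t1], t1))
    sol <- tryCatch(
      deSolve::ode(y = state, times = seg_times, func = model_i$fn,
                   parms = NULL, method = "lsoda",
                   rtol = tol, atol = tol * 1e-2),
      warning = function(w) {
        stop("integration failed in segment [", signif(t0, 6), ", ",
             signif(t1, 6), "]: ", conditionMessage(w), call. = FALSE)
      })
    undershoot <- min(sol[, -1L, drop = FALSE])
    if (undershoot < -10 * tol) {
      stop("state became negative beyond tolerance (", undershoot,
           ") in segment [", signif(t0, 6), ", ", signif(t1, 6), "]",
           call. = FALSE)
    }
    sol[, -1L][sol[, -1L] < 0] <- 0
    state <- as.numeric(sol[nrow(sol), -1L])
    keep <- if (i < length(breaks) - 1L) -nrow(sol) else TRUE
    out <- rbind(out, sol[keep, , drop = FALSE])
  }
  traj <- as.data.frame(out)
  names(traj) <- c("time", model$names)
  structure(traj,
            class = c("ta_trajectory", "data.frame"),
            representation = representation,
            variant = variant,
            solver = list(method = "lsoda", rtol = tol,
                          atol = tol * 1e-2),
            source = "ode")
}

#' Write a trajectory and its provenance to disk
#'
#' The trajectory is written as a tidy CSV (time plus one column per
#' species) with a JSON sidecar recording representation, variant, solver
#' or seed metadata.
#'
#' @param traj A `ta_trajectory` or `ta_ssa_trajectory`.
#' @param path CSV output path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  meta <- list(representation = attr(traj, "representation"),
               source = attr(traj, "source"),
               variant = unclass(attr(traj, "variant")),
               solver = attr(traj, "solver"),
               seed = attr(traj, "seed"),
               volume_factor = attr(traj, "volume_factor"))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
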