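# Model constants, unit conversions and nondimensionalization for the
# mazEF-type toxin-antitoxin module. Units are fixed by convention:
# seconds and molecules per cell; molar only enters at the conversion
# boundary (see volume_factor).

# Avogadro's number as used in the molecules-per-cell conversion (3 s.f.).
.AVOGADRO <- 6.02e23

#' Molecules-per-molar conversion factor for a cell of given volume
#'
#' Converts a molar concentration into molecules per cell:
#' `N_A * 1000 (l/m^3) * v_cell`. For the default E. coli volume of
#' 0.6 um^3 this gives 3.612e8 molecules/(cell M).
#'
#' @param v_cell Cell volume in m^3 (0.6 um^3 = `0.6e-18`).
#' @return Conversion factor in molecules per cell per molar.
#' @export
#' @examples
#' volume_factor(0.6e-18)
volume_factor <- function(v_cell) {
  if (!is.numeric(v_cell) || length(v_cell) != 1L || !is.finite(v_cell) ||
      v_cell <= 0) {
    stop("`v_cell` must be a single positive volume in m^3", call. = FALSE)
  }
  .AVOGADRO * 1000 * v_cell
}

#' Convert a molar association rate to a per-molecule rate
#'
#' Bimolecular rate constants measured in M^-1 s^-1 are divided by the
#' volume factor to obtain the per-molecule rate used in single-cell
#' (count-based) models.
#'
#' @param k Rate constant in M^-1 s^-1 (non-negative).
#' @param v_cell Cell volume in m^3.
#' @return Rate in s^-1 per molecule.
#' @export
#' @examples
#' molar_rate_to_count_rate(1.32e5, 0.6e-18)  # ~0.000365 s^-1
molar_rate_to_count_rate <- function(k, v_cell) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("`k` must be a single non-negative rate in M^-1 s^-1", call. = FALSE)
  }
  k / volume_factor(v_cell)
}

#' First-order decay rate from a half-life
#'
#' @param t_half Half-life in seconds (positive).
#' @return Decay rate `log(2) / t_half` in s^-1.
#' @export
#' @examples
#' halflife_to_rate(5.7 * 60)  # mRNA decay, ~0.002 s^-1
halflife_to_rate <- function(t_half) {
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0) {
    stop("`t_half` must be a single positive duration in seconds",
         call. = FALSE)
  }
  log(2) / t_half
}

.TA_PARAM_FIELDS <- c("r_F", "d_m", "d_large", "K_t", "n", "b_1", "b_2",
                      "a_T", "d_c", "d_a", "F", "D", "v_cell")

#' Dimensional parameter set for the toxin-antitoxin module
#'
#' All rates are in s^-1 (per molecule where bimolecular), thresholds and
#' copy numbers in molecules. Defaults reproduce the mazEF reference
#' parameterization: transcription at 0.121 s^-1, translation rates
#' 0.122/0.009 s^-1, mRNA decay 0.002 s^-1 (5.7 min half-life), maximal
#' cleavage-induced extra decay 0.198 s^-1, cleavage threshold 15 toxins
#' with Hill coefficient 2, association rate 1.32e5 M^-1 s^-1 converted by
#' the volume factor, dilution from a 40 min cell cycle and antitoxin
#' degradation at 8 times the dilution rate.
#'
#' @param r_F Transcription rate per gene copy (s^-1).
#' @param d_m Basal mRNA decay rate (s^-1).
#' @param d_large Maximal cleavage-induced extra mRNA decay rate (s^-1).
#' @param K_t Cleavage threshold (molecules).
#' @param n Hill coefficient (integer >= 1).
#' @param b_1 Antitoxin translation rate (s^-1).
#' @param b_2 Toxin translation rate (s^-1); must satisfy `b_2 < b_1`.
#' @param a_T Toxin-antitoxin association rate (s^-1 per molecule).
#' @param d_c Dilution rate from cell division (s^-1).
#' @param d_a Free-antitoxin degradation rate (s^-1).
#' @param F In-complex antitoxin degradation fraction; `d_a2 = F * d_a`.
#' @param D Gene copy number.
#' @param v_cell Cell volume in m^3.
#' @return An object of class `ta_params` (named list).
#' @seealso [ta_params_table1()], [normalize_params()]
#' @export
ta_params <- function(r_F = 0.121,
                      d_m = 0.002,
                      d_large = 0.198,
                      K_t = 15,
                      n = 2,
                      b_1 = 0.122,
                      b_2 = 0.009,
                      a_T = molar_rate_to_count_rate(1.32e5, 0.6e-18),
                      d_c = log(2) / 2400,
                      d_a = 8 * log(2) / 2400,
                      F = 0.1,
                      D = 1,
                      v_cell = 0.6e-18) {
  p <- list(r_F = r_F, d_m = d_m, d_large = d_large, K_t = K_t, n = n,
            b_1 = b_1, b_2 = b_2, a_T = a_T, d_c = d_c, d_a = d_a,
            F = F, D = D, v_cell = v_cell)
  validate_ta_params(p)
  structure(p, class = "ta_params")
}

validate_ta_params <- function(p) {
  for (f in .TA_PARAM_FIELDS) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", f, "` must be a single finite number",
           call. = FALSE)
    }
  }
  pos <- c("r_F", "d_m", "d_large", "K_t", "b_1", "b_2", "a_T", "d_c",
           "d_a", "D", "v_cell")
  for (f in pos) {
    if (p[[f]] <= 0) stop("parameter `", f, "` must be positive",
                          call. = FALSE)
  }
  if (p$F <= 0 || p$F > 1) stop("`F` must lie in (0, 1]", call. = FALSE)
  if (p$b_2 >= p$b_1) {
    stop("`b_2` must be smaller than `b_1`: the antitoxin is translated ",
         "at a higher rate than the toxin", call. = FALSE)
  }
  if (p$n < 1 || p$n != round(p$n)) {
    stop("Hill coefficient `n` must be an integer >= 1", call. = FALSE)
  }
  invisible(p)
}

#' Reference parameter presets
#'
#' Returns the reference dimensional parameter set. Two presets differ only
#' in the dilution rate: `"derived"` uses `d_c = log(2)/(40 min)` (and
#' `d_a = 8 * d_c`), which is the value consistent with the published
#' normalized dilution rate `delta_c = 1.96`; `"printed"` uses the rounded
#' `d_c = 0.00028 s^-1` and `d_a = 0.00231 s^-1`.
#'
#' @param d_c_preset `"derived"` (default) or `"printed"`.
#' @return A [ta_params()] object.
#' @export
ta_params_table1 <- function(d_c_preset = c("derived", "printed")) {
  d_c_preset <- match.arg(d_c_preset)
  if (d_c_preset == "derived") {
    ta_params()
  } else {
    ta_params(d_c = 0.00028, d_a = 0.00231)
  }
}

.TA_NORM_FIELDS <- c("delta_c", "delta_a", "delta_AT", "beta", "alpha",
                     "gamma", "epsilon", "kappa", "n")

#' Dimensionless parameter set for the normalized model
#'
#' Direct constructor for the normalized parameters. `delta_AT` defaults to
#' `F * delta_a / epsilon` with `F = 0.1`, the relation that ties the
#' in-complex antitoxin degradation to the free-antitoxin degradation.
#'
#' @param delta_c Normalized dilution rate.
#' @param delta_a Normalized antitoxin degradation rate.
#' @param beta Ratio of maximal to basal mRNA decay (`d_large/d_m + 1`).
#' @param alpha Normalized toxin-antitoxin association rate.
#' @param gamma Normalized translation flux.
#' @param epsilon Ratio of toxin to antitoxin translation rates (in (0,1)).
#' @param kappa Cleavage threshold in normalized toxin units.
#' @param n Hill coefficient.
#' @param delta_AT Normalized in-complex degradation rate.
#' @param F In-complex degradation fraction used for the default
#'   `delta_AT`.
#' @return An object of class `ta_norm_params`.
#' @export
ta_norm_params <- function(delta_c, delta_a, beta, alpha, gamma, epsilon,
                           kappa, n = 2, delta_AT = F * delta_a / epsilon,
                           F = 0.1) {
  np <- list(delta_c = delta_c, delta_a = delta_a, delta_AT = delta_AT,
             beta = beta, alpha = alpha, gamma = gamma, epsilon = epsilon,
             kappa = kappa, n = n)
  validate_ta_norm_params(np)
  structure(np, class = "ta_norm_params")
}

validate_ta_norm_params <- function(np) {
  for (f in .TA_NORM_FIELDS) {
    v <- np[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("normalized parameter `", f, "` must be a single finite number",
           call. = FALSE)
    }
    if (f != "n" && v <= 0) {
      stop("normalized parameter `", f, "` must be positive", call. = FALSE)
    }
  }
  if (np$epsilon >= 1) {
    stop("`epsilon` must be smaller than 1 (toxin translated more slowly ",
         "than antitoxin)", call. = FALSE)
  }
  if (np$beta < 1) stop("`beta` must be >= 1", call. = FALSE)
  if (np$n < 1 || np$n != round(np$n)) {
    stop("Hill coefficient `n` must be an integer >= 1", call. = FALSE)
  }
  invisible(np)
}

#' Nondimensionalize a parameter set
#'
#' Maps the dimensional constants onto the dimensionless parameters of the
#' normalized model, using the variable scalings `m = (d_m/(r_F D eps)) M`,
#' `a = (d_m/eps) A`, `x = (d_m/eps) T`, `y = (d_m/eps) AT`, `tau = d_m t`:
#' \deqn{\epsilon = b_2/b_1,\quad \beta = d_{large}/d_m + 1,\quad
#'       \kappa = K_t d_m/\epsilon,\quad \alpha = \epsilon a_T/d_m^2,}
#' \deqn{\gamma = r_F D b_1/d_m,\quad \delta_a = d_a/d_m,\quad
#'       \delta_c = d_c/(d_m \epsilon),\quad
#'       \delta_{AT} = F d_a/(d_m \epsilon).}
#'
#' @param p A [ta_params()] object.
#' @return A [ta_norm_params()] object.
#' @export
#' @examples
#' np <- normalize_params(ta_params_table1())
#' signif(np$gamma, 3)  # 7.38
normalize_params <- function(p) {
  stopifnot(inherits(p, "ta_params"))
  if (p$b_1 == 0) stop("`b_1` must be nonzero", call. = FALSE)
  eps <- p$b_2 / p$b_1
  ta_norm_params(
    delta_c  = p$d_c / (p$d_m * eps),
    delta_a  = p$d_a / p$d_m,
    delta_AT = p$F * p$d_a / (p$d_m * eps),
    beta     = p$d_large / p$d_m + 1,
    alpha    = eps * p$a_T / p$d_m^2,
    gamma    = p$r_F * p$D * p$b_1 / p$d_m,
    epsilon  = eps,
    kappa    = p$K_t * p$d_m / eps,
    n        = p$n
  )
}

#' Recover dimensional parameters from a normalized set
#'
#' Inverts [normalize_params()] given the dimensional anchors that the
#' nondimensionalization removed (`d_m`, `b_1`, `D`, `v_cell`). The
#' in-complex degradation fraction is recovered as
#' `F = delta_AT * epsilon / delta_a`.
#'
#' @param np A [ta_norm_params()] object.
#' @param d_m Basal mRNA decay rate anchor (s^-1).
#' @param b_1 Antitoxin translation rate anchor (s^-1).
#' @param D Gene copy number anchor.
#' @param v_cell Cell volume anchor (m^3).
#' @return A [ta_params()] object.
#' @export
denormalize_params <- function(np, d_m = 0.002, b_1 = 0.122, D = 1,
                               v_cell = 0.6e-18) {
  stopifnot(inherits(np, "ta_norm_params"))
  eps <- np$epsilon
  ta_params(
    r_F = np$gamma * d_m / (D * b_1),
    d_m = d_m,
    d_large = (np$beta - 1) * d_m,
    K_t = np$kappa * eps / d_m,
    n = np$n,
    b_1 = b_1,
    b_2 = eps * b_1,
    a_T = np$alpha * d_m^2 / eps,
    d_c = np$delta_c * d_m * eps,
    d_a = np$delta_a * d_m,
    F = np$delta_AT * eps / np$delta_a,
    D = D,
    v_cell = v_cell
  )
}

#' Round a normalized value the way the reference table reports it
#'
#' Three significant figures, rounding half away from zero, computed from
#' unrounded intermediates.
#'
#' @param x Numeric vector.
#' @return `x` rounded to 3 significant figures (half away from zero).
#' @export
report_3sf <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    e <- floor(log10(abs(v))) - 2
    sgn <- sign(v)
    sgn * floor(abs(v) / 10^e + 0.5) * 10^e
  }, numeric(1))
}

#' Apply a stress transformation to a parameter set
#'
#' Nutritional stress is modeled as an increase in the antitoxin
#' degradation rate (Lon protease activity) and/or the toxin translation
#' rate. For a dimensional set, `d_a` (and with it `d_a2 = F d_a`) is
#' multiplied by `multiplier_da` and `b_2` by `multiplier_eps`. For a
#' normalized set the same transformations are expressed in normalized
#' space: `delta_a` and `delta_AT` scale with `multiplier_da`, and a
#' `b_2` change scales `epsilon` and `alpha` by `multiplier_eps` and
#' `delta_c`, `kappa`, `delta_AT` by its inverse (every
#' epsilon-dependent normalized parameter co-varies, so that
#' `normalize_params()` and `apply_stress()` commute).
#'
#' @param p A `ta_params` or `ta_norm_params` object.
#' @param multiplier_da Positive factor applied to the antitoxin
#'   degradation rate.
#' @param multiplier_eps Positive factor applied to the toxin translation
#'   rate.
#' @return An object of the same class as `p`.
#' @export
apply_stress <- function(p, multiplier_da = 1, multiplier_eps = 1) {
  UseMethod("apply_stress")
}

#' @export
apply_stress.ta_params <- function(p, multiplier_da = 1,
                                   multiplier_eps = 1) {
  check_multipliers(multiplier_da, multiplier_eps)
  p$d_a <- p$d_a * multiplier_da
  p$b_2 <- p$b_2 * multiplier_eps
  validate_ta_params(p)
  p
}

#' @export
apply_stress.ta_norm_params <- function(p, multiplier_da = 1,
                                        multiplier_eps = 1) {
  check_multipliers(multiplier_da, multiplier_eps)
  p$delta_a <- p$delta_a * multiplier_da
  p$delta_AT <- p$delta_AT * multiplier_da / multiplier_eps
  p$epsilon <- p$epsilon * multiplier_eps
  p$delta_c <- p$delta_c / multiplier_eps
  p$kappa <- p$kappa / multiplier_eps
  p$alpha <- p$alpha * multiplier_eps
  validate_ta_norm_params(p)
  p
}

check_multipliers <- function(multiplier_da, multiplier_eps) {
  if (!is.numeric(multiplier_da) || length(multiplier_da) != 1L ||
      !is.finite(multiplier_da) || multiplier_da <= 0 ||
      !is.numeric(multiplier_eps) || length(multiplier_eps) != 1L ||
      !is.finite(multiplier_eps) || multiplier_eps <= 0) {
    stop("stress multipliers must be single positive numbers",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Override the stress parameters of a normalized set
#'
#' Convenience for bifurcation scans: sets `delta_a` and/or `epsilon` to
#' absolute values. The in-complex degradation fraction
#' `F = delta_AT * epsilon / delta_a` is kept fixed, so `delta_AT`
#' co-varies with both. An `epsilon` change stands for a change of the
#' dimensional toxin translation rate, so the other epsilon-dependent
#' normalized parameters co-vary as in [apply_stress()] (`delta_c` and
#' `kappa` inversely, `alpha` proportionally).
#'
#' @param np A `ta_norm_params` object.
#' @param delta_a Optional new antitoxin degradation rate.
#' @param epsilon Optional new translation-rate ratio.
#' @return A `ta_norm_params` object.
#' @export
set_stress <- function(np, delta_a = NULL, epsilon = NULL) {
  stopifnot(inherits(np, "ta_norm_params"))
  mult_da <- if (is.null(delta_a)) 1 else delta_a / np$delta_a
  mult_eps <- if (is.null(epsilon)) 1 else epsilon / np$epsilon
  apply_stress(np, multiplier_da = mult_da, multiplier_eps = mult_eps)
}

#' Piecewise-constant stress schedule
#'
#' Stress windows over which the degradation and translation multipliers
#' apply; parameters are piecewise-constant in time and switch
#' instantaneously at window boundaries. Windows must be ordered and
#' non-overlapping.
#'
#' @param t_start,t_end Window boundaries (seconds for dimensional models,
#'   tau units for normalized ones); vectors of equal length.
#' @param mult_da,mult_eps Positive multipliers, recycled to the number of
#'   windows.
#' @return A data frame of class `ta_stress_schedule`.
#' @export
stress_schedule <- function(t_start, t_end, mult_da = 1, mult_eps = 1) {
  if (length(t_start) != length(t_end)) {
    stop("`t_start` and `t_end` must have equal length", call. = FALSE)
  }
  sched <- data.frame(t_start = as.numeric(t_start),
                      t_end = as.numeric(t_end),
                      mult_da = rep_len(as.numeric(mult_da),
                                        length(t_start)),
                      mult_eps = rep_len(as.numeric(mult_eps),
                                         length(t_start)))
  if (any(sched$t_end <= sched$t_start)) {
    stop("stress windows must have `t_end > t_start`", call. = FALSE)
  }
  if (any(sched$mult_da <= 0) || any(sched$mult_eps <= 0)) {
    stop("stress multipliers must be positive", call. = FALSE)
  }
  if (nrow(sched) > 1L) {
    o <- order(sched$t_start)
    sched <- sched[o, , drop = FALSE]
    if (any(sched$t_start[-1L] < sched$t_end[-nrow(sched)])) {
      stop("stress windows must not overlap", call. = FALSE)
    }
  }
  class(sched) <- c("ta_stress_schedule", "data.frame")
  sched
}

#' Read or write parameter sets as flat JSON
#'
#' Parameter files are flat key-value JSON objects whose keys are the
#' ascii parameter symbols (`"d_a"`, `"delta_a"`, ...). A file containing
#' the normalized keys is read as a `ta_norm_params`; one containing the
#' dimensional keys as a `ta_params`.
#'
#' @param path File path.
#' @return For `read_params`, a `ta_params` or `ta_norm_params` object.
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (all(.TA_NORM_FIELDS %in% names(x))) {
    do.call(ta_norm_params, x[.TA_NORM_FIELDS])
  } else if (all(.TA_PARAM_FIELDS %in% names(x))) {
    do.call(ta_params, x[.TA_PARAM_FIELDS])
  } else {
    stop("`", path, "` holds neither a full dimensional nor a full ",
         "normalized parameter set", call. = FALSE)
  }
}

#' @rdname read_params
#' @param p Parameter set to write.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "ta_params") || inherits(p, "ta_norm_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.ta_params <- function(x, ...) {
  cat("Toxin-antitoxin dimensional parameters (s, molecules):\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' @export
print.ta_norm_params <- function(x, ...) {
  cat("Toxin-antitoxin normalized parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}
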