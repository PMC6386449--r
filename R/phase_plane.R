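# Nullclines, fixed points, stability and regime classification for the
# reduced 2-D system (and its DNA-binding / inhibition variants).

#' Nullclines of the reduced system
#'
#' `NC(x)` collects the points where `dx/dtau = 0`,
#' \deqn{NC(x):\; y = \frac{\alpha a(x) x + \epsilon\delta_c x
#'   - \epsilon\gamma m(x)}{\epsilon\delta_{AT}},}
#' and `NC(y)` those where `dy/dtau = 0`,
#' \deqn{NC(y):\; y = \frac{\alpha a(x) x}
#'   {\epsilon(\delta_c + \delta_{AT})}.}
#' With a Hill coefficient of at least two (or translational inhibition),
#' `NC(x)` is folded: its middle branch, between the two folds, acts as
#' the excitation threshold. With DNA binding the curves are solved
#' implicitly in `y` at each grid point.
#'
#' @param np A [ta_norm_params()] object.
#' @param x_grid Positive increasing grid of normalized toxin levels;
#'   default log-spaced over `[1e-3, 1e3]`.
#' @param variant A [ta_variant()].
#' @return An object of class `ta_nullclines`: a data frame with columns
#'   `x`, `nc_x`, `nc_y`, plus attributes `folds` (x locations of the
#'   local extrema of `NC(x)`, refined by golden-section search) and the
#'   inputs.
#' @export
nullclines <- function(np, x_grid = NULL, variant = ta_variant()) {
  stopifnot(inherits(np, "ta_norm_params"))
  if (is.null(x_grid)) {
    x_grid <- 10^seq(-3, 3, length.out = 1200L)
  }
  if (any(diff(x_grid) <= 0) || any(x_grid <= 0)) {
    stop("`x_grid` must be positive and strictly increasing",
         call. = FALSE)
  }
  ncx_fun <- function(x) nc_x_value(x, np, variant)
  ncy_fun <- function(x) nc_y_value(x, np, variant)
  nc_x <- vapply(x_grid, ncx_fun, numeric(1))
  nc_y <- vapply(x_grid, ncy_fun, numeric(1))
  folds <- find_folds(ncx_fun, x_grid, nc_x)
  structure(data.frame(x = x_grid, nc_x = nc_x, nc_y = nc_y),
            class = c("ta_nullclines", "data.frame"),
            folds = folds, np = np, variant = variant)
}

# y on NC(x) at a single x; for DNA binding, solved implicitly in y.
nc_x_value <- function(x, np, variant) {
  explicit <- function(y_for_qss) {
    m <- mrna_qss(x, np, variant, y_for_qss)
    a <- f_m(x, variant) * np$gamma * m / (np$alpha * x + np$delta_a)
    (np$alpha * a * x + np$epsilon * f_t(x, variant) * np$delta_c * x -
       np$epsilon * f_m(x, variant) * np$gamma * m) /
      (np$epsilon * np$delta_AT)
  }
  if (!variant$dna_binding) return(explicit(0))
  g <- function(y) explicit(y) - y
  up <- 1
  while (g(up) > 0 && up < 1e8) up <- up * 10
  lo <- explicit(1e6)  # strongest repression -> lower bound for the root
  lo <- min(lo, 0)
  if (g(up) > 0 || !is.finite(g(lo)) || g(lo) < 0) return(explicit(0))
  stats::uniroot(g, c(lo, up), tol = 1e-12)$root
}

nc_y_value <- function(x, np, variant) {
  explicit <- function(y_for_qss) {
    a <- antitoxin_qss(x, np, variant, y_for_qss)
    np$alpha * a * x /
      (np$epsilon * (f_t(x, variant) * np$delta_c + np$delta_AT))
  }
  if (!variant$dna_binding) return(explicit(0))
  g <- function(y) explicit(y) - y
  up <- 1
  while (g(up) > 0 && up < 1e8) up <- up * 10
  if (g(up) > 0) return(explicit(0))
  stats::uniroot(g, c(0, up), tol = 1e-12)$root
}

# locate local extrema of NC(x) from grid sign changes of the slope,
# refined by optimize() on each bracketing interval
find_folds <- function(ncx_fun, x_grid, nc_x) {
  d <- diff(nc_x)
  sgn <- sign(d)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0) + 1L
  folds <- numeric(0)
  for (i in idx) {
    lo <- x_grid[max(i - 1L, 1L)]
    hi <- x_grid[min(i + 1L, length(x_grid))]
    maximum <- d[i - 1L] > 0
    opt <- stats::optimize(ncx_fun, c(lo, hi), maximum = maximum,
                           tol = 1e-10)
    folds <- c(folds, if (maximum) opt$maximum else opt$minimum)
  }
  folds
}

# analytic Jacobian of the minimal reduced system; numeric (central
# differences) for DNA-binding / inhibition variants
reduced_jacobian <- function(x, y, np, variant = ta_variant()) {
  if (!variant$dna_binding && !variant$growth_inhibition &&
      !variant$translation_inhibition && variant$cleavage) {
    kn <- np$kappa^np$n
    xn <- x^np$n
    den <- np$beta * xn + kn
    m <- (1 / np$epsilon) * (xn + kn) / den
    dm <- if (x > 0) {
      (1 / np$epsilon) * np$n * x^(np$n - 1) * kn * (1 - np$beta) / den^2
    } else 0
    q <- np$alpha * x + np$delta_a
    a <- np$gamma * m / q
    da <- np$gamma * (dm * q - m * np$alpha) / q^2
    j11 <- -np$alpha * (da * x + a) +
      np$epsilon * (np$gamma * dm - np$delta_c)
    j12 <- np$epsilon * np$delta_AT
    j21 <- np$alpha * (da * x + a)
    j22 <- -np$epsilon * (np$delta_c + np$delta_AT)
    return(matrix(c(j11, j21, j12, j22), 2, 2))
  }
  numeric_jacobian(function(s) rhs_reduced(s[1], s[2], np, variant),
                   c(x, y))
}

numeric_jacobian <- function(fn, s) {
  n <- length(s)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(1, abs(s[i]))
    sp <- s; sm <- s
    sp[i] <- sp[i] + h
    sm[i] <- max(sm[i] - h, 0)
    J[, i] <- (fn(sp) - fn(sm)) / (sp[i] - sm[i])
  }
  J
}

new_fixed_point <- function(state, np, variant, rhs_fn) {
  J <- if (length(state) == 2L) {
    reduced_jacobian(state[1], state[2], np, variant)
  } else {
    numeric_jacobian(rhs_fn, state)
  }
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(x = state[1], y = state[2],
                 z = if (length(state) > 2L) state[3] else NULL,
                 jacobian = J,
                 eigenvalues = ev,
                 stable = max(Re(ev)) < 0,
                 oscillatory = any(abs(Im(ev)) > 1e-9),
                 residual = max(abs(rhs_fn(state)))),
            class = "ta_fixed_point")
}

#' @export
print.ta_fixed_point <- function(x, ...) {
  cat(sprintf("Fixed point at (x = %.6g, y = %.6g)%s: %s %s\n",
              x$x, x$y,
              if (!is.null(x$z)) sprintf(", z = %.6g", x$z) else "",
              if (x$stable) "stable" else "unstable",
              if (x$oscillatory) "focus" else "node"))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Locate the fixed points of a reduced model
#'
#' Roots of the reduced right-hand side inside a positive bounded box.
#' Candidate toxin levels come from sign changes of `dx/dtau` along
#' `NC(y)` on a log-spaced grid; each candidate seeds a damped Newton
#' iteration on the full system, and converged roots closer than `1e-6`
#' relative are merged.
#'
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()]; the TAT variant is solved in 3-D.
#' @param x_range Positive range searched for the toxin coordinate.
#' @param grid_n Number of log-spaced seeding points.
#' @param tol Newton residual tolerance.
#' @return A list of `ta_fixed_point` objects (empty, with a warning, if
#'   no seed converges).
#' @export
find_fixed_points <- function(np, variant = ta_variant(),
                              x_range = c(1e-3, 1e3), grid_n = 400L,
                              tol = 1e-12) {
  stopifnot(inherits(np, "ta_norm_params"))
  tat <- variant$tat
  rhs_fn <- if (tat) {
    function(s) rhs_tat(s[1], s[2], s[3], np, variant)
  } else {
    function(s) rhs_reduced(s[1], s[2], np, variant)
  }
  xs <- 10^seq(log10(x_range[1]), log10(x_range[2]),
               length.out = grid_n)
  # seed from dx/dtau sign changes along NC(y) (x-coordinate bracketing)
  seed_state <- function(x) {
    y <- nc_y_value(x, np, variant)
    if (tat) {
      # z in quasi-steady state given x, y
      z <- np$alpha * x * y /
        (np$epsilon * (f_t(x, variant) * np$delta_c + np$delta_AT))
      c(x, y, z)
    } else {
      c(x, y)
    }
  }
  gv <- vapply(xs, function(x) rhs_fn(seed_state(x))[1], numeric(1))
  idx <- which(gv[-1] * gv[-length(gv)] < 0)
  seeds <- lapply(idx, function(i) seed_state(sqrt(xs[i] * xs[i + 1L])))
  if (!length(seeds)) seeds <- lapply(xs[c(100L, 200L, 300L)], seed_state)

  roots <- list()
  for (s0 in seeds) {
    root <- newton_solve(rhs_fn, s0, tol = tol)
    if (is.null(root)) next
    dup <- any(vapply(roots, function(r) {
      all(abs(r - root) <= 1e-6 * pmax(abs(r), 1e-12))
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- root
  }
  if (!length(roots)) {
    warning("no fixed point converged from any seed")
    return(list())
  }
  roots <- roots[order(vapply(roots, `[`, numeric(1), 1L))]
  lapply(roots, new_fixed_point, np = np, variant = variant,
         rhs_fn = rhs_fn)
}

# damped Newton with positivity floor; NULL on failure
newton_solve <- function(fn, s0, tol = 1e-12, max_iter = 60L) {
  s <- s0
  for (i in seq_len(max_iter)) {
    fv <- fn(s)
    if (max(abs(fv)) < tol) return(s)
    J <- numeric_jacobian(fn, s)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      s_new <- pmax(s - lambda * step, 1e-14)
      if (max(abs(fn(s_new))) < max(abs(fv)) || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    s <- s_new
  }
  if (max(abs(fn(s))) < tol * 1e4) s else NULL
}

#' Classify the dynamical regime of the reduced system
#'
#' With a single fixed point the system is labeled `"oscillatory"` when
#' the fixed point is unstable (the system converges to a limit cycle),
#' `"excitable"` when the fixed point is a stable focus (complex
#' eigenvalues, the signature of a nearby Hopf bifurcation) and a probe
#' displacement just past the excitation threshold (the middle branch of
#' `NC(x)`) produces an excursion with `max x >= excursion_factor * x*`,
#' and `"monostable"` otherwise. The probe starts at the fixed point with
#' `x` displaced to `probe_factor` times the threshold-branch toxin level
#' at `y = y*` and is integrated for `tau = 50/eps`.
#'
#' @param np A [ta_norm_params()] object.
#' @param variant A [ta_variant()].
#' @param probe_factor Relative displacement past the threshold branch.
#' @param excursion_factor Excursion size (relative to the fixed point
#'   toxin level) that counts as an excitation.
#' @return Character label, with the fixed point and probe details in
#'   attributes. `"unclassified"` (with a warning) when no single fixed
#'   point is found.
#' @export
classify_regime <- function(np, variant = ta_variant(),
                            probe_factor = 1.05,
                            excursion_factor = 10) {
  fps <- find_fixed_points(np, variant)
  if (length(fps) != 1L) {
    warning("expected exactly one fixed point, found ", length(fps))
    return(structure("unclassified", fixed_points = fps))
  }
  fp <- fps[[1L]]
  if (!fp$stable) {
    return(structure("oscillatory", fixed_point = fp))
  }
  if (!fp$oscillatory) {
    # stable node: far from the Hopf, threshold out of reach
    return(structure("monostable", fixed_point = fp))
  }
  thr <- threshold_branch_x(np, variant, fp)
  if (is.na(thr)) {
    return(structure("monostable", fixed_point = fp))
  }
  state0 <- c(max(probe_factor * thr, fp$x), fp$y)
  traj <- ta_integrate(np, state0, 50 / np$epsilon,
                       representation = "reduced", variant = variant,
                       tol = 1e-8, n_out = 2000L)
  excited <- max(traj$x) >= excursion_factor * fp$x
  structure(if (excited) "excitable" else "monostable",
            fixed_point = fp, threshold_x = thr,
            probe_max_x = max(traj$x))
}

# x on the middle (threshold) branch of NC(x) at y = y*; NA if NC(x) has
# no fold or no crossing at that height
threshold_branch_x <- function(np, variant, fp) {
  nc <- nullclines(np, variant = variant)
  folds <- attr(nc, "folds")
  if (length(folds) < 2L) return(NA_real_)
  g <- function(x) nc_x_value(x, np, variant) - fp$y
  lo <- folds[1L]; hi <- folds[2L]
  glo <- g(lo); ghi <- g(hi)
  if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) {
    return(NA_real_)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-12)$root
}

#' Flow field of the reduced system
#'
#' Evaluates the reduced right-hand side on a rectangular grid, for
#' phase-plane vector plots.
#'
#' @param np A [ta_norm_params()] object.
#' @param x_grid,y_grid Positive grids.
#' @param variant A [ta_variant()].
#' @return A data frame with columns `x`, `y`, `dx`, `dy`, `magnitude`.
#' @export
flow_field <- function(np, x_grid, y_grid, variant = ta_variant()) {
  stopifnot(all(x_grid > 0), all(y_grid > 0))
  grid <- expand.grid(x = x_grid, y = y_grid)
  d <- t(mapply(function(x, y) rhs_reduced(x, y, np, variant),
                grid$x, grid$y))
  grid$dx <- d[, 1L]
  grid$dy <- d[, 2L]
  grid$magnitude <- sqrt(grid$dx^2 + grid$dy^2)
  grid
}
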