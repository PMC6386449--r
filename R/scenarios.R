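# Bundled scenarios mirroring the reference figures, and a runner that
# turns a scenario (or a config list of the same shape) into trajectories,
# events and reports with a provenance manifest.

#' Catalog of bundled scenarios
#'
#' Each scenario resolves to a complete runnable job: model variant(s),
#' parameter set, stress schedule, engine and seeds.
#'
#' * `fig1` - Gillespie runs of the minimal, TAT + DNA-binding, and fully
#'   inhibited systems with a transient doubling of the antitoxin
#'   degradation rate (stress window over the middle third of the run),
#'   with and without mRNA cleavage. The caption constants of the
#'   minimal Gillespie panel (`c1`, `c2`) are stored verbatim as opaque
#'   extras; their reaction-level roles are not defined by the main-text
#'   model and they are not used.
#' * `fig2` - deterministic excitation at `delta_a = 1.5`,
#'   `epsilon = 0.074`: reduced 2-D and full 4-D trajectories from a
#'   super-threshold kick plus the closed-form estimate.
#' * `fig3` - the three regimes at `delta_a` in {1, 2, 3}, reduced ODE
#'   and Gillespie engines.
#' * `fig4` - excitation-time sweeps over `(delta_a, epsilon)` and the
#'   two continuation branches (over `delta_a` at `epsilon = 0.074`, and
#'   over `epsilon` at `delta_a = 2`).
#' * `fig5` - variant comparison (minimal, TAT, DNA binding with a
#'   4.9-molecule operator-binding parameter,
#'   TAT + DNA) at low (`delta_a = 1.5`) and high (`delta_a = 3`)
#'   stress, Gillespie engine.
#' * `fig6` - growth-rate and translational inhibition
#'   (`B_t = B_m = S_t = S_m = 1`) for Hill coefficients 1 and 2,
#'   deterministic engine.
#'
#' @return A named list of scenario definitions (class `ta_scenario`
#'   each).
#' @export
list_scenarios <- function() {
  np <- normalize_params(ta_params_table1())
  base <- ta_params_table1()
  r_op <- dna_r_from_counts(4.9, np)  # binding parameter, 4.9 molecules
  sc <- list(
    fig1 = list(
      name = "fig1",
      engine = "ssa",
      params = base,
      variants = list(minimal = ta_variant(),
                      minimal_nocleave = ta_variant(cleavage = FALSE),
                      tat_dna = ta_variant(tat = TRUE,
                                           dna_binding = TRUE,
                                           r = r_op),
                      full = ta_variant(tat = TRUE, dna_binding = TRUE,
                                        r = r_op,
                                        growth_inhibition = TRUE,
                                        translation_inhibition = TRUE)),
      t_end = 3e5,
      stress = stress_schedule(1e5, 2e5, mult_da = 2),
      seeds = 1L,
      extras = list(c_1 = 1.28e-5, c_2 = 0.00231,
                    s_t = 1, s_m = 1, b_t = 0.027, b_m = 0.027)),
    fig2 = list(
      name = "fig2",
      engine = "ode",
      np = set_stress(np, delta_a = 1.5, epsilon = 0.074),
      variants = list(minimal = ta_variant()),
      kick = "threshold",
      tau_end = NA),
    fig3 = list(
      name = "fig3",
      engine = "both",
      np = np,
      delta_a = c(1, 2, 3),
      variants = list(minimal = ta_variant()),
      t_end = 2e5,
      seeds = 1L),
    fig4 = list(
      name = "fig4",
      engine = "ode",
      np = np,
      variants = list(minimal = ta_variant()),
      delta_a_range = c(1, 4),
      eps_range = c(0.02, 0.15),
      branch_eps = 0.074,
      branch_delta_a = 2),
    fig5 = list(
      name = "fig5",
      engine = "ssa",
      params = base,
      delta_a = c(1.5, 3),
      variants = list(minimal = ta_variant(),
                      tat = ta_variant(tat = TRUE),
                      dna = ta_variant(dna_binding = TRUE, r = r_op),
                      tat_dna = ta_variant(tat = TRUE,
                                           dna_binding = TRUE,
                                           r = r_op)),
      t_end = 2e5,
      seeds = 1L),
    fig6 = list(
      name = "fig6",
      engine = "ode",
      np = set_stress(np, delta_a = 2),
      n = c(1, 2),
      variants = list(
        plain = ta_variant(),
        transl = ta_variant(translation_inhibition = TRUE),
        growth = ta_variant(growth_inhibition = TRUE),
        both = ta_variant(growth_inhibition = TRUE,
                          translation_inhibition = TRUE)))
  )
  lapply(sc, function(s) structure(s, class = "ta_scenario"))
}

validate_scenario <- function(config) {
  if (!is.list(config)) stop("scenario config must be a list",
                             call. = FALSE)
  for (key in c("name", "engine")) {
    if (is.null(config[[key]])) {
      stop("scenario config is missing key `", key, "`", call. = FALSE)
    }
  }
  if (!config$engine %in% c("ode", "ssa", "both")) {
    stop("scenario key `engine` must be \"ode\", \"ssa\" or \"both\"",
         call. = FALSE)
  }
  if (is.null(config$params) && is.null(config$np)) {
    stop("scenario config is missing key `params` (or `np`)",
         call. = FALSE)
  }
  if (is.null(config$variants)) {
    stop("scenario config is missing key `variants`", call. = FALSE)
  }
  invisible(config)
}

#' Run a bundled or user-supplied scenario
#'
#' Executes the scenario's simulations (deterministic, stochastic or
#' both) and returns trajectories, detected excitation events and
#' summary metrics. Outputs are deterministic given the seed. When
#' `outdir` is supplied, trajectories and event tables are written as
#' CSV with JSON sidecars plus a provenance manifest
#' (`manifest.json`), and nothing is written if validation fails.
#'
#' @param config A scenario name from [list_scenarios()] or a config
#'   list of the same shape.
#' @param seed Integer seed overriding the scenario's seeds.
#' @param outdir Optional output directory (created if needed).
#' @return A list of per-variant results, invisibly when writing.
#' @export
run_scenario <- function(config, seed = 1L, outdir = NULL) {
  if (is.character(config)) {
    catalog <- list_scenarios()
    if (!config %in% names(catalog)) {
      stop("unknown scenario `", config, "`; see list_scenarios()",
           call. = FALSE)
    }
    config <- catalog[[config]]
  }
  validate_scenario(config)
  out <- switch(config$name,
    fig2 = run_fig2(config),
    fig4 = run_fig4(config),
    fig6 = run_fig6(config),
    run_generic(config, seed))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_bundle(out, config, seed, outdir)
    return(invisible(out))
  }
  out
}

run_generic <- function(config, seed) {
  das <- if (!is.null(config$delta_a)) config$delta_a else NA
  res <- list()
  for (da in das) {
    if (!is.na(da)) {
      np_i <- set_stress(normalize_params(
        if (!is.null(config$params)) config$params
        else ta_params_table1()), delta_a = da)
      p_i <- denormalize_params(np_i)
    } else {
      p_i <- config$params
      np_i <- normalize_params(p_i)
    }
    for (vn in names(config$variants)) {
      v <- config$variants[[vn]]
      key <- if (is.na(da)) vn else paste0(vn, "_da", da)
      entry <- list(variant = v, delta_a = da)
      if (config$engine %in% c("ode", "both")) {
        lab <- tryCatch(classify_regime(np_i, v),
                        error = function(e) "unclassified")
        entry$regime <- as.character(lab)
        m <- limit_cycle_metrics(np_i, v, tau_end = 200 / np_i$epsilon,
                                 n_out = 6000L)
        entry$ode_metrics <- m[c("amplitude", "period",
                                 "excitation_time", "n_cycles")]
        entry$ode_trajectory <- m$trajectory
      }
      if (config$engine %in% c("ssa", "both")) {
        rs <- build_reactions(v, p_i)
        tr <- gillespie_run(rs, initial_counts(np_i, p_i, v),
                            config$t_end, seed = seed,
                            sample_dt = config$t_end / 4000,
                            stress_schedule = config$stress)
        entry$ssa_trajectory <- tr
        entry$ssa_events <- detect_excitations(tr, p_i$K_t,
                                               species = "T")
        entry$ssa_stats <- excitation_stats(tr, p_i$K_t)
      }
      res[[key]] <- entry
    }
  }
  res
}

run_fig2 <- function(config) {
  np <- config$np
  fp <- find_fixed_points(np)[[1L]]
  x0 <- np$kappa  # kick to the cleavage threshold
  tau_end <- 60 / np$epsilon
  red <- ta_integrate(np, c(x0, fp$y), tau_end,
                      representation = "reduced", n_out = 4000L)
  m0 <- mrna_qss(x0, np)
  a0 <- antitoxin_qss(x0, np)
  full <- ta_integrate(np, c(m0, a0, x0, fp$y), tau_end,
                       representation = "normalized", n_out = 4000L)
  full_xy <- data.frame(time = full$time, x = full$x, y = full$y)
  # closed-form estimate anchored at the kick point
  est <- data.frame(time = red$time,
                    x = analytic_excitation(x0, fp$y, np, red$time))
  list(fig2 = list(
    reduced = red, full = full, analytic = est,
    nullclines = nullclines(np),
    fixed_point = fp,
    events = detect_excitations(red, np$kappa),
    reduction_check = compare_excursion(red, full_xy, np$kappa),
    analytic_check = compare_excursion(red, est, np$kappa)))
}

run_fig4 <- function(config) {
  np <- config$np
  branch_da <- continue_branch(set_stress(np,
                                          epsilon = config$branch_eps),
                               "delta_a", config$delta_a_range,
                               steps = 41L)
  branch_eps <- continue_branch(set_stress(np,
                                           delta_a = config$branch_delta_a),
                                "epsilon", config$eps_range, steps = 41L)
  list(fig4 = list(
    hopf_da = detect_hopf(branch_da),
    hopf_eps = detect_hopf(branch_eps),
    branch_da = branch_da,
    branch_eps = branch_eps,
    sweep = sweep_excitation_time(np, config$delta_a_range,
                                  config$eps_range, resolution = 5L,
                                  engine = "ode")))
}

run_fig6 <- function(config) {
  res <- list()
  for (n in config$n) {
    np_n <- config$np
    np_n$n <- n
    for (vn in names(config$variants)) {
      v <- config$variants[[vn]]
      nc <- nullclines(np_n, variant = v)
      folds <- attr(nc, "folds")
      # the bend in NC(x) (nonlinearity of degree >= 2) is the
      # structural prerequisite for an excitation threshold
      entry <- list(n = n, variant = v, n_folds = length(folds),
                    has_threshold = length(folds) >= 2L)
      fps <- suppressWarnings(find_fixed_points(np_n, v))
      if (length(fps) >= 1L) {
        fp <- fps[[1L]]
        traj <- ta_integrate(np_n, c(0.9 * np_n$kappa, fp$y),
                             120 / np_n$epsilon,
                             representation = "reduced", variant = v,
                             n_out = 6000L)
        ev <- detect_excitations(traj, np_n$kappa)
        entry$excitation_time <- if (nrow(ev)) max(ev$duration) else 0
        entry$peak <- max(traj$x)
        entry$trajectory <- traj
      } else {
        entry$excitation_time <- 0
      }
      res[[paste0("n", n, "_", vn)]] <- entry
    }
  }
  list(fig6 = res)
}

write_bundle <- function(out, config, seed, outdir) {
  manifest <- list(scenario = config$name, seed = seed,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   extras = config$extras,
                   files = character(0))
  flatten <- function(x, prefix) {
    for (nm in names(x)) {
      v <- x[[nm]]
      path <- file.path(outdir, paste0(prefix, nm, ".csv"))
      if (inherits(v, "data.frame")) {
        utils::write.csv(as.data.frame(v), path, row.names = FALSE)
        manifest$files <<- c(manifest$files, basename(path))
      } else if (is.list(v) && !inherits(v, "ta_variant") &&
                 !inherits(v, "ta_fixed_point")) {
        flatten(v, paste0(prefix, nm, "_"))
      }
    }
  }
  flatten(out, "")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
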