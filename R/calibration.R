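aux_stat_order <- function() {
  per_gender <- c(paste0("mean_R", 1:3), paste0("sd_R", 1:3),
                  "mean_D1", "mean_D3", "sd_D1", "sd_D3",
                  "mean_S1", "mean_S3", "sd_S1", "sd_S3")
  c(paste0("girl_", per_gender), paste0("boy_", per_gender),
    "cor_R1_R2", "cor_R2_R3", "cor_D1_D3", "cor_S1_S3",
    "cor_R1_D3", "cor_D1_R3", "cor_S1_R3", "cor_S1_D3")
}

# panel in wide per-individual form: id, gender, R1..R3, D1, D3, S1, S3
#' @keywords internal
#' @noRd
panel_wide <- function(panel) {
  w <- tidyr::pivot_wider(
    dplyr::select(panel, "id", "gender", "wave", "cdi", "rumination",
                  "stressors"),
    names_from = "wave", values_from = c("rumination", "cdi", "stressors")
  )
  dplyr::rename(w, R1 = "rumination_1", R2 = "rumination_2",
                R3 = "rumination_3", D1 = "cdi_1", D3 = "cdi_3",
                S1 = "stressors_1", S3 = "stressors_3")
}

#' @keywords internal
#' @noRd
aux_stats_wide <- function(w) {
  safe_cor <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warn("degenerate variance in a correlation statistic; recording 0",
           class = "rumidyn_degenerate_stat")
      return(0)
    }
    cor(x, y)
  }
  per_gender <- function(gd) {
    s <- w[w$gender == gd, ]
    c(mean(s$R1), mean(s$R2), mean(s$R3), sd(s$R1), sd(s$R2), sd(s$R3),
      mean(s$D1), mean(s$D3), sd(s$D1), sd(s$D3),
      mean(s$S1), mean(s$S3), sd(s$S1), sd(s$S3))
  }
  vals <- c(per_gender("girl"), per_gender("boy"),
            safe_cor(w$R1, w$R2), safe_cor(w$R2, w$R3),
            safe_cor(w$D1, w$D3), safe_cor(w$S1, w$S3),
            safe_cor(w$R1, w$D3), safe_cor(w$D1, w$R3),
            safe_cor(w$S1, w$R3), safe_cor(w$S1, w$D3))
  setNames(vals, aux_stat_order())
}

#' Auxiliary statistics of a three-wave panel
#'
#' Computes the fixed, ordered vector of auxiliary statistics the
#' indirect-inference estimator matches: per-gender means and sample SDs of
#' rumination at all three waves and of depression and stressor counts at
#' waves 1 and 3 (28 statistics), plus eight pooled cross-wave and
#' cross-construct Pearson correlations:
#' `cor(R1,R2)`, `cor(R2,R3)`, `cor(D1,D3)`, `cor(S1,S3)`, `cor(R1,D3)`,
#' `cor(D1,R3)`, `cor(S1,R3)`, `cor(S1,D3)`. These are the moments the
#' three-wave design identifies. A degenerate (zero-variance) correlation
#' is recorded as 0 with a warning rather than an error.
#'
#' @param panel A valid panel (see [generate_panel()]); at least two
#'   individuals per gender.
#' @return A tibble with columns `stat` and `value`, in the estimator's
#'   fixed order.
#' @export
aux_stats <- function(panel) {
  validate_panel(panel)
  w <- panel_wide(panel)
  if (any(table(factor(w$gender, c("girl", "boy"))) < 2)) {
    abort("need at least 2 individuals per gender",
          class = "rumidyn_invalid_input")
  }
  v <- aux_stats_wide(w)
  tibble::tibble(stat = names(v), value = unname(v))
}

#' Bootstrap weights for the calibration objective
#'
#' Estimates the sampling variance of each auxiliary statistic by a
#' nonparametric bootstrap of the empirical panel (resampling individuals
#' with replacement, stratified by gender) and returns diagonal weights
#' equal to the inverse variances. Statistics with (numerically) zero
#' bootstrap variance get weight 0 with a warning.
#'
#' @param panel The empirical panel.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Integer seed.
#' @return A tibble with columns `stat` and `weight`.
#' @export
aux_weights <- function(panel, B = 500, seed = 1) {
  validate_panel(panel)
  w <- panel_wide(panel)
  idx_g <- which(w$gender == "girl")
  idx_b <- which(w$gender == "boy")
  set.seed(child_seed(seed, 0))
  reps <- matrix(NA_real_, B, length(aux_stat_order()))
  for (b in seq_len(B)) {
    take <- c(sample(idx_g, length(idx_g), replace = TRUE),
              sample(idx_b, length(idx_b), replace = TRUE))
    reps[b, ] <- suppressWarnings(aux_stats_wide(w[take, ]))
  }
  v <- apply(reps, 2, stats::var)
  wt <- ifelse(v > 1e-12, 1 / v, 0)
  if (any(v <= 1e-12)) {
    warn("some auxiliary statistics have ~zero bootstrap variance; weight set to 0",
         class = "rumidyn_degenerate_stat")
  }
  tibble::tibble(stat = aux_stat_order(), weight = wt)
}

#' Default box bounds for the behavioural parameters
#'
#' Generous bounds used by [calibrate_model()] when none are supplied. They
#' encode only structural requirements: `theta8 < 1` (finite depression
#' fixed point), `theta9 > 0`, noise SDs non-negative, and a correlation
#' time compatible with the integration step.
#'
#' @param params A [model_params()] object (for the `dt`-dependent lower
#'   bound on `theta12`).
#' @return A tibble with columns `term`, `lower`, `upper`.
#' @export
default_bounds <- function(params = model_params()) {
  tibble::tibble(
    term = paste0("theta", 1:12),
    lower = c(-20, -5, -20, -5, -0.99, -20, -2, -0.99, 0.01, 0, 0, 4 * params$dt),
    upper = c(20, 5, 20, 5, 0.99, 20, 2, 0.99, 10, 40, 40, 24)
  )
}

#' Indirect-inference objective
#'
#' The weighted quadratic distance between simulated and empirical
#' auxiliary statistics,
#' `(s_sim(theta) - s_emp)' W (s_sim(theta) - s_emp)` with diagonal `W`.
#' Simulated statistics condition on the empirical panel's wave-1 records
#' ([panel_profiles()]): each objective evaluation re-simulates `n_sim`
#' synthetic copies of the cohort with the *same* seed set (common random
#' numbers) and averages their statistics, so the objective is a
#' deterministic function of `theta`. Parameter vectors violating the
#' structural bounds return a large penalty (not an error), keeping the
#' objective optimizer-friendly.
#'
#' @param theta Named numeric vector of behavioural parameters to override
#'   (subset of `theta1`...`theta12`).
#' @param empirical Empirical auxiliary statistics, as from [aux_stats()].
#' @param panel The empirical panel (supplies wave-1 conditioning).
#' @param params Baseline [model_params()]; entries named in `theta` are
#'   replaced.
#' @param weights Diagonal weights, as from [aux_weights()]; default: unit
#'   weights.
#' @param n_sim Synthetic cohort copies averaged per evaluation.
#' @param seed_set Integer vector of length `n_sim`, reused at every
#'   `theta`.
#' @param spec A [cohort_spec()] carrying the assessment schedule.
#' @param bounds Bounds tibble as [default_bounds()].
#' @return A non-negative scalar.
#' @export
calib_objective <- function(theta, empirical, panel, params = model_params(),
                            weights = NULL, n_sim = 5,
                            seed_set = child_seed(1, seq_len(n_sim) - 1),
                            spec = cohort_spec(), bounds = default_bounds(params)) {
  stopifnot(length(seed_set) == n_sim)
  bl <- setNames(bounds$lower, bounds$term)
  bu <- setNames(bounds$upper, bounds$term)
  viol <- sum(pmax(bl[names(theta)] - theta, 0) +
                pmax(theta - bu[names(theta)], 0))
  if (is.na(viol) || viol > 0) {
    return(1e8 * (1 + ifelse(is.na(viol), 1, viol)))
  }
  p2 <- params
  p2[names(theta)] <- as.list(unname(theta))
  ok <- tryCatch({
    validate_params(p2)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(2e8)

  prof <- panel_profiles(panel)
  emp <- setNames(empirical$value, empirical$stat)[aux_stat_order()]
  wt <- if (is.null(weights)) {
    rep(1, length(emp))
  } else {
    setNames(weights$weight, weights$stat)[aux_stat_order()]
  }
  sims <- vapply(seed_set, function(s) {
    pan <- generate_panel(prof, p2, spec, seed = s)
    suppressWarnings(aux_stats_wide(panel_wide(pan)))
  }, numeric(length(emp)))
  s_sim <- rowMeans(sims)
  sum(wt * (s_sim - emp)^2)
}

#' Calibrate the model by indirect inference
#'
#' Minimizes [calib_objective()] over a chosen subset of the behavioural
#' parameters with a derivative-free simplex (Nelder--Mead) restarted from
#' jittered starting points. Common random numbers make the objective
#' deterministic in `theta`; restarts guard against the kinks a simulated
#' objective retains even then.
#'
#' @param panel The empirical (or synthetic) panel to fit.
#' @param init Named numeric vector: the free parameters and their starting
#'   values; all other parameters stay fixed at `params`.
#' @param params Baseline [model_params()].
#' @param bounds Bounds tibble (see [default_bounds()]); `init` must lie
#'   inside.
#' @param options List of optimizer settings: `n_starts` (default 10),
#'   `maxit` (300 Nelder--Mead iterations per start), `reltol` (1e-8),
#'   `n_sim` (5 cohort copies per evaluation), `seed` (1), `jitter`
#'   (relative start spread 0.25), `weights_B` (500 bootstrap replicates
#'   for the weight matrix), `weights` (precomputed weights tibble,
#'   overrides `weights_B`), `spec` (a [cohort_spec()]).
#' @return An object of class `rumidyn_calibration` with elements
#'   `estimate` (named vector), `params_hat` (full parameter object at the
#'   optimum), `objective`, `n_eval`, `converged`, `starts`, `seed_set`,
#'   `weights`, `init`, `bounds`. Supports [tidy()], [glance()], and
#'   [bootstrap_se()].
#' @examples
#' \donttest{
#' spec <- cohort_spec(n_girls = 60, n_boys = 60)
#' panel <- generate_panel(sample_profiles(spec, 1), model_params(), spec, 1)
#' fit <- calibrate_model(panel, init = c(theta9 = 1.4741),
#'                        options = list(n_starts = 1, maxit = 40,
#'                                       n_sim = 2, weights_B = 50))
#' tidy(fit)
#' }
#' @export
calibrate_model <- function(panel, init, params = model_params(),
                            bounds = default_bounds(params),
                            options = list()) {
  validate_panel(panel)
  o <- modifyList(list(n_starts = 10, maxit = 300, reltol = 1e-8, n_sim = 5,
                       seed = 1, jitter = 0.25, weights_B = 500,
                       weights = NULL, spec = cohort_spec()), options)
  if (is.null(names(init)) || !all(names(init) %in% paste0("theta", 1:12))) {
    abort("`init` must be a named vector of theta parameters",
          class = "rumidyn_invalid_config")
  }
  bl <- setNames(bounds$lower, bounds$term)[names(init)]
  bu <- setNames(bounds$upper, bounds$term)[names(init)]
  if (any(init < bl | init > bu)) {
    abort("`init` violates the parameter bounds",
          class = "rumidyn_invalid_config")
  }
  weights <- o$weights %||%
    aux_weights(panel, B = o$weights_B, seed = child_seed(o$seed, 101))
  empirical <- suppressWarnings(aux_stats(panel))
  seed_set <- child_seed(o$seed, seq_len(o$n_sim) - 1)

  n_eval <- 0L
  fn <- function(th) {
    n_eval <<- n_eval + 1L
    calib_objective(setNames(th, names(init)), empirical, panel, params,
                    weights, o$n_sim, seed_set, o$spec, bounds)
  }
  f0 <- fn(init)

  starts <- list(init)
  if (o$n_starts > 1) {
    set.seed(child_seed(o$seed, 202))
    for (j in seq_len(o$n_starts - 1)) {
      jit <- init * (1 + o$jitter * runif(length(init), -1, 1)) +
        o$jitter * 0.05 * (bu - bl) * runif(length(init), -1, 1)
      starts[[j + 1]] <- pmin(pmax(jit, bl), bu)
    }
  }
  best <- NULL
  for (st in starts) {
    res <- if (length(init) == 1) {
      optim(st, fn, method = "Brent", lower = bl, upper = bu,
            control = list(maxit = o$maxit))
    } else {
      optim(st, fn, method = "Nelder-Mead",
            control = list(maxit = o$maxit, reltol = o$reltol))
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  est <- setNames(as.numeric(best$par), names(init))
  p_hat <- params
  p_hat[names(est)] <- as.list(unname(est))

  structure(list(
    estimate = est,
    params_hat = p_hat,
    std_error = NULL,
    objective = best$value,
    init_objective = f0,
    n_eval = n_eval,
    converged = best$value <= f0 + 1e-12,
    starts = length(starts),
    seed_set = seed_set,
    n_sim = o$n_sim,
    weights = weights,
    weight_description = "diagonal inverse bootstrap variance",
    init = init,
    bounds = bounds,
    options = o,
    n_individuals = length(unique(panel$id))
  ), class = "rumidyn_calibration")
}

#' Parametric-bootstrap standard errors for a calibration fit
#'
#' Simulates `B` synthetic panels at the estimated parameters (conditioning
#' on the empirical wave-1 records), re-estimates the free parameters on
#' each, and reports the standard deviation of the replicate estimates.
#' Replicates whose re-estimation fails to improve on its start are dropped
#' with a warning; if fewer than `B/2` replicates remain, an error is
#' raised.
#'
#' @param panel The empirical panel the fit was obtained from.
#' @param fit A `rumidyn_calibration` object.
#' @param B Number of bootstrap replicates (`>= 2`).
#' @param options Optimizer options for the replicate fits; defaults to the
#'   original fit's options with a single start. `replicate_seeds` (integer
#'   vector of length `B`) overrides the derived per-replicate seeds.
#' @param seed Master seed for replicate simulation.
#' @return The fit, with `std_error` (named vector) and `bootstrap` (a
#'   tibble of replicate estimates) attached; [tidy()] then reports the
#'   SEs.
#' @export
bootstrap_se <- function(panel, fit, B = 20, options = list(), seed = 1) {
  stopifnot(inherits(fit, "rumidyn_calibration"))
  if (B < 2) abort("`B` must be >= 2", class = "rumidyn_invalid_config")
  o <- modifyList(fit$options, list(n_starts = 1, weights = fit$weights))
  o <- modifyList(o, options)
  rep_seeds <- o$replicate_seeds %||% child_seed(seed, 1000 + seq_len(B))
  stopifnot(length(rep_seeds) == B)
  prof <- panel_profiles(panel)
  ests <- vector("list", B)
  for (b in seq_len(B)) {
    pan_b <- generate_panel(prof, fit$params_hat, o$spec, seed = rep_seeds[b])
    fit_b <- calibrate_model(pan_b, init = fit$estimate,
                             params = fit$params_hat, bounds = fit$bounds,
                             options = o)
    ests[[b]] <- if (fit_b$converged) fit_b$estimate else NULL
  }
  dropped <- sum(vapply(ests, is.null, logical(1)))
  if (dropped > 0) {
    warn(sprintf("%d of %d bootstrap replicates did not converge and were dropped",
                 dropped, B), class = "rumidyn_bootstrap_dropped")
  }
  if (B - dropped < B / 2) {
    abort("fewer than half the bootstrap replicates converged",
          class = "rumidyn_bootstrap_failed")
  }
  mat <- do.call(rbind, ests[!vapply(ests, is.null, logical(1))])
  fit$std_error <- apply(mat, 2, sd)
  fit$bootstrap <- tibble::as_tibble(mat)
  fit$bootstrap_B <- B
  fit
}

#' @export
print.rumidyn_calibration <- function(x, ...) {
  cat("<rumidyn_calibration>\n")
  cat(sprintf("  %d free parameter(s), objective %.6g after %d evaluations (%s)\n",
              length(x$estimate), x$objective, x$n_eval,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `rumidyn_calibration` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `term`, `estimate`, and `std.error`
#'   (NA until [bootstrap_se()] has been run). `glance()`: a one-row
#'   tibble with the objective value, evaluation count, convergence flag,
#'   start count, and cohort size.
#' @export
tidy.rumidyn_calibration <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = if (is.null(x$std_error)) NA_real_ else unname(x$std_error)
  )
}

#' @rdname tidy.rumidyn_calibration
#' @export
glance.rumidyn_calibration <- function(x, ...) {
  tibble::tibble(
    objective = x$objective,
    n_eval = x$n_eval,
    converged = x$converged,
    n_starts = x$starts,
    n_sim = x$n_sim,
    n_individuals = x$n_individuals
  )
}
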