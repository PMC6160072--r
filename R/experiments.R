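#' The 2^4 factorial profile design
#'
#' Builds the sixteen experimental groups for one gender: every combination
#' of high/low initial depressive symptoms (`D0`), initial rumination
#' (`R0`), prior stressors (`S0`), and ongoing-stressor inflow. High and
#' low levels of `D0` and `R0` are the gender's wave-1 mean plus/minus one
#' SD; the high level of `S0` and of the six-month stressor total is the
#' mean plus two SDs, and the low level is zero (stressor counts cannot go
#' negative). The inflow is the six-month total divided by six
#' (events/month).
#'
#' Group ordering: groups 1--8 have high `D0`; within each half, groups are
#' blocked by `R0` (high first), then `S0`, then inflow, so group 1 is
#' all-high and group 16 all-low.
#'
#' @param gender `"girl"` or `"boy"`.
#' @param moments Wave-1 moments tibble (default [table1_moments()]).
#' @param n_rep Replicates simulated per group (default 2500).
#' @param horizon Simulation horizon in months (default 120).
#' @return A tibble of 16 rows: `group`, `gender`, the four level flags
#'   (`"high"`/`"low"`), the resolved `D0`, `R0`, `S0`, `inflow`, and
#'   `n_rep`, `horizon`.
#' @examples
#' factorial_levels("girl")[1:2, ]
#' @export
factorial_levels <- function(gender = c("girl", "boy"),
                             moments = table1_moments(),
                             n_rep = 2500L, horizon = 120) {
  gender <- match.arg(gender)
  mo <- moments[moments$gender == gender, ]
  if (nrow(mo) != 3) {
    abort("`moments` must contain D, R, S rows for the requested gender",
          class = "rumidyn_invalid_config")
  }
  mv <- function(v) mo[mo$variable == v, ]
  lv <- tidyr::expand_grid(
    d0_level = c("high", "low"), r0_level = c("high", "low"),
    s0_level = c("high", "low"), inflow_level = c("high", "low")
  )
  lvl <- function(level, hi, lo) ifelse(level == "high", hi, lo)
  dplyr::mutate(
    lv,
    group = dplyr::row_number(),
    gender = gender,
    D0 = lvl(.data$d0_level, mv("D")$mean + mv("D")$sd,
              mv("D")$mean - mv("D")$sd),
    R0 = lvl(.data$r0_level, mv("R")$mean + mv("R")$sd,
              mv("R")$mean - mv("R")$sd),
    S0 = lvl(.data$s0_level, mv("S")$mean + 2 * mv("S")$sd, 0),
    inflow = lvl(.data$inflow_level, (mv("S")$mean + 2 * mv("S")$sd) / 6, 0),
    n_rep = as.integer(n_rep),
    horizon = horizon,
    .before = 1
  )[, c("group", "gender", "d0_level", "r0_level", "s0_level", "inflow_level",
        "D0", "R0", "S0", "inflow", "n_rep", "horizon")]
}

#' Monte-Carlo trajectory ensemble for one experimental group
#'
#' Simulates `n_rep` individuals with identical inputs, differing only in
#' the realization of the autocorrelated process noise, and summarises the
#' depressive-symptom trajectories at each month: the ensemble mean, the
#' 12.5th and 87.5th percentiles (the band enveloping 75% of replicate
#' trajectories), and the fraction above the clinical threshold of 16.
#'
#' @param group A one-row data frame with `gender`, `D0`, `R0`, `S0`,
#'   `inflow`, and optionally `n_rep` and `horizon` (one row of
#'   [factorial_levels()]).
#' @param params A [model_params()] object.
#' @param seed Integer seed.
#' @param n_rep,horizon Override the group's replicate count / horizon.
#' @param noise Set `FALSE` for a deterministic (zero-width envelope) run.
#' @return A tibble of class `rumidyn_scenario`: `month`, `mean_D`, `lo`
#'   (12.5th pct), `hi` (87.5th pct), `frac_clinical`.
#' @examples
#' g1 <- factorial_levels("girl")[1, ]
#' run_scenario(g1, model_params(), seed = 1, n_rep = 50, horizon = 24)
#' @export
run_scenario <- function(group, params, seed = 1,
                         n_rep = group$n_rep %||% 2500L,
                         horizon = group$horizon %||% 120,
                         noise = TRUE) {
  validate_params(params)
  stopifnot(nrow(group) == 1)
  n <- if (noise) n_rep else 1L
  eng <- sim_engine(rep(group$D0, n), rep(group$R0, n), rep(group$S0, n),
                    rep(gender01(group$gender), n), rep(group$inflow, n),
                    params, horizon, seed, noise = noise, record = "monthly")
  qs <- apply(eng$D, 1, quantile, probs = c(0.125, 0.875), names = FALSE)
  out <- tibble::tibble(
    month = eng$times,
    mean_D = rowMeans(eng$D),
    lo = qs[1, ],
    hi = qs[2, ],
    frac_clinical = rowMeans(eng$D > 16)
  )
  class(out) <- c("rumidyn_scenario", class(out))
  attr(out, "group") <- group
  out
}

#' Run several factorial groups
#'
#' Convenience wrapper: [run_scenario()] over the rows of a
#' [factorial_levels()] table, with per-group child seeds derived from the
#' master seed, bound into one long tibble.
#'
#' @param groups A [factorial_levels()] tibble (or subset of rows).
#' @param params A [model_params()] object.
#' @param seed Master seed; group `g` runs on `child_seed(seed, g)`.
#' @param ... Passed to [run_scenario()].
#' @return A tibble with a `group` column prepended to the
#'   [run_scenario()] columns.
#' @export
run_factorial <- function(groups, params, seed = 1, ...) {
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    res <- run_scenario(g, params, seed = child_seed(seed, g$group), ...)
    dplyr::mutate(tibble::as_tibble(res), group = g$group, .before = 1)
  })
}

#' Terminal depressive symptoms over a rumination-by-inflow grid
#'
#' The sensitivity analysis behind the contour view of long-run outcomes:
#' initial depressive symptoms and prior stressors are pinned at their
#' wave-1 means while initial rumination and the ongoing-stressor inflow
#' vary over a grid. Each cell reports the mean depressive-symptom level at
#' the end of the horizon across `n_rep` noise replicates, and whether the
#' cell mean reaches the clinical threshold of 16.
#'
#' @param params A [model_params()] object.
#' @param gender `"girl"` or `"boy"`.
#' @param R0_values,inflow_values Grid axes (rumination score; events per
#'   month).
#' @param D0,S0 Fixed initial depression and prior stressors; defaults are
#'   the girls' wave-1 means (9.98 and 4.97).
#' @param n_rep Noise replicates per cell (default 100).
#' @param horizon Months simulated (default 120).
#' @param seed Integer seed.
#' @param noise Set `FALSE` for the deterministic grid.
#' @return A tibble of class `rumidyn_sensitivity`: `R0`, `inflow`,
#'   `mean_D`, `depressed` (`mean_D >= 16`).
#' @examples
#' sensitivity_grid(model_params(), R0_values = c(5, 20),
#'                  inflow_values = c(0, 1), n_rep = 10, seed = 1)
#' @export
sensitivity_grid <- function(params, gender = "girl",
                             R0_values = seq(0, 25, length.out = 10),
                             inflow_values = seq(0, 2, length.out = 10),
                             D0 = 9.98, S0 = 4.97,
                             n_rep = 100, horizon = 120, seed = 1,
                             noise = TRUE) {
  validate_params(params)
  if (!length(R0_values) || !length(inflow_values)) {
    abort("grid axes must be non-empty", class = "rumidyn_invalid_input")
  }
  cells <- tidyr::expand_grid(R0 = R0_values, inflow = inflow_values)
  n <- if (noise) n_rep else 1L
  idx <- rep(seq_len(nrow(cells)), each = n)
  eng <- sim_engine(rep(D0, length(idx)), cells$R0[idx], rep(S0, length(idx)),
                    rep(gender01(gender), length(idx)), cells$inflow[idx],
                    params, horizon, seed, noise = noise, record = "terminal")
  mean_D <- as.numeric(tapply(eng$terminal$D, idx, mean))
  out <- dplyr::mutate(cells, mean_D = mean_D, depressed = mean_D >= 16)
  class(out) <- c("rumidyn_sensitivity", class(out))
  out
}

#' Memory time by gender and baseline rumination
#'
#' The memory-time experiment: every individual in a cohort is simulated
#' over the study horizon (7 months by default, process noise on), memory
#' time `M(t) = max(theta9 * R(t), M_min)` is averaged over the whole
#' integration grid for each individual, and group means are reported for
#' all girls and all boys and for the initially depressed (`D0 >` the
#' clinical cut) split at baseline rumination above/below the cohort mean
#' cut. Each row carries the Welch t-test p-value for the girl--boy
#' contrast of per-individual average memory times.
#'
#' @param profiles Profile tibble (e.g. from [sample_profiles()]).
#' @param params A [model_params()] object.
#' @param horizon Months simulated (default 7, the study span).
#' @param seed Integer seed.
#' @param rum_cut Baseline-rumination split point (default 11.59, the
#'   published overall wave-1 mean, fixed rather than recomputed).
#' @param dep_cut Clinical depression threshold on `D0` (default 16).
#' @param noise Process noise on/off.
#' @return A tibble with columns `group` (`"all"`,
#'   `"depressed_high_rum"`, `"depressed_low_rum"`), `mean_girls`,
#'   `mean_boys`, `n_girls`, `n_boys`, `p_value`. Empty subgroups yield
#'   `NA` means and p-values rather than errors.
#' @examples
#' prof <- sample_profiles(cohort_spec(n_girls = 30, n_boys = 30), seed = 1)
#' memory_time_summary(prof, model_params(), seed = 1)
#' @export
memory_time_summary <- function(profiles, params, horizon = 7, seed = 1,
                                rum_cut = 11.59, dep_cut = 16, noise = TRUE) {
  validate_params(params)
  eng <- sim_engine(profiles$D0, profiles$R0, profiles$S0,
                    gender01(profiles$gender), profiles$inflow,
                    params, horizon, child_seed(seed, 0),
                    noise = noise, record = "none")
  d <- tibble::tibble(
    gender = profiles$gender,
    D0 = profiles$D0, R0 = profiles$R0,
    avg_M = eng$avg_M
  )
  one_group <- function(label, sub) {
    g <- sub$avg_M[sub$gender == "girl"]
    b <- sub$avg_M[sub$gender == "boy"]
    p <- if (length(g) >= 2 && length(b) >= 2 && (sd(g) > 0 || sd(b) > 0)) {
      t.test(g, b)$p.value
    } else NA_real_
    tibble::tibble(
      group = label,
      mean_girls = if (length(g)) mean(g) else NA_real_,
      mean_boys = if (length(b)) mean(b) else NA_real_,
      n_girls = length(g), n_boys = length(b),
      p_value = p
    )
  }
  dplyr::bind_rows(
    one_group("all", d),
    one_group("depressed_high_rum", d[d$D0 > dep_cut & d$R0 > rum_cut, ]),
    one_group("depressed_low_rum", d[d$D0 > dep_cut & d$R0 < rum_cut, ])
  )
}
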