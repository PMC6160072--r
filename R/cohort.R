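#' Specification of a synthetic three-wave cohort
#'
#' Describes the study design the generator emulates: per-gender counts and
#' wave-1 moments of the three instruments, truncation bounds, the
#' stressor-inflow rule, measurement-noise standard deviations, and the
#' assessment schedule (three waves at months 0, 4, and 7; rumination
#' observed at all three, depression and stressor counts at waves 1 and 3
#' only). Defaults reproduce the published cohort: 353 girls and 308 boys
#' with the wave-1 means/SDs of [table1_moments()].
#'
#' @param n_girls,n_boys Cohort sizes.
#' @param moments Wave-1 moments, a tibble like [table1_moments()] with
#'   columns `gender`, `variable` (`"D"`, `"R"`, `"S"`), `mean`, `sd`.
#' @param bounds Named list of `c(lower, upper)` truncation bounds for
#'   `D`, `R`, `S` (defaults: instrument ranges 0--52, 0--39, 0--25).
#' @param correlation 3x3 correlation matrix (order `D`, `R`, `S`) of the
#'   Gaussian copula coupling the initial conditions; identity by default
#'   (independent truncated normals; the study reports only marginal
#'   moments).
#' @param inflow_rule Function mapping the wave-1 stressor count `S0` to a
#'   constant inflow rate (events/month). The default `S0 / 6` reads the
#'   checklist, which covers the past six months, as a rate.
#' @param s0_scale Multiplier applied to the wave-1 stressor count to set
#'   the initial past-stressors-kept-alive stock (default 1: all reported
#'   events start alive).
#' @param meas_sd Named numeric, measurement-noise SD per instrument
#'   (`D`, `R`, `S`); all zero by default (the estimation treats process
#'   noise only).
#' @param wave_months Assessment months, strictly increasing from 0.
#' @param cdi_waves,rum_waves,stress_waves Waves at which each instrument
#'   is observed.
#' @return An object of class `rumidyn_cohort_spec`.
#' @seealso [sample_profiles()], [generate_panel()]
#' @export
cohort_spec <- function(n_girls = 353L, n_boys = 308L,
                        moments = table1_moments(),
                        bounds = list(D = c(0, 52), R = c(0, 39), S = c(0, 25)),
                        correlation = diag(3),
                        inflow_rule = function(s0) s0 / 6,
                        s0_scale = 1,
                        meas_sd = c(D = 0, R = 0, S = 0),
                        wave_months = c(0, 4, 7),
                        cdi_waves = c(1L, 3L),
                        rum_waves = 1:3,
                        stress_waves = c(1L, 3L)) {
  if (n_girls < 0 || n_boys < 0) {
    abort("cohort counts must be >= 0", class = "rumidyn_invalid_config")
  }
  if (any(moments$sd < 0)) {
    abort("moment `sd` values must be >= 0", class = "rumidyn_invalid_config")
  }
  if (wave_months[1] != 0 || is.unsorted(wave_months, strictly = TRUE) ||
      length(wave_months) != 3) {
    abort("`wave_months` must be three strictly increasing months starting at 0",
          class = "rumidyn_invalid_config")
  }
  if (any(meas_sd < 0)) {
    abort("`meas_sd` must be >= 0", class = "rumidyn_invalid_config")
  }
  if (!isTRUE(all.equal(dim(correlation), c(3, 3))) ||
      any(abs(correlation - t(correlation)) > 1e-12)) {
    abort("`correlation` must be a symmetric 3x3 matrix",
          class = "rumidyn_invalid_config")
  }
  # infeasible truncation: mean further than 6 SD outside the interval
  for (v in c("D", "R", "S")) {
    mo <- moments[moments$variable == v, ]
    b <- bounds[[v]]
    bad <- mo$sd > 0 &
      (mo$mean < b[1] - 6 * mo$sd | mo$mean > b[2] + 6 * mo$sd)
    if (any(bad) || any(mo$sd == 0 & (mo$mean < b[1] | mo$mean > b[2]))) {
      abort(paste0("moments for `", v, "` are infeasible under its bounds"),
            class = "rumidyn_invalid_config")
    }
  }
  structure(list(
    n_girls = as.integer(n_girls), n_boys = as.integer(n_boys),
    moments = moments, bounds = bounds, correlation = correlation,
    inflow_rule = inflow_rule, s0_scale = s0_scale, meas_sd = meas_sd,
    wave_months = wave_months, cdi_waves = as.integer(cdi_waves),
    rum_waves = as.integer(rum_waves), stress_waves = as.integer(stress_waves)
  ), class = "rumidyn_cohort_spec")
}

# inverse-CDF truncated-normal sampler driven by standard-normal draws
# (Gaussian copula when draws are correlated)
#' @keywords internal
#' @noRd
qtrunc_norm <- function(z, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), length(z)))
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  qnorm(p_lo + pnorm(z) * (p_hi - p_lo), mean, sd)
}

#' Draw individual profiles for a synthetic cohort
#'
#' Samples initial conditions (`D0`, `R0`, `S0`) per gender from truncated
#' normal distributions at the spec's wave-1 moments, coupled through a
#' Gaussian copula with the spec's correlation matrix (identity by default,
#' i.e. independent marginals), and assigns each individual a constant
#' stressor inflow through the spec's inflow rule.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the draw is deterministic given `(spec, seed)`.
#' @return A tibble of profiles: `id`, `gender`, `D0`, `R0`, `S0`,
#'   `inflow`, ready for [simulate_profiles()] or [generate_panel()].
#' @examples
#' prof <- sample_profiles(cohort_spec(n_girls = 5, n_boys = 5), seed = 1)
#' prof
#' @export
sample_profiles <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "rumidyn_cohort_spec"))
  set.seed(child_seed(seed, 0))
  Lc <- chol(spec$correlation)
  one_gender <- function(gender, n) {
    if (n == 0) {
      return(tibble::tibble(gender = character(), D0 = numeric(),
                            R0 = numeric(), S0 = numeric()))
    }
    Z <- matrix(rnorm(3 * n), n, 3) %*% Lc
    mo <- spec$moments[spec$moments$gender == gender, ]
    draw <- function(j, v) {
      m <- mo[mo$variable == v, ]
      qtrunc_norm(Z[, j], m$mean, m$sd, spec$bounds[[v]][1], spec$bounds[[v]][2])
    }
    tibble::tibble(gender = gender, D0 = draw(1, "D"), R0 = draw(2, "R"),
                   S0 = draw(3, "S"))
  }
  out <- dplyr::bind_rows(one_gender("girl", spec$n_girls),
                          one_gender("boy", spec$n_boys))
  out$S0 <- out$S0 * spec$s0_scale
  dplyr::mutate(out,
                id = dplyr::row_number(),
                inflow = spec$inflow_rule(.data$S0),
                .before = 1)
}

#' Simulate a three-wave measurement panel from profiles
#'
#' Runs the stock-flow model for every profile over the assessment horizon
#' (process noise on), reads the stocks at the wave months, adds optional
#' measurement noise, rounds to integer instrument scores, and clips to the
#' instrument ranges. The wave-1 records therefore equal the (noisified,
#' rounded) initial conditions. Instruments not scheduled at a wave are
#' recorded as missing, matching the study design: depression and stressor
#' counts are absent at wave 2.
#'
#' @param profiles Profile tibble as from [sample_profiles()].
#' @param params A [model_params()] object.
#' @param spec A [cohort_spec()] (assessment schedule and measurement
#'   noise).
#' @param seed Integer seed; process and measurement noise streams are
#'   derived from it.
#' @return A long panel tibble: `id`, `gender`, `wave`, `month`, `cdi`,
#'   `rumination`, `stressors`.
#' @examples
#' spec <- cohort_spec(n_girls = 4, n_boys = 4)
#' panel <- generate_panel(sample_profiles(spec, 1), model_params(), spec, 1)
#' panel
#' @export
generate_panel <- function(profiles, params, spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "rumidyn_cohort_spec"))
  validate_params(params)
  horizon <- max(spec$wave_months)
  eng <- sim_engine(profiles$D0, profiles$R0, profiles$S0,
                    gender01(profiles$gender), profiles$inflow,
                    params, horizon, child_seed(seed, 0),
                    noise = TRUE, record = "grid")
  w_idx <- vapply(spec$wave_months,
                  function(m) which.min(abs(eng$times - m)), integer(1))
  n <- nrow(profiles)
  set.seed(child_seed(seed, 1))
  measure <- function(x, sd_m, rng) {
    x <- x + if (sd_m > 0) rnorm(length(x), 0, sd_m) else 0
    pmin(pmax(round(x), rng[1]), rng[2])
  }
  rows <- purrr::map(1:3, function(w) {
    tibble::tibble(
      id = profiles$id,
      gender = profiles$gender,
      wave = w,
      month = spec$wave_months[w],
      cdi = if (w %in% spec$cdi_waves) {
        measure(eng$D[w_idx[w], ], spec$meas_sd[["D"]], c(0, 52))
      } else NA_real_,
      rumination = if (w %in% spec$rum_waves) {
        measure(eng$R[w_idx[w], ], spec$meas_sd[["R"]], c(0, 39))
      } else NA_real_,
      stressors = if (w %in% spec$stress_waves) {
        measure(eng$S[w_idx[w], ], spec$meas_sd[["S"]], c(0, 25))
      } else NA_real_
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$id, .data$wave)
}

#' Recover simulation profiles from a panel's first wave
#'
#' Reads each individual's wave-1 record as initial conditions (`D0` from
#' `cdi`, `R0` from `rumination`, `S0` from `stressors`) and sets the
#' constant inflow with `inflow_rule` (default: wave-1 stressor count over
#' six months). This is the conditioning step of the indirect-inference
#' estimator: simulated panels share the observed baseline.
#'
#' @param panel A panel tibble (see [generate_panel()]).
#' @param inflow_rule Function of the wave-1 stressor count.
#' @return A profile tibble usable by [generate_panel()].
#' @export
panel_profiles <- function(panel, inflow_rule = function(s0) s0 / 6) {
  validate_panel(panel)
  w1 <- dplyr::filter(panel, .data$wave == 1)
  tibble::tibble(
    id = w1$id, gender = w1$gender,
    D0 = w1$cdi, R0 = w1$rumination, S0 = w1$stressors,
    inflow = inflow_rule(w1$stressors)
  )
}

#' Validate, read, and write measurement panels
#'
#' The panel CSV schema is long format with columns `id`, `gender`, `wave`
#' (1--3), `month`, `cdi` (0--52, waves 1 and 3), `rumination` (0--39, all
#' waves), `stressors` (0--25, waves 1 and 3). `validate_panel()` checks the
#' schema and the missingness pattern and errors naming the offending
#' field; the read/write pair round-trips losslessly including missingness.
#'
#' @param panel A panel tibble.
#' @param path CSV file path.
#' @return `validate_panel()` returns the panel invisibly; `read_panel()` a
#'   validated tibble; `write_panel()` the path invisibly.
#' @export
validate_panel <- function(panel) {
  need <- c("id", "gender", "wave", "month", "cdi", "rumination", "stressors")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    abort(paste0("panel is missing column(s): ", paste(miss, collapse = ", ")),
          class = "rumidyn_schema_error")
  }
  if (nrow(panel) == 0) return(invisible(panel))
  if (any(!panel$wave %in% 1:3)) {
    abort("field `wave` must be in 1..3", class = "rumidyn_schema_error")
  }
  if (any(!gender01(panel$gender) %in% c(0, 1))) {
    abort("field `gender` invalid", class = "rumidyn_schema_error")
  }
  rng_check <- function(x, lo, hi, field) {
    if (any(!is.na(x) & (x < lo | x > hi))) {
      abort(paste0("field `", field, "` outside [", lo, ", ", hi, "]"),
            class = "rumidyn_schema_error")
    }
  }
  rng_check(panel$cdi, 0, 52, "cdi")
  rng_check(panel$rumination, 0, 39, "rumination")
  rng_check(panel$stressors, 0, 25, "stressors")
  if (any(is.na(panel$rumination))) {
    abort("field `rumination` must be observed at every wave",
          class = "rumidyn_schema_error")
  }
  w2 <- panel[panel$wave == 2, ]
  if (any(!is.na(w2$cdi)) || any(!is.na(w2$stressors))) {
    abort("fields `cdi`/`stressors` must be missing at wave 2",
          class = "rumidyn_schema_error")
  }
  w13 <- panel[panel$wave != 2, ]
  if (any(is.na(w13$cdi)) || any(is.na(w13$stressors))) {
    abort("fields `cdi`/`stressors` must be observed at waves 1 and 3",
          class = "rumidyn_schema_error")
  }
  n_waves <- table(panel$id)
  if (any(n_waves != 3)) {
    abort("every `id` must appear at exactly 3 waves",
          class = "rumidyn_schema_error")
  }
  invisible(panel)
}

#' @rdname validate_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel, path, na = "NA")
  invisible(path)
}

#' @rdname validate_panel
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_integer(), gender = readr::col_character(),
      wave = readr::col_integer(), month = readr::col_double(),
      cdi = readr::col_double(), rumination = readr::col_double(),
      stressors = readr::col_double()
    )
  )
  validate_panel(panel)
  panel
}
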