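#' Model parameters for the depression--rumination--stressor system
#'
#' Construct the full parameter set of the stock-flow model: the twelve
#' estimated behavioural parameters (`theta1`--`theta12`), the stock
#' adjustment times, the memory-time floor, the integration step, and the
#' instrument clamp bounds for each stock.
#'
#' The behavioural parameters are, in order: the rumination constant
#' (`theta1`, score units), the effect of depression on rumination
#' (`theta2`), the gender coefficient applied to girls (`theta3`, score
#' units), the effect of stress on rumination (`theta4`, score per stressor),
#' the rumination self-coefficient (`theta5`), the depression constant
#' (`theta6`, score units), the effect of rumination on depression
#' (`theta7`), the depression self-coefficient (`theta8`), the effect of
#' rumination on memory time (`theta9`, months per rumination unit), the
#' stationary standard deviations of the rumination and depression process
#' noise (`theta10`, `theta11`, score units), and the noise correlation time
#' (`theta12`, months). Defaults are the published indirect-inference
#' estimates for the 661-adolescent cohort.
#'
#' `tau_R` and `tau_D` are the first-order adjustment times (months) with
#' which the rumination and depression stocks chase their indicated values;
#' both default to one month so that one model month corresponds to one step
#' of the discrete-time reading of the indicated-value equations. `M_min`
#' floors memory time away from zero so the let-it-go outflow stays bounded.
#'
#' @param theta1,theta2,theta3,theta4,theta5,theta6,theta7,theta8,theta9,theta10,theta11,theta12
#'   Behavioural parameters, see Details.
#' @param tau_R,tau_D Stock adjustment times in months.
#' @param M_min Memory-time floor in months.
#' @param dt Euler integration step in months. Must satisfy
#'   `dt <= min(tau_R, tau_D, theta12) / 4`.
#' @param clamp_D,clamp_R,clamp_S Length-2 numeric `c(lower, upper)` clamp
#'   bounds for the depression, rumination, and stressor stocks. Defaults are
#'   the instrument ranges: CDI 0--52, rescaled rumination subscale 0--39,
#'   and a non-negative, unbounded stressor stock.
#'
#' @return An object of class `rumidyn_params`: a named list of the fields
#'   above, validated.
#' @seealso [read_params()], [write_params()], [steady_state()]
#' @examples
#' p <- model_params()
#' p$theta9
#' model_params(theta10 = 0, theta11 = 0) # noise-free variant
#' @export
model_params <- function(theta1 = -1.2504,
                         theta2 = 0.4236,
                         theta3 = 2.5152,
                         theta4 = 0.2518,
                         theta5 = 0.1639,
                         theta6 = 0.3730,
                         theta7 = 0.0699,
                         theta8 = 0.8894,
                         theta9 = 1.4741,
                         theta10 = 7.8735,
                         theta11 = 0.0002,
                         theta12 = 1.6008,
                         tau_R = 1,
                         tau_D = 1,
                         M_min = 0.25,
                         dt = 0.125,
                         clamp_D = c(0, 52),
                         clamp_R = c(0, 39),
                         clamp_S = c(0, Inf)) {
  p <- list(
    theta1 = theta1, theta2 = theta2, theta3 = theta3, theta4 = theta4,
    theta5 = theta5, theta6 = theta6, theta7 = theta7, theta8 = theta8,
    theta9 = theta9, theta10 = theta10, theta11 = theta11, theta12 = theta12,
    tau_R = tau_R, tau_D = tau_D, M_min = M_min, dt = dt,
    clamp_D = as.numeric(clamp_D), clamp_R = as.numeric(clamp_R),
    clamp_S = as.numeric(clamp_S)
  )
  class(p) <- "rumidyn_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a [model_params()] object: positivity
#' of the time constants and the integration step, non-negative noise
#' standard deviations, the stability constraint
#' `dt <= min(tau_R, tau_D, theta12) / 4`, and ordered clamp bounds.
#'
#' @param params A `rumidyn_params` object (or plain named list with the same
#'   fields).
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_params <- function(params) {
  num1 <- function(field) {
    v <- params[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      abort(paste0("parameter `", field, "` must be a single finite number"),
            class = "rumidyn_invalid_params")
    }
    v
  }
  for (f in paste0("theta", 1:12)) num1(f)
  for (f in c("tau_R", "tau_D", "M_min", "dt")) {
    if (num1(f) <= 0) {
      abort(paste0("parameter `", f, "` must be > 0"),
            class = "rumidyn_invalid_params")
    }
  }
  if (params$theta9 <= 0) {
    abort("`theta9` (effect of rumination on memory time) must be > 0",
          class = "rumidyn_invalid_params")
  }
  if (params$theta12 <= 0) {
    abort("`theta12` (noise correlation time) must be > 0",
          class = "rumidyn_invalid_params")
  }
  if (params$theta10 < 0 || params$theta11 < 0) {
    abort("noise standard deviations `theta10`/`theta11` must be >= 0",
          class = "rumidyn_invalid_params")
  }
  if (params$dt > min(params$tau_R, params$tau_D, params$theta12) / 4) {
    abort("`dt` must be <= min(tau_R, tau_D, theta12) / 4 for a stable Euler step",
          class = "rumidyn_invalid_params")
  }
  for (f in c("clamp_D", "clamp_R", "clamp_S")) {
    b <- params[[f]]
    if (!is.numeric(b) || length(b) != 2 || is.na(b[1]) || is.na(b[2]) ||
        b[1] > b[2]) {
      abort(paste0("`", f, "` must be c(lower, upper) with lower <= upper"),
            class = "rumidyn_invalid_params")
    }
  }
  invisible(params)
}

#' @export
print.rumidyn_params <- function(x, ...) {
  cat("<rumidyn_params>\n")
  th <- unlist(x[paste0("theta", 1:12)])
  print(round(th, 4))
  cat(sprintf("tau_R = %g, tau_D = %g, M_min = %g, dt = %g months\n",
              x$tau_R, x$tau_D, x$M_min, x$dt))
  cat(sprintf("clamps: D [%g, %g], R [%g, %g], S [%g, %g]\n",
              x$clamp_D[1], x$clamp_D[2], x$clamp_R[1], x$clamp_R[2],
              x$clamp_S[1], x$clamp_S[2]))
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameters are stored as flat JSON with keys `theta1`...`theta12`,
#' `tau_R`, `tau_D`, `M_min`, `dt`, and `clamp_D`/`clamp_R`/`clamp_S`
#' (two-element arrays). The file shipped at
#' `system.file("extdata", "table2_defaults.json", package = "rumidyn")`
#' carries the published estimates and matches `model_params()` defaults.
#'
#' @param path File path.
#' @param params A `rumidyn_params` object.
#' @return `read_params()` returns a validated `rumidyn_params`;
#'   `write_params()` returns `path` invisibly.
#' @examples
#' p <- read_params(system.file("extdata", "table2_defaults.json",
#'                              package = "rumidyn"))
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_params))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    abort(paste0("unknown parameter field(s) in `", path, "`: ",
                 paste(extra, collapse = ", ")),
          class = "rumidyn_invalid_params")
  }
  raw <- lapply(raw, function(v) {
    v[v == "Inf"] <- Inf
    v[v == "-Inf"] <- -Inf
    as.numeric(v)
  })
  do.call(model_params, raw)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  validate_params(params)
  out <- unclass(params)
  # JSON has no Inf literal; encode open clamp bounds as strings
  out <- lapply(out, function(v) {
    if (is.numeric(v) && any(is.infinite(v))) {
      v <- as.character(v)
    }
    v
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Published wave-1 instrument moments by gender
#'
#' Means and standard deviations of the three instruments at the first
#' assessment (month 0) for the 661-adolescent cohort (353 girls, 308 boys):
#' depressive symptoms (CDI, 0--52), rumination (rescaled response-styles
#' subscale, 0--39), and stressful-life-event counts (0--25). These moments
#' seed the synthetic cohort generator and the factorial experiment levels.
#'
#' @return A tibble with columns `gender`, `variable` (`"D"`, `"R"`, `"S"`),
#'   `mean`, `sd`, and `n`.
#' @examples
#' table1_moments()
#' @export
table1_moments <- function() {
  tibble::tibble(
    gender   = rep(c("girl", "boy"), each = 3),
    variable = rep(c("D", "R", "S"), 2),
    mean     = c(9.98, 12.78, 4.97, 8.91, 10.23, 4.96),
    sd       = c(6.45, 7.71, 3.14, 6.04, 7.06, 3.52),
    n        = rep(c(353L, 308L), each = 3)
  )
}
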