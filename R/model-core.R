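#' @keywords internal
#' @noRd
gender01 <- function(gender) {
  if (is.factor(gender)) gender <- as.character(gender)
  if (is.character(gender)) {
    bad <- !gender %in% c("girl", "boy")
    if (any(bad)) {
      abort("`gender` must be \"girl\" or \"boy\"", class = "rumidyn_invalid_input")
    }
    return(as.numeric(gender == "girl"))
  }
  if (is.numeric(gender) || is.logical(gender)) {
    g <- as.numeric(gender)
    if (any(!g %in% c(0, 1))) {
      abort("numeric `gender` must be 0 (boy) or 1 (girl)",
            class = "rumidyn_invalid_input")
    }
    return(g)
  }
  abort("`gender` must be character or 0/1", class = "rumidyn_invalid_input")
}

check_finite <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    if (!all(is.finite(vals[[nm]]))) {
      abort(paste0("`", nm, "` must be finite"), class = "rumidyn_invalid_input")
    }
  }
  invisible(TRUE)
}

#' Indicated rumination and depression
#'
#' The linear indicated values toward which the rumination and depression
#' stocks adjust with first-order delays `tau_R` and `tau_D`. Indicated
#' rumination is
#' `theta1 + theta2 * D + theta3 * G + theta4 * S + theta5 * R + epsR`,
#' where `G` is 1 for girls and 0 for boys; indicated depression is
#' `theta6 + theta7 * R + theta8 * D + epsD`. The autocorrelated process
#' noise enters here, on the indicated values, so noise-free steady states
#' of the stocks are exact. No clamping is applied at this stage.
#'
#' @param D,R,S Current depression, rumination, and past-stressors stocks
#'   (vectorised).
#' @param gender `"girl"`/`"boy"` (or 1/0).
#' @param epsR,epsD Current noise states (score units).
#' @param params A [model_params()] object.
#' @return Numeric vector of indicated scores (unclamped).
#' @examples
#' p <- model_params()
#' indicated_rumination(0, 0, 0, "boy", 0, p)   # theta1
#' indicated_depression(0, 0, 0, p)             # theta6
#' @export
indicated_rumination <- function(D, R, S, gender, epsR, params) {
  g <- gender01(gender)
  check_finite(D = D, R = R, S = S, epsR = epsR)
  params$theta1 + params$theta2 * D + params$theta3 * g +
    params$theta4 * S + params$theta5 * R + epsR
}

#' @rdname indicated_rumination
#' @export
indicated_depression <- function(D, R, epsD, params) {
  check_finite(D = D, R = R, epsD = epsD)
  params$theta6 + params$theta7 * R + params$theta8 * D + epsD
}

#' Memory time and the let-it-go outflow
#'
#' Memory time is the characteristic time over which a retained stressor is
#' released, modelled as proportional to rumination:
#' `M = max(theta9 * R, M_min)`. The floor `M_min` keeps the outflow bounded
#' when rumination approaches zero. The let-it-go flow drains the
#' past-stressors-kept-alive stock at rate `S / M` (events per month), the
#' stock-and-drain analogy of coming to terms with past events: the more a
#' person ruminates, the longer the memory time and the slower the release.
#'
#' @param R Rumination stock (vectorised).
#' @param S Past stressors kept alive (events, `>= 0`).
#' @param M Memory time in months, at least `M_min`.
#' @param params A [model_params()] object.
#' @return `memory_time()`: months; `let_it_go()`: events per month.
#' @examples
#' p <- model_params()
#' memory_time(10, p)        # 14.741
#' let_it_go(14, 7, p)       # 2
#' @export
memory_time <- function(R, params) {
  check_finite(R = R)
  pmax(params$theta9 * R, params$M_min)
}

#' @rdname memory_time
#' @export
let_it_go <- function(S, M, params) {
  check_finite(S = S, M = M)
  if (any(S < 0)) {
    abort("`S` must be >= 0", class = "rumidyn_invalid_input")
  }
  if (any(M < params$M_min - 1e-12)) {
    abort("`M` below the memory-time floor `M_min`",
          class = "rumidyn_contract_violation")
  }
  S / M
}

#' One update of the autocorrelated process noise
#'
#' The noise on each indicated value is a stationary first-order
#' (Ornstein--Uhlenbeck-type) process with stationary standard deviation
#' `sigma` and correlation time `corr_time`: autocorrelation at lag `delta`
#' months is approximately `exp(-delta / corr_time)`. The discrete update
#' uses the Euler decay factor `phi = 1 - dt / corr_time` with innovation
#' standard deviation `sigma * sqrt(1 - phi^2)`, which reproduces the
#' stationary variance exactly at any step size (the lag-`dt`
#' autocorrelation is `phi`, the first-order expansion of
#' `exp(-dt / corr_time)`). With `sigma = 0` the state decays
#' deterministically to zero.
#'
#' @param eps Current noise state (vectorised).
#' @param sigma Stationary standard deviation, `>= 0`.
#' @param corr_time Correlation time in months, `> 0`.
#' @param dt Step in months, `0 < dt < corr_time`.
#' @param draw Standard-normal draw(s); defaults to `rnorm`.
#' @return Updated noise state(s).
#' @examples
#' ou_step(1, 0, 1.6008, 0.125, 0)  # pure decay: 1 - dt/corr_time
#' @export
ou_step <- function(eps, sigma, corr_time, dt, draw = rnorm(length(eps))) {
  if (sigma < 0) abort("`sigma` must be >= 0", class = "rumidyn_invalid_input")
  if (corr_time <= 0) {
    abort("`corr_time` must be > 0", class = "rumidyn_invalid_input")
  }
  if (dt >= corr_time) {
    abort("`dt` must be < `corr_time` for a stable noise update",
          class = "rumidyn_invalid_config")
  }
  phi <- 1 - dt / corr_time
  eps * phi + sigma * sqrt(1 - phi^2) * draw
}

# Recursive form of ou_step over a whole draw sequence (one chain).
# Identical arithmetic to iterating ou_step, evaluated by stats::filter.
#' @keywords internal
#' @noRd
ou_path <- function(eps0, sigma, corr_time, dt, draws) {
  if (dt >= corr_time) {
    abort("`dt` must be < `corr_time`", class = "rumidyn_invalid_config")
  }
  phi <- 1 - dt / corr_time
  innov <- sigma * sqrt(1 - phi^2) * draws
  as.numeric(stats::filter(innov, phi, method = "recursive", init = eps0))
}

#' One Euler step of the full system
#'
#' Advances a single system state by one integration step `dt`: the
#' rumination and depression stocks move toward their indicated values with
#' first-order delays, the past-stressors stock integrates inflow minus
#' let-it-go, all three stocks are clamped to their instrument bounds, and
#' the two noise states advance by [ou_step()].
#'
#' @param state A one-row data frame or named list with `t`, `D`, `R`, `S`,
#'   `epsR`, `epsD`.
#' @param profile A one-row data frame or named list with `gender` and
#'   `inflow` (events/month; a constant or a function of time).
#' @param params A [model_params()] object.
#' @param draw_R,draw_D Standard-normal draws for the two noise updates;
#'   default random. Pass 0 for a noise-frozen step.
#' @return A one-row tibble with the updated state at `t + dt`.
#' @examples
#' p <- model_params()
#' st <- tibble::tibble(t = 0, D = 10, R = 10, S = 5, epsR = 0, epsD = 0)
#' sim_step(st, list(gender = "girl", inflow = 0.8), p, draw_R = 0, draw_D = 0)
#' @export
sim_step <- function(state, profile, params, draw_R = rnorm(1),
                     draw_D = rnorm(1)) {
  u <- profile$inflow
  if (is.function(u)) u <- u(state$t)
  check_finite(D = state$D, R = state$R, S = state$S,
               epsR = state$epsR, epsD = state$epsD, inflow = u)
  M <- memory_time(state$R, params)
  L <- let_it_go(state$S, M, params)
  iR <- indicated_rumination(state$D, state$R, state$S, profile$gender,
                             state$epsR, params)
  iD <- indicated_depression(state$D, state$R, state$epsD, params)
  dt <- params$dt
  clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])
  tibble::tibble(
    t = state$t + dt,
    D = clamp(state$D + dt * (iD - state$D) / params$tau_D, params$clamp_D),
    R = clamp(state$R + dt * (iR - state$R) / params$tau_R, params$clamp_R),
    S = clamp(state$S + dt * (u - L), params$clamp_S),
    epsR = ou_step(state$epsR, params$theta10, params$theta12, dt, draw_R),
    epsD = ou_step(state$epsD, params$theta11, params$theta12, dt, draw_D)
  )
}

# Vectorised Euler(-Maruyama) engine over a cohort of individuals.
# d0, r0, s0, g, u are vectors of one entry per individual (u may be a
# function of time returning a scalar or length-n vector). Returns the
# states at the recorded times plus the per-individual time average of
# memory time over the whole grid (used by the memory-time experiment).
#' @keywords internal
#' @noRd
sim_engine <- function(d0, r0, s0, g, u, params, horizon, seed,
                       noise = TRUE,
                       record = c("grid", "monthly", "terminal", "none")) {
  record <- match.arg(record)
  n <- length(d0)
  stopifnot(length(r0) == n, length(s0) == n, length(g) == n)
  dt <- params$dt
  n_steps <- as.integer(round(horizon / dt))
  if (n_steps <= 0) abort("`horizon` must be > 0", class = "rumidyn_invalid_input")
  times <- (0:n_steps) * dt
  u_fn <- if (is.function(u)) u else {
    uu <- rep_len(as.numeric(u), n)
    function(t) uu
  }
  if (any(!is.finite(c(d0, r0, s0)))) {
    abort("initial conditions must be finite", class = "rumidyn_invalid_input")
  }

  rec_idx <- switch(record,
    grid = seq_along(times),
    monthly = which(abs(times - round(times)) < 1e-9),
    terminal = length(times),
    none = integer(0)
  )
  n_rec <- length(rec_idx)
  Dm <- Rm <- Sm <- Em <- Fm <- if (n_rec) {
    matrix(NA_real_, n_rec, n)
  } else NULL

  if (noise) {
    set.seed(seed)
    epsR <- rnorm(n, 0, params$theta10)
    epsD <- rnorm(n, 0, params$theta11)
  } else {
    epsR <- epsD <- numeric(n)
  }

  D <- pmin(pmax(d0, params$clamp_D[1]), params$clamp_D[2])
  R <- pmin(pmax(r0, params$clamp_R[1]), params$clamp_R[2])
  S <- pmin(pmax(s0, params$clamp_S[1]), params$clamp_S[2])

  phiR <- 1 - dt / params$theta12
  sdR <- params$theta10 * sqrt(1 - phiR^2)
  sdD <- params$theta11 * sqrt(1 - phiR^2)

  m_sum <- numeric(n)
  rec_pos <- 1L
  for (i in seq_along(times)) {
    M <- pmax(params$theta9 * R, params$M_min)
    m_sum <- m_sum + M
    if (n_rec && rec_pos <= n_rec && i == rec_idx[rec_pos]) {
      Dm[rec_pos, ] <- D; Rm[rec_pos, ] <- R; Sm[rec_pos, ] <- S
      Em[rec_pos, ] <- epsR; Fm[rec_pos, ] <- epsD
      rec_pos <- rec_pos + 1L
    }
    if (i > n_steps) break
    t_now <- times[i]
    L <- S / M
    iR <- params$theta1 + params$theta2 * D + params$theta3 * g +
      params$theta4 * S + params$theta5 * R + epsR
    iD <- params$theta6 + params$theta7 * R + params$theta8 * D + epsD
    D <- D + dt * (iD - D) / params$tau_D
    R <- R + dt * (iR - R) / params$tau_R
    S <- S + dt * (u_fn(t_now) - L)
    D <- pmin(pmax(D, params$clamp_D[1]), params$clamp_D[2])
    R <- pmin(pmax(R, params$clamp_R[1]), params$clamp_R[2])
    S <- pmin(pmax(S, params$clamp_S[1]), params$clamp_S[2])
    if (noise) {
      epsR <- epsR * phiR + sdR * rnorm(n)
      epsD <- epsD * phiR + sdD * rnorm(n)
    } else {
      epsR <- epsR * phiR
      epsD <- epsD * phiR
    }
  }

  list(times = times[rec_idx], D = Dm, R = Rm, S = Sm, epsR = Em, epsD = Fm,
       avg_M = m_sum / length(times),
       terminal = list(D = D, R = R, S = S))
}

#' Simulate trajectories for a set of individual profiles
#'
#' Runs the stochastic stock-flow model for each row of a profile table and
#' returns the trajectories in long (tidy) format, including the derived
#' memory-time series `M = max(theta9 * R, M_min)` and let-it-go series
#' `L = S / M`.
#'
#' All individuals share one master seed; noise draws are deterministic
#' given `(profiles, params, horizon, seed)`, so re-running returns an
#' identical table. If `profiles` carries a `seed` column, each individual
#' is instead simulated on its own stream keyed by that value, making any
#' single row reproducible in isolation.
#'
#' @param profiles A data frame with columns `id`, `gender`
#'   (`"girl"`/`"boy"`), `D0`, `R0`, `S0`, `inflow` (events/month), and
#'   optionally `seed`.
#' @param params A [model_params()] object.
#' @param horizon Simulation length in months.
#' @param seed Master seed for the noise streams.
#' @param noise If `FALSE`, both process-noise states are held at zero.
#' @param record Which time points to return: every integration step
#'   (`"grid"`), integer months (`"monthly"`), or only the final state
#'   (`"terminal"`).
#' @return A tibble with columns `id`, `t`, `D`, `R`, `S`, `epsR`, `epsD`,
#'   `M`, `L`, one row per individual per recorded time.
#' @examples
#' prof <- tibble::tibble(id = 1, gender = "girl", D0 = 16.43, R0 = 20.49,
#'                        S0 = 11.25, inflow = 1.875)
#' tr <- simulate_profiles(prof, model_params(), horizon = 12, seed = 1)
#' tail(tr, 3)
#' @export
simulate_profiles <- function(profiles, params, horizon = 120, seed = 1,
                              noise = TRUE,
                              record = c("grid", "monthly", "terminal")) {
  record <- match.arg(record)
  validate_params(params)
  need <- c("id", "gender", "D0", "R0", "S0", "inflow")
  miss <- setdiff(need, names(profiles))
  if (length(miss)) {
    abort(paste0("`profiles` is missing column(s): ",
                 paste(miss, collapse = ", ")),
          class = "rumidyn_invalid_input")
  }
  if (any(profiles$S0 < 0) ||
      (is.numeric(profiles$inflow) && any(profiles$inflow < 0))) {
    abort("`S0` and `inflow` must be >= 0", class = "rumidyn_invalid_input")
  }
  run_one <- function(prof, sd) {
    sim_engine(prof$D0, prof$R0, prof$S0, gender01(prof$gender), prof$inflow,
               params, horizon, sd, noise = noise, record = record)
  }
  to_tbl <- function(eng, ids) {
    n_t <- length(eng$times)
    n <- length(ids)
    M <- pmax(params$theta9 * eng$R, params$M_min)
    tibble::tibble(
      id = rep(ids, each = n_t),
      t = rep(eng$times, n),
      D = as.vector(eng$D), R = as.vector(eng$R), S = as.vector(eng$S),
      epsR = as.vector(eng$epsR), epsD = as.vector(eng$epsD),
      M = as.vector(M), L = as.vector(eng$S / M)
    )
  }
  if ("seed" %in% names(profiles)) {
    out <- purrr::map(seq_len(nrow(profiles)), function(i) {
      to_tbl(run_one(profiles[i, ], profiles$seed[i]), profiles$id[i])
    })
    return(dplyr::bind_rows(out))
  }
  to_tbl(run_one(profiles, seed), profiles$id)
}

#' Loop gain and analytic steady state of the noise-free system
#'
#' For a constant stressor inflow `u` the noise-free model is linear, and
#' its fixed point solves
#' `R (1 - theta5) = theta1 + theta2 * D + theta3 * G + theta4 * S` with
#' `D = (theta6 + theta7 * R) / (1 - theta8)` and `S = u * M(R)`. The
#' combined gain of the two reinforcing loops at this operating point is
#' `g = theta5 + theta2 * theta7 / (1 - theta8) + theta4 * u * theta9`;
#' when `g >= 1` no finite stable fixed point exists and trajectories grow
#' until the instrument clamps bind (`divergent = TRUE`).
#'
#' When the fixed point would sit below the memory-time floor
#' (`theta9 * R < M_min`), the stressor outflow time is pinned at `M_min`
#' and the fixed point is re-solved with `S = u * M_min`.
#'
#' @param params A [model_params()] object; requires `theta8 < 1`.
#' @param gender `"girl"` or `"boy"` (vectorised, recycled against
#'   `inflow`).
#' @param inflow Constant ongoing-stressor rate, events/month (vectorised).
#' @return A tibble with one row per `(gender, inflow)` pair: columns
#'   `gender`, `inflow`, `D`, `R`, `S`, `M`, `loop_gain`, `divergent`
#'   (stocks are `NA` when divergent).
#' @examples
#' p <- model_params()
#' steady_state(p, "girl", 4.97 / 6)   # interior fixed point
#' steady_state(p, "girl", 1.875)      # loop gain > 1: divergent
#' @export
steady_state <- function(params, gender = "girl", inflow = 0) {
  validate_params(params)
  if (params$theta8 >= 1) {
    abort("`theta8` must be < 1 for a finite depression fixed point",
          class = "rumidyn_invalid_params")
  }
  if (any(inflow < 0)) {
    abort("`inflow` must be >= 0", class = "rumidyn_invalid_input")
  }
  k <- max(length(gender), length(inflow))
  gender <- rep_len(gender, k)
  inflow <- rep_len(inflow, k)
  g01 <- gender01(gender)

  a <- params$theta2 * params$theta7 / (1 - params$theta8)
  b <- params$theta1 + params$theta3 * g01 +
    params$theta2 * params$theta6 / (1 - params$theta8)
  gain <- params$theta5 + a + params$theta4 * inflow * params$theta9

  Rstar <- b / (1 - params$theta5 - a - params$theta4 * inflow * params$theta9)
  # fixed point below the memory-time floor: outflow time pinned at M_min
  floored <- !is.na(Rstar) & params$theta9 * Rstar < params$M_min
  if (any(floored)) {
    denom2 <- 1 - params$theta5 - a
    Rstar[floored] <- (b[floored] +
                         params$theta4 * inflow[floored] * params$M_min) / denom2
  }
  divergent <- gain >= 1 | (floored & (params$theta5 + a) >= 1)
  Rstar[divergent] <- NA_real_
  Dstar <- (params$theta6 + params$theta7 * Rstar) / (1 - params$theta8)
  Mstar <- pmax(params$theta9 * Rstar, params$M_min)
  Sstar <- inflow * Mstar

  tibble::tibble(gender = gender, inflow = inflow,
                 D = Dstar, R = Rstar, S = Sstar, M = Mstar,
                 loop_gain = gain, divergent = divergent)
}
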