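# Full-model simulation: phase-aware integration under forcing with
# life-stage events, brooding, spawning and starvation death.

#' Simulation options
#'
#' @param dt_out output grid spacing (days).
#' @param rtol,atol integrator tolerances; `atol = NULL` scales the absolute
#'   tolerance automatically from the initial state.
#' @param max_step largest integrator step (days); defaults to 1 day under
#'   time-varying forcing (the forcing is piecewise linear) and unrestricted
#'   under constant forcing.
#' @param ageing integrate the Weibull--Gompertz ageing states.
#' @param spawning enable the discrete spawning rule (adults only).
#' @param spawn_temp_C spawning is only triggered at temperatures at or above
#'   this value (degrees Celsius).
#' @param spawn_buffer_frac trigger threshold: spawning occurs when the
#'   reproduction buffer density `E_R/V` exceeds this fraction of the maximum
#'   reserve capacity `E_m`.
#' @param spawn_refractory_d minimum number of days between spawning events.
#' @param brooding for species with a release threshold `E_Hr` (the flat
#'   oyster), spawning as a female starts a brooding period during which the
#'   feeding level is multiplied by `brood_factor`.
#' @param brood_factor feeding multiplier while brooding (default 0.8).
#' @param brood_duration fixed brooding duration in days, or `NULL` to
#'   derive the duration from the embryo solution: the time for a brooded
#'   embryo to develop from fertilisation to `E_Hr` at the ambient
#'   temperature.
#' @param e_death scaled reserve density below which the individual dies of
#'   starvation.
#' @param stop_at name of a maturity event (`"birth"`, `"release"`,
#'   `"settlement"`, `"metamorphosis"`, `"puberty"`) at which the simulation
#'   stops, or `NULL` to run to the horizon.
#' @param ingestion_temp optional named list with the six Arrhenius keys
#'   (`T_ref`, `T_A`, `T_L`, `T_AL`, `T_H`, `T_AH`) used for the feeding
#'   fluxes only, decoupling the thermal response of ingestion from that of
#'   maintenance and maturation; `NULL` (default) keeps the coupled
#'   correction the parameters were estimated under.
#' @return list of options for [simulate_deb()].
#' @export
deb_options <- function(dt_out = 1, rtol = 1e-8, atol = NULL, max_step = NULL,
                        ageing = FALSE, spawning = FALSE,
                        spawn_temp_C = 15, spawn_buffer_frac = 0.05,
                        spawn_refractory_d = 30,
                        brooding = TRUE, brood_factor = 0.8,
                        brood_duration = NULL, e_death = 1e-4,
                        stop_at = NULL, ingestion_temp = NULL) {
  list(dt_out = dt_out, rtol = rtol, atol = atol, max_step = max_step,
       ageing = ageing, spawning = spawning, spawn_temp_C = spawn_temp_C,
       spawn_buffer_frac = spawn_buffer_frac,
       spawn_refractory_d = spawn_refractory_d,
       brooding = brooding, brood_factor = brood_factor,
       brood_duration = brood_duration, e_death = e_death,
       stop_at = stop_at, ingestion_temp = ingestion_temp)
}

# automatic absolute-tolerance vector from an initial state
auto_atol <- function(params, y0, rtol) {
  E_m <- params$p_Am / params$v
  e_scale <- max(y0[1], E_m * y0[2], 1e-12)
  base <- c(e_scale, max(y0[2], 1e-12),
            max(y0[3], if (!is.null(params$E_Hb)) params$E_Hb else 1e-6),
            e_scale, 1e-18, 1e-12, 1e-6, e_scale, e_scale, e_scale)
  1e-10 * base
}

# maturity thresholds of a parameter set, in crossing order
maturity_thresholds <- function(params) {
  if (attr(params, "mode") != "asj") return(numeric(0))
  thr <- c(birth = params$E_Hb, release = params$E_Hr,
           settlement = params$E_Hs, metamorphosis = params$E_Hj,
           puberty = params$E_Hp)
  thr[!is.na(thr)]
}

#' Simulate an individual through time
#'
#' Integrates the asj DEB state under a [forcing] from an initial
#' [organism_state()] over `horizon` days.  Life-stage thresholds (birth,
#' larval release, settlement, end of metamorphosis, puberty) are located by
#' root finding and logged; the acceleration factor is 1 before settlement,
#' grows as `L/L_s` during metamorphosis and is frozen at its value when
#' maturity reaches `E_Hj`.  Optional discrete events: spawning (a fraction
#' `kap_R` of the reproduction buffer is released when the buffer density
#' and temperature exceed their thresholds) and, for brooding species,
#' a feeding reduction until the brooded larvae reach `E_Hr`.  Starvation
#' death (scaled reserve density below `e_death`) ends the trajectory.
#'
#' @param params a [deb_params] object.
#' @param fc a [forcing] object.
#' @param init initial state from [organism_state()] or [init_from_weight()].
#' @param horizon simulated span (days).
#' @param options list from [deb_options()].
#' @param L_s structural length at settlement when the initial state is
#'   already inside the acceleration window (rarely needed).
#' @return object of class `deb_trajectory`: list with `time`, `state`
#'   (matrix of the 10 state slots), `observables` (data frame: day,
#'   length_cm, dw_g, ww_g, e, f, temp_C), `events`, `spawns`, `died`,
#'   `s_M_used`, plus the inputs.
#' @export
#' @examples
#' p <- deb_species("o_edulis")
#' st <- init_from_weight(p, 0.87, wet = TRUE)
#' tr <- simulate_deb(p, constant_forcing(20, chl = 10), st, horizon = 42)
#' utils::tail(tr$observables, 1)
simulate_deb <- function(params, fc, init, horizon, options = deb_options(),
                         L_s = NULL) {
  stopifnot(inherits(params, "deb_params"), inherits(fc, "deb_forcing"))
  opt <- utils::modifyList(deb_options(), options)
  y <- as_state_vector(init)
  if (y[2] <= 0) stop("initial structural volume must be positive")
  mode <- attr(params, "mode")
  E_m <- params$p_Am / params$v
  s_M_cap <- if (!is.null(params$s_M)) params$s_M else Inf

  # environment interpolants (temperature in C, food as scaled f)
  if (fc$constant) {
    T_C0 <- fc$temp_C[1]
    f0 <- if (fc$mode == "chl") functional_response(fc$food[1], params$K_X) else fc$food[1]
    env_T <- function(t) T_C0
    env_f <- function(t) f0
    TC0 <- temperature_correction(params, T_C0 + 273.15)
    max_step <- if (is.null(opt$max_step)) Inf else opt$max_step
  } else {
    TC0 <- NULL
    tf <- stats::approxfun(fc$time, fc$temp_C, rule = 2)
    food_series <- if (fc$mode == "chl") {
      functional_response(fc$food, params$K_X)
    } else fc$food
    ff <- stats::approxfun(fc$time, food_series, rule = 2)
    env_T <- tf
    env_f <- ff
    max_step <- if (is.null(opt$max_step)) 1 else opt$max_step
  }

  thr <- maturity_thresholds(params)
  # acceleration bookkeeping
  if (mode == "asj") {
    if (y[3] >= params$E_Hj) {
      s_now <- if (is.finite(s_M_cap)) s_M_cap else 1
      L_s_now <- NA_real_
    } else if (y[3] >= params$E_Hs) {
      L_s_now <- if (!is.null(L_s)) L_s else
        y[2]^(1 / 3) / min(max((y[3] / params$E_Hs)^(1 / 3), 1), s_M_cap)
      s_now <- NA_real_  # computed from L/L_s in the RHS
    } else {
      s_now <- 1
      L_s_now <- NA_real_
    }
  } else {
    s_now <- if (is.finite(s_M_cap)) s_M_cap else 1
    L_s_now <- NA_real_
  }

  brood_until <- -Inf
  brood_mult <- 1
  last_spawn <- -Inf
  has_release <- mode == "asj" && !is.null(params$E_Hr)

  rtol <- opt$rtol
  atol <- if (is.null(opt$atol)) auto_atol(params, y, rtol) else opt$atol
  wts <- c(1, 1, 1, 1, 0, 0, if (opt$ageing) 1 else 0, 0, 0, 0)

  t_out <- seq(0, horizon, by = opt$dt_out)
  if (t_out[length(t_out)] < horizon) t_out <- c(t_out, horizon)

  times <- numeric(0)
  states <- NULL
  events_log <- data.frame(event = character(0), time = numeric(0),
                           length_cm = numeric(0), dryweight_g = numeric(0))
  spawns <- data.frame(time = numeric(0), energy_J = numeric(0),
                       eggs = numeric(0), brooding = logical(0))
  died <- FALSE
  death_time <- NA_real_

  core <- fast_deriv_factory(params, ageing = opt$ageing)

  t <- 0
  push_rows <- function(tt, yy) {
    keep <- !(tt %in% times)
    times <<- c(times, tt[keep])
    states <<- rbind(states, yy[keep, , drop = FALSE])
  }

  log_event <- function(name, tt, yy) {
    del <- if (mode == "asj" && yy[3] < params$E_Hj) params$del_Mb else params$del_M
    events_log <<- rbind(events_log, data.frame(
      event = name, time = tt,
      length_cm = yy[2]^(1 / 3) / del,
      dryweight_g = params$d_V * yy[2] +
        params$w_E * (yy[1] + yy[4]) / params$mu_E))
  }

  while (t < horizon - 1e-9 && !died) {
    # next hard stop: spawn checks happen on a daily grid
    t_stop <- horizon
    if (opt$spawning) t_stop <- min(t_stop, floor(t + 1e-9) + 1)

    # brooding state
    brood_mult <- if (t < brood_until) opt$brood_factor else 1

    in_accel <- mode == "asj" && y[3] >= params$E_Hs && y[3] < params$E_Hj
    L_s_loc <- L_s_now
    s_loc <- s_now
    cap <- s_M_cap
    tp_ing <- opt$ingestion_temp
    rhs <- if (fc$constant && brood_mult == 1 && is.null(tp_ing)) {
      f_const <- min(f0, 1)
      function(tt, yy) {
        s <- if (in_accel) min(max(yy[2]^(1 / 3) / L_s_loc, 1), cap) else s_loc
        core(yy, f = f_const, TC = TC0, s = s)
      }
    } else {
      function(tt, yy) {
        s <- if (in_accel) min(max(yy[2]^(1 / 3) / L_s_loc, 1), cap) else s_loc
        T_K <- env_T(tt) + 273.15
        TC <- if (!is.null(TC0)) TC0 else temperature_correction(params, T_K)
        TC_A <- if (is.null(tp_ing)) TC else temperature_correction(tp_ing, T_K)
        f <- env_f(tt) * brood_mult
        core(yy, f = min(f, 1), TC = TC, s = s, TC_A = TC_A)
      }
    }

    evs <- list()
    nxt <- thr[thr > y[3] + 0]
    if (length(nxt)) {
      thr_val <- nxt[1]
      evs[[names(nxt)[1]]] <- function(tt, yy) yy[3] - thr_val
    }
    e_death <- opt$e_death
    evs[["death"]] <- function(tt, yy) yy[1] / (pmax(yy[2], 1e-300) * E_m) - e_death
    if (opt$ageing) {
      evs[["survival_floor"]] <- function(tt, yy) yy[7] + 20.7  # S = 1e-9
    }

    seg <- rk45(rhs, y, t, t_stop, rtol = rtol, atol = atol,
                err_weights = wts, max_step = max_step,
                t_eval = t_out[t_out > t & t_out <= t_stop],
                events = evs)
    push_rows(seg$t[-1], seg$y[-1, , drop = FALSE])
    t <- seg$t_end
    y <- seg$y_end
    names(y) <- .state_names

    if (!is.na(seg$event)) {
      if (seg$event == "death") {
        died <- TRUE
        death_time <- t
        log_event("starvation_death", t, y)
        break
      } else if (seg$event == "survival_floor") {
        died <- TRUE
        death_time <- t
        log_event("ageing_death", t, y)
        break
      } else {
        # maturity threshold crossed
        y[3] <- thr[seg$event]  # pin to the threshold exactly
        log_event(seg$event, t, y)
        if (!is.null(opt$stop_at) && identical(seg$event, opt$stop_at)) {
          push_rows(t, matrix(y, nrow = 1))
          break
        }
        if (seg$event == "settlement") {
          L_s_now <- y[2]^(1 / 3)
          s_now <- NA_real_
        } else if (seg$event == "metamorphosis") {
          s_now <- if (!is.na(L_s_now)) {
            min(max(y[2]^(1 / 3) / L_s_now, 1), s_M_cap)
          } else if (is.finite(s_M_cap)) s_M_cap else 1
          L_s_now <- NA_real_
        }
        next
      }
    }

    # daily spawn check
    if (opt$spawning && t < horizon - 1e-9 && abs(t - round(t)) < 1e-6) {
      adult <- !is.null(params$E_Hp) && !is.na(params$E_Hp) && y[3] >= params$E_Hp
      T_C <- env_T(t)
      trigger <- adult && t >= last_spawn + opt$spawn_refractory_d &&
        t >= brood_until &&
        y[4] / y[2] >= opt$spawn_buffer_frac * E_m &&
        T_C >= opt$spawn_temp_C
      if (trigger && y[4] > 0) {
        sp <- apply_spawning(y, params,
                             T_K = T_C + 273.15)
        y <- sp$state
        starts_brood <- has_release && opt$brooding
        spawns <- rbind(spawns, data.frame(
          time = t, energy_J = sp$energy_released, eggs = sp$eggs,
          brooding = starts_brood))
        last_spawn <- t
        if (starts_brood) {
          dur <- if (!is.null(opt$brood_duration)) {
            opt$brood_duration
          } else {
            brood_development_time(params, T_K = T_C + 273.15)
          }
          brood_until <- t + dur
          log_event("brood_start", t, y)
        }
      }
    }
  }

  if (!length(times) || times[1] > 0) {
    times <- c(0, times)
    y0 <- as_state_vector(init)
    states <- rbind(matrix(y0, nrow = 1), states)
  }
  ord <- order(times)
  times <- times[ord]
  states <- states[ord, , drop = FALSE]
  colnames(states) <- .state_names

  # derived observables on the stored grid
  del <- if (mode == "asj") {
    ifelse(states[, "EH"] < params$E_Hj, params$del_Mb, params$del_M)
  } else rep(params$del_M, length(times))
  dw <- params$d_V * states[, "V"] +
    params$w_E * (states[, "E"] + states[, "ER"]) / params$mu_E
  obs <- data.frame(
    day = times,
    length_cm = states[, "V"]^(1 / 3) / del,
    dw_g = dw,
    ww_g = dw / params$dw_ww_ratio,
    e = states[, "E"] / (states[, "V"] * E_m),
    f = vapply(times, function(tt) env_f(tt), numeric(1)),
    temp_C = vapply(times, function(tt) env_T(tt), numeric(1)))

  structure(list(time = times, state = states, observables = obs,
                 events = events_log, spawns = spawns,
                 died = died, death_time = death_time,
                 s_M_used = if (!is.na(s_now)) s_now else NA_real_,
                 L_s = L_s_now,
                 params = params, forcing = fc, options = opt),
            class = "deb_trajectory")
}

#' @export
print.deb_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat("DEB trajectory: ", n, " stored states over ",
      signif(x$time[n], 6), " d", if (x$died) " (died)", "\n", sep = "")
  if (nrow(x$events)) {
    cat("events:\n")
    print(x$events, row.names = FALSE)
  }
  if (nrow(x$spawns)) cat(nrow(x$spawns), "spawning event(s)\n")
  invisible(x)
}

#' Reconstruct a state from a measured weight
#'
#' Field initialisation: given a total (wet or dry) tissue weight, solves for
#' the structural volume under an assumed scaled reserve density
#' (default `e = 0.8`, "fit animals"), an empty reproduction buffer and full
#' maturity (`E_H = E_Hp`).  The weight model is
#' `dw = d_V*V + w_E*(E + E_R)/mu_E`, `ww = dw / dw_ww_ratio`; the round trip
#' weight -> state -> weight reproduces the input to 1e-9 relative.
#'
#' @param params a [deb_params] object.
#' @param weight total weight (g).
#' @param wet is `weight` wet (`TRUE`, default) or dry?
#' @param e assumed scaled reserve density.
#' @param E_R assumed reproduction buffer (J).
#' @param E_H assumed maturity (J); default `E_Hp` (or 0 in std mode without
#'   a puberty threshold).
#' @return an [organism_state()].
#' @export
init_from_weight <- function(params, weight, wet = TRUE, e = 0.8, E_R = 0,
                             E_H = NULL) {
  stopifnot(weight > 0, e >= 0, E_R >= 0)
  p <- params
  if (is.null(E_H)) E_H <- if (!is.null(p$E_Hp)) p$E_Hp else 0
  dw <- if (wet) weight * p$dw_ww_ratio else weight
  E_m <- p$p_Am / p$v
  dw_struct <- dw - p$w_E * E_R / p$mu_E
  if (dw_struct <= 0) stop("weight below the mass of the assumed buffer")
  g <- function(V) {
    p$d_V * V + p$w_E * (e * E_m * V) / p$mu_E - dw_struct
  }
  V_hi <- dw_struct / p$d_V
  sol <- stats::uniroot(g, lower = V_hi * 1e-12, upper = V_hi * (1 + 1e-9),
                        tol = .Machine$double.eps^0.75)
  V <- sol$root
  organism_state(E = e * E_m * V, V = V, E_H = E_H, E_R = E_R)
}

#' Energy-balance audit of a trajectory
#'
#' Over any stored window the full budget must close:
#' `int p_A = dE + dE_R + dE_H + E_G*dV + int p_S + int p_J + spawned`,
#' using the cumulative assimilation/maintenance integrals carried in the
#' state vector.  Returns the relative closure error, which should be at
#' solver tolerance (~1e-6 or better).
#'
#' @param trajectory a `deb_trajectory`.
#' @param from,to window bounds (days); defaults to the full trajectory.
#' @return list with the budget terms and `rel_error`.
#' @export
energy_balance <- function(trajectory, from = NULL, to = NULL) {
  tr <- trajectory
  p <- tr$params
  t <- tr$time
  if (is.null(from)) from <- t[1]
  if (is.null(to)) to <- t[length(t)]
  i0 <- which.min(abs(t - from))
  i1 <- which.min(abs(t - to))
  s0 <- tr$state[i0, ]
  s1 <- tr$state[i1, ]
  spawned <- if (nrow(tr$spawns)) {
    idx <- tr$spawns$time > t[i0] & tr$spawns$time <= t[i1]
    # total buffer removed = released / kap_R (the rest is spawning overhead
    # only when kap_R < 1 is interpreted as efficiency; here the rule empties
    # kap_R*E_R, so removed equals released)
    sum(tr$spawns$energy_J[idx])
  } else 0
  assim <- s1["cA"] - s0["cA"]
  maint <- (s1["cS"] - s0["cS"]) + (s1["cJ"] - s0["cJ"])
  storage <- (s1["E"] - s0["E"]) + (s1["ER"] - s0["ER"]) + (s1["EH"] - s0["EH"])
  growth <- p$E_G * (s1["V"] - s0["V"])
  lhs <- assim
  rhs <- storage + growth + maint + spawned
  scale <- max(abs(lhs), abs(rhs), s0["E"] + s0["ER"] + p$E_G * s0["V"], 1e-300)
  list(assimilated = unname(assim), storage = unname(storage),
       growth = unname(growth), maintenance = unname(maint),
       spawned = spawned,
       rel_error = unname(abs(lhs - rhs) / scale))
}

#' Run a named simulation scenario
#'
#' Thin orchestration over [simulate_deb()]: builds parameters and forcing
#' from a configuration list, initialises from a weight or an egg, simulates,
#' and (when observation datasets are supplied) computes per-dataset relative
#' errors with the printed-loss machinery.
#'
#' @param config list with elements `species` (name or [deb_params]),
#'   `forcing` (a [forcing] or a data frame with columns `day`, `temp_C` and
#'   `chl` or `f`), `init_weight_g` (wet weight; alternatively `init_state`),
#'   `horizon`, optional `options` (see [deb_options()]), optional
#'   `observations` (list of datasets, see [deb_dataset()]).
#' @return list with `trajectory`, `observables`, and when observations are
#'   given, `errors` (per-dataset RE and the pooled MRE).
#' @export
run_scenario <- function(config) {
  cf <- config
  params <- if (inherits(cf$species, "deb_params")) cf$species else deb_species(cf$species)
  fc <- cf$forcing
  if (is.data.frame(fc)) {
    if (!"day" %in% names(fc)) stop("forcing table needs a 'day' column")
    if ("chl" %in% names(fc)) {
      fc <- forcing(fc$day, fc$temp_C, chl = fc$chl)
    } else if ("f" %in% names(fc)) {
      fc <- forcing(fc$day, fc$temp_C, f = fc$f)
    } else stop("forcing table needs a 'chl' or 'f' column")
  }
  init <- if (!is.null(cf$init_state)) cf$init_state else
    init_from_weight(params, cf$init_weight_g, wet = TRUE)
  opt <- utils::modifyList(deb_options(spawning = TRUE), cf$options %||% list())
  tr <- simulate_deb(params, fc, init, horizon = cf$horizon, options = opt)
  out <- list(trajectory = tr, observables = tr$observables)
  if (!is.null(cf$observations)) {
    preds <- lapply(cf$observations, function(d) predict_dataset(params, d))
    out$errors <- mre_report(cf$observations, preds)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
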