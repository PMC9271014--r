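# Life-stage thresholds and discrete events: initial reserve, embryo
# development, event detection, spawning, brooding, ageing and lifespan.

# integrate an embryo (no feeding) from a tiny structure until maturity
# reaches `EH_stop`, reserve is exhausted, or `t_max` elapses.
embryo_path <- function(params, E_0, T_K = params$T_ref, EH_stop = params$E_Hb,
                        V_0 = 1e-12, t_max = 200, t_eval = NULL) {
  p <- params
  TC <- temperature_correction(p, T_K)
  y0 <- organism_state(E = E_0, V = V_0, E_H = 0)
  core <- fast_deriv_factory(p)
  rhs <- function(t, y) core(y, f = 0, TC = TC, s = 1)
  E_m <- p$p_Am / p$v
  evs <- list(
    target = function(t, y) y[3] - EH_stop,
    exhausted = function(t, y) y[1] / (max(y[2], 1e-300) * E_m) - 1e-3
  )
  atol <- 1e-12 * c(E_0, max(V_0, 1e-12), EH_stop, E_0, 1, 1, 1, E_0, E_0, E_0)
  sol <- rk45(rhs, y0, 0, t_max, rtol = 1e-8, atol = atol,
              err_weights = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
              t_eval = t_eval, events = evs)
  reached <- identical(sol$event, "target")
  ye <- sol$y_end
  names(ye) <- .state_names
  list(reached = reached, age = sol$t_end, state = ye,
       e = unname(ye[1] / (ye[2] * E_m)), t = sol$t, y = sol$y)
}

#' Initial reserve of an egg
#'
#' Solves the classical DEB initial-reserve problem: the egg energy `E_0`
#' such that an embryo developing without feeding from `(E_0, V ~ 0,
#' E_H = 0)` reaches the birth threshold `E_Hb` with scaled reserve density
#' `e = e_b`.  Solved by root bracketing and bisection on `E_0`, with the
#' embryo initial-value problem as the inner solver.
#'
#' @param params a [deb_params] object (asj mode).
#' @param e_b target scaled reserve density at birth, in `(0, 1]`.
#' @param T_K temperature (Kelvin) at which the embryo develops.
#' @param tol relative tolerance on `E_0` (default 1e-7, comfortably inside
#'   the 1e-6 fixed-point check used in the tests).
#' @return list with `E_0` (J), `age_at_birth` (d), `state_at_birth`,
#'   `e_at_birth`.
#' @export
#' @examples
#' \donttest{
#' ir <- initial_reserve(deb_species("o_edulis"), e_b = 1)
#' ir$E_0
#' }
initial_reserve <- function(params, e_b = 1, T_K = params$T_ref, tol = 1e-7) {
  if (attr(params, "mode") != "asj") {
    stop("initial_reserve requires maturity thresholds (asj mode)")
  }
  if (e_b <= 0 || e_b > 1) stop("e_b must lie in (0, 1]")
  # residual: e at birth minus target (monotone increasing in E_0);
  # an embryo that dies before E_Hb counts as maximally negative.
  resid <- function(E_0) {
    sol <- embryo_path(params, E_0, T_K = T_K)
    if (!sol$reached) return(-e_b)
    sol$e - e_b
  }
  # scaling guess: structure at birth ~ kap*E_Hb/((1-kap)*E_G), egg energy of
  # the order of the reserve capacity over that volume
  V_b_guess <- params$kap * params$E_Hb / ((1 - params$kap) * params$E_G)
  guess <- max(params$p_Am / params$v * V_b_guess * e_b, params$E_Hb * 2)
  lo <- guess / 4
  hi <- guess * 4
  r_lo <- resid(lo)
  r_hi <- resid(hi)
  it <- 0
  while (r_lo > 0 && it < 40) {           # bracket downwards
    hi <- lo; r_hi <- r_lo
    lo <- lo / 4
    r_lo <- resid(lo)
    it <- it + 1
  }
  while (r_hi < 0 && it < 40) {           # bracket upwards
    lo <- hi; r_lo <- r_hi
    hi <- hi * 4
    r_hi <- resid(hi)
    it <- it + 1
  }
  if (r_lo > 0 || r_hi < 0) {
    stop("initial_reserve: failed to bracket E_0 (e_b = ", e_b, ")")
  }
  sol <- stats::uniroot(resid, lower = lo, upper = hi,
                        f.lower = r_lo, f.upper = r_hi, tol = tol * hi)
  E_0 <- sol$root
  birth <- embryo_path(params, E_0, T_K = T_K)
  list(E_0 = E_0, age_at_birth = birth$age, state_at_birth = birth$state,
       e_at_birth = birth$e)
}

# development time of a brooded embryo from fertilisation to the release
# threshold E_Hr at ambient temperature (flat oyster brooding duration)
brood_development_time <- function(params, T_K, e_b = 1) {
  if (is.null(params$E_Hr)) return(0)
  ir <- initial_reserve(params, e_b = e_b, T_K = T_K)
  sol <- embryo_path(params, ir$E_0, T_K = T_K, EH_stop = params$E_Hr)
  if (!sol$reached) return(ir$age_at_birth)  # conservative fallback
  sol$age
}

#' Feeding multiplier of a brooding individual
#'
#' While a flat oyster broods larvae in its mantle cavity its food intake is
#' reduced by a fixed factor (0.8); outside the brooding period the
#' multiplier is exactly 1.
#'
#' @param active is the individual currently brooding?
#' @param factor feeding multiplier while brooding.
#' @return scalar multiplier applied to the scaled functional response.
#' @export
brooding_multiplier <- function(active, factor = 0.8) {
  stopifnot(factor > 0, factor <= 1)
  if (isTRUE(active)) factor else 1
}

#' Detect life-history events on a trajectory
#'
#' Extracts ages, physical lengths and dry weights at the maturity
#' thresholds (birth, release, settlement, end of metamorphosis, puberty)
#' from a simulated trajectory.  Events located by the simulator's
#' root-finding are used when present; otherwise crossing times are obtained
#' by monotone interpolation of maturity over the stored grid.  Lengths use
#' the pre-metamorphic shape coefficient `del_Mb` before `E_Hj` and `del_M`
#' after.
#'
#' @param trajectory a `deb_trajectory` from [simulate_deb()].
#' @param params a [deb_params] object; defaults to the trajectory's own.
#' @return data frame with columns `event`, `age_d`, `length_cm`,
#'   `dryweight_g`; thresholds never reached are absent.
#' @export
detect_events <- function(trajectory, params = trajectory$params) {
  tr <- trajectory
  thr <- maturity_thresholds(params)
  if (!length(thr)) {
    return(data.frame(event = character(0), age_d = numeric(0),
                      length_cm = numeric(0), dryweight_g = numeric(0)))
  }
  out <- data.frame(event = character(0), age_d = numeric(0),
                    length_cm = numeric(0), dryweight_g = numeric(0))
  logged <- tr$events
  EH <- tr$state[, "EH"]
  for (i in seq_along(thr)) {
    nm <- names(thr)[i]
    if (nrow(logged) && nm %in% logged$event) {
      row <- logged[logged$event == nm, ][1, ]
      out <- rbind(out, data.frame(event = nm, age_d = row$time,
                                   length_cm = row$length_cm,
                                   dryweight_g = row$dryweight_g))
    } else if (any(EH >= thr[i]) && any(EH < thr[i])) {
      j <- which(EH >= thr[i])[1]
      if (j > 1) {
        w <- (thr[i] - EH[j - 1]) / (EH[j] - EH[j - 1])
        age <- tr$time[j - 1] + w * (tr$time[j] - tr$time[j - 1])
        V <- tr$state[j - 1, "V"] + w * (tr$state[j, "V"] - tr$state[j - 1, "V"])
        E <- tr$state[j - 1, "E"] + w * (tr$state[j, "E"] - tr$state[j - 1, "E"])
        del <- if (nm %in% c("metamorphosis", "puberty")) params$del_M else params$del_Mb
        out <- rbind(out, data.frame(
          event = nm, age_d = age, length_cm = V^(1 / 3) / del,
          dryweight_g = params$d_V * V + params$w_E * E / params$mu_E))
      }
    }
  }
  out
}

#' Apply a spawning event
#'
#' Empties a fraction `kap_R` of the reproduction buffer:
#' `E_R' = (1 - kap_R) * E_R`, energy released `kap_R * E_R`.  The egg count
#' is the released energy divided by the per-egg cost `E_0` evaluated at the
#' spawner's current reserve density (`e_b = e`).
#'
#' @param state adult [organism_state()] with `E_H = E_Hp` and `E_R > 0`.
#' @param params a [deb_params] object.
#' @param E_0 per-egg energy cost; computed from [initial_reserve()] when
#'   `NULL` (asj mode) and left `NA` otherwise.
#' @param T_K ambient temperature for the egg-cost evaluation.
#' @return list with `state` (buffer reduced), `energy_released` (J),
#'   `eggs` (count, `NA` when no egg cost is available).
#' @export
apply_spawning <- function(state, params, E_0 = NULL, T_K = params$T_ref) {
  y <- as_state_vector(state)
  if (!is.null(params$E_Hp) && y[3] < params$E_Hp) {
    stop("spawning before puberty")
  }
  kR <- params$kap_R
  released <- kR * y[4]
  y[4] <- (1 - kR) * y[4]
  eggs <- NA_real_
  if (released > 0) {
    if (is.null(E_0) && attr(params, "mode") == "asj") {
      e_now <- scaled_reserve_density(params, y)
      E_0 <- initial_reserve(params, e_b = min(max(e_now, 0.05), 1),
                             T_K = T_K)$E_0
    }
    if (!is.null(E_0)) eggs <- released / E_0
  } else if (!is.null(E_0)) {
    eggs <- 0
  } else {
    eggs <- 0
  }
  class(y) <- "deb_state"
  list(state = y, energy_released = unname(released), eggs = unname(eggs))
}

#' Expected lifespan under constant conditions
#'
#' Integrates the full life cycle from an egg with the Weibull--Gompertz
#' ageing module switched on, at constant scaled food `f` and temperature,
#' and returns the expected age at death `int S(t) dt` where
#' `S = exp(lnS)` is the survival probability implied by the hazard state.
#'
#' @param params a [deb_params] object (asj mode).
#' @param f constant scaled functional response in `(0, 1]`.
#' @param T_K temperature (Kelvin).
#' @param horizon integration cap (days); the run stops earlier once
#'   survival drops below 1e-9.
#' @return list with `mean_lifespan_d`, `trajectory`.
#' @export
lifespan <- function(params, f = 1, T_K = params$T_ref, horizon = 60000) {
  if (attr(params, "mode") != "asj") stop("lifespan requires asj mode")
  ir <- initial_reserve(params, e_b = min(f + 0.0, 1), T_K = T_K)
  init <- organism_state(E = ir$E_0, V = 1e-12, E_H = 0)
  fc <- constant_forcing(kelvin_to_celsius(T_K), f = f)
  opt <- deb_options(dt_out = horizon / 2000, ageing = TRUE,
                     spawning = FALSE, rtol = 1e-7)
  tr <- simulate_deb(params, fc, init, horizon = horizon, options = opt)
  S <- exp(tr$state[, "lnS"])
  t <- tr$time
  mean_ls <- sum(diff(t) * (S[-1] + S[-length(S)]) / 2)
  list(mean_lifespan_d = mean_ls, trajectory = tr)
}
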