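# Mapping model state to measurable quantities: shell length, weights,
# growth rate, fecundity, clearance and respiration proxies.

#' Physical (shell) length from structural volume
#'
#' `L_w = V^(1/3) / delta` with the shape coefficient `del_Mb` before the
#' end of metamorphosis (`E_H < E_Hj`) and `del_M` after; the change is a
#' step at `E_Hj` (the isomorphy assumption visibly breaks at settlement, so
#' no interpolation is attempted).
#'
#' @param V structural volume (cm^3), vectorised.
#' @param params a [deb_params] object.
#' @param E_H maturity used to pick the shape coefficient; defaults to
#'   post-metamorphic.
#' @return physical length (cm).
#' @export
physical_length <- function(V, params, E_H = NULL) {
  if (any(V < 0)) stop("V must be non-negative")
  del <- if (attr(params, "mode") == "asj" && !is.null(E_H)) {
    ifelse(E_H < params$E_Hj, params$del_Mb, params$del_M)
  } else {
    params$del_M
  }
  V^(1 / 3) / del
}

#' Tissue dry and wet weight of a state
#'
#' Dry weight `= d_V*V + w_E*(E + E_R)/mu_E`; wet weight `= dry /
#' dw_ww_ratio` (the measured dry-tissue to total-weight ratios: 0.015 for
#' the flat oyster, 0.018 for the Pacific oyster).
#'
#' @param params a [deb_params] object.
#' @param state an [organism_state()].
#' @param include_buffer include the reproduction buffer mass (default yes).
#' @return weight in grams.
#' @export
dry_weight <- function(params, state, include_buffer = TRUE) {
  y <- as_state_vector(state)
  res <- y[1] + if (include_buffer) y[4] else 0
  unname(params$d_V * y[2] + params$w_E * res / params$mu_E)
}

#' @rdname dry_weight
#' @export
wet_weight <- function(params, state, include_buffer = TRUE) {
  dry_weight(params, state, include_buffer) / params$dw_ww_ratio
}

#' Growth rate from start and end dry weights
#'
#' The growth-rate definition used for the constant-condition laboratory
#' comparisons: `(DW_end - DW_start) / time`, in g dry weight per day.
#' Negative values are allowed (shrinkage under starvation).
#'
#' @param dw_start,dw_end dry weights (g).
#' @param days elapsed time (d), `> 0`.
#' @return growth rate (g DW d^-1).
#' @export
growth_rate <- function(dw_start, dw_end, days) {
  if (any(days <= 0)) stop("days must be positive")
  (dw_end - dw_start) / days
}

#' Continuous reproduction rate
#'
#' Egg production rate of an adult at structural length `L` and scaled food
#' `f`: `R = kap_R * p_R / E_0` with `p_R = (1-kap)*p_C - k_J*E_Hp`
#' evaluated at reserve equilibrium (`e = f`) and the per-egg cost `E_0`
#' from [initial_reserve()] at `e_b = f`.  Below the puberty length the rate
#' is zero with a warning.
#'
#' @param params a [deb_params] object (asj mode).
#' @param f scaled functional response.
#' @param T_K temperature (Kelvin).
#' @param L structural length (cm).
#' @param E_0 per-egg cost; computed when `NULL`.
#' @return eggs per day.
#' @export
reproduction_rate <- function(params, f, T_K = params$T_ref, L,
                              E_0 = NULL) {
  p <- params
  TC <- temperature_correction(p, T_K)
  s_M <- if (!is.null(p$s_M)) p$s_M else 1
  E_m <- p$p_Am / p$v
  V <- L^3
  st <- organism_state(E = f * E_m * V, V = V,
                       E_H = if (!is.null(p$E_Hp)) p$E_Hp else 0)
  fl <- compute_fluxes(p, st, f = f, T_corr = TC, s = s_M)
  if (fl$p_R <= 0) {
    warning("no surplus for reproduction at this length/food level")
    return(0)
  }
  if (is.null(E_0)) {
    if (attr(p, "mode") != "asj") stop("E_0 required in std mode")
    E_0 <- initial_reserve(p, e_b = min(max(f, 0.05), 1), T_K = T_K)$E_0
  }
  p$kap_R * fl$p_R / E_0
}

#' Relative oxygen-consumption proxy
#'
#' A weighted sum of the dissipating powers: somatic plus maturity
#' maintenance, the assimilation overhead `p_A*(1 - kap_X - kap_P)/kap_X`,
#' and the growth overhead `(1 - kap_G)*p_G`.  With the default unit
#' weights the proxy is proportional to total dissipation; absolute
#' calibration to micromoles of O2 is out of scope, so the output is
#' relative and the coefficients are configurable.
#'
#' @param fluxes a `deb_fluxes` object from [compute_fluxes()].
#' @param params a [deb_params] object.
#' @param coefficients named list: `maintenance`, `assimilation`, `growth`
#'   weights (all `>= 0`).
#' @param kap_G growth efficiency used for the growth overhead.
#' @return non-negative relative respiration value.
#' @export
respiration_proxy <- function(fluxes, params,
                              coefficients = list(maintenance = 1,
                                                  assimilation = 1,
                                                  growth = 1),
                              kap_G = 0.8) {
  co <- utils::modifyList(list(maintenance = 1, assimilation = 1, growth = 1),
                          coefficients)
  if (any(unlist(co) < 0)) stop("respiration coefficients must be non-negative")
  assim_overhead <- fluxes$p_A * (1 - params$kap_X - params$kap_P) / params$kap_X
  growth_overhead <- (1 - kap_G) * max(fluxes$p_G, 0)
  co$maintenance * (fluxes$p_S + fluxes$p_J) +
    co$assimilation * assim_overhead +
    co$growth * growth_overhead
}

#' Clearance-rate proxy
#'
#' `F_m * s_M * V^(2/3) * TC` per gram dry weight, for comparison with
#' reported maximum clearance rates (litres per hour per gram); reported for
#' inspection only, since the per-gram normalisation conditions of the
#' literature values are not standardised.
#'
#' @param params a [deb_params] object (requires `F_m`).
#' @param state an [organism_state()].
#' @param T_K temperature (Kelvin).
#' @return clearance rate in L h^-1 g^-1 dry weight.
#' @export
clearance_rate <- function(params, state, T_K = params$T_ref) {
  if (is.null(params$F_m)) stop("parameter set has no F_m")
  y <- as_state_vector(state)
  s_M <- if (!is.null(params$s_M)) params$s_M else 1
  TC <- temperature_correction(params, T_K)
  litres_per_day <- params$F_m * s_M * y[2]^(2 / 3) * TC
  litres_per_day / 24 / dry_weight(params, y)
}

#' Plot a simulated trajectory
#'
#' Stacked dry-weight partition over time: structure, reserve and
#' reproduction buffer (the classical presentation of a multi-year
#' simulation), with life events marked.
#'
#' @param x a `deb_trajectory`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.deb_trajectory <- function(x, ...) {
  dec <- dw_decomposition(x)
  graphics::plot(dec$day, dec$total_g, type = "n", xlab = "day",
                 ylab = "tissue dry weight (g)", ...)
  graphics::polygon(c(dec$day, rev(dec$day)),
                    c(rep(0, nrow(dec)), rev(dec$structure_g)),
                    col = "grey20", border = NA)
  graphics::polygon(c(dec$day, rev(dec$day)),
                    c(dec$structure_g, rev(dec$structure_g + dec$reserve_g)),
                    col = "grey55", border = NA)
  graphics::polygon(c(dec$day, rev(dec$day)),
                    c(dec$structure_g + dec$reserve_g, rev(dec$total_g)),
                    col = "grey85", border = NA)
  if (nrow(x$events)) {
    graphics::abline(v = x$events$time, lty = 3, col = "grey40")
  }
  graphics::legend("topleft", bty = "n", fill = c("grey20", "grey55", "grey85"),
                   legend = c("structure", "reserve", "reproduction buffer"))
  invisible(x)
}

#' Dry-weight decomposition of a trajectory
#'
#' Splits tissue dry weight into structure, reserve and reproduction-buffer
#' contributions (the partition shown in the two-year simulations of both
#' species); the three components sum exactly to the reported total.
#'
#' @param trajectory a `deb_trajectory`.
#' @return data frame with columns `day`, `structure_g`, `reserve_g`,
#'   `buffer_g`, `total_g`.
#' @export
dw_decomposition <- function(trajectory) {
  p <- trajectory$params
  st <- trajectory$state
  structure_g <- p$d_V * st[, "V"]
  reserve_g <- p$w_E * st[, "E"] / p$mu_E
  buffer_g <- p$w_E * st[, "ER"] / p$mu_E
  data.frame(day = trajectory$time, structure_g = structure_g,
             reserve_g = reserve_g, buffer_g = buffer_g,
             total_g = structure_g + reserve_g + buffer_g)
}
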