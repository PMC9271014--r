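# asj DEB core: organism state, energy fluxes, state derivatives.
#
# State vector layout used throughout the package (all energies J, volume
# cm^3, time d):
#   1 E    reserve energy
#   2 V    structural volume
#   3 EH   maturity (frozen at E_Hp)
#   4 ER   reproduction buffer
#   5 q    ageing acceleration (d^-2)
#   6 h    hazard rate (d^-1)
#   7 lnS  log survival probability
#   8 cA   cumulative assimilated energy  (diagnostic)
#   9 cS   cumulative somatic maintenance (diagnostic)
#  10 cJ   cumulative maturity maintenance (diagnostic)

.state_names <- c("E", "V", "EH", "ER", "q", "h", "lnS", "cA", "cS", "cJ")

#' Construct an organism state
#'
#' Instantaneous state of the modelled individual: reserve `E` (J),
#' structural volume `V` (cm^3), maturity `E_H` (J), reproduction buffer
#' `E_R` (J), plus the Weibull--Gompertz ageing states `q` (d^-2) and `h`
#' (d^-1) and the log survival probability `lnS`.  Three trailing slots
#' accumulate assimilation and maintenance integrals for energy-balance
#' checks.
#'
#' @param E reserve energy (J).
#' @param V structural volume (cm^3).
#' @param E_H maturity (J).
#' @param E_R reproduction buffer (J), default 0.
#' @param q,h,lnS ageing states, default 0.
#' @return named numeric vector of length 10 with class `deb_state`.
#' @export
organism_state <- function(E, V, E_H, E_R = 0, q = 0, h = 0, lnS = 0) {
  if (any(c(E, V, E_R) < 0)) stop("E, V and E_R must be non-negative")
  if (E_H < 0) stop("maturity must be non-negative")
  y <- c(E, V, E_H, E_R, q, h, lnS, 0, 0, 0)
  names(y) <- .state_names
  class(y) <- "deb_state"
  y
}

# coerce list/vector input to the internal 10-slot state vector
as_state_vector <- function(state) {
  if (inherits(state, "deb_state") || (is.numeric(state) && length(state) == 10L)) {
    y <- unclass(state)
    names(y) <- .state_names
    return(y)
  }
  if (is.list(state)) {
    return(organism_state(E = state$E, V = state$V,
                          E_H = if (is.null(state$E_H)) state$EH else state$E_H,
                          E_R = if (is.null(state$E_R)) {
                            if (is.null(state$ER)) 0 else state$ER
                          } else state$E_R))
  }
  stop("cannot interpret 'state'; use organism_state()")
}

#' Scaled reserve density
#'
#' `e = E / (V * E_m)` with `E_m = {p_Am}/v`.  The acceleration factor
#' cancels because it multiplies `{p_Am}` and `v` alike.  Under constant food
#' `e` relaxes towards the scaled functional response `f` (weak homeostasis).
#'
#' @param params a [deb_params] object.
#' @param state an [organism_state()] (or anything coercible).
#' @return dimensionless scaled reserve density.
#' @export
scaled_reserve_density <- function(params, state) {
  y <- as_state_vector(state)
  E_m <- params$p_Am / params$v
  unname(y[1] / (y[2] * E_m))
}

#' Metabolic acceleration factor
#'
#' In the 'asj' model `{p_Am}` and `v` are multiplied by the acceleration
#' factor `s`: 1 before settlement (`E_H < E_Hs`), `L/L_s` between
#' settlement and the end of metamorphosis, and frozen at
#' `s_M = L_j/L_s` afterwards.  The simulator tracks `L_s` explicitly; when
#' it is not available (an isolated state) the factor is approximated by
#' `(E_H/E_Hs)^(1/3)` capped to `[1, s_M]`, which is exact in the limit of
#' maturity growing proportionally to structure during the exponential
#' metamorphic phase.
#'
#' @param params a [deb_params] object.
#' @param state organism state.
#' @param L_s structural length at settlement (cm), if known.
#' @return dimensionless acceleration factor `>= 1`.
#' @export
acceleration_factor <- function(params, state, L_s = NULL) {
  mode <- attr(params, "mode")
  s_M <- if (!is.null(params$s_M)) params$s_M else 1
  if (is.null(mode) || mode != "asj") return(s_M)
  y <- as_state_vector(state)
  E_H <- y[3]
  if (E_H < params$E_Hs) return(1)
  if (E_H >= params$E_Hj) return(s_M)
  if (!is.null(L_s)) {
    return(min(max(y[2]^(1 / 3) / L_s, 1), s_M))
  }
  min(max((E_H / params$E_Hs)^(1 / 3), 1), s_M)
}

#' Energy fluxes of the asj DEB model
#'
#' Evaluates all powers (J/d) at a given state, feeding level and
#' temperature correction:
#' \itemize{
#'   \item assimilation `p_A = s * {p_Am} * f * V^(2/3) * TC` (zero before
#'     birth, `E_H < E_Hb`), ingestion `p_X = p_A / kap_X`;
#'   \item somatic maintenance `p_S = [p_M]*V*TC + {p_T}*V^(2/3)*TC`;
#'   \item mobilisation `p_C = E * (E_G*s*v*TC/L + p_S/V) / (kap*E/V + E_G)`;
#'   \item the kappa rule: `p_G = kap*p_C - p_S` (somatic growth) and
#'     `p_R = (1-kap)*p_C - p_J` with maturity maintenance `p_J = k_J*E_H*TC`.
#' }
#' When `kap*p_C < p_S` the somatic branch cannot pay maintenance and the
#' `starvation` flag is set (handling is done by [state_derivatives()]).
#'
#' @param params a [deb_params] object.
#' @param state an [organism_state()].
#' @param f scaled functional response in `[0, 1]`.
#' @param T_corr temperature correction factor (> 0), see
#'   [temperature_correction()].
#' @param s acceleration factor; default from [acceleration_factor()].
#' @param T_corr_ingestion separate temperature correction applied to the
#'   feeding fluxes (`p_X`, `p_A`) only; defaults to `T_corr` (coupled
#'   correction, the form the parameters were estimated under).  Supplying a
#'   different value decouples the thermal response of ingestion from that
#'   of respiration/maintenance.
#' @return object of class `deb_fluxes`: named list with `p_X`, `p_A`,
#'   `p_C`, `p_S`, `p_J`, `p_G`, `p_R`, plus `s`, `e` (scaled reserve
#'   density) and logical `starvation`.
#' @export
#' @examples
#' p <- deb_species("o_edulis")
#' st <- organism_state(E = 4550, V = 1, E_H = p$E_Hp)
#' fl <- compute_fluxes(p, st, f = 1, T_corr = 1)
#' all.equal(fl$p_G + fl$p_S, p$kap * fl$p_C)  # kappa-rule balance
compute_fluxes <- function(params, state, f, T_corr, s = NULL,
                           T_corr_ingestion = T_corr) {
  y <- as_state_vector(state)
  E <- y[1]; V <- y[2]; E_H <- y[3]
  if (any(c(E, V, E_H) < 0)) stop("negative state component")
  if (V <= 0) stop("structural volume must be positive")
  if (f < 0 || f > 1) stop("scaled functional response must lie in [0, 1]")
  if (T_corr <= 0 || T_corr_ingestion <= 0) {
    stop("temperature correction must be positive")
  }
  p <- params
  if (is.null(s)) s <- acceleration_factor(p, y)
  L <- V^(1 / 3)
  embryo <- attr(p, "mode") == "asj" && E_H < p$E_Hb
  p_A <- if (embryo) 0 else s * p$p_Am * f * V^(2 / 3) * T_corr_ingestion
  p_X <- p_A / p$kap_X
  p_S <- (p$p_M * V + p$p_T * V^(2 / 3)) * T_corr
  p_C <- E * (p$E_G * s * p$v * T_corr / L + p_S / V) / (p$kap * E / V + p$E_G)
  p_J <- p$k_J * E_H * T_corr
  p_G <- p$kap * p_C - p_S
  p_R <- (1 - p$kap) * p_C - p_J
  structure(list(p_X = unname(p_X), p_A = unname(p_A), p_C = unname(p_C),
                 p_S = unname(p_S), p_J = unname(p_J), p_G = unname(p_G),
                 p_R = unname(p_R), s = s,
                 e = unname(E / (V * p$p_Am / p$v)),
                 starvation = unname(p_G < 0)),
            class = "deb_fluxes")
}

#' Time derivatives of the organism state
#'
#' Assembles the state derivative vector from [compute_fluxes()]:
#' `dE/dt = p_A - p_C`, `dV/dt = p_G/E_G`, `dE_H/dt = p_R` before puberty
#' (frozen at `E_Hp`), `dE_R/dt = p_R` after, plus the Weibull--Gompertz
#' ageing pair and the survival log-probability.  Under starvation
#' (`kap*p_C < p_S`) the somatic shortfall is paid first from the
#' reproduction buffer, then by shrinking structure at cost `E_G` per cm^3;
#' death (scaled reserve density below 1e-4) is detected by the simulator,
#' not here.
#'
#' @inheritParams compute_fluxes
#' @param ageing integrate the ageing/survival states (slots 5-7); when
#'   `FALSE` their derivatives are zero, which leaves growth unaffected
#'   because ageing does not feed back on the energetics.
#' @return named numeric vector of length 10 (see [organism_state()]).
#' @export
state_derivatives <- function(params, state, f, T_corr, s = NULL,
                              ageing = FALSE, T_corr_ingestion = T_corr) {
  y <- as_state_vector(state)
  p <- params
  if (is.null(s)) s <- acceleration_factor(p, y)
  fl <- compute_fluxes(p, y, f, T_corr, s = s,
                       T_corr_ingestion = T_corr_ingestion)
  E <- y[1]; V <- y[2]; E_H <- y[3]; E_R <- y[4]
  adult <- !is.null(p$E_Hp) && E_H >= p$E_Hp

  dE <- fl$p_A - fl$p_C
  if (fl$p_G >= 0) {
    dV <- fl$p_G / p$E_G
    dER_starv <- 0
  } else {
    shortfall <- -fl$p_G                     # p_S - kap*p_C > 0
    if (adult && E_R > 0) {
      dV <- 0
      dER_starv <- -shortfall
    } else {
      dV <- -shortfall / p$E_G               # shrink structure
      dER_starv <- 0
    }
  }
  if (adult) {
    dEH <- 0
    dER <- fl$p_R + dER_starv
    if (dER < 0 && E_R <= 0) {
      dV <- dV + dER / p$E_G   # empty buffer: maintenance paid from structure
      dER <- 0
    }
  } else {
    dEH <- fl$p_R
    dER <- 0
    if (dEH < 0 && fl$p_G < 0) {
      dV <- dV + dEH / p$E_G   # no rejuvenation: shrink structure instead
      dEH <- 0
    }
  }

  dq <- dh <- dlnS <- 0
  if (ageing && !is.null(p$h_a) && p$h_a > 0) {
    L_m <- p$kap * p$p_Am / p$p_M
    s_M <- if (!is.null(p$s_M)) p$s_M else 1
    V_m <- (s_M * L_m)^3
    r <- dV / V
    e <- fl$e
    v_T <- s * p$v * T_corr
    L <- V^(1 / 3)
    dq <- (y[5] * (V / V_m) * p$s_g + p$h_a) * e * (v_T / L - r) - r * y[5]
    dh <- y[5] - r * y[6]
    dlnS <- -y[6]
  }

  dy <- c(dE, dV, dEH, dER, dq, dh, dlnS, fl$p_A, fl$p_S, fl$p_J)
  names(dy) <- .state_names
  dy
}
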