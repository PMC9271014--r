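# Environmental forcing: temperature correction and functional response.

#' Celsius/Kelvin conversion helpers
#'
#' Temperatures are Kelvin internally and degrees Celsius at I/O boundaries;
#' the offset is 273.15 K.
#'
#' @param T_C,T_K temperature in degrees Celsius / Kelvin.
#' @return numeric temperature in the other unit.
#' @export
celsius_to_kelvin <- function(T_C) T_C + 273.15

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(T_K) T_K - 273.15

#' Five-parameter Arrhenius temperature correction
#'
#' Computes the multiplicative correction applied to all metabolic rates:
#' \deqn{TC(T) = \exp(T_A/T_{ref} - T_A/T) \cdot s(T_{ref})/s(T)}
#' with the tolerance-boundary factor
#' \deqn{s(T) = 1 + \exp(T_{AL}/T - T_{AL}/T_L) + \exp(T_{AH}/T_H - T_{AH}/T).}
#' By construction `TC(T_ref) = 1` exactly, `TC > 0` everywhere, and the
#' correction decays outside the tolerance range `[T_L, T_H]`.
#'
#' @param params a [deb_params] object (its `T_ref`, `T_A`, `T_L`, `T_AL`,
#'   `T_H`, `T_AH` entries are used), or a named list holding those six keys.
#' @param T_K temperature in Kelvin (vectorised).
#' @return positive correction factor(s).
#' @export
#' @examples
#' p <- deb_species("o_edulis")
#' temperature_correction(p, p$T_ref)  # exactly 1
temperature_correction <- function(params, T_K) {
  if (any(T_K <= 0)) stop("absolute temperature must be positive")
  p <- params
  s <- function(T) {
    1 + exp(p$T_AL / T - p$T_AL / p$T_L) + exp(p$T_AH / p$T_H - p$T_AH / T)
  }
  exp(p$T_A / p$T_ref - p$T_A / T_K) * s(p$T_ref) / s(T_K)
}

#' Holling type-II scaled functional response
#'
#' Feeding level as a saturating function of food density:
#' `f = X / (X + K_X)`, with `f(K_X) = 0.5` and `f` in `[0, 1)`.
#' Chlorophyll-a concentration is used as the food proxy.
#'
#' @param X food density (micrograms chlorophyll-a per litre), `X >= 0`
#'   (vectorised).
#' @param K_X half-saturation constant in the same unit, `K_X > 0`.
#' @return scaled functional response in `[0, 1)`.
#' @export
#' @examples
#' functional_response(10, 1.84)  # ~0.84, flat oyster at the high lab ration
functional_response <- function(X, K_X) {
  if (any(X < 0)) stop("food density X must be non-negative")
  if (K_X <= 0) stop("half-saturation constant K_X must be positive")
  X / (X + K_X)
}

#' Build a forcing object
#'
#' A forcing couples a time grid (days) to water temperature (degrees C) and
#' food, the latter either as chlorophyll-a density (`chl`, micrograms per
#' litre, converted to a scaled functional response through `K_X` at
#' evaluation time) or directly as a scaled functional response (`f`).
#' Series are linearly interpolated between grid points and clamped (with a
#' warning) outside the grid.  Constant forcings may be built with
#' `constant_forcing()`.
#'
#' @param time numeric vector of days, strictly increasing.
#' @param temp_C temperature series, degrees Celsius.
#' @param chl chlorophyll-a series (exclusive with `f`).
#' @param f scaled-functional-response series in `[0, 1]` (exclusive with
#'   `chl`).
#' @return an object of class `deb_forcing`.
#' @export
forcing <- function(time, temp_C, chl = NULL, f = NULL) {
  time <- as.numeric(time)
  if (length(time) < 1L) stop("empty forcing")
  if (is.unsorted(time, strictly = TRUE)) {
    stop("forcing time grid must be strictly increasing")
  }
  if (is.null(chl) == is.null(f)) {
    stop("supply exactly one of 'chl' or 'f'")
  }
  mode <- if (is.null(chl)) "f" else "chl"
  food <- if (mode == "chl") as.numeric(chl) else as.numeric(f)
  temp_C <- as.numeric(temp_C)
  if (length(temp_C) == 1L) temp_C <- rep(temp_C, length(time))
  if (length(food) == 1L) food <- rep(food, length(time))
  if (length(temp_C) != length(time) || length(food) != length(time)) {
    stop("temperature and food series must match the time grid length")
  }
  if (mode == "f" && any(food < 0 | food > 1)) {
    stop("scaled functional response must lie in [0, 1]")
  }
  if (mode == "chl" && any(food < 0)) stop("chlorophyll must be non-negative")
  structure(list(time = time, temp_C = temp_C, food = food, mode = mode,
                 constant = length(time) == 1L ||
                   (all(temp_C == temp_C[1]) && all(food == food[1]))),
            class = "deb_forcing")
}

#' @rdname forcing
#' @param horizon span in days covered by a constant forcing.
#' @export
constant_forcing <- function(temp_C, chl = NULL, f = NULL, horizon = Inf) {
  fc <- forcing(0, temp_C, chl = chl, f = f)
  fc$horizon <- horizon
  fc
}

#' Evaluate forcing at a time point
#'
#' Linear interpolation on the forcing grid; times outside the grid are
#' clamped to the first/last record with a warning (once per call).
#'
#' @param fc a [forcing] object.
#' @param t time (days), vectorised.
#' @param K_X half-saturation constant used to convert chlorophyll to a
#'   scaled functional response; required when the forcing is in `chl` mode
#'   and `as_f = TRUE`.
#' @param as_f return food as scaled functional response (default) rather
#'   than raw chlorophyll.
#' @return list with elements `T_K` (Kelvin), `T_C`, and `f` or `X`.
#' @export
forcing_at <- function(fc, t, K_X = NULL, as_f = TRUE) {
  stopifnot(inherits(fc, "deb_forcing"))
  n <- length(fc$time)
  if (n == 1L || fc$constant) {
    T_C <- rep(fc$temp_C[1], length(t))
    food <- rep(fc$food[1], length(t))
  } else {
    if (any(t < fc$time[1] - 1e-9) || any(t > fc$time[n] + 1e-9)) {
      warning("forcing evaluated outside its span; clamping to end values")
    }
    tc <- pmin(pmax(t, fc$time[1]), fc$time[n])
    T_C <- stats::approx(fc$time, fc$temp_C, xout = tc, rule = 2)$y
    food <- stats::approx(fc$time, fc$food, xout = tc, rule = 2)$y
  }
  out <- list(T_C = T_C, T_K = celsius_to_kelvin(T_C))
  if (fc$mode == "f") {
    out$f <- food
  } else if (as_f) {
    if (is.null(K_X)) stop("K_X needed to convert chlorophyll forcing to f")
    out$X <- food
    out$f <- functional_response(food, K_X)
  } else {
    out$X <- food
  }
  out
}

#' @export
print.deb_forcing <- function(x, ...) {
  cat("DEB forcing (", x$mode, " mode, ",
      if (x$constant) "constant" else paste0(length(x$time), " records"),
      ")\n", sep = "")
  cat("  T: ", paste(range(x$temp_C), collapse = " to "), " degC; food: ",
      paste(signif(range(x$food), 4), collapse = " to "), "\n", sep = "")
  invisible(x)
}
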