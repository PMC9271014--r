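# Parameter estimation: dataset model, the printed mean-relative-error
# loss, prediction dispatch, Nelder-Mead covariation optimisation, and
# half-saturation calibration.

#' Construct observation datasets
#'
#' `zero_variate()` describes a single life-history trait observation (one
#' value, one weight, an evaluation context); `deb_dataset()` describes a
#' uni-variate series (abscissa, observations, per-point weights, shared
#' context).  Registered zero-variate trait names: `ab` (age at birth, d),
#' `Lb`, `Lr`, `Ls` (physical lengths at birth/release/settlement, cm),
#' `Wd0` (initial egg dry weight, g), `Wwp` (wet weight at puberty, g),
#' `Li` (ultimate physical length, cm), `Wdi` (ultimate dry weight, g),
#' `am` (mean lifespan, d), `Ri` (ultimate reproduction rate, eggs/d),
#' `CR_max` (clearance rate, L/h/g).  Registered series types:
#' `growth_dw`, `growth_ww`, `growth_length` (time series under the
#' context's forcing), `respiration_T` (respiration proxy versus
#' temperature), `fecundity_length` (egg rate versus physical length).
#'
#' The context list understands: `temp_C` (scalar), `f` or `chl` (food
#' level), `init_weight_g` + `init_e` (initial condition for series,
#' wet weight and assumed reserve density), `e_b` (egg reserve density for
#' embryo-based traits), `forcing` (a [forcing] object overriding
#' `temp_C`/food for series).
#'
#' @param name trait name (zero-variate) or dataset label.
#' @param value observed trait value (`Y != 0`).
#' @param unit unit string, documentation only.
#' @param weight weight coefficient `beta >= 0`; by convention 1 per
#'   zero-variate trait and `1/m` per point of an `m`-point series.
#' @param context named list, see Details.
#' @param label data-source label, documentation only.
#' @return an object of class `deb_zero_variate` / `deb_dataset`.
#' @export
zero_variate <- function(name, value, unit = "", weight = 1,
                         context = list(), label = "") {
  if (value == 0) stop("zero-variate value must be non-zero (relative error)")
  if (weight < 0) stop("weight must be non-negative")
  structure(list(name = name, y = value, unit = unit, weights = weight,
                 context = context, label = label),
            class = "deb_zero_variate")
}

#' @rdname zero_variate
#' @param type series type, see Details.
#' @param x abscissa (days, degrees C, or cm depending on `type`).
#' @param y observations, same length as `x`, all non-zero.
#' @param weights per-point weights; default `1/length(y)` each, so one
#'   series carries the weight of one dataset.
#' @export
deb_dataset <- function(type, x, y, weights = NULL, context = list(),
                        name = type) {
  if (length(x) != length(y) || length(y) < 1L) {
    stop("x and y must have equal length >= 1")
  }
  if (any(y == 0)) stop("observations must be non-zero (relative error)")
  if (is.null(weights)) weights <- rep(1 / length(y), length(y))
  if (length(weights) == 1L) weights <- rep(weights, length(y))
  if (any(weights < 0)) stop("weights must be non-negative")
  structure(list(type = type, name = name, x = x, y = y, weights = weights,
                 context = context),
            class = "deb_dataset")
}

.zero_variate_traits <- c("ab", "Lb", "Lr", "Ls", "Wd0", "Wwp", "Li", "Wdi",
                          "am", "Ri", "CR_max")
.series_types <- c("growth_dw", "growth_ww", "growth_length",
                   "respiration_T", "fecundity_length")

# context helpers -------------------------------------------------------------
ctx_f <- function(params, ctx) {
  if (!is.null(ctx$f)) return(ctx$f)
  if (!is.null(ctx$chl)) return(functional_response(ctx$chl, params$K_X))
  1
}
ctx_TK <- function(params, ctx) {
  if (!is.null(ctx$temp_C)) celsius_to_kelvin(ctx$temp_C) else params$T_ref
}

#' Predict a dataset from a parameter set
#'
#' Dispatches a zero-variate trait or a uni-variate series to the
#' life-cycle, simulation and observable machinery, evaluated in the
#' dataset's context (temperature, food level, initial condition), and
#' returns one prediction per observation.
#'
#' @param params a [deb_params] object.
#' @param dataset a [zero_variate()] or [deb_dataset()].
#' @return numeric vector of predictions (length 1 for zero-variate).
#' @export
predict_dataset <- function(params, dataset) {
  if (inherits(dataset, "deb_zero_variate")) {
    return(predict_trait(params, dataset$name, dataset$context))
  }
  if (!inherits(dataset, "deb_dataset")) {
    stop("dataset must be a zero_variate() or deb_dataset()")
  }
  type <- dataset$type
  ctx <- dataset$context
  if (!type %in% .series_types) {
    stop("unknown dataset type '", type, "'; registered types: ",
         paste(.series_types, collapse = ", "))
  }
  if (type %in% c("growth_dw", "growth_ww", "growth_length")) {
    fc <- if (!is.null(ctx$forcing)) ctx$forcing else {
      if (!is.null(ctx$chl)) {
        constant_forcing(ctx$temp_C %||% kelvin_to_celsius(params$T_ref),
                         chl = ctx$chl)
      } else {
        constant_forcing(ctx$temp_C %||% kelvin_to_celsius(params$T_ref),
                         f = ctx$f %||% 1)
      }
    }
    init <- init_from_weight(params, ctx$init_weight_g, wet = TRUE,
                             e = ctx$init_e %||% 0.8)
    horizon <- max(dataset$x)
    opt <- deb_options(dt_out = 1, spawning = FALSE)
    tr <- simulate_deb(params, fc, init, horizon = horizon, options = opt)
    idx <- vapply(dataset$x, function(d) {
      i <- which.min(abs(tr$time - d))
      if (abs(tr$time[i] - d) > 0.5) stop("no simulated point within 0.5 d of day ", d)
      i
    }, integer(1))
    col <- switch(type, growth_dw = "dw_g", growth_ww = "ww_g",
                  growth_length = "length_cm")
    return(tr$observables[[col]][idx])
  }
  if (type == "respiration_T") {
    st <- init_from_weight(params, ctx$init_weight_g, wet = TRUE,
                           e = ctx$init_e %||% 0.8)
    f <- ctx_f(params, ctx)
    vapply(dataset$x, function(T_C) {
      TC <- temperature_correction(params, celsius_to_kelvin(T_C))
      fl <- compute_fluxes(params, st, f = f, T_corr = TC)
      respiration_proxy(fl, params)
    }, numeric(1))
  } else {  # fecundity_length
    f <- ctx_f(params, ctx)
    T_K <- ctx_TK(params, ctx)
    E_0 <- initial_reserve(params, e_b = min(max(f, 0.05), 1), T_K = T_K)$E_0
    vapply(dataset$x, function(Lw) {
      L <- Lw * params$del_M
      suppressWarnings(reproduction_rate(params, f = f, T_K = T_K, L = L,
                                         E_0 = E_0))
    }, numeric(1))
  }
}

# zero-variate trait predictions
predict_trait <- function(params, name, ctx = list()) {
  p <- params
  f <- ctx_f(p, ctx)
  T_K <- ctx_TK(p, ctx)
  e_b <- ctx$e_b %||% 1
  cp <- compound_parameters(p, f = f)
  switch(name,
    ab = initial_reserve(p, e_b = e_b, T_K = T_K)$age_at_birth,
    Lb = {
      st <- initial_reserve(p, e_b = e_b, T_K = T_K)$state_at_birth
      st[2]^(1 / 3) / p$del_Mb
    },
    Lr = {
      if (is.null(p$E_Hr)) stop("parameter set has no release threshold E_Hr")
      ir <- initial_reserve(p, e_b = e_b, T_K = T_K)
      sol <- embryo_path(p, ir$E_0, T_K = T_K, EH_stop = p$E_Hr)
      sol$state[2]^(1 / 3) / p$del_Mb
    },
    Ls = {
      tr <- grow_from_egg(p, f = f, T_K = T_K, until = "settlement")
      ev <- tr$events
      ev$length_cm[ev$event == "settlement"][1]
    },
    Wd0 = p$w_E * initial_reserve(p, e_b = e_b, T_K = T_K)$E_0 / p$mu_E,
    Wwp = {
      tr <- grow_from_egg(p, f = f, T_K = T_K, until = "puberty")
      ev <- tr$events
      i <- which(tr$time == ev$time[ev$event == "puberty"][1])[1]
      if (is.na(i)) i <- nrow(tr$state)
      wet_weight(p, tr$state[i, ])
    },
    Li = cp$Lw_inf,
    Wdi = {
      V_inf <- cp$L_inf^3
      V_inf * (p$d_V + f * cp$E_m * p$w_E / p$mu_E)
    },
    am = lifespan(p, f = f, T_K = T_K)$mean_lifespan_d,
    Ri = {
      E_0 <- initial_reserve(p, e_b = min(max(f, 0.05), 1), T_K = T_K)$E_0
      suppressWarnings(
        reproduction_rate(p, f = f, T_K = T_K, L = 0.999 * cp$L_inf, E_0 = E_0))
    },
    CR_max = {
      V_inf <- cp$L_inf^3
      st <- organism_state(E = f * cp$E_m * V_inf, V = V_inf,
                           E_H = if (!is.null(p$E_Hp)) p$E_Hp else 0)
      clearance_rate(p, st, T_K = T_K)
    },
    stop("unknown zero-variate trait '", name, "'; registered traits: ",
         paste(.zero_variate_traits, collapse = ", "))
  )
}

#' Simulate the full life cycle from an egg
#'
#' Solves the initial reserve, then simulates from `(E_0, V ~ 0, E_H = 0)`
#' at constant feeding level and temperature until a named maturity event
#' (default puberty), with spawning disabled.  Convenient for life-history
#' traits: pass the result to [detect_events()].
#'
#' @param params a [deb_params] object (asj mode).
#' @param f constant scaled functional response.
#' @param T_K temperature (Kelvin).
#' @param until stopping event (`"birth"`, `"release"`, `"settlement"`,
#'   `"metamorphosis"`, `"puberty"`).
#' @param horizon safety cap (days).
#' @return a `deb_trajectory`.
#' @export
grow_from_egg <- function(params, f = 1, T_K = params$T_ref,
                          until = "puberty", horizon = 20000) {
  ir <- initial_reserve(params, e_b = 1, T_K = T_K)
  init <- organism_state(E = ir$E_0, V = 1e-12, E_H = 0)
  fc <- constant_forcing(kelvin_to_celsius(T_K), f = f)
  opt <- deb_options(dt_out = 1, spawning = FALSE, stop_at = until)
  simulate_deb(params, fc, init, horizon = horizon, options = opt)
}

#' Weighted mean relative error (the estimation loss)
#'
#' The printed loss:
#' \deqn{MRE = \sqrt{ \frac{\sum_i \sum_j \beta_{ij} ((Y_{ij} -
#'   \hat Y_{ij})/Y_{ij})^2 }{ \sum_i \sum_j \beta_{ij} } }}
#' over all datasets `i` and points `j`.  Each zero-variate value counts as
#' one dataset.  A symmetric variant (weighted mean of
#' `2|Y - Yhat| / (|Y| + |Yhat|)`, no square root) is available for
#' cross-checking against Add-my-Pet style parameter sets.
#'
#' @param observations list of [zero_variate()] / [deb_dataset()] objects
#'   (or plain lists with `y` and `weights`).
#' @param predictions list of numeric prediction vectors matched 1:1.
#' @param symmetric use the symmetric variant instead of the printed
#'   formula.
#' @return non-negative scalar loss.
#' @export
#' @examples
#' o <- list(zero_variate("Li", 2))
#' loss_mre(o, list(1))  # sqrt(((2-1)/2)^2) = 0.5
loss_mre <- function(observations, predictions, symmetric = FALSE) {
  if (length(observations) != length(predictions)) {
    stop("observations and predictions must match 1:1")
  }
  num <- 0
  den <- 0
  for (i in seq_along(observations)) {
    ob <- observations[[i]]
    y <- ob$y
    w <- ob$weights
    yhat <- as.numeric(predictions[[i]])
    if (length(yhat) != length(y)) {
      stop("prediction length mismatch in dataset ", i)
    }
    if (any(y == 0)) stop("observed values must be non-zero")
    if (symmetric) {
      num <- num + sum(w * 2 * abs(y - yhat) / (abs(y) + abs(yhat)))
    } else {
      num <- num + sum(w * ((y - yhat) / y)^2)
    }
    den <- den + sum(w)
  }
  if (den <= 0) stop("total weight must be positive")
  if (symmetric) num / den else sqrt(num / den)
}

#' Per-dataset relative errors and the pooled loss
#'
#' @param observations,predictions as in [loss_mre()].
#' @return list with `per_dataset` (named numeric vector of single-dataset
#'   RE values) and `mre` (pooled loss over all datasets).
#' @export
mre_report <- function(observations, predictions) {
  per <- vapply(seq_along(observations), function(i) {
    loss_mre(observations[i], predictions[i])
  }, numeric(1))
  names(per) <- vapply(observations, function(o) o$name, character(1))
  list(per_dataset = per, mre = loss_mre(observations, predictions))
}

# parameter transforms: log10 for positive quantities, logit for fractions
.logit_params <- c("kap", "kap_X", "kap_R", "kap_P", "del_M", "del_Mb",
                   "dw_ww_ratio")
to_internal <- function(name, value) {
  if (name %in% .logit_params) log(value / (1 - value)) else log10(value)
}
from_internal <- function(name, value) {
  if (name %in% .logit_params) 1 / (1 + exp(-value)) else 10^value
}

#' Nelder-Mead simplex minimisation (internal engine)
#'
#' Standard reflection/expansion/contraction/shrink simplex with
#' coefficients (1, 2, 0.5, 0.5), convergence when the spread of function
#' values over the simplex drops below `tol`, plus optional restarts from
#' the best vertex with a fresh simplex.  Returns the accepted-step trace
#' (best value per iteration, non-increasing).
#'
#' @param fn objective function of a numeric vector.
#' @param x0 start point.
#' @param step initial simplex edge length (per coordinate).
#' @param tol convergence tolerance on the value spread.
#' @param max_iter iteration cap per (re)start.
#' @param restarts number of restarts from the best vertex.
#' @return list with `par`, `value`, `trace`, `iterations`, `converged`.
#' @keywords internal
nelder_mead <- function(fn, x0, step = 0.05, tol = 1e-6, max_iter = 2000,
                        restarts = 3) {
  n <- length(x0)
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  best_par <- x0
  best_val <- fn(x0)
  trace <- best_val
  total_iter <- 0L
  converged <- FALSE
  for (r in 0:restarts) {
    # fresh simplex around the incumbent best
    simplex <- matrix(rep(best_par, n + 1), nrow = n + 1, byrow = TRUE)
    for (i in seq_len(n)) {
      simplex[i + 1, i] <- simplex[i + 1, i] +
        step * if (r == 0) 1 else 0.5^r
    }
    vals <- apply(simplex, 1, fn)
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      ord <- order(vals)
      simplex <- simplex[ord, , drop = FALSE]
      vals <- vals[ord]
      if (vals[1] < best_val) {
        best_val <- vals[1]
        best_par <- simplex[1, ]
      }
      trace <- c(trace, best_val)
      if (is.finite(vals[n + 1]) && vals[n + 1] - vals[1] < tol) {
        converged <- TRUE
        break
      }
      centroid <- colMeans(simplex[1:n, , drop = FALSE])
      xr <- centroid + alpha * (centroid - simplex[n + 1, ])
      fr <- fn(xr)
      if (fr < vals[1]) {
        xe <- centroid + gamma * (xr - centroid)
        fe <- fn(xe)
        if (fe < fr) { simplex[n + 1, ] <- xe; vals[n + 1] <- fe }
        else { simplex[n + 1, ] <- xr; vals[n + 1] <- fr }
      } else if (fr < vals[n]) {
        simplex[n + 1, ] <- xr; vals[n + 1] <- fr
      } else {
        xc <- centroid + rho * (simplex[n + 1, ] - centroid)
        fc_ <- fn(xc)
        if (fc_ < vals[n + 1]) {
          simplex[n + 1, ] <- xc; vals[n + 1] <- fc_
        } else {
          for (i in 2:(n + 1)) {
            simplex[i, ] <- simplex[1, ] + sigma * (simplex[i, ] - simplex[1, ])
            vals[i] <- fn(simplex[i, ])
          }
        }
      }
    }
    total_iter <- total_iter + it
    if (converged && r >= 1) break
  }
  list(par = best_par, value = best_val, trace = trace,
       iterations = total_iter, converged = converged)
}

#' Estimate DEB parameters by covariation Nelder-Mead
#'
#' Minimises the printed mean-relative-error loss ([loss_mre()]) over a
#' chosen free-parameter subset, all other parameters held fixed.  Free
#' parameters are optimised in log10 space (fractions in logit space) so
#' positivity and range constraints hold by construction; candidate sets
#' that fail validation receive an infinite loss.  Deterministic given its
#' inputs.
#'
#' @param init_params starting [deb_params].
#' @param datasets list of [zero_variate()] / [deb_dataset()] objects.
#' @param free character vector of free parameter names (length >= 0).
#' @param max_iter,tol,restarts Nelder-Mead controls (see [nelder_mead()]).
#' @param step initial simplex edge in internal (log/logit) units; 0.05 in
#'   log10 is about a 12 percent parameter perturbation.
#' @param symmetric use the symmetric loss variant.
#' @param seed integer recorded with the fit; the procedure itself is fully
#'   deterministic (simplex moves and restarts involve no randomness), so
#'   the seed only guards any stochastic code inside user-supplied dataset
#'   contexts.
#' @return object of class `deb_fit`: list with `params` (best set),
#'   `mre`, `per_dataset` RE, `trace` (best loss per iteration,
#'   non-increasing), `converged`, `free`, `iterations`.
#' @export
estimate_deb <- function(init_params, datasets, free,
                         max_iter = 2000, tol = 1e-6, restarts = 3,
                         step = 0.05, symmetric = FALSE, seed = 1L) {
  set.seed(seed)
  stopifnot(inherits(init_params, "deb_params"))
  if (!length(datasets)) stop("no datasets supplied")
  unknown <- setdiff(free, names(init_params))
  if (length(unknown)) {
    stop("free parameter(s) not in the parameter set: ",
         paste(unknown, collapse = ", "))
  }
  predict_all <- function(p) lapply(datasets, function(d) predict_dataset(p, d))
  objective <- function(theta) {
    x <- as.list(init_params)
    for (i in seq_along(free)) x[[free[i]]] <- from_internal(free[i], theta[i])
    p <- tryCatch(deb_params(x, species = attr(init_params, "species")),
                  error = function(e) NULL)
    if (is.null(p)) return(Inf)
    preds <- tryCatch(predict_all(p), error = function(e) NULL)
    if (is.null(preds) || any(!is.finite(unlist(preds)))) return(Inf)
    loss_mre(datasets, preds, symmetric = symmetric)
  }
  if (!length(free)) {
    preds <- predict_all(init_params)
    rep0 <- mre_report(datasets, preds)
    return(structure(list(params = init_params, mre = rep0$mre,
                          per_dataset = rep0$per_dataset, trace = rep0$mre,
                          converged = TRUE, free = character(0),
                          iterations = 0L),
                     class = "deb_fit"))
  }
  theta0 <- vapply(seq_along(free),
                   function(i) to_internal(free[i], init_params[[free[i]]]),
                   numeric(1))
  v0 <- objective(theta0)
  if (!is.finite(v0)) {
    # identify the offending dataset for the error message
    x <- as.list(init_params)
    p <- deb_params(x, species = attr(init_params, "species"))
    for (d in datasets) {
      bad <- tryCatch(any(!is.finite(predict_dataset(p, d))),
                      error = function(e) TRUE)
      if (bad) stop("non-finite loss at the initial parameters (dataset '",
                    d$name, "')")
    }
    stop("non-finite loss at the initial parameters")
  }
  fit <- nelder_mead(objective, theta0, step = step, tol = tol,
                     max_iter = max_iter, restarts = restarts)
  x <- as.list(init_params)
  for (i in seq_along(free)) x[[free[i]]] <- from_internal(free[i], fit$par[i])
  best <- deb_params(x, species = attr(init_params, "species"))
  preds <- predict_all(best)
  repb <- mre_report(datasets, preds)
  structure(list(params = best, mre = repb$mre,
                 per_dataset = repb$per_dataset, trace = fit$trace,
                 converged = fit$converged, free = free,
                 iterations = fit$iterations, seed = seed),
            class = "deb_fit")
}

#' @export
print.deb_fit <- function(x, ...) {
  cat("DEB fit: MRE =", signif(x$mre, 5),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  if (length(x$free)) {
    est <- vapply(x$free, function(k) x$params[[k]], numeric(1))
    print(data.frame(estimate = signif(est, 6), row.names = x$free))
  }
  invisible(x)
}

#' Calibrate the half-saturation constant
#'
#' One-dimensional minimisation of the MRE loss over `K_X > 0` with all
#' other parameters fixed; every dataset must carry chlorophyll-mode food
#' (a `chl` context or a chlorophyll forcing), since `K_X` is the link
#' between chlorophyll and the scaled functional response.
#'
#' @param params fixed [deb_params].
#' @param datasets list of datasets with chlorophyll food context.
#' @param interval search interval for `K_X` (micrograms chl per litre).
#' @return list with `K_X`, `mre`, and the implied `f` at the dataset
#'   chlorophyll levels.
#' @export
calibrate_KX <- function(params, datasets, interval = c(0.05, 100)) {
  uses_chl <- vapply(datasets, function(d) {
    !is.null(d$context$chl) ||
      (!is.null(d$context$forcing) && d$context$forcing$mode == "chl")
  }, logical(1))
  if (!all(uses_chl)) {
    stop("all datasets must use chlorophyll-mode food to calibrate K_X")
  }
  obj <- function(logK) {
    x <- as.list(params)
    x$K_X <- exp(logK)
    p <- deb_params(x, species = attr(params, "species"))
    preds <- tryCatch(lapply(datasets, function(d) predict_dataset(p, d)),
                      error = function(e) NULL)
    if (is.null(preds)) return(Inf)
    loss_mre(datasets, preds)
  }
  opt <- stats::optimize(obj, interval = log(interval), tol = 1e-8)
  vals <- exp(opt$minimum)
  if (min(abs(log(vals / interval))) < 1e-3) {
    warning("K_X calibration hit the search boundary (food-insensitive loss?)")
  }
  chl_levels <- sort(unique(unlist(lapply(datasets, function(d) {
    if (!is.null(d$context$chl)) d$context$chl else d$context$forcing$food
  }))))
  list(K_X = vals, mre = opt$objective,
       f_implied = stats::setNames(functional_response(chl_levels, vals),
                                   paste0("chl_", chl_levels)))
}
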