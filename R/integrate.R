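# Adaptive embedded Runge-Kutta (Cash-Karp 4/5) integrator with cubic
# Hermite dense output and sign-change event localisation.  Written here
# because no ODE solver package is available in the target environment; the
# DEB right-hand side is smooth within a life phase, so an explicit 5th
# order pair with PI step control is appropriate.

.ck_a <- list(
  c(1 / 5),
  c(3 / 40, 9 / 40),
  c(3 / 10, -9 / 10, 6 / 5),
  c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
  c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
)
.ck_c <- c(0, 1 / 5, 3 / 10, 3 / 5, 1, 7 / 8)
.ck_b5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
.ck_b4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

# cubic Hermite interpolation within a step
hermite_interp <- function(theta, h, y0, y1, f0, f1) {
  t2 <- theta * theta
  t3 <- t2 * theta
  h00 <- 2 * t3 - 3 * t2 + 1
  h10 <- t3 - 2 * t2 + theta
  h01 <- -2 * t3 + 3 * t2
  h11 <- t3 - t2
  h00 * y0 + h10 * h * f0 + h01 * y1 + h11 * h * f1
}

#' Adaptive Runge-Kutta integration (internal engine)
#'
#' Integrates `dy/dt = rhs(t, y)` from `t0` to `t1` with the Cash-Karp
#' embedded 4(5) pair, proportional step control, dense output on `t_eval`
#' and localisation of the first root of any event function.  Event
#' functions `g(t, y)` trigger when their sign changes across an accepted
#' step; the root is located on the Hermite interpolant to `root_tol` days.
#'
#' This is an internal workhorse; model-facing entry points are
#' [simulate_deb()] and the lifecycle solvers.
#'
#' @param rhs function `(t, y) -> dy` (numeric vector).
#' @param y0 initial state.
#' @param t0,t1 integration window (days), `t1 > t0`.
#' @param rtol,atol relative tolerance (scalar) and absolute tolerance
#'   (scalar or vector) of the error norm.
#' @param err_weights 0/1 weights selecting which components enter the error
#'   norm (diagnostic integrals are excluded by the callers).
#' @param max_step largest allowed step (days).
#' @param t_eval times at which the dense solution is recorded (in addition
#'   to `t0` and the stop time).
#' @param events named list of event functions `g(t, y)`.
#' @param root_tol absolute tolerance (days) of event-time localisation.
#' @param max_steps safety cap on accepted+rejected steps.
#' @return list with `t`, `y` (matrix, rows = times), `event` (name or
#'   `NA`), `t_event`, `y_end`, `t_end`, `nfev`.
#' @keywords internal
rk45 <- function(rhs, y0, t0, t1, rtol = 1e-8, atol = 1e-10,
                 err_weights = NULL, max_step = Inf, t_eval = NULL,
                 events = NULL, root_tol = 1e-6, max_steps = 100000L) {
  stopifnot(t1 > t0)
  n <- length(y0)
  if (length(atol) == 1L) atol <- rep(atol, n)
  if (is.null(err_weights)) err_weights <- rep(1, n)
  wsel <- err_weights > 0
  if (!any(wsel)) stop("err_weights must select at least one component")

  t <- t0
  y <- as.numeric(y0)
  f0 <- rhs(t, y)
  nfev <- 1L

  # initial step heuristic
  sc <- atol + rtol * abs(y)
  d0 <- sqrt(mean((y[wsel] / sc[wsel])^2))
  d1 <- sqrt(mean((f0[wsel] / sc[wsel])^2))
  h <- if (d1 > 1e-10) 0.01 * d0 / d1 else 1e-6
  h <- min(max(h, 1e-10), max_step, t1 - t0)

  ev_names <- names(events)
  g_prev <- if (length(events)) {
    vapply(events, function(g) g(t, y), numeric(1))
  } else numeric(0)

  ts <- t
  ys <- matrix(y, nrow = 1)
  t_eval <- if (is.null(t_eval)) numeric(0) else sort(t_eval[t_eval > t0 & t_eval <= t1])
  ev_hit <- NA_character_
  t_hit <- NA_real_

  k <- matrix(0, nrow = n, ncol = 6)
  steps <- 0L
  while (t < t1 - 1e-12) {
    steps <- steps + 1L
    if (steps > max_steps) {
      stop("rk45: step limit exceeded at t = ", signif(t, 8))
    }
    h <- min(h, t1 - t, max_step)
    k[, 1] <- f0
    for (i in 1:5) {
      yi <- y + h * as.numeric(k[, 1:i, drop = FALSE] %*% .ck_a[[i]])
      k[, i + 1] <- rhs(t + .ck_c[i + 1] * h, yi)
    }
    nfev <- nfev + 5L
    y5 <- y + h * as.numeric(k %*% .ck_b5)
    y4 <- y + h * as.numeric(k %*% .ck_b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5[wsel] - y4[wsel]) / sc[wsel])^2))

    if (!is.finite(err)) {
      h <- h / 10
      if (h < 1e-14) stop("rk45: step size underflow (non-finite error)")
      next
    }
    if (err > 1) {                       # reject
      h <- h * max(0.2, 0.9 * err^(-0.25))
      if (h < 1e-14) stop("rk45: step size underflow at t = ", signif(t, 8))
      next
    }

    # accepted
    f1 <- rhs(t + h, y5)
    nfev <- nfev + 1L
    t_new <- t + h
    y_new <- y5

    # event check on this step
    theta_stop <- NA_real_
    if (length(events)) {
      g_new <- vapply(events, function(g) g(t_new, y_new), numeric(1))
      crossed <- which(g_prev * g_new < 0 | (g_prev != 0 & g_new == 0))
      if (length(crossed)) {
        # locate earliest root by bisection on the Hermite interpolant
        best_theta <- Inf
        best_ev <- NA_integer_
        for (j in crossed) {
          lo <- 0; hi <- 1
          glo <- g_prev[j]
          while ((hi - lo) * h > root_tol) {
            mid <- (lo + hi) / 2
            ym <- hermite_interp(mid, h, y, y_new, f0, f1)
            gm <- events[[j]](t + mid * h, ym)
            if (glo * gm <= 0) hi <- mid else { lo <- mid; glo <- gm }
          }
          th <- (lo + hi) / 2
          if (th < best_theta) { best_theta <- th; best_ev <- j }
        }
        theta_stop <- best_theta
        ev_hit <- if (!is.null(ev_names)) ev_names[best_ev] else as.character(best_ev)
      }
      g_prev <- g_new
    }

    if (!is.na(theta_stop)) {
      t_stop <- t + theta_stop * h
      y_stop <- hermite_interp(theta_stop, h, y, y_new, f0, f1)
      while (length(t_eval) && t_eval[1] <= t_stop + 1e-12) {
        th <- (t_eval[1] - t) / h
        ys <- rbind(ys, hermite_interp(th, h, y, y_new, f0, f1))
        ts <- c(ts, t_eval[1])
        t_eval <- t_eval[-1]
      }
      if (!length(ts) || abs(ts[length(ts)] - t_stop) > 1e-12) {
        ts <- c(ts, t_stop)
        ys <- rbind(ys, y_stop)
      }
      t_hit <- t_stop
      return(list(t = ts, y = ys, event = ev_hit, t_event = t_hit,
                  t_end = t_stop, y_end = y_stop, nfev = nfev))
    }

    while (length(t_eval) && t_eval[1] <= t_new + 1e-12) {
      th <- (t_eval[1] - t) / h
      ys <- rbind(ys, hermite_interp(th, h, y, y_new, f0, f1))
      ts <- c(ts, t_eval[1])
      t_eval <- t_eval[-1]
    }

    t <- t_new
    y <- y_new
    f0 <- f1
    h <- h * min(5, max(0.2, 0.9 * err^(-0.2)))
  }

  if (!length(ts) || abs(ts[length(ts)] - t) > 1e-12) {
    ts <- c(ts, t)
    ys <- rbind(ys, y)
  }
  list(t = ts, y = ys, event = NA_character_, t_event = NA_real_,
       t_end = t, y_end = y, nfev = nfev)
}

# fixed-step forward Euler; the brute-force oracle used in tests
euler <- function(rhs, y0, t0, t1, dt) {
  nstep <- ceiling((t1 - t0) / dt - 1e-12)
  y <- as.numeric(y0)
  t <- t0
  for (i in seq_len(nstep)) {
    h <- min(dt, t1 - t)
    y <- y + h * rhs(t, y)
    t <- t + h
  }
  names(y) <- names(y0)
  y
}
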