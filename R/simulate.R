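# Numerical integration of the network ODEs and steady-state computation.

.new_timecourse <- function(times, states, network) {
  colnames(states) <- network$forms
  structure(list(times = times, states = states, variant = network$variant),
            class = "phos_timecourse")
}

#' @export
print.phos_timecourse <- function(x, ...) {
  cat("phos_timecourse (variant ", x$variant, "): ", length(x$times),
      " samples over ", max(x$times), " s, ", ncol(x$states), " forms\n",
      sep = "")
  invisible(x)
}

#' Fixed-step fourth-order Runge-Kutta integration
#'
#' Classical RK4 with a default step of 1 s.  If any state drifts below
#' `-1e-9 * total` or becomes non-finite, the integration restarts with the
#' step reduced to 0.1 s and then 0.01 s; failure at the smallest step is an
#' error recommending the adaptive integrator.
#'
#' @param params `phos_params`.
#' @param enzymes `phos_enzymes`.
#' @param y0 initial concentrations in canonical form order, mol/L.
#' @param duration_s integration span, s.
#' @param dt step size, s (default 1).
#' @param record_every output sampling interval, s (default 60; clipped to
#'   `dt` if smaller).
#' @param rate_mode `"mm"` or `"tqssa"`.
#' @return `phos_timecourse` object.
#' @export
integrate_rk4 <- function(params, enzymes, y0, duration_s, dt = 1,
                          record_every = 60, rate_mode = "mm") {
  stopifnot(dt > 0, duration_s >= dt)
  eng <- phos_engine(params, enzymes, rate_mode)
  if (length(y0) != eng$n) stop("y0 has wrong length for variant ",
                                params$variant, call. = FALSE)
  total <- sum(y0)
  for (step in c(dt, 0.1, 0.01)) {
    if (step > dt) next
    out <- .rk4_run(eng$rhs, y0, duration_s, step,
                    max(step, record_every), -1e-9 * total)
    if (!is.null(out)) {
      return(.new_timecourse(out$times, out$states, eng$network))
    }
  }
  stop("RK4 failed at dt = 0.01 s; use integrate_adaptive()",
       call. = FALSE)
}

.rk4_run <- function(rhs, y0, duration, dt, record_every, floor_ok) {
  n_steps <- ceiling(duration / dt)
  rec_stride <- max(1L, round(record_every / dt))
  keep <- seq(0L, n_steps, by = rec_stride)
  if (keep[length(keep)] != n_steps) keep <- c(keep, n_steps)
  states <- matrix(NA_real_, length(keep), length(y0))
  times <- keep * dt
  states[1, ] <- y0
  y <- y0
  k_rec <- 2L
  for (i in seq_len(n_steps)) {
    k1 <- rhs(0, y)
    k2 <- rhs(0, y + dt / 2 * k1)
    k3 <- rhs(0, y + dt / 2 * k2)
    k4 <- rhs(0, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)) || any(y < floor_ok)) return(NULL)
    if (k_rec <= length(keep) && i == keep[k_rec]) {
      states[k_rec, ] <- y
      k_rec <- k_rec + 1L
    }
  }
  list(times = times, states = states)
}

#' Adaptive integration (LSODA)
#'
#' Stiff/non-stiff switching integration via [deSolve::lsoda()].
#'
#' @inheritParams integrate_rk4
#' @param times output times, s; defaults to every 60 s.
#' @param rtol,atol relative and absolute tolerances (absolute tolerance
#'   defaults to `1e-12 * sum(y0)`).
#' @return `phos_timecourse` object.
#' @export
integrate_adaptive <- function(params, enzymes, y0, duration_s,
                               times = NULL, rtol = 1e-8, atol = NULL,
                               rate_mode = "mm") {
  stopifnot(rtol > 0)
  eng <- phos_engine(params, enzymes, rate_mode)
  if (length(y0) != eng$n) stop("y0 has wrong length for variant ",
                                params$variant, call. = FALSE)
  if (is.null(atol)) atol <- 1e-12 * max(sum(y0), .Machine$double.eps)
  if (is.null(times)) times <- unique(c(seq(0, duration_s, by = 60),
                                        duration_s))
  sol <- deSolve::lsoda(y = unname(y0), times = times, func = eng$desolve,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("LSODA integration failed (istate ", attr(sol, "istate")[1], ")",
         call. = FALSE)
  }
  .new_timecourse(sol[, 1], unname(sol[, -1, drop = FALSE]), eng$network)
}

#' Steady state of the network
#'
#' Integrates until the residual `max|dy/dt| / total` drops below `tol`
#' (default 1e-9 per second) or the horizon is reached; if not converged,
#' the window is doubled repeatedly up to 64x the horizon.  The claim is
#' operational (residual-based), not a uniqueness proof.
#'
#' @inheritParams integrate_rk4
#' @param horizon_s first integration window, s (default 3600).
#' @param tol residual tolerance in 1/s units of the total (default 1e-9).
#' @return list with `state` (named concentrations), `converged` flag,
#'   `residual` and `t_end`.
#' @export
steady_state <- function(params, enzymes, y0, horizon_s = 3600,
                         tol = 1e-9, rate_mode = "mm") {
  eng <- phos_engine(params, enzymes, rate_mode)
  if (length(y0) != eng$n) stop("y0 has wrong length for variant ",
                                params$variant, call. = FALSE)
  total <- sum(y0)
  atol <- 1e-12 * max(total, .Machine$double.eps)
  y <- unname(y0)
  t_end <- 0
  # staged windows: residual is checked at horizon/4 increments first, so
  # fast-converging systems stop early; afterwards windows double up to the
  # 64x-horizon cap
  windows <- c(rep(horizon_s / 4, 4), horizon_s * 2^(0:5))
  for (window in windows) {
    sol <- deSolve::lsoda(y = y, times = c(0, window), func = eng$desolve,
                          parms = NULL, rtol = 1e-9, atol = atol)
    y <- pmax(as.numeric(sol[nrow(sol), -1]), 0)
    t_end <- t_end + window
    resid <- max(abs(eng$rhs(0, y))) / total
    if (resid < tol) break
  }
  names(y) <- eng$network$forms
  list(state = y, converged = resid < tol, residual = resid, t_end = t_end)
}
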