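# Mass-transport-limited SPR sensorgram model and fitting.
# Two-step reaction scheme: bulk ligand <-> surface ligand (rate k_t both
# ways) followed by 1:1 binding with effective constants k_on / k_off.
# On the response scale (conversion [PL] = alpha * r, [P]_tot = alpha *
# r_max) the coupled ODEs are
#   dr/dt      = k_on * L_surf * (r_max - r) - k_off * r
#   dL_surf/dt = k_t * (L_bulk - L_surf) - alpha * dr/dt
# Fit results for the rate constants are insensitive to alpha because the
# quasi-steady approximation dL_surf/dt ~ 0 holds for flow cells.

#' Construct a sensorgram
#'
#' A timed response-unit trace with its phase schedule and the bulk ligand
#' concentration applied during the association phase.
#'
#' @param time times (s), strictly increasing.
#' @param response responses (RU), finite.
#' @param L_bulk bulk ligand concentration during association (M).
#' @param schedule named list `baseline_end`, `association_end`,
#'   `dissociation_end` (s), ordered.
#' @return object of class `sensorgram` (a data.frame with attributes).
#' @export
sensorgram <- function(time, response, L_bulk, schedule) {
  stopifnot(length(time) == length(response))
  if (any(diff(time) <= 0)) stop("times must be strictly increasing",
                                 call. = FALSE)
  if (!all(is.finite(response))) stop("responses must be finite",
                                      call. = FALSE)
  need <- c("baseline_end", "association_end", "dissociation_end")
  if (!all(need %in% names(schedule))) {
    stop("schedule needs baseline_end, association_end, dissociation_end",
         call. = FALSE)
  }
  s <- unlist(schedule[need])
  if (any(diff(s) <= 0)) stop("schedule must be ordered", call. = FALSE)
  structure(data.frame(time = time, response = response),
            L_bulk = L_bulk, schedule = as.list(s),
            class = c("sensorgram", "data.frame"))
}

sg_schedule <- function(sg) attr(sg, "schedule")
sg_L_bulk <- function(sg) attr(sg, "L_bulk")

phase_idx <- function(sg, phase = c("baseline", "association",
                                    "dissociation")) {
  phase <- match.arg(phase)
  s <- sg_schedule(sg)
  t <- sg$time
  switch(phase,
         baseline = which(t <= s$baseline_end),
         association = which(t > s$baseline_end & t <= s$association_end),
         dissociation = which(t > s$association_end &
                                t <= s$dissociation_end))
}

#' Right-hand side of the transport-limited binding ODE
#'
#' @param t time (s); unused (autonomous), present for deSolve.
#' @param state numeric `c(L_surf, r)`: free ligand concentration at the
#'   surface (M) and bound response (RU).
#' @param params list/vector with `k_t` (s^-1), `k_on` (M^-1 s^-1),
#'   `k_off` (s^-1), `r_max` (RU), `alpha` (M/RU), `L_bulk` (M).
#' @return list of the two derivatives, deSolve convention.
#' @export
spr_ode_rhs <- function(t, state, params) {
  L_surf <- state[[1]]
  r <- state[[2]]
  p <- as.list(params)
  dr <- p$k_on * L_surf * (p$r_max - r) - p$k_off * r
  dL <- p$k_t * (p$L_bulk - L_surf) - p$alpha * dr
  list(c(dL, dr))
}

# Numeric solution of the binding response over `times` (times relative to
# phase start). init = c(L_surf, r).
solve_spr <- function(times, init, k_t, k_on, k_off, r_max, alpha, L_bulk) {
  params <- list(k_t = k_t, k_on = k_on, k_off = k_off, r_max = r_max,
                 alpha = alpha, L_bulk = L_bulk)
  tt <- times
  prepend <- FALSE
  if (tt[1] > 0) { tt <- c(0, tt); prepend <- TRUE }
  # pathological optimizer iterates can defeat the solver; NA responses
  # are penalized by the residual functions
  sol <- suppressWarnings(
    deSolve::lsoda(y = init, times = tt, func = spr_ode_rhs,
                   parms = params, rtol = 1e-8, atol = 1e-10))
  r <- rep(NA_real_, length(tt))
  r[seq_len(nrow(sol))] <- sol[, 3]
  if (prepend) r <- r[-1]
  r
}

penalize <- function(res) {
  res[!is.finite(res)] <- 1e3
  res
}

#' Exponential drift correction
#'
#' Fits `a * exp(-b t) + c` jointly over the pre-injection baseline window
#' and the tail of the dissociation phase, then subtracts the fitted drift
#' from the whole trace. Falls back to a linear drift model if the
#' exponential fit does not converge (with a warning).
#'
#' @param sg a [sensorgram()].
#' @param window_pre length (s) of the baseline window before injection,
#'   default 60.
#' @param window_tail length (s) of the dissociation tail window, default
#'   100.
#' @return drift-corrected sensorgram; the fitted drift model is attached
#'   as attribute `drift_fit`.
#' @export
correct_drift <- function(sg, window_pre = 60, window_tail = 100) {
  s <- sg_schedule(sg)
  pre <- sg$time >= (s$baseline_end - window_pre) & sg$time <= s$baseline_end
  tail_w <- sg$time >= (s$dissociation_end - window_tail) &
    sg$time <= s$dissociation_end
  if (sum(pre) < 5 || sum(tail_w) < 5) {
    stop("drift windows must each contain at least 5 points",
         call. = FALSE)
  }
  idx <- pre | tail_w
  df <- data.frame(t = sg$time[idx], y = sg$response[idx])
  fit <- tryCatch({
    b0 <- 1 / max(df$t)
    a0 <- df$y[1] - df$y[nrow(df)]
    minpack.lm::nlsLM(y ~ a * exp(-b * t) + c0, data = df,
                      start = list(a = a0, b = b0, c0 = mean(df$y)),
                      lower = c(-Inf, 0, -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential drift fit did not converge; using linear fallback")
    lfit <- stats::lm(y ~ t, data = df)
    drift <- stats::predict(lfit, newdata = data.frame(t = sg$time))
    model <- list(form = "linear", coef = stats::coef(lfit))
  } else {
    cf <- stats::coef(fit)
    drift <- cf[["a"]] * exp(-cf[["b"]] * sg$time) + cf[["c0"]]
    model <- list(form = "exponential", coef = cf)
  }
  out <- sensorgram(sg$time, sg$response - drift, sg_L_bulk(sg),
                    sg_schedule(sg))
  attr(out, "truth") <- attr(sg, "truth")
  attr(out, "drift_fit") <- model
  out
}

# Least-squares fit of the association-phase ODE solution with k_on fixed
# and k_off substituted by K_d * k_on; free parameters k_t, r_max (log
# scale) and optionally a vertical offset.
#' Fit the association phase at fixed k_on
#'
#' Initial conditions `L_surf = 0`, `r = 0` at injection start; fit
#' parameters `k_t` and `r_max` (and optionally a vertical offset), with
#' `k_off = K_d * k_on_fixed`.
#'
#' @param sg drift-corrected [sensorgram()].
#' @param K_d dissociation constant used to tie `k_off` to `k_on` (M).
#' @param k_on_fixed fixed effective on-rate constant (M^-1 s^-1).
#' @param alpha RU-to-concentration conversion (M/RU), default 1e-6
#'   (1 uM/RU); rate results are insensitive to it.
#' @param fit_offset also fit a vertical offset (used for the preliminary
#'   unconstrained-k_on offset determination).
#' @param start optional named list overriding `k_t`/`r_max` starts.
#' @return list with `k_t`, `r_max`, `offset`, `ssr`, `n`, `converged`.
#' @export
fit_association <- function(sg, K_d, k_on_fixed, alpha = 1e-6,
                            fit_offset = FALSE, start = NULL) {
  stopifnot(k_on_fixed > 0, K_d > 0)
  s <- sg_schedule(sg)
  i <- phase_idx(sg, "association")
  if (length(i) < 5) stop("association window has too few points",
                          call. = FALSE)
  tt <- sg$time[i] - s$baseline_end
  y <- sg$response[i]
  L <- sg_L_bulk(sg)
  k_off <- K_d * k_on_fixed
  r_max0 <- max(max(y) * (1 + K_d / L), 0.1 * max(abs(y), 0.1))
  # initial-slope transport guess: dr/dt|0 ~ k_t L / alpha when transport
  # limited; clip into a sane range
  sl <- max((y[min(5, length(y))] - y[1]) / (tt[min(5, length(y))] - tt[1]),
            1e-6)
  k_t0 <- min(max(sl * alpha / max(L, 1e-12) *
                    (1 + alpha * k_on_fixed * r_max0 / 10), 1e-3), 1e4)
  starts <- list(c(k_t = k_t0, r_max = r_max0),
                 c(k_t = 10, r_max = r_max0),
                 c(k_t = 100, r_max = r_max0))
  if (!is.null(start)) starts <- c(list(unlist(start)), starts)
  resid_fn <- function(par) {
    k_t <- exp(par[[1]]); r_max <- exp(par[[2]])
    off <- if (fit_offset) par[[3]] else 0
    r <- solve_spr(tt, c(0, 0), k_t, k_on_fixed, k_off, r_max, alpha, L)
    penalize(y - (r + off))
  }
  best <- NULL
  lower <- c(log(1e-4), log(1e-4))
  upper <- c(log(1e6), log(1e4))
  if (fit_offset) { lower <- c(lower, -Inf); upper <- c(upper, Inf) }
  for (st in starts) {
    par0 <- c(log(st[["k_t"]]), log(st[["r_max"]]))
    if (fit_offset) par0 <- c(par0, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = fit$par, ssr = ssr, info = fit$info)
    }
  }
  if (is.null(best)) stop("association fit failed for all starts",
                          call. = FALSE)
  list(k_t = exp(best$par[[1]]), r_max = exp(best$par[[2]]),
       offset = if (fit_offset) best$par[[3]] else 0,
       ssr = best$ssr, n = length(i), converged = best$info %in% 1:4,
       k_on = k_on_fixed, k_off = k_off)
}

#' Fit the early dissociation phase at fixed k_on
#'
#' Fits the first `window` seconds of the dissociation phase with the single
#' parameter `k_t`, using initial conditions `L_surf = L_bulk` and
#' `r = r_max / (1 + K_d / L_bulk)` with `r_max` taken from the association
#' fit.
#'
#' @inheritParams fit_association
#' @param assoc_fit result of [fit_association()] (supplies `r_max`).
#' @param window length (s) of the fitted dissociation window, default 50.
#' @return list with `k_t`, `ssr`, `n`, `converged`.
#' @export
fit_dissociation <- function(sg, assoc_fit, K_d, k_on_fixed = assoc_fit$k_on,
                             window = 50, alpha = 1e-6) {
  s <- sg_schedule(sg)
  i <- phase_idx(sg, "dissociation")
  i <- i[sg$time[i] <= s$association_end + window]
  if (length(i) < 5) stop("dissociation window has too few points",
                          call. = FALSE)
  tt <- sg$time[i] - s$association_end
  y <- sg$response[i]
  L <- sg_L_bulk(sg)
  k_off <- K_d * k_on_fixed
  r0 <- assoc_fit$r_max / (1 + K_d / L)
  resid_fn <- function(par) {
    r <- solve_spr(tt, c(L, r0), exp(par[[1]]), k_on_fixed, k_off,
                   assoc_fit$r_max, alpha, 0)
    penalize(y - r)
  }
  fit <- minpack.lm::nls.lm(par = log(max(assoc_fit$k_t, 1e-3)),
                            fn = resid_fn,
                            lower = log(1e-4), upper = log(1e6),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10))
  list(k_t = exp(fit$par[[1]]), ssr = sum(fit$fvec^2), n = length(i),
       converged = fit$info %in% 1:4)
}

#' Rescaled SSR profile over a k_on grid
#'
#' For each grid value of the effective on-rate constant, fits the
#' association phase (parameters `k_t`, `r_max`) and the early dissociation
#' phase (parameter `k_t`) with `k_off = K_d k_on`, records the total sum of
#' squared residuals and rescales the profile by its minimum so the plateau
#' sits at 1. Transport dominance makes the profile flat above a knee and
#' rising below it; the knee is the identifiability limit for `k_on`.
#'
#' @inheritParams fit_association
#' @param k_on_grid log-spaced grid of on-rate constants (M^-1 s^-1),
#'   default 30 points over 1e5..1e10.
#' @param diss_window dissociation window (s) passed to
#'   [fit_dissociation()].
#' @return data.frame of class `ssr_profile` with columns `k_on`, `ssr`,
#'   `ssr_rescaled`, `ok`; attribute `L_bulk`.
#' @export
ssr_profile <- function(sg, K_d, k_on_grid = 10^seq(5, 10, length.out = 30),
                        alpha = 1e-6, diss_window = 50) {
  k_on_grid <- sort(k_on_grid)
  ssr <- rep(NA_real_, length(k_on_grid))
  ok <- rep(FALSE, length(k_on_grid))
  prev <- NULL
  for (j in seq_along(k_on_grid)) {
    res <- tryCatch({
      af <- fit_association(sg, K_d, k_on_grid[j], alpha = alpha,
                            start = prev)
      df <- fit_dissociation(sg, af, K_d, k_on_grid[j],
                             window = diss_window, alpha = alpha)
      prev <<- list(k_t = af$k_t, r_max = af$r_max)
      af$ssr + df$ssr
    }, error = function(e) NA_real_)
    ssr[j] <- res
    ok[j] <- is.finite(res)
  }
  m <- min(ssr[ok])
  out <- data.frame(k_on = k_on_grid, ssr = ssr, ssr_rescaled = ssr / m,
                    ok = ok)
  attr(out, "L_bulk") <- sg_L_bulk(sg)
  class(out) <- c("ssr_profile", "data.frame")
  out
}

#' Lower bound on k_on from a rescaled SSR profile
#'
#' Reads the plateau-versus-rise structure of a rescaled SSR profile: the
#' bound is the smallest grid `k_on` whose rescaled SSR is at most
#' `threshold_factor`. A globally flat profile yields an `unbounded_below`
#' flag (no information); a profile minimized at an interior grid point
#' yields an `identifiable` flag (the sensorgram determines `k_on`, no
#' bound is reported).
#'
#' @param profile an [ssr_profile()].
#' @param threshold_factor plateau acceptance factor, default 1.05.
#' @return list with `k_on_lower_bound` (NA when flagged), `flag` one of
#'   `"bound"`, `"unbounded_below"`, `"identifiable"`, and
#'   `monotone_violations` (count of rescaled-SSR increases towards higher
#'   `k_on` below the bound).
#' @export
k_on_lower_bound <- function(profile, threshold_factor = 1.05) {
  p <- profile[profile$ok, ]
  if (nrow(p) < 1) stop("no usable profile points", call. = FALSE)
  r <- p$ssr_rescaled
  if (max(r) <= threshold_factor) {
    return(list(k_on_lower_bound = p$k_on[1], flag = "unbounded_below",
                monotone_violations = 0L))
  }
  imin <- which.min(r)
  # interior minimum: SSR rises towards the upper grid end as well
  if (imin < nrow(p) && r[nrow(p)] > threshold_factor) {
    return(list(k_on_lower_bound = NA_real_, flag = "identifiable",
                k_on_optimum = p$k_on[imin], monotone_violations = 0L))
  }
  below <- which(r <= threshold_factor)
  i0 <- min(below)
  viol <- sum(diff(r[seq_len(i0)]) > 0)
  list(k_on_lower_bound = p$k_on[i0], flag = "bound",
       monotone_violations = as.integer(viol))
}

#' Sensorgram quality screen
#'
#' Quantitative surrogates for the usual discard criteria applied before
#' kinetic fitting: the association phase must reach binding equilibrium,
#' the initial rise must be sampled by enough points, and the trace must
#' not drift markedly at equilibrium. Cycles failing the rise criterion
#' (large ligand concentration) are still usable for equilibrium-affinity
#' analysis.
#'
#' @param sg a (drift-corrected) [sensorgram()].
#' @param eq_tol relative settling tolerance at the association end,
#'   default 0.05.
#' @param min_rise_points minimum association points below `1 - exp(-1)`
#'   of the plateau, default 5.
#' @param drift_slope_max maximum absolute residual slope (RU/s) over the
#'   dissociation tail, default 0.01.
#' @return list with logicals `equilibrated`, `rise_resolved`,
#'   `drift_ok`, `pass` (all three) and the measured `plateau` (RU).
#' @export
sensorgram_quality <- function(sg, eq_tol = 0.05, min_rise_points = 5,
                               drift_slope_max = 0.01) {
  s <- sg_schedule(sg)
  ia <- phase_idx(sg, "association")
  ta <- sg$time[ia]
  last5 <- ia[ta > s$association_end - 5]
  prev5 <- ia[ta > s$association_end - 10 & ta <= s$association_end - 5]
  plateau <- mean(sg$response[last5])
  equilibrated <- abs(plateau - mean(sg$response[prev5])) <=
    eq_tol * max(abs(plateau), 1e-6)
  rise_resolved <- sum(sg$response[ia] < (1 - exp(-1)) * plateau) >=
    min_rise_points
  itail <- phase_idx(sg, "dissociation")
  itail <- itail[sg$time[itail] > s$dissociation_end - 50]
  slope <- stats::coef(stats::lm(sg$response[itail] ~
                                   sg$time[itail]))[[2]]
  drift_ok <- abs(slope) <= drift_slope_max
  list(equilibrated = equilibrated, rise_resolved = rise_resolved,
       drift_ok = drift_ok,
       pass = equilibrated && rise_resolved && drift_ok,
       plateau = plateau)
}

#' Equilibrium K_d from maximal responses
#'
#' Nonlinear least-squares fit of maximal sensorgram responses versus bulk
#' ligand concentration with `f = c / (1 + K_d / [L])`.
#'
#' @param concentrations ligand concentrations (M), at least 3 distinct.
#' @param responses maximal responses (RU).
#' @return list with `K_d`, `c`, their standard errors, and the `nls` fit.
#' @export
fit_equilibrium_Kd <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(unique(concentrations)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  df <- data.frame(L = concentrations, y = responses)
  Kd0 <- stats::median(df$L)
  fit <- minpack.lm::nlsLM(y ~ cmax / (1 + Kd / L), data = df,
                           start = list(cmax = max(df$y), Kd = Kd0),
                           lower = c(0, 0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf <- summary(fit)$coefficients
  span <- range(df$L)
  if (cf["Kd", "Estimate"] < span[1] / 20 ||
      cf["Kd", "Estimate"] > span[2] * 20) {
    warning("concentration ladder poorly spans the fitted K_d; ",
            "estimate may be ill-conditioned")
  }
  list(K_d = cf["Kd", "Estimate"], K_d_se = cf["Kd", "Std. Error"],
       c = cf["cmax", "Estimate"], c_se = cf["cmax", "Std. Error"],
       fit = fit)
}
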