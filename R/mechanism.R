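# Bound propagation: convert experimental constraints (affinity range,
# on-rate bounds, population and exchange-rate ceilings) into rate bounds
# for the CS and IF pathways and a compatibility verdict. Thresholds are
# pure inequalities; uncertainty enters only through the input bounds.
# Every derived number carries a replayable trail entry
# (name, formula, inputs, value).

#' Experimental constraint set for mechanism discrimination
#'
#' @param K_d_range dissociation-constant range `c(lower, upper)` (M).
#' @param k_on_range effective on-rate bounds `c(lower, upper)`
#'   (M^-1 s^-1).
#' @param L_max highest tested ligand concentration (M).
#' @param closed_population_ceiling upper bound on the closed-state
#'   population `k_e / (k_e + k_r)` of the ligand-free protein (fraction),
#'   default 0.10 (single-molecule FRET screen).
#' @param exchange_rate_ceiling upper bound (s^-1) on conformational
#'   exchange rates detectable by the FRET screens, default 100 (no
#'   exchange seen between 100 ns and 10 ms).
#' @param fast_exchange_floor timescale (s) below which exchange escapes
#'   all screens, default 100e-9.
#' @return list of class `mechanism_constraints`.
#' @export
mechanism_constraints <- function(K_d_range, k_on_range, L_max,
                                  closed_population_ceiling = 0.10,
                                  exchange_rate_ceiling = 100,
                                  fast_exchange_floor = 100e-9) {
  stopifnot(length(K_d_range) == 2, length(k_on_range) == 2)
  if (K_d_range[1] > K_d_range[2] || k_on_range[1] > k_on_range[2]) {
    stop("ranges must be ordered c(lower, upper)", call. = FALSE)
  }
  if (any(c(K_d_range, k_on_range, L_max) <= 0)) {
    stop("constraints must be positive", call. = FALSE)
  }
  if (closed_population_ceiling <= 0 || closed_population_ceiling >= 1) {
    stop("closed_population_ceiling must be in (0,1)", call. = FALSE)
  }
  structure(list(K_d_range = K_d_range, k_on_range = k_on_range,
                 L_max = L_max,
                 closed_population_ceiling = closed_population_ceiling,
                 exchange_rate_ceiling = exchange_rate_ceiling,
                 fast_exchange_floor = fast_exchange_floor),
            class = "mechanism_constraints")
}

#' Constraint set of the glutamine-binding-protein study
#'
#' Convenience constructor with the experimental bounds of the GlnBP
#' analysis: K_d 10-20 nM, k_on 3e7-1e8 M^-1 s^-1, highest sensorgram
#' ligand concentration 500 nM, 10% closed-population ceiling, 100 s^-1
#' exchange-rate ceiling, 100 ns fast-exchange floor.
#'
#' @export
glnbp_constraints <- function() {
  mechanism_constraints(K_d_range = c(10e-9, 20e-9),
                        k_on_range = c(3e7, 1e8), L_max = 500e-9)
}

trail_entry <- function(name, formula, inputs, value) {
  list(name = name, formula = formula, inputs = inputs, value = value)
}

#' Rate bounds forced on a conformational-selection pathway
#'
#' Propagates the constraint chain: the two-state approximation
#' `k_obs ~ k_on [L] + k_off` (valid for a small closed population and
#' `[L] > K_d`) gives `k_obs(L_max) >= k_on_lb L_max + K_d_lb k_on_lb`.
#' Whether `k_obs` rises (`k_e > k_-`) or falls (`k_e < k_-`) with `[L]`,
#' its large-`[L]` limit `k_e` must exceed that bound, so
#' `k_e_min = k_obs_min`. The population ceiling `k_e/(k_e+k_r) <= c`
#' then forces `k_r >= k_e (1/c - 1)`. CS is declared incompatible when
#' the forced `k_r` exceeds the exchange-rate ceiling — unless exchange is
#' faster than the fast-exchange floor, where all screens are blind.
#'
#' @param constraints a [mechanism_constraints()].
#' @return list with `k_obs_min`, `k_e_min`, `k_r_min`,
#'   `implied_timescale_max` (s), `compatible`, `escape_regime`, `trail`.
#' @export
cs_bounds <- function(constraints) {
  stopifnot(inherits(constraints, "mechanism_constraints"))
  cn <- constraints
  if (cn$L_max <= cn$K_d_range[2]) {
    warning("L_max does not exceed K_d: the two-state approximation ",
            "regime condition [L] > K_d fails")
  }
  k_on_lb <- cn$k_on_range[1]
  K_d_lb <- cn$K_d_range[1]
  k_off_lb <- K_d_lb * k_on_lb
  k_obs_min <- k_on_lb * cn$L_max + k_off_lb
  k_e_min <- k_obs_min
  cc <- cn$closed_population_ceiling
  k_r_min <- k_e_min * (1 / cc - 1)
  ts_max <- 1 / k_r_min
  compatible <- k_r_min <= cn$exchange_rate_ceiling
  trail <- list(
    trail_entry("k_off_lb", "K_d_lb * k_on_lb",
                c(K_d_lb = K_d_lb, k_on_lb = k_on_lb), k_off_lb),
    trail_entry("k_obs_min", "k_on_lb * L_max + k_off_lb",
                c(k_on_lb = k_on_lb, L_max = cn$L_max,
                  k_off_lb = k_off_lb), k_obs_min),
    trail_entry("k_e_min", "k_obs_min",
                c(k_obs_min = k_obs_min), k_e_min),
    trail_entry("k_r_min", "k_e_min * (1 / ceiling - 1)",
                c(k_e_min = k_e_min, ceiling = cc), k_r_min),
    trail_entry("implied_timescale_max", "1 / k_r_min",
                c(k_r_min = k_r_min), ts_max))
  list(k_obs_min = k_obs_min, k_e_min = k_e_min, k_r_min = k_r_min,
       implied_timescale_max = ts_max, compatible = compatible,
       escape_regime = if (compatible) NA_character_ else
         sprintf("exchange faster than %.3g s", cn$fast_exchange_floor),
       trail = trail)
}

#' Rate bounds on an induced-fit pathway
#'
#' The effective off-rate range is `[K_d_lb k_on_lb, K_d_ub k_on_ub]`.
#' The IF structure forces `k_off < k_e < k_r` (from
#' `k_- = k_off k_r / (k_e - k_off)` requiring `k_off < k_e`), so IF is
#' feasible iff the exchange-rate ceiling leaves room above `k_off_min`.
#' The open-liganded population among the liganded states is then bounded
#' below by `P_OL >= k_off_min / (k_off_min + exchange_rate_ceiling)`.
#'
#' @inheritParams cs_bounds
#' @return list with `k_off_min`, `k_off_max`, `P_OL_min`, `compatible`,
#'   `trail`.
#' @export
if_bounds <- function(constraints) {
  stopifnot(inherits(constraints, "mechanism_constraints"))
  cn <- constraints
  k_off_min <- cn$K_d_range[1] * cn$k_on_range[1]
  k_off_max <- cn$K_d_range[2] * cn$k_on_range[2]
  if (k_off_min > k_off_max) stop("empty k_off range", call. = FALSE)
  ceiling_r <- cn$exchange_rate_ceiling
  compatible <- k_off_min < ceiling_r
  P_OL_min <- k_off_min / (k_off_min + ceiling_r)
  trail <- list(
    trail_entry("k_off_min", "K_d_lb * k_on_lb",
                c(K_d_lb = cn$K_d_range[1], k_on_lb = cn$k_on_range[1]),
                k_off_min),
    trail_entry("k_off_max", "K_d_ub * k_on_ub",
                c(K_d_ub = cn$K_d_range[2], k_on_ub = cn$k_on_range[2]),
                k_off_max),
    trail_entry("P_OL_min", "k_off_min / (k_off_min + ceiling)",
                c(k_off_min = k_off_min, ceiling = ceiling_r), P_OL_min))
  list(k_off_min = k_off_min, k_off_max = k_off_max, P_OL_min = P_OL_min,
       compatible = compatible, trail = trail)
}

#' Mechanism compatibility verdict
#'
#' Composes [cs_bounds()] and [if_bounds()] into a serializable report
#' carrying the full equation trail.
#'
#' @inheritParams cs_bounds
#' @return list of class `mechanism_verdict` with elements `cs`, `if_`,
#'   `constraints`.
#' @export
discriminate <- function(constraints) {
  structure(list(cs = cs_bounds(constraints), if_ = if_bounds(constraints),
                 constraints = unclass(constraints)),
            class = "mechanism_verdict")
}

#' @export
print.mechanism_verdict <- function(x, ...) {
  cat("Mechanism compatibility verdict\n")
  cat(sprintf("  CS: k_e > %.3g s-1, k_r > %.3g s-1 (timescale < %.3g ms)",
              x$cs$k_e_min, x$cs$k_r_min,
              1e3 * x$cs$implied_timescale_max))
  cat(sprintf(" -> %s\n", if (x$cs$compatible) "compatible" else
    sprintf("INCOMPATIBLE (escape: %s)", x$cs$escape_regime)))
  cat(sprintf("  IF: %.3g < k_off < %.3g s-1, P_OL > %.3g%%",
              x$if_$k_off_min, x$if_$k_off_max, 100 * x$if_$P_OL_min))
  cat(sprintf(" -> %s\n", if (x$if_$compatible) "compatible" else
    "INCOMPATIBLE"))
  invisible(x)
}

#' Replay the equation trail of a verdict
#'
#' Recomputes every trail entry from its recorded formula and inputs and
#' checks agreement with the stored value.
#'
#' @param verdict a [discriminate()] result.
#' @param rtol relative tolerance, default 1e-12.
#' @return TRUE invisibly; errors on any mismatch.
#' @export
replay_trail <- function(verdict, rtol = 1e-12) {
  for (side in list(verdict$cs, verdict$if_)) {
    env <- new.env(parent = baseenv())
    for (e in side$trail) {
      for (nm in names(e$inputs)) assign(nm, e$inputs[[nm]], envir = env)
      v <- eval(parse(text = e$formula), envir = env)
      if (abs(v - e$value) > rtol * max(abs(e$value), 1)) {
        stop("trail replay mismatch at ", e$name, call. = FALSE)
      }
      assign(e$name, e$value, envir = env)
    }
  }
  invisible(TRUE)
}

#' Serialize a verdict to JSON
#'
#' @param verdict a [discriminate()] result.
#' @param path optional output file; when NULL the JSON string is
#'   returned.
#' @export
verdict_json <- function(verdict, path = NULL) {
  x <- unclass(verdict)
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
}

#' Censored-exponential dwell-time estimate
#'
#' Maximum-likelihood mean dwell time from right-censored exponential
#' first-passage times: `mean = (sum of observed times + n_censored * T) /
#' n_observed`, with a profile-likelihood confidence interval. With zero
#' observed transitions only a lower bound is reported.
#'
#' @param data a `dwell_data` list (`observed`, `n_censored`, `horizon`),
#'   e.g. from [simulate_dwells()].
#' @param level confidence level, default 0.95.
#' @return list with `mean`, `ci` (length 2), `n_observed`, `n_censored`,
#'   `lower_bound_only` flag.
#' @export
dwell_mle_censored <- function(data, level = 0.95) {
  obs <- data$observed
  ncen <- data$n_censored
  T_h <- data$horizon
  n_obs <- length(obs)
  total <- sum(obs) + ncen * T_h
  if (n_obs == 0) {
    return(list(mean = NA_real_, ci = c(total, Inf), n_observed = 0L,
                n_censored = ncen, lower_bound_only = TRUE))
  }
  mhat <- total / n_obs
  ll <- function(m) -n_obs * log(m) - total / m
  crit <- stats::qchisq(level, df = 1) / 2
  f <- function(m) ll(mhat) - ll(m) - crit
  tol <- mhat * 1e-9   # dwell scales span ns..s; tolerance must follow
  lo <- stats::uniroot(f, lower = mhat * 1e-4, upper = mhat,
                       tol = tol)$root
  hi <- tryCatch(stats::uniroot(f, lower = mhat, upper = mhat * 1e4,
                                tol = tol)$root,
                 error = function(e) Inf)
  list(mean = mhat, ci = c(lo, hi), n_observed = n_obs,
       n_censored = as.integer(ncen), lower_bound_only = FALSE)
}
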