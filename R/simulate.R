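# Synthetic-data generators for every pipeline input: usALEX photon
# streams with two-state CTMC FRET dynamics, transport-limited SPR cycles,
# binding titrations, and right-censored dwell trajectories. Every
# generator embeds its truth parameters and seed in the output attributes;
# recovery tests read truth only from there.

#' Simulation configuration for usALEX photon streams
#'
#' Defaults emulate a confocal usALEX measurement of a freely diffusing
#' two-conformation protein: 50 us alternation (donor excitation in the
#' first half-period), 100 ns timestamp clock, bursts placed as a Poisson
#' process with log-normal durations (median 1 ms) and a raised-cosine
#' entry/exit brightness envelope. Diffusion is not modeled explicitly —
#' the analyses consume photon windows, not spatial trajectories.
#'
#' @param seed integer seed recorded in all outputs.
#' @param alternation_period full alternation cycle (s), default 50e-6
#'   (donor- and acceptor-excitation half-periods of 25 us).
#' @param clock timestamp resolution (s), default 100e-9.
#' @param brightness_D detected molecule photon rate during
#'   donor-excitation half-periods (photons/s), default 4e5.
#' @param brightness_A detected acceptor photon rate during
#'   acceptor-excitation half-periods (photons/s), default 4e5 (puts the
#'   doubly-labeled species at stoichiometry S* near 0.5).
#' @param background named rates (photons/s within the matching excitation
#'   window) for streams `DD`, `DA`, `AA`.
#' @param E1,E2 FRET efficiencies of the two conformational states (use
#'   `E2 = NULL` for a static molecule at `E1`). Defaults 0.51/0.68, the
#'   apparent apo (mid-FRET, open) and holo (high-FRET, closed) means.
#' @param k_12,k_21 state switching rates 1->2 and 2->1 (s^-1); 0 for
#'   static.
#' @param burst_rate burst arrival rate (s^-1), default 20.
#' @param duration_meanlog,duration_sdlog log-normal burst-duration
#'   parameters, default `log(1e-3)` and 0.5.
#' @param donor_only_frac,acceptor_only_frac impurity burst fractions.
#' @param alpha,beta,gamma direct-excitation, crosstalk and detection
#'   correction factors applied by the generator (defaults 0, 0, 1: off)
#'   so [accurate_fret()] has a truth to recover; `gamma >= 1`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, alternation_period = 50e-6,
                       clock = 100e-9, brightness_D = 4e5,
                       brightness_A = 4e5,
                       background = c(DD = 1500, DA = 800, AA = 1200),
                       E1 = 0.51, E2 = 0.68, k_12 = 0, k_21 = 0,
                       burst_rate = 20, duration_meanlog = log(1e-3),
                       duration_sdlog = 0.5, donor_only_frac = 0,
                       acceptor_only_frac = 0, alpha = 0, beta = 0,
                       gamma = 1) {
  stopifnot(alternation_period > 0, clock > 0, k_12 >= 0, k_21 >= 0,
            gamma >= 1, alpha >= 0, beta >= 0)
  Es <- c(E1, if (!is.null(E2)) E2)
  if (any(Es < 0 | Es > 1)) stop("E values must be in [0,1]",
                                 call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

# fold a cumulative within-window time u into absolute time for the given
# half (0 = first half / Dex, 1 = second half / Aex)
unfold_half <- function(u, period, half_id) {
  h <- period / 2
  floor(u / h) * period + (u %% h) + half_id * h
}

in_dex <- function(t, period) (t %% period) < period / 2

# CTMC state path over [0, d]: returns step function data
ctmc_path <- function(d, k_12, k_21) {
  if (k_12 <= 0 || k_21 <= 0) {
    return(list(times = 0, states = 1L))
  }
  p1 <- k_21 / (k_12 + k_21)
  s <- if (stats::runif(1) < p1) 1L else 2L
  times <- 0; states <- s; t <- 0
  repeat {
    rate <- if (s == 1L) k_12 else k_21
    t <- t + stats::rexp(1, rate)
    if (t >= d) break
    s <- 3L - s
    times <- c(times, t); states <- c(states, s)
  }
  list(times = times, states = states)
}

state_at <- function(path, tt) path$states[findInterval(tt, path$times)]

#' Simulate a usALEX photon stream
#'
#' Photons are drawn as Poisson processes per (excitation, detection)
#' stream. During donor-excitation half-periods each molecule photon is an
#' acceptor photon with probability equal to the current-state FRET
#' efficiency; during acceptor-excitation half-periods acceptor photons
#' appear at the direct-excitation brightness. The conformational state
#' switches as a continuous-time Markov chain within each burst.
#'
#' @param config a [sim_config()].
#' @param duration measurement length (s).
#' @return photon-stream data.frame (`timestamp` s, `ticks`, `channel`,
#'   `excitation`) sorted by time, with attributes `background` (rates
#'   over total time for the burst searches), `config`, and `truth`
#'   (per-burst start, duration, type).
#' @export
simulate_photon_stream <- function(config, duration) {
  stopifnot(inherits(config, "sim_config"), duration >= 0)
  set.seed(config$seed)
  p <- config$alternation_period
  h <- p / 2
  emit <- function(n, t, ch, ex) {
    data.frame(timestamp = t, channel = rep(ch, n), excitation = rep(ex, n))
  }
  parts <- list()
  if (duration > 0) {
    # background: rates are within-excitation-window rates; each stream has
    # duration/2 of live time
    for (st in c("DD", "DA", "AA")) {
      lam <- config$background[[st]] * duration / 2
      n <- stats::rpois(1, lam)
      if (n > 0) {
        u <- stats::runif(n, 0, duration / 2)
        t <- unfold_half(u, p, if (st == "AA") 1 else 0)
        parts[[length(parts) + 1L]] <-
          emit(n, t, if (st == "DD") "D" else "A",
               if (st == "AA") "Aex" else "Dex")
      }
    }
  }
  truth <- data.frame(start = numeric(0), duration = numeric(0),
                      type = character(0))
  n_bursts <- stats::rpois(1, config$burst_rate * duration)
  if (n_bursts > 0) {
    starts <- sort(stats::runif(n_bursts, 0, duration))
    durs <- stats::rlnorm(n_bursts, config$duration_meanlog,
                          config$duration_sdlog)
    types <- sample(c("DA", "Donly", "Aonly"), n_bursts, replace = TRUE,
                    prob = c(1 - config$donor_only_frac -
                               config$acceptor_only_frac,
                             config$donor_only_frac,
                             config$acceptor_only_frac))
    truth <- data.frame(start = starts, duration = durs, type = types)
    env <- function(tt, d) {  # raised-cosine 20% entry/exit ramps
      ramp <- 0.2 * d
      e <- rep(1, length(tt))
      i <- tt < ramp
      e[i] <- 0.5 * (1 - cos(pi * tt[i] / ramp))
      j <- tt > d - ramp
      e[j] <- 0.5 * (1 - cos(pi * (d - tt[j]) / ramp))
      e
    }
    for (b in seq_len(n_bursts)) {
      t0 <- starts[b]; d <- durs[b]; ty <- types[b]
      path <- ctmc_path(d, config$k_12, config$k_21)
      # donor-excitation molecule photons
      if (ty != "Aonly") {
        n <- stats::rpois(1, config$brightness_D * d)
        if (n > 0) {
          tt <- sort(stats::runif(n, 0, d))
          keep <- in_dex(t0 + tt, p) & stats::runif(n) < env(tt, d)
          tt <- tt[keep]
          if (length(tt)) {
            Ecur <- if (ty == "Donly") 0 else {
              st <- state_at(path, tt)
              ifelse(st == 1L, config$E1,
                     if (is.null(config$E2)) config$E1 else config$E2)
            }
            is_acc <- stats::runif(length(tt)) < Ecur
            # acceptor-emitted photons -> A channel
            na <- sum(is_acc)
            if (na) parts[[length(parts) + 1L]] <-
                emit(na, t0 + tt[is_acc], "A", "Dex")
            # donor-emitted: green detection w.p. 1/gamma, independent
            # crosstalk photon in A w.p. beta/gamma
            td <- tt[!is_acc]
            if (length(td)) {
              gkeep <- stats::runif(length(td)) < 1 / config$gamma
              if (any(gkeep)) parts[[length(parts) + 1L]] <-
                  emit(sum(gkeep), t0 + td[gkeep], "D", "Dex")
              xk <- stats::runif(length(td)) <
                config$beta / config$gamma
              if (any(xk)) parts[[length(parts) + 1L]] <-
                  emit(sum(xk), t0 + td[xk], "A", "Dex")
            }
          }
        }
        # direct acceptor excitation during Dex at alpha * brightness_A
        if (ty == "DA" && config$alpha > 0) {
          n <- stats::rpois(1, config$alpha * config$brightness_A * d)
          if (n > 0) {
            tt <- sort(stats::runif(n, 0, d))
            keep <- in_dex(t0 + tt, p) & stats::runif(n) < env(tt, d)
            if (any(keep)) parts[[length(parts) + 1L]] <-
                emit(sum(keep), t0 + tt[keep], "A", "Dex")
          }
        }
      }
      # acceptor-excitation photons
      if (ty != "Donly") {
        n <- stats::rpois(1, config$brightness_A * d)
        if (n > 0) {
          tt <- sort(stats::runif(n, 0, d))
          keep <- !in_dex(t0 + tt, p) & stats::runif(n) < env(tt, d)
          if (any(keep)) parts[[length(parts) + 1L]] <-
              emit(sum(keep), t0 + tt[keep], "A", "Aex")
        }
      }
    }
  }
  out <- if (length(parts)) do.call(rbind, parts) else
    data.frame(timestamp = numeric(0), channel = character(0),
               excitation = character(0))
  out$timestamp <- round(out$timestamp / config$clock) * config$clock
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  out$ticks <- round(out$timestamp / config$clock)
  bg <- config$background
  attr(out, "background") <- list(
    DD = bg[["DD"]] / 2, DA = bg[["DA"]] / 2, AA = bg[["AA"]] / 2,
    Dex = (bg[["DD"]] + bg[["DA"]]) / 2, Aex = bg[["AA"]] / 2)
  attr(out, "config") <- config
  attr(out, "truth") <- truth
  out
}

#' Simulate a transport-limited SPR cycle
#'
#' Numerically solves the transport + binding ODE ([spr_ode_rhs()]) over a
#' baseline / association / dissociation schedule and adds Gaussian noise
#' and optional exponential drift. Truth parameters are stored in the
#' `truth` attribute.
#'
#' @param params named list: `k_t` (s^-1), `k_on` (M^-1 s^-1), `K_d` (M),
#'   `r_max` (RU), `alpha` (M/RU). `k_off` is `K_d * k_on`.
#' @param L_bulk bulk ligand concentration during association (M).
#' @param schedule phase schedule (s); default baseline 60 s, association
#'   50 s, dissociation 360 s.
#' @param dt sampling interval (s), default 0.5.
#' @param noise_sd Gaussian noise SD (RU), default 0.06.
#' @param drift `NULL` or list `a` (RU), `b` (s^-1), `c` (RU) for an
#'   `a exp(-b t) + c` drift added to the trace.
#' @param seed RNG seed.
#' @return a [sensorgram()] with attribute `truth`.
#' @export
simulate_sensorgram <- function(params, L_bulk,
                                schedule = list(baseline_end = 60,
                                                association_end = 110,
                                                dissociation_end = 470),
                                dt = 0.5, noise_sd = 0.06, drift = NULL,
                                seed = 1) {
  set.seed(seed)
  k_off <- params$K_d * params$k_on
  s <- schedule
  t_all <- seq(0, s$dissociation_end, by = dt)
  r <- numeric(length(t_all))
  ia <- t_all > s$baseline_end & t_all <= s$association_end
  id <- t_all > s$association_end
  ta <- t_all[ia] - s$baseline_end
  # association from (L_surf, r) = (0, 0)
  sol_a <- deSolve::lsoda(y = c(0, 0),
                          times = unique(c(0, ta, s$association_end -
                                             s$baseline_end)),
                          func = spr_ode_rhs,
                          parms = list(k_t = params$k_t,
                                       k_on = params$k_on, k_off = k_off,
                                       r_max = params$r_max,
                                       alpha = params$alpha,
                                       L_bulk = L_bulk),
                          rtol = 1e-8, atol = 1e-10)
  r[ia] <- sol_a[match(ta, sol_a[, 1]), 3]
  end_state <- sol_a[nrow(sol_a), 2:3]
  td <- t_all[id] - s$association_end
  if (length(td)) {
    sol_d <- deSolve::lsoda(y = unname(end_state),
                            times = unique(c(0, td)),
                            func = spr_ode_rhs,
                            parms = list(k_t = params$k_t,
                                         k_on = params$k_on,
                                         k_off = k_off,
                                         r_max = params$r_max,
                                         alpha = params$alpha,
                                         L_bulk = 0),
                            rtol = 1e-8, atol = 1e-10)
    r[id] <- sol_d[match(td, sol_d[, 1]), 3]
  }
  y <- r + stats::rnorm(length(r), 0, noise_sd)
  if (!is.null(drift)) {
    cdrift <- if (is.null(drift$c)) 0 else drift$c
    y <- y + drift$a * exp(-drift$b * t_all) + cdrift
  }
  out <- sensorgram(t_all, y, L_bulk, s)
  attr(out, "truth") <- list(params = params, k_off = k_off,
                             L_bulk = L_bulk, noise_sd = noise_sd,
                             drift = drift, seed = seed, r_clean = r)
  out
}

#' Simulate a binding titration
#'
#' Per concentration, the closed-state fraction is drawn as a binomial
#' proportion around the isotherm `[L] / (K_d + [L])` from
#' `n_bursts_per_point` bursts.
#'
#' @param K_d dissociation constant (M).
#' @param concentrations ligand concentrations (M).
#' @param n_bursts_per_point bursts classified per titration point.
#' @param seed RNG seed.
#' @return data.frame `L`, `fraction_closed`, `n_bursts` with attribute
#'   `truth`.
#' @export
simulate_titration <- function(K_d, concentrations,
                               n_bursts_per_point = 500, seed = 1) {
  stopifnot(all(concentrations > 0), K_d > 0)
  set.seed(seed)
  f_true <- concentrations / (K_d + concentrations)
  k <- stats::rbinom(length(f_true), n_bursts_per_point, f_true)
  out <- data.frame(L = concentrations, fraction_closed =
                      k / n_bursts_per_point,
                    n_bursts = n_bursts_per_point)
  attr(out, "truth") <- list(K_d = K_d, seed = seed)
  out
}

#' Simulate right-censored dwell times
#'
#' Exponential first-passage times censored at a fixed horizon, emulating
#' opening transitions observed on a finite set of finite-length
#' trajectories.
#'
#' @param mean_dwell true mean dwell time (s).
#' @param n_traj number of trajectories.
#' @param horizon censoring horizon (s).
#' @param seed RNG seed.
#' @return list of class `dwell_data`: `observed` (transition times, s),
#'   `n_censored`, `horizon`, plus attribute `truth`.
#' @export
simulate_dwells <- function(mean_dwell, n_traj, horizon, seed = 1) {
  stopifnot(mean_dwell > 0, n_traj >= 1, horizon > 0)
  set.seed(seed)
  t <- stats::rexp(n_traj, 1 / mean_dwell)
  obs <- t[t <= horizon]
  out <- structure(list(observed = obs, n_censored = sum(t > horizon),
                        horizon = horizon),
                   class = "dwell_data")
  attr(out, "truth") <- list(mean_dwell = mean_dwell, seed = seed)
  out
}
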