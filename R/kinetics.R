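# Linearized three-state relaxation kinetics of the two limiting
# ligand-binding pathways of a bilobed substrate-binding protein:
#   IF (induced fit):            O  --k+[L]/k- -->  OL  --k_r/k_e-->  CL
#   CS (conformational selection): O --k_e/k_r -->  C   --k+[L]/k- -->  CL
# k_e / k_r are the conformational excitation/relaxation rates of the
# pathway's conformational step; k_+ / k_- the microscopic association
# (per molar) and dissociation rates of the binding-competent conformation.
# Ligand enters only as k_+ * [L] (pseudo-first-order; no depletion).

#' Microscopic rate constants of a binding pathway
#'
#' Bundles the four microscopic rates of either limiting pathway together
#' with the pathway tag. All rates must be strictly positive and finite.
#'
#' @param k_e conformational excitation rate (s^-1): ground -> high-free-energy
#'   conformation of the pathway's conformational step.
#' @param k_r conformational relaxation rate (s^-1), the reverse of `k_e`.
#' @param k_plus association rate constant of the binding-competent
#'   conformation (M^-1 s^-1).
#' @param k_minus dissociation rate of the bound state (s^-1).
#' @param pathway `"IF"` (ligand binds the open state, closing follows) or
#'   `"CS"` (the closed state pre-exists, the ligand selects it).
#' @return An object of class `pathway_rates`.
#' @export
pathway_rates <- function(k_e, k_r, k_plus, k_minus, pathway = c("IF", "CS")) {
  pathway <- match.arg(pathway)
  rates <- c(k_e = k_e, k_r = k_r, k_plus = k_plus, k_minus = k_minus)
  if (!all(is.finite(rates)) || any(rates <= 0)) {
    stop("all rates must be strictly positive and finite", call. = FALSE)
  }
  structure(list(k_e = k_e, k_r = k_r, k_plus = k_plus, k_minus = k_minus,
                 pathway = pathway),
            class = "pathway_rates")
}

#' @export
print.pathway_rates <- function(x, ...) {
  cat(sprintf("<pathway_rates %s> k_e=%.4g k_r=%.4g k_+=%.4g k_-=%.4g\n",
              x$pathway, x$k_e, x$k_r, x$k_plus, x$k_minus))
  invisible(x)
}

check_L <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0) {
    stop("ligand concentration L must be a single finite value >= 0",
         call. = FALSE)
  }
  L
}

#' Pseudo-first-order generator matrix of a pathway
#'
#' Returns the 3x3 rate (generator) matrix of the linearized scheme at fixed
#' ligand concentration, with the binding step entered as `k_plus * L`.
#' States are ordered unbound ground conformation, intermediate
#' (closed-unbound for CS, open-liganded for IF), bound ground state.
#' Columns sum to zero (probability conservation); `dp/dt = Q %*% p`.
#'
#' @param rates a [pathway_rates()] object.
#' @param L ligand concentration (M).
#' @return 3x3 numeric matrix with dimnames by state.
#' @export
rate_matrix <- function(rates, L) {
  stopifnot(inherits(rates, "pathway_rates"))
  check_L(L)
  kl <- rates$k_plus * L
  if (rates$pathway == "CS") {
    # O --k_e--> C --k+L--> CL, reverse k_r, k_minus
    Q <- matrix(c(-rates$k_e,            rates$k_r,                0,
                   rates$k_e, -(rates$k_r + kl),        rates$k_minus,
                   0,                    kl,           -rates$k_minus),
                nrow = 3, byrow = TRUE)
    states <- c("open_unbound", "closed_unbound", "closed_bound")
  } else {
    # O --k+L--> OL --k_r--> CL, reverse k_minus, k_e
    Q <- matrix(c(-kl,          rates$k_minus,                 0,
                   kl, -(rates$k_minus + rates$k_r),   rates$k_e,
                   0,            rates$k_r,           -rates$k_e),
                nrow = 3, byrow = TRUE)
    states <- c("open_unbound", "open_bound", "closed_bound")
  }
  dimnames(Q) <- list(states, states)
  Q
}

#' Exact dominant relaxation rate of a pathway
#'
#' Slowest nonzero relaxation rate of the linearized three-state scheme at
#' ligand concentration `L`. With `S = k_e + k_r + k_+ [L] + k_-`, the rate is
#' `(S - sqrt(S^2 - 4 c)) / 2` where
#' `c = k_e (k_+ [L] + k_-) + k_r k_-` for CS and
#' `c = k_+ [L] (k_e + k_r) + k_e k_-` for IF. Evaluated in the equivalent
#' cancellation-free form `2 c / (S + sqrt(S^2 - 4 c))`; equals the
#' smallest-magnitude nonzero eigenvalue of [rate_matrix()].
#'
#' @inheritParams rate_matrix
#' @return dominant relaxation rate (s^-1), positive and at most `S/2`.
#' @export
exact_relaxation_rate <- function(rates, L) {
  stopifnot(inherits(rates, "pathway_rates"))
  check_L(L)
  kl <- rates$k_plus * L
  S <- rates$k_e + rates$k_r + kl + rates$k_minus
  cc <- if (rates$pathway == "CS") {
    rates$k_e * (kl + rates$k_minus) + rates$k_r * rates$k_minus
  } else {
    kl * (rates$k_e + rates$k_r) + rates$k_e * rates$k_minus
  }
  disc <- S^2 - 4 * cc
  if (disc < 0) {
    # both nonzero eigenvalues are real for these schemes; tiny negative
    # discriminants are roundoff
    if (disc > -1e-12 * S^2) disc <- 0
    else stop("negative discriminant beyond tolerance: inconsistent rates",
              call. = FALSE)
  }
  2 * cc / (S + sqrt(disc))
}

#' Effective rates of a pathway
#'
#' Two-state lumping of the three-state scheme valid when the intermediate
#' state is sparsely populated. For CS (concentration dependent):
#' `k_on = k_e k_+ / (k_r + k_+ [L])`, `k_off = k_r k_- / (k_r + k_+ [L])`.
#' For IF (concentration independent):
#' `k_on = k_+ k_r / (k_- + k_r)`, `k_off = k_- k_e / (k_- + k_r)`.
#' The `K_d` element is `k_off / k_on`; see [equilibrium_Kd()] for the exact
#' equilibrium dissociation constant of the full scheme.
#'
#' @inheritParams rate_matrix
#' @param L ligand concentration (M); required (and used) only for CS.
#' @return list with elements `k_on` (M^-1 s^-1), `k_off` (s^-1), `K_d` (M).
#' @export
effective_rates <- function(rates, L = NULL) {
  stopifnot(inherits(rates, "pathway_rates"))
  if (rates$pathway == "CS") {
    if (is.null(L)) stop("CS effective rates depend on L; supply L",
                         call. = FALSE)
    check_L(L)
    denom <- rates$k_r + rates$k_plus * L
    k_on <- rates$k_e * rates$k_plus / denom
    k_off <- rates$k_r * rates$k_minus / denom
  } else {
    denom <- rates$k_minus + rates$k_r
    k_on <- rates$k_plus * rates$k_r / denom
    k_off <- rates$k_minus * rates$k_e / denom
  }
  list(k_on = k_on, k_off = k_off, K_d = k_off / k_on)
}

#' @rdname effective_rates
#' @details `effective_rates_cs()` and `effective_rates_if()` are strict
#'   variants that error on a pathway mismatch.
#' @export
effective_rates_cs <- function(rates, L) {
  if (rates$pathway != "CS") stop("pathway mismatch: CS rates required",
                                  call. = FALSE)
  effective_rates(rates, L)
}

#' @rdname effective_rates
#' @export
effective_rates_if <- function(rates) {
  if (rates$pathway != "IF") stop("pathway mismatch: IF rates required",
                                  call. = FALSE)
  effective_rates(rates)
}

#' Exact equilibrium dissociation constant of a pathway
#'
#' Ligand concentration at which half of the protein is in the bound ground
#' state at equilibrium of the full three-state scheme:
#' `K_d = k_- (k_e + k_r) / (k_+ k_e)` for CS and
#' `K_d = k_- k_e / (k_+ (k_e + k_r))` for IF counting both liganded states
#' as bound; the commonly quoted IF value `k_- k_e / (k_+ k_r)` is
#' `k_off/k_on` of [effective_rates()] and agrees for `k_e << k_r`.
#'
#' @inheritParams rate_matrix
#' @return dissociation constant (M).
#' @export
equilibrium_Kd <- function(rates) {
  stopifnot(inherits(rates, "pathway_rates"))
  if (rates$pathway == "CS") {
    rates$k_minus * (rates$k_e + rates$k_r) / (rates$k_plus * rates$k_e)
  } else {
    rates$k_minus * rates$k_e / (rates$k_plus * (rates$k_e + rates$k_r))
  }
}

#' Approximate dominant CS relaxation rate
#'
#' Simplified form of the CS relaxation rate,
#' `k_obs ~ k_e k_- (1 + [L]/K_d) / (k_e + k_- [L]/K_d)` with
#' `K_d = k_- k_r / (k_+ k_e)`, valid for a small closed-state population and
#' `[L] > K_d`. Its large-`[L]` limit is `k_e`; it increases with `[L]` iff
#' `k_e > k_-`.
#'
#' @inheritParams rate_matrix
#' @return approximate relaxation rate (s^-1).
#' @export
approx_relaxation_rate_cs <- function(rates, L) {
  stopifnot(inherits(rates, "pathway_rates"))
  if (rates$pathway != "CS") stop("pathway mismatch: CS rates required",
                                  call. = FALSE)
  check_L(L)
  Kd <- rates$k_minus * rates$k_r / (rates$k_plus * rates$k_e)
  x <- L / Kd
  rates$k_e * rates$k_minus * (1 + x) / (rates$k_e + rates$k_minus * x)
}

#' Microscopic dissociation rate from the effective IF off-rate
#'
#' Inverts the IF effective off-rate `k_off = k_- k_e / (k_- + k_r)`:
#' `k_- = k_off k_r / (k_e - k_off)`. Defined only for `k_off < k_e` — the
#' structural reason the IF pathway forces `k_off < k_e`.
#'
#' @param k_off effective off-rate (s^-1).
#' @param k_r,k_e conformational rates of the liganded protein (s^-1).
#' @return microscopic dissociation rate `k_-` (s^-1).
#' @export
k_minus_from_koff <- function(k_off, k_r, k_e) {
  if (any(c(k_off, k_r, k_e) <= 0)) stop("rates must be positive",
                                         call. = FALSE)
  if (k_off >= k_e) stop("k_off must be smaller than k_e for an IF pathway",
                         call. = FALSE)
  k_off * k_r / (k_e - k_off)
}

#' Integrate the linearized scheme
#'
#' Solves `dp/dt = Q p` with `Q = rate_matrix(rates, L)` using a
#' stiff-capable adaptive integrator (deSolve::lsoda).
#'
#' @inheritParams rate_matrix
#' @param init length-3 occupancy vector summing to 1.
#' @param t_grid times (s) at which to report the solution.
#' @param rtol,atol solver tolerances.
#' @return data.frame with column `time` and one occupancy column per state.
#' @export
integrate_scheme <- function(rates, L, init, t_grid,
                             rtol = 1e-8, atol = 1e-10) {
  Q <- rate_matrix(rates, L)
  if (length(init) != 3L || abs(sum(init) - 1) > 1e-8 || any(init < 0)) {
    stop("init must be a 3-vector of occupancies summing to 1",
         call. = FALSE)
  }
  rhs <- function(t, y, parms) list(as.vector(parms %*% y))
  sol <- deSolve::lsoda(y = init, times = t_grid, func = rhs, parms = Q,
                        rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE solver failed to converge (istate = ",
         attr(sol, "istate")[1], ")", call. = FALSE)
  }
  out <- as.data.frame(sol)
  names(out) <- c("time", colnames(Q))
  out
}

#' Stationary distribution of a pathway scheme
#'
#' Closed-form equilibrium occupancies of the chain (detailed balance holds
#' exactly for these linear schemes).
#'
#' @inheritParams rate_matrix
#' @return named length-3 occupancy vector summing to 1.
#' @export
stationary_distribution <- function(rates, L) {
  Q <- rate_matrix(rates, L)
  kl <- rates$k_plus * L
  pi_raw <- if (rates$pathway == "CS") {
    c(rates$k_r * rates$k_minus, rates$k_e * rates$k_minus, rates$k_e * kl)
  } else {
    c(rates$k_minus * rates$k_e, kl * rates$k_e, kl * rates$k_r)
  }
  out <- pi_raw / sum(pi_raw)
  names(out) <- colnames(Q)
  out
}

#' Standard binding free energy from a dissociation constant
#'
#' `dG = R T ln(K_d / 1 M)` with `R = 8.314 J mol^-1 K^-1`, reported in
#' kJ/mol (negative for sub-molar `K_d`). For K_d = 35 nM at 298.15 K this
#' gives -42.6 kJ/mol.
#'
#' @param K_d dissociation constant (M).
#' @param T_K absolute temperature (K), default 298.15.
#' @return binding free energy (kJ/mol).
#' @export
binding_free_energy <- function(K_d, T_K = 298.15) {
  if (!is.finite(K_d) || K_d <= 0 || !is.finite(T_K) || T_K <= 0) {
    stop("K_d and T must be positive and finite", call. = FALSE)
  }
  8.314 * T_K * log(K_d) / 1000
}
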