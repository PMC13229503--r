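# Burst detection and E*/S* statistics for usALEX photon streams.
# A photon stream is a data.frame(timestamp, channel, excitation) sorted by
# timestamp (seconds), channel in {"D","A"} (detection), excitation in
# {"Dex","Aex"} (alternation phase). The three analysed streams are
#   DD: Dex + D detection, DA: Dex + A detection, AA: Aex + A detection.
# Proximity ratio E* = F_DA / (F_DD + F_DA); stoichiometry
# S* = (F_DD + F_DA) / (F_DD + F_DA + F_AA). Both are left uncorrected for
# background in burst tables.

stream_of <- function(stream) {
  ifelse(stream$excitation == "Dex",
         ifelse(stream$channel == "D", "DD", "DA"),
         ifelse(stream$channel == "A", "AA", "AD"))
}

burst_table <- function(stream, runs) {
  lab <- stream_of(stream)
  n <- length(runs)
  out <- data.frame(start = numeric(n), stop = numeric(n),
                    n_photons = integer(n), F_DD = integer(n),
                    F_DA = integer(n), F_AA = integer(n),
                    E_star = numeric(n), S_star = numeric(n),
                    duration = numeric(n), flagged = logical(n))
  for (b in seq_len(n)) {
    i <- runs[[b]]
    t <- stream$timestamp[i]
    f <- table(factor(lab[i], levels = c("DD", "DA", "AA", "AD")))
    dd <- f[["DD"]]; da <- f[["DA"]]; aa <- f[["AA"]]
    es <- burst_proximity(dd, da, aa)
    out$start[b] <- t[1]; out$stop[b] <- t[length(t)]
    out$n_photons[b] <- length(i)
    out$F_DD[b] <- dd; out$F_DA[b] <- da; out$F_AA[b] <- aa
    out$E_star[b] <- es$E_star; out$S_star[b] <- es$S_star
    out$duration[b] <- t[length(t)] - t[1]
    out$flagged[b] <- es$flagged
  }
  attr(out, "photon_index") <- runs
  attr(out, "stream") <- stream
  class(out) <- c("burst_set", "data.frame")
  out
}

#' All-photon burst search
#'
#' Sliding-window neighborhood count: a photon belongs to a burst region if
#' at least `threshold` photons (itself included) fall within a centered
#' time window of length `window` around it; bursts are maximal runs of
#' such photons, and bursts with fewer than `min_total` photons
#' (F_DD + F_DA + F_AA + others) are discarded.
#'
#' @param stream photon-stream data.frame (`timestamp` s, `channel`,
#'   `excitation`), sorted by timestamp.
#' @param window centered window length (s), default 500e-6.
#' @param threshold minimum photons in the window, default 15.
#' @param min_total minimum total photons per burst, default 150.
#' @return a `burst_set` data.frame (one row per burst, E*/S* columns);
#'   photon indices per burst in attribute `photon_index`.
#' @export
all_photon_burst_search <- function(stream, window = 500e-6,
                                    threshold = 15, min_total = 150) {
  if (nrow(stream) == 0) return(burst_table(stream, list()))
  t <- stream$timestamp
  if (is.unsorted(t)) stop("stream must be sorted by timestamp",
                           call. = FALSE)
  half <- window / 2
  # photons within [t_i - half, t_i + half], inclusive
  lo <- findInterval(t - half, t, left.open = TRUE)
  hi <- findInterval(t + half, t)
  counts <- hi - lo
  inb <- counts >= threshold
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- Map(seq.int, starts[r$values], ends[r$values])
  lab <- stream_of(stream)
  runs <- Filter(function(i) sum(lab[i] != "AD") >= min_total, runs)
  burst_table(stream, runs)
}

# Rate-criterion burst regions on one photon substream: photon i is "hot"
# if some window of m consecutive substream photons containing i spans at
# most m / (F * bg_rate). Returns a 2-column matrix of [start, stop] times.
rate_regions <- function(t, m, F_mult, bg_rate) {
  n <- length(t)
  if (n < m) return(matrix(numeric(0), ncol = 2))
  span <- t[m:n] - t[1:(n - m + 1)]
  ok <- span <= m / (F_mult * bg_rate)   # window j covers photons j..j+m-1
  hot <- logical(n)
  for (j in which(ok)) hot[j:(j + m - 1L)] <- TRUE
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(t[starts[r$values]], t[ends[r$values]])
}

intersect_regions <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(matrix(numeric(0), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
    if (lo <= hi) out <- rbind(out, c(lo, hi))
    if (a[i, 2] < b[j, 2]) i <- i + 1L else j <- j + 1L
  }
  out
}

#' Dual-channel (AND-gate) burst search
#'
#' Evaluates the sliding-window rate criterion (windows of `m` consecutive
#' photons at an instantaneous rate of at least `F` times the background
#' rate) separately on the donor-excitation photon stream (DD + DA) and the
#' acceptor-excitation stream (AA), keeps only time regions where both
#' criteria hold, and filters bursts to at least `min_D` donor-excitation
#' and `min_A` acceptor-excitation photons. Rejects donor-only and
#' acceptor-only molecules by construction.
#'
#' @inheritParams all_photon_burst_search
#' @param m sliding-window size (photons), default 10.
#' @param F_mult rate multiple over background, default 6.
#' @param min_D,min_A minimum donor-/acceptor-excitation photons per burst,
#'   default 50 each.
#' @param background named list/vector with per-stream background rates
#'   (photons/s): needs `Dex` (DD+DA) and `Aex` (AA); taken from
#'   `attr(stream, "background")` when missing.
#' @return a `burst_set` data.frame.
#' @export
dual_channel_burst_search <- function(stream, m = 10, F_mult = 6,
                                      min_D = 50, min_A = 50,
                                      background = attr(stream,
                                                        "background")) {
  if (is.null(background)) {
    stop("background rates required (argument or stream attribute)",
         call. = FALSE)
  }
  bg <- as.list(background)
  if (is.null(bg$Dex)) {
    bg$Dex <- sum(unlist(bg[c("DD", "DA")]), na.rm = TRUE)
  }
  if (is.null(bg$Aex)) bg$Aex <- bg$AA
  if (is.null(bg$Dex) || is.null(bg$Aex) || bg$Dex <= 0 || bg$Aex <= 0) {
    stop("background must give positive Dex and Aex rates", call. = FALSE)
  }
  if (nrow(stream) == 0) return(burst_table(stream, list()))
  t <- stream$timestamp
  if (is.unsorted(t)) stop("stream must be sorted by timestamp",
                           call. = FALSE)
  lab <- stream_of(stream)
  dex <- which(lab %in% c("DD", "DA"))
  aex <- which(lab == "AA")
  reg <- intersect_regions(rate_regions(t[dex], m, F_mult, bg$Dex),
                           rate_regions(t[aex], m, F_mult, bg$Aex))
  runs <- list()
  for (k in seq_len(nrow(reg))) {
    i0 <- findInterval(reg[k, 1], t, left.open = TRUE) + 1L
    i1 <- findInterval(reg[k, 2], t)
    if (i1 < i0) next
    i <- i0:i1
    if (sum(lab[i] %in% c("DD", "DA")) >= min_D &&
        sum(lab[i] == "AA") >= min_A) {
      runs[[length(runs) + 1L]] <- i
    }
  }
  burst_table(stream, runs)
}

#' Proximity ratio and stoichiometry from burst counts
#'
#' `E* = F_DA / (F_DD + F_DA)`,
#' `S* = (F_DD + F_DA) / (F_DD + F_DA + F_AA)`, uncorrected for background.
#' Donor-only bursts have S* near 1, acceptor-only bursts S* near 0 with an
#' undefined E* (flagged, `E_star = NA`).
#'
#' @param F_DD,F_DA,F_AA photon counts by (excitation, detection) stream.
#' @return list `E_star`, `S_star`, `flagged`.
#' @export
burst_proximity <- function(F_DD, F_DA, F_AA) {
  if (any(c(F_DD, F_DA, F_AA) < 0)) stop("counts must be non-negative",
                                         call. = FALSE)
  dex <- F_DD + F_DA
  tot <- dex + F_AA
  flagged <- FALSE
  if (dex > 0) E <- F_DA / dex else { E <- NA_real_; flagged <- TRUE }
  if (tot > 0) S <- dex / tot else { S <- NA_real_; flagged <- TRUE }
  list(E_star = E, S_star = S, flagged = flagged)
}

#' Accurate FRET efficiency with correction factors
#'
#' `E = (F_GR - alpha F_RR - beta F_GG) /
#'      (F_GR - alpha F_RR - beta F_GG + gamma F_GG)` where `alpha` corrects
#' direct acceptor excitation, `beta` spectral crosstalk and `gamma` the
#' detection/quantum-yield imbalance. Reduces to the proximity ratio at
#' `alpha = beta = 0`, `gamma = 1`.
#'
#' @param F_GG,F_GR,F_RR background-corrected signals: green-excited green
#'   and red detection, and red-excited red detection.
#' @param alpha,beta,gamma correction factors.
#' @return corrected FRET efficiency (NA with a flag on zero denominator).
#' @export
accurate_fret <- function(F_GG, F_GR, F_RR, alpha = 0, beta = 0,
                          gamma = 1) {
  num <- F_GR - alpha * F_RR - beta * F_GG
  den <- num + gamma * F_GG
  ifelse(den == 0, NA_real_, num / den)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tau_DA / tau_D0`: donor lifetime in the presence of the
#' acceptor over the donor-only lifetime. Defines the static FRET line in
#' E-versus-lifetime plots.
#'
#' @param tau_DA donor lifetime with acceptor present (s), in
#'   `(0, tau_D0]`.
#' @param tau_D0 donor-only lifetime (s).
#' @return FRET efficiency in `[0, 1)`.
#' @export
lifetime_fret <- function(tau_DA, tau_D0) {
  if (any(tau_DA <= 0) || any(tau_D0 <= 0) || any(tau_DA > tau_D0)) {
    stop("need 0 < tau_DA <= tau_D0", call. = FALSE)
  }
  1 - tau_DA / tau_D0
}

#' Gaussian fit of FRET populations
#'
#' Maximum-likelihood Gaussian mixture fit of burst E* values (mclust,
#' unequal variances); a histogram least-squares mode (bin width 0.02) is
#' available as an option.
#'
#' @param E_values burst proximity ratios (NA dropped), at least 50.
#' @param n_components number of Gaussian components.
#' @param method `"mle"` (default) or `"histogram"`.
#' @param bin_width histogram bin width when `method = "histogram"`.
#' @return list of class `population_fit`: `mean`, `sigma`, `weight`
#'   vectors (sorted by mean), `n_components`, `degenerate` flag.
#' @export
fit_population_gaussian <- function(E_values, n_components = 1,
                                    method = c("mle", "histogram"),
                                    bin_width = 0.02) {
  method <- match.arg(method)
  E <- E_values[is.finite(E_values)]
  if (length(E) < 50) stop("need at least 50 bursts", call. = FALSE)
  if (stats::sd(E) < 1e-12) {
    return(structure(list(mean = mean(E), sigma = bin_width / 2,
                          weight = 1, n_components = 1L,
                          degenerate = TRUE),
                     class = "population_fit"))
  }
  if (method == "mle") {
    fit <- mclust::Mclust(E, G = n_components,
                          modelNames = if (n_components == 1) "X" else "V",
                          verbose = FALSE)
    if (is.null(fit)) stop("Gaussian mixture fit failed to converge",
                           call. = FALSE)
    mu <- as.numeric(fit$parameters$mean)
    sig <- sqrt(rep(as.numeric(fit$parameters$variance$sigmasq),
                    length.out = n_components))
    w <- as.numeric(fit$parameters$pro)
    if (is.null(w)) w <- 1
  } else {
    br <- seq(min(E) - bin_width, max(E) + bin_width, by = bin_width)
    h <- graphics::hist(E, breaks = br, plot = FALSE)
    df <- data.frame(x = h$mids, y = h$density)
    km <- stats::kmeans(E, centers = n_components)
    ord <- order(km$centers)
    mu0 <- as.numeric(km$centers)[ord]
    s0 <- pmax(sqrt(km$withinss / km$size)[ord], bin_width)
    w0 <- (km$size / length(E))[ord]
    par0 <- c(mu0, log(s0), log(w0 / w0[1])[-1])
    k <- n_components
    model <- function(p) {
      mu <- p[1:k]; sig <- exp(p[(k + 1):(2 * k)])
      lw <- c(0, p[-(1:(2 * k))]); w <- exp(lw) / sum(exp(lw))
      rowSums(sapply(seq_len(k), function(i)
        w[i] * stats::dnorm(df$x, mu[i], sig[i])))
    }
    fit <- minpack.lm::nls.lm(par0, fn = function(p) df$y - model(p))
    p <- fit$par
    mu <- p[1:k]; sig <- exp(p[(k + 1):(2 * k)])
    lw <- c(0, p[-(1:(2 * k))]); w <- exp(lw) / sum(exp(lw))
  }
  ord <- order(mu)
  structure(list(mean = mu[ord], sigma = sig[ord], weight = w[ord],
                 n_components = as.integer(n_components),
                 degenerate = FALSE),
            class = "population_fit")
}

#' Fraction of bursts outside the main FRET population(s)
#'
#' Fraction of E* values outside the union of the bands
#' `mean_i +/- k_sigma * sigma_i` over the fitted components. Used as an
#' upper-bound screen for poorly sampled low-abundance conformations.
#'
#' @param E_values burst proximity ratios.
#' @param fit a [fit_population_gaussian()] result.
#' @param k_sigma band half-width in sigmas, default 1.
#' @return fraction in `[0, 1]`.
#' @export
fraction_outside <- function(E_values, fit, k_sigma = 1) {
  E <- E_values[is.finite(E_values)]
  inside <- rep(FALSE, length(E))
  for (i in seq_along(fit$mean)) {
    inside <- inside | (E >= fit$mean[i] - k_sigma * fit$sigma[i] &
                          E <= fit$mean[i] + k_sigma * fit$sigma[i])
  }
  mean(!inside)
}

#' Burst variance analysis
#'
#' For each burst, partitions the donor-excitation photons into consecutive
#' windows of `n` photons (trailing partial window dropped), computes the
#' window proximity ratios `#DA / n` and their standard deviation, and
#' compares against the shot-noise semicircle `sqrt(E*(1-E*)/n)`. Dynamic
#' bursts exceed the semicircle; static ones sit on it.
#'
#' @param bursts a `burst_set` from a burst search (photon indices
#'   retained).
#' @param n window size (photons), default 5.
#' @return data.frame of class `bva_result` with per-burst `E_star`,
#'   `sd_E` (window-SD, denominator `n_windows - 1`), `n_windows`,
#'   `semicircle`; bursts with fewer than 2 windows are skipped and counted
#'   in attribute `n_skipped`.
#' @export
bva <- function(bursts, n = 5) {
  if (n < 2) stop("window size n must be at least 2", call. = FALSE)
  stream <- attr(bursts, "stream")
  runs <- attr(bursts, "photon_index")
  if (is.null(stream) || is.null(runs)) {
    stop("bursts must retain photon-level streams (attribute lost?)",
         call. = FALSE)
  }
  lab <- stream_of(stream)
  rows <- list()
  skipped <- 0L
  for (b in seq_along(runs)) {
    i <- runs[[b]]
    dex <- i[lab[i] %in% c("DD", "DA")]
    nw <- length(dex) %/% n
    if (nw < 2) { skipped <- skipped + 1L; next }
    isDA <- lab[dex[seq_len(nw * n)]] == "DA"
    Ew <- colMeans(matrix(isDA, nrow = n))
    Eb <- mean(isDA)
    rows[[length(rows) + 1L]] <-
      data.frame(E_star = Eb, sd_E = stats::sd(Ew), n_windows = nw,
                 semicircle = sqrt(Eb * (1 - Eb) / n))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(E_star = numeric(0), sd_E = numeric(0),
               n_windows = integer(0), semicircle = numeric(0))
  attr(out, "n") <- n
  attr(out, "n_skipped") <- skipped
  class(out) <- c("bva_result", "data.frame")
  out
}

#' Semicircle reference of burst variance analysis
#'
#' Shot-noise standard deviation of window proximity ratios for a static
#' molecule: `sqrt(E (1 - E) / n)`.
#'
#' @param E proximity ratio.
#' @param n window size (photons).
#' @return reference SD.
#' @export
bva_semicircle <- function(E, n) sqrt(E * (1 - E) / n)

#' Hill (n = 1) titration fit
#'
#' Least-squares fit of the closed-state fraction versus ligand
#' concentration with the binding isotherm `f = [L] / (K_d + [L])` (Hill
#' exponent fixed at 1; valid when protein concentration is far below
#' K_d).
#'
#' @param L ligand concentrations (M), at least 3.
#' @param fraction_closed observed closed-state fractions.
#' @return list with `K_d`, `K_d_se`, and the `nls` fit.
#' @export
hill_titration_fit <- function(L, fraction_closed) {
  stopifnot(length(L) == length(fraction_closed))
  if (length(unique(L)) < 3) stop("need at least 3 concentrations",
                                  call. = FALSE)
  f <- fraction_closed
  if (all(f > 0.95) || all(f < 0.05)) {
    warning("titration is all-saturated or all-zero; K_d ill-conditioned")
  }
  df <- data.frame(L = L, f = f)
  fit <- minpack.lm::nlsLM(f ~ L / (Kd + L), data = df,
                           start = list(Kd = stats::median(L)),
                           lower = 0,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  cf <- summary(fit)$coefficients
  list(K_d = cf["Kd", "Estimate"], K_d_se = cf["Kd", "Std. Error"],
       fit = fit)
}
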