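# Independent oracles used across the suite. These deliberately use naive
# direct evaluation (per-photon loops, eigendecomposition, binomial
# sampling) so they stay independent of the package implementations they
# check.

# smallest-magnitude nonzero eigenvalue of a generator matrix
eigen_relaxation_rate <- function(Q) {
  ev <- sort(abs(Re(eigen(Q)$values)))
  ev[2]
}

random_rates <- function(pathway) {
  pathway_rates(k_e = 10^runif(1, -1, 3), k_r = 10^runif(1, -1, 3),
                k_plus = 10^runif(1, 5, 9), k_minus = 10^runif(1, -1, 3),
                pathway = pathway)
}

# brute-force all-photon burst search: per-photon neighborhood count
brute_apbs <- function(stream, window = 500e-6, threshold = 15,
                       min_total = 150) {
  t <- stream$timestamp
  n <- length(t)
  inb <- vapply(seq_len(n), function(i) {
    sum(t >= t[i] - window / 2 & t <= t[i] + window / 2) >= threshold
  }, logical(1))
  lab <- ifelse(stream$excitation == "Dex",
                ifelse(stream$channel == "D", "DD", "DA"),
                ifelse(stream$channel == "A", "AA", "AD"))
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (inb[i]) {
      j <- i
      while (j < n && inb[j + 1L]) j <- j + 1L
      idx <- i:j
      if (sum(lab[idx] != "AD") >= min_total) {
        runs[[length(runs) + 1L]] <- idx
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# brute-force dual-channel search: per-photon membership in m-photon
# windows meeting the rate criterion, evaluated by direct scan
brute_dcbs <- function(stream, m = 10, F_mult = 6, min_D = 50, min_A = 50,
                       bg_Dex, bg_Aex) {
  t <- stream$timestamp
  lab <- ifelse(stream$excitation == "Dex",
                ifelse(stream$channel == "D", "DD", "DA"),
                ifelse(stream$channel == "A", "AA", "AD"))
  hot_intervals <- function(ts, rate) {
    n <- length(ts)
    hot <- logical(n)
    if (n >= m) {
      for (j in 1:(n - m + 1)) {
        if (ts[j + m - 1] - ts[j] <= m / (F_mult * rate)) {
          hot[j:(j + m - 1)] <- TRUE
        }
      }
    }
    iv <- NULL
    i <- 1L
    while (i <= n) {
      if (hot[i]) {
        j <- i
        while (j < n && hot[j + 1L]) j <- j + 1L
        iv <- rbind(iv, c(ts[i], ts[j]))
        i <- j + 1L
      } else i <- i + 1L
    }
    if (is.null(iv)) matrix(numeric(0), ncol = 2) else iv
  }
  ivD <- hot_intervals(t[lab %in% c("DD", "DA")], bg_Dex)
  ivA <- hot_intervals(t[lab == "AA"], bg_Aex)
  in_iv <- function(x, iv) {
    if (nrow(iv) == 0) return(rep(FALSE, length(x)))
    sapply(x, function(xx) any(xx >= iv[, 1] & xx <= iv[, 2]))
  }
  both <- in_iv(t, ivD) & in_iv(t, ivA)
  runs <- list()
  i <- 1L
  n <- length(t)
  while (i <= n) {
    if (both[i]) {
      j <- i
      while (j < n && both[j + 1L]) j <- j + 1L
      idx <- i:j
      if (sum(lab[idx] %in% c("DD", "DA")) >= min_D &&
          sum(lab[idx] == "AA") >= min_A) {
        runs[[length(runs) + 1L]] <- idx
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  runs
}

# a hand-built photon stream: vectors of times with given stream labels
make_stream <- function(t, lab) {
  stopifnot(length(t) == length(lab))
  o <- order(t)
  data.frame(timestamp = t[o],
             channel = ifelse(lab[o] %in% c("DA", "AA"), "A", "D"),
             excitation = ifelse(lab[o] == "AA", "Aex", "Dex"))[
               , c("timestamp", "channel", "excitation")]
}

# Monte-Carlo binomial oracle for the BVA window-SD statistic: draws
# windows as iid Binomial(n, E)/n and returns per-burst sample SDs
binomial_bva_oracle <- function(E, n, n_windows, n_bursts) {
  vapply(seq_len(n_bursts), function(b) {
    sd(rbinom(n_windows, n, E) / n)
  }, numeric(1))
}
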