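# Independent oracle implementations used to cross-check the package.
# Each is coded directly from first principles / the published equations,
# separately from the package internals.

# pure-tone atmospheric absorption, dB/m, re-derived from the standard's
# published equations (structured differently from the package version:
# explicit intermediate quantities, pressure handled in atm).
iso_alpha_oracle <- function(f_khz, temp_c = 20, rh = 60, p_kpa = 101.325) {
  f <- f_khz * 1e3
  Tk <- temp_c + 273.15
  p_atm <- p_kpa / 101.325
  # saturation vapour pressure over the reference pressure, then the
  # molar water concentration in percent
  C_exp <- -6.8346 * (273.16 / Tk)^1.261 + 4.6151
  h_pct <- rh * (10^C_exp) / p_atm
  theta <- Tk / 293.15
  frO <- p_atm * (24 + 40400 * h_pct * (0.02 + h_pct) / (0.391 + h_pct))
  frN <- p_atm / sqrt(theta) *
    (9 + 280 * h_pct * exp(-4.170 * (theta^(-1 / 3) - 1)))
  term_cl <- 1.84e-11 / p_atm * sqrt(theta)
  term_O <- 0.01275 * exp(-2239.1 / Tk) * (frO + f^2 / frO)^-1
  term_N <- 0.1068 * exp(-3352 / Tk) * (frN + f^2 / frN)^-1
  8.686 * f^2 * (term_cl + theta^(-5 / 2) * (term_O + term_N))
}

# exhaustive 1 mm grid search for the sonar-equation root
grid_distance_oracle <- function(SL, alpha, thr, mode = "one_way",
                                 r_max = 2000) {
  spread <- if (mode == "one_way") 20 else 40
  aeff <- if (mode == "one_way") alpha else 2 * alpha
  r <- seq(1, r_max, by = 0.001)
  excess <- SL - spread * log10(r) - aeff * r - thr
  r[which.min(abs(excess))]
}

# exhaustive window scan for maximal feeding-buzz runs: returns a
# data.frame of (first, last) call indices of every maximal contiguous
# window whose internal intervals are all <= max_iv and which has at
# least min_int intervals.
buzz_windows_oracle <- function(times_ms, max_iv = 10, min_int = 3) {
  n <- length(times_ms)
  found <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i < min_int) next
      iv <- diff(times_ms[i:j])
      if (any(iv > max_iv)) next
      # maximality: cannot extend left or right
      left_ok <- i == 1 || (times_ms[i] - times_ms[i - 1]) > max_iv
      right_ok <- j == n || (times_ms[j + 1] - times_ms[j]) > max_iv
      if (left_ok && right_ok)
        found[[length(found) + 1]] <- c(first = i, last = j)
    }
  }
  if (length(found) == 0)
    return(data.frame(first = integer(), last = integer()))
  unique(as.data.frame(do.call(rbind, found)))
}

# O(n^2) partition scan: number of clusters when elements are merged
# whenever some chain of pairwise gaps <= max_gap connects them
# (transitive closure of the proximity relation).
partition_count_oracle <- function(times, max_gap) {
  A <- abs(outer(times, times, "-")) <= max_gap
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  nrow(unique(A))
}

# closed-form least-squares intersection of two rays (normal equations)
ls_two_ray_oracle <- function(o1, d1, o2, d2) {
  A <- cbind(d1, -d2)
  rhs <- o2 - o1
  ts <- solve(t(A) %*% A, t(A) %*% rhs)
  p1 <- o1 + ts[1] * d1
  p2 <- o2 + ts[2] * d2
  (p1 + p2) / 2
}

# orthonormal polynomial contrasts built by Gram-Schmidt on the
# Vandermonde matrix of level indices
gram_schmidt_poly_oracle <- function(n, degree) {
  X <- outer(seq_len(n), 0:degree, `^`)
  Q <- qr.Q(qr(X))[, -1, drop = FALSE]   # drop the constant column
  # fix signs so leading entries of each column follow contr.poly's
  # convention (last element positive)
  for (k in seq_len(ncol(Q))) if (Q[n, k] < 0) Q[, k] <- -Q[, k]
  Q
}

# expected species(-group) assignment for a synthetic single-species
# sequence: species with their own end-frequency band are identifiable,
# the rest resolve to the Nyctaloid group
expected_assignment <- function(species) {
  own_band <- c("Nyctalus noctula", "Pipistrellus nathusii",
                "Pipistrellus pipistrellus", "Pipistrellus pygmaeus")
  ifelse(species %in% own_band, species, "Nyctaloid")
}
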