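# Independent oracles and small fixture builders shared across tests.
# These deliberately avoid the package's own code paths.

# 1:1 speciation by bisection on the mass-balance residual
bisect_complex <- function(H0, G0, K, iter = 300L) {
  f <- function(x) K * (H0 - x) * (G0 - x) - x
  lo <- 0; hi <- min(H0, G0)
  if (f(hi) >= 0) return(hi)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# cumulative-heat ITC oracle: explicit concentration bookkeeping, heats as
# finite differences of the expelled-volume-corrected cumulative heat
oracle_itc_heats <- function(cell0, syr, V0, vols, n, K, dH) {
  N <- length(vols)
  M <- numeric(N); X <- numeric(N)
  m <- cell0; x <- 0
  for (i in seq_len(N)) {
    f <- 1 - vols[i] / V0
    m <- m * f
    x <- x * f + syr * vols[i] / V0
    M[i] <- m; X[i] <- x
  }
  bound <- vapply(seq_len(N), function(i) bisect_complex(n * M[i], X[i], K), 0)
  Q <- dH * V0 * bound
  q <- numeric(N)
  prev <- 0
  for (i in seq_len(N)) {
    q[i] <- Q[i] - prev * (1 - vols[i] / V0)
    prev <- Q[i]
  }
  q
}

# random rigid motion (proper rotation + translation), seeded
rigid_motion <- function(seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_motion <- function(structure, motion) {
  P <- as.matrix(structure[, c("x", "y", "z")]) %*% t(motion$R)
  P <- sweep(P, 2, motion$t, "+")
  structure_coordinates(structure$atom_id, structure$element,
                        P[, 1], P[, 2], P[, 3])
}

# regular hexagon "ring" centred at origin in the xy-plane
hexagon_structure <- function(extra = NULL, r = 1.39) {
  th <- 2 * pi * (0:5) / 6
  ids <- paste0("R", 1:6)
  el <- rep("C", 6)
  x <- r * cos(th); y <- r * sin(th); z <- rep(0, 6)
  if (!is.null(extra)) {
    ids <- c(ids, extra$atom_id); el <- c(el, extra$element)
    x <- c(x, extra$x); y <- c(y, extra$y); z <- c(z, extra$z)
  }
  structure_coordinates(ids, el, x, y, z)
}

# noiseless NH titration series at the stated design
nh_series <- function(K, H0 = 1.6e-3, max_equiv = 12, n_points = 14,
                      delta_free = 8.0, delta_bound = 10.0) {
  generate_nmr_titration(nmr_scenario(
    K_true = K, H0 = H0,
    equivalents = seq(0, max_equiv, length.out = n_points),
    signals = list(NH = list(owner = "host", delta_free = delta_free,
                             delta_bound = delta_bound)),
    noise_sd = 0))
}
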