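#' Exact 1:1 host-guest speciation
#'
#' Solves the mass-balance equations for a single H + G = HG equilibrium:
#' given total concentrations `H0`, `G0` and association constant `K`, the
#' complex concentration is the smaller root of
#' \eqn{K x^2 - (K H_0 + K G_0 + 1) x + K H_0 G_0 = 0}, evaluated in the
#' numerically stable subtractive form with a bisection fallback when the
#' discriminant underflows. Vectorised over `H0` and `G0`.
#'
#' @param H0 total host concentration(s), M; > 0.
#' @param G0 total guest concentration(s), M; >= 0.
#' @param K association constant, M^-1; > 0.
#' @return A data.frame of class `species_concentrations` with columns
#'   `free_host`, `free_guest`, `complex` (all M).
#' @export
#' @examples
#' solve_1to1(1.6e-3, 3.2e-3, 5150)
solve_1to1 <- function(H0, G0, K) {
  if (any(!is.finite(H0)) || any(H0 <= 0)) {
    stop("H0 must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(G0)) || any(G0 < 0)) {
    stop("G0 must be finite and >= 0", call. = FALSE)
  }
  stopifnot(length(K) == 1L, is.finite(K), K > 0)
  n <- max(length(H0), length(G0))
  H0 <- rep_len(H0, n); G0 <- rep_len(G0, n)
  x <- .complex_1to1(H0, G0, K)
  structure(data.frame(free_host = H0 - x, free_guest = G0 - x, complex = x),
            class = c("species_concentrations", "data.frame"))
}

# numeric kernel: complex concentration only, no container overhead
.complex_1to1 <- function(H0, G0, K) {
  b <- H0 + G0 + 1 / K
  disc <- b * b - 4 * H0 * G0
  disc[disc < 0] <- 0
  # smaller root via the conjugate form: 2*H0*G0 / (b + sqrt(disc)) avoids
  # cancellation of b - sqrt(disc) when 4*H0*G0 << b^2
  x <- 2 * H0 * G0 / (b + sqrt(disc))
  x <- pmin(x, pmin(H0, G0))
  # two Newton polish steps take the root to machine precision
  for (it in 1:2) {
    f <- K * (H0 - x) * (G0 - x) - x
    fp <- K * (2 * x - H0 - G0) - 1
    step <- f / fp
    xn <- x - step
    ok <- is.finite(xn) & xn >= 0 & xn <= pmin(H0, G0)
    x[ok] <- xn[ok]
  }
  # bisection fallback where the polished form still fails the residual
  bad <- which(!.speciation_ok(H0, G0, K, x))
  for (i in bad) x[i] <- .bisect_1to1(H0[i], G0[i], K)
  x
}

.speciation_ok <- function(H0, G0, K, x, tol = 1e-10) {
  fh <- H0 - x; fg <- G0 - x
  res <- K * fh * fg - x
  scale <- pmax(x, K * H0 * G0, .Machine$double.xmin)
  fh >= 0 & fg >= 0 & abs(res) / scale <= tol
}

.bisect_1to1 <- function(H0, G0, K, iter = 200L) {
  f <- function(x) K * (H0 - x) * (G0 - x) - x
  lo <- 0; hi <- min(H0, G0)
  if (f(hi) >= 0) return(hi)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Predicted fast-exchange NMR chemical shift
#'
#' Under fast exchange the observed shift is the population-weighted average
#' of the free and bound shifts. The bound fraction is `[HG]/H0` for a
#' host-owned signal and `[HG]/G0` for a guest-owned signal.
#'
#' @param H0,G0 total concentrations, M (vectorised).
#' @param K association constant, M^-1.
#' @param delta_free,delta_bound limiting shifts, ppm.
#' @param owner `"host"` or `"guest"` — which species the nucleus belongs to.
#' @return Observed shift(s), ppm. A guest-owned signal at `G0 = 0` has no
#'   defined shift and errors.
#' @export
predict_shift <- function(H0, G0, K, delta_free, delta_bound,
                          owner = c("host", "guest")) {
  owner <- match.arg(owner)
  sp <- solve_1to1(H0, G0, K)
  if (owner == "guest" && any(G0 <= 0)) {
    stop("guest-owned signal undefined at G0 = 0 (no guest present)",
         call. = FALSE)
  }
  f_bound <- if (owner == "host") sp$complex / rep_len(H0, nrow(sp))
             else sp$complex / rep_len(G0, nrow(sp))
  delta_free + f_bound * (delta_bound - delta_free)
}

#' NMR titration series container
#'
#' @param H0,G0 per-point total host and guest concentrations, M.
#' @param shifts data.frame or matrix, one column per signal, ppm; row i is
#'   titration point i.
#' @param owners character vector, `"host"`/`"guest"` per signal.
#' @param temperature K.
#' @return A `titration_series` object.
#' @export
titration_series <- function(H0, G0, shifts, owners, temperature = 298.0) {
  shifts <- as.data.frame(shifts)
  n <- length(H0)
  if (n < 2L) stop("a titration needs at least 2 points", call. = FALSE)
  if (length(G0) != n || nrow(shifts) != n) {
    stop("H0, G0 and shift columns must have the same length", call. = FALSE)
  }
  if (length(owners) != ncol(shifts)) {
    stop("one owner per signal column required", call. = FALSE)
  }
  if (!all(owners %in% c("host", "guest"))) {
    stop("owners must be 'host' or 'guest'", call. = FALSE)
  }
  if (any(H0 <= 0) || any(G0 < 0)) {
    stop("require H0 > 0 and G0 >= 0", call. = FALSE)
  }
  owners <- stats::setNames(owners, colnames(shifts))
  structure(list(H0 = H0, G0 = G0, shifts = shifts, owners = owners,
                 temperature = temperature),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("NMR titration: %d points, %d signal(s) [%s], T = %g K\n",
              length(x$H0), ncol(x$shifts),
              paste(colnames(x$shifts), collapse = ", "), x$temperature))
  invisible(x)
}

#' ITC experiment container
#'
#' @param cell_conc initial host concentration in the cell, M.
#' @param syringe_conc guest concentration in the syringe, M.
#' @param cell_volume active cell volume, L.
#' @param injection_volumes per-injection volumes, L.
#' @param heats measured heat per injection, kcal (same length as
#'   `injection_volumes`); may be `NULL` for a design not yet measured.
#' @param temperature K (the experiment temperature; free energies are
#'   reported at the analysis temperature, stored separately on fit results).
#' @return An `itc_experiment` object.
#' @export
itc_experiment <- function(cell_conc, syringe_conc, cell_volume,
                           injection_volumes, heats = NULL,
                           temperature = 298.0) {
  stopifnot(cell_conc > 0, syringe_conc > 0)
  if (cell_volume <= 0) stop("cell volume must be > 0", call. = FALSE)
  if (any(injection_volumes <= 0)) {
    stop("injection volumes must be > 0", call. = FALSE)
  }
  if (!is.null(heats) && length(heats) != length(injection_volumes)) {
    stop("one heat per injection required", call. = FALSE)
  }
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 heats = heats, temperature = temperature),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf(
    "ITC experiment: cell %.3g mM / %.3g mL, syringe %.3g mM, %d injections, T = %g K\n",
    x$cell_conc * 1e3, x$cell_volume * 1e3, x$syringe_conc * 1e3,
    length(x$injection_volumes), x$temperature))
  invisible(x)
}

#' Predicted heat per injection for a 1:1 ITC titration
#'
#' Wiseman-type forward model with the perfusion (overfilled cell) dilution
#' convention: each injection of volume \eqn{v_i} displaces an equal volume
#' of cell liquid, so both total concentrations are scaled by
#' \eqn{1 - v_i/V_0} before the new guest is added. After injection i the
#' complex concentration `bound_i` comes from [solve_1to1()] with the host
#' site concentration `n * host_total`, and
#' \deqn{q_i = \Delta H \, V_0 \, (bound_i - bound_{i-1}(1 - v_i/V_0)).}
#' At saturation the heats telescope so that their sum equals
#' \eqn{n \Delta H} times the initial moles of host in the cell.
#'
#' @param exp an [itc_experiment()] (its `heats` are ignored).
#' @param n stoichiometry (site number), > 0.
#' @param K association constant, M^-1.
#' @param dH molar enthalpy of binding, kcal mol^-1.
#' @return Numeric vector of heats per injection, kcal.
#' @export
predict_itc_heats <- function(exp, n = 1, K, dH) {
  stopifnot(inherits(exp, "itc_experiment"), n > 0, K > 0)
  V0 <- exp$cell_volume
  vols <- exp$injection_volumes
  heats <- numeric(length(vols))
  M <- exp$cell_conc; X <- 0; bound_prev <- 0
  for (i in seq_along(vols)) {
    f <- 1 - vols[i] / V0
    if (f <= 0) stop("injection volume exceeds cell volume", call. = FALSE)
    M <- M * f
    X <- X * f + exp$syringe_conc * vols[i] / V0
    bound <- if (X > 0) .complex_1to1(n * M, X, K) else 0
    heats[i] <- dH * V0 * (bound - bound_prev * f)
    bound_prev <- bound
  }
  heats
}

#' Wiseman c-parameter
#'
#' `c = n * K * cell_conc`; gauges how sharply the isotherm bends and hence
#' whether K is determinable from curve shape (conventionally 1-1000).
#'
#' @inheritParams predict_itc_heats
#' @return Dimensionless c.
#' @export
wiseman_c <- function(exp, n = 1, K) {
  stopifnot(inherits(exp, "itc_experiment"))
  n * K * exp$cell_conc
}
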