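#' Binding fit result
#'
#' Container for an association constant determined from titration data,
#' with asymptotic uncertainties and the derived free energy
#' \eqn{\Delta G = -RT\ln K} at the analysis temperature.
#'
#' @keywords internal
binding_result <- function(host_id = NA_character_, guest_id = NA_character_,
                           K, K_sigma, method, temperature = 298.0,
                           n = NA_real_, n_sigma = NA_real_,
                           dH = NA_real_, dH_sigma = NA_real_,
                           rms = NA_real_, converged = TRUE,
                           signal_params = NULL, boot = NULL,
                           const = thermo_constants(temperature)) {
  dG <- if (is.finite(K)) K_to_free_energy(K, const) else NA_real_
  # sigma(dG) = RT * sigma(K)/K  (delta method on -RT ln K)
  dG_sigma <- if (is.finite(K) && is.finite(K_sigma)) {
    const$R * const$T * K_sigma / K
  } else NA_real_
  structure(list(host_id = host_id, guest_id = guest_id,
                 K = K, K_sigma = K_sigma, dG = dG, dG_sigma = dG_sigma,
                 method = method, temperature = temperature,
                 n = n, n_sigma = n_sigma, dH = dH, dH_sigma = dH_sigma,
                 fit_diagnostics = list(rms = rms, converged = converged),
                 signal_params = signal_params, boot = boot),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  lab <- if (!is.na(x$host_id)) sprintf(" %s@%s", x$guest_id, x$host_id) else ""
  cat(sprintf("1:1 binding fit (%s)%s\n", x$method, lab))
  cat(sprintf("  K    = %.4g +/- %.2g M^-1\n", x$K, x$K_sigma))
  cat(sprintf("  dG   = %.3f +/- %.3f kcal/mol at %g K\n",
              x$dG, x$dG_sigma, x$temperature))
  if (is.finite(x$dH)) {
    cat(sprintf("  dH   = %.3f +/- %.3f kcal/mol, n = %.3f\n",
                x$dH, x$dH_sigma, x$n))
  }
  cat(sprintf("  rms residual %.3g; converged: %s\n",
              x$fit_diagnostics$rms, x$fit_diagnostics$converged))
  invisible(x)
}

# bound fraction per signal given K, honouring ownership; NA where undefined
.fraction_bound <- function(H0, G0, K, owner) {
  x <- .complex_1to1(H0, G0, K)
  if (owner == "host") x / H0 else ifelse(G0 > 0, x / G0, NA_real_)
}

# profiled RSS over log10(K): limiting shifts enter linearly per signal
.nmr_profile <- function(series, log10K) {
  K <- 10^log10K
  rss <- 0
  coefs <- list()
  for (s in names(series$owners)) {
    fb <- .fraction_bound(series$H0, series$G0, K, series$owners[[s]])
    y <- series$shifts[[s]]
    ok <- is.finite(fb) & is.finite(y)
    fit <- stats::lm.fit(cbind(1, fb[ok]), y[ok])
    rss <- rss + sum(fit$residuals^2)
    coefs[[s]] <- c(delta_free = unname(fit$coefficients[1]),
                    delta_bound = unname(sum(fit$coefficients)))
  }
  list(rss = rss, coefs = coefs)
}

.num_jacobian <- function(fn, par, eps = 1e-6) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

#' Fit a 1:1 binding model to an NMR titration (global shared-K fit)
#'
#' Minimises the summed squared shift residuals over all signals with a
#' single shared association constant. The optimisation is over
#' \eqn{\log_{10} K} (positivity and conditioning); for each K the limiting
#' shifts enter linearly and are profiled out, so the search is
#' one-dimensional, started from an 8-point log-spaced grid spanning
#' 10^-1 to 10^8 M^-1 to avoid local minima. Standard errors come from the
#' residual-variance-scaled parameter covariance of the full
#' (K, per-signal delta_free/delta_bound) problem.
#'
#' @param series a [titration_series()].
#' @param init optional starting K, M^-1 (added to the multi-start grid).
#' @param noise_floor ppm; if no signal moves by more than this across the
#'   titration, K is unidentifiable and an error is thrown.
#' @param host_id,guest_id labels carried into the result.
#' @param const [thermo_constants()] used for the dG conversion.
#' @return A `binding_result` with per-signal fitted limiting shifts in
#'   `$signal_params`.
#' @export
fit_nmr_titration <- function(series, init = NULL, noise_floor = 1e-4,
                              host_id = NA_character_,
                              guest_id = NA_character_,
                              const = thermo_constants()) {
  stopifnot(inherits(series, "titration_series"))
  nsig <- ncol(series$shifts)
  npts <- sum(is.finite(as.matrix(series$shifts)))
  npar <- 1L + 2L * nsig
  if (npts <= npar) {
    stop("need more shift observations (", npts, ") than free parameters (",
         npar, ")", call. = FALSE)
  }
  ranges <- vapply(series$shifts,
                   function(y) diff(range(y[is.finite(y)])), 0)
  if (max(ranges) < noise_floor) {
    stop("K unidentifiable: all signals flat (max |delta shift| ",
         signif(max(ranges), 3), " ppm below the noise floor)", call. = FALSE)
  }

  grid <- seq(-1, 8, length.out = 8L)
  if (!is.null(init)) grid <- sort(c(grid, log10(init)))
  vals <- vapply(grid, function(lk) .nmr_profile(series, lk)$rss, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(lk) .nmr_profile(series, lk)$rss,
                         c(lo, hi), tol = 1e-10)
  log10K <- opt$minimum
  prof <- .nmr_profile(series, log10K)
  K <- 10^log10K
  converged <- log10K > min(grid) + 1e-6 && log10K < max(grid) - 1e-6

  # full-parameter residuals for the covariance: (log10K, df_s, db_s, ...)
  sig_names <- names(series$owners)
  par <- c(log10K, unlist(prof$coefs, use.names = FALSE))
  resid_fn <- function(p) {
    Kp <- 10^p[1]
    out <- c()
    for (j in seq_along(sig_names)) {
      s <- sig_names[j]
      fb <- .fraction_bound(series$H0, series$G0, Kp, series$owners[[s]])
      y <- series$shifts[[s]]
      ok <- is.finite(fb) & is.finite(y)
      df <- p[2 * j]; db <- p[2 * j + 1]
      out <- c(out, (df + fb[ok] * (db - df)) - y[ok])
    }
    out
  }
  r <- resid_fn(par)
  dof <- length(r) - length(par)
  s2 <- sum(r^2) / max(dof, 1L)
  J <- .num_jacobian(resid_fn, par)
  cv <- try(s2 * solve(crossprod(J)), silent = TRUE)
  if (inherits(cv, "try-error")) {
    se <- rep(NA_real_, length(par))
    converged <- FALSE
  } else {
    se <- sqrt(pmax(diag(cv), 0))
  }
  K_sigma <- log(10) * K * se[1]

  sp <- data.frame(signal = sig_names,
                   owner = unname(series$owners[sig_names]),
                   delta_free = vapply(prof$coefs, `[[`, 0, "delta_free"),
                   delta_bound = vapply(prof$coefs, `[[`, 0, "delta_bound"),
                   delta_free_se = se[2 * seq_along(sig_names)],
                   delta_bound_se = se[2 * seq_along(sig_names) + 1L],
                   row.names = NULL)

  fitted_all <- resid_fn(par) + unlist(lapply(sig_names, function(s) {
    y <- series$shifts[[s]]
    fb <- .fraction_bound(series$H0, series$G0, K, series$owners[[s]])
    y[is.finite(fb) & is.finite(y)]
  }))
  res <- binding_result(host_id, guest_id, K, K_sigma, "NMR",
                        temperature = const$T,
                        rms = sqrt(mean(r^2)), converged = converged,
                        signal_params = sp, const = const)
  res$boot <- list(fitted = fitted_all, residuals = r,
                   refit = function(ynew) {
                     s2 <- series
                     idx <- 1L
                     for (s in sig_names) {
                       y <- s2$shifts[[s]]
                       fb <- .fraction_bound(s2$H0, s2$G0, K, s2$owners[[s]])
                       ok <- is.finite(fb) & is.finite(y)
                       y[ok] <- ynew[idx:(idx + sum(ok) - 1L)]
                       idx <- idx + sum(ok)
                       s2$shifts[[s]] <- y
                     }
                     g2 <- sort(c(grid, log10(K)))
                     v2 <- vapply(g2, function(lk) .nmr_profile(s2, lk)$rss, 0)
                     i2 <- which.min(v2)
                     10^stats::optimize(function(lk) .nmr_profile(s2, lk)$rss,
                                        c(g2[max(1L, i2 - 1L)],
                                          g2[min(length(g2), i2 + 1L)]),
                                        tol = 1e-10)$minimum
                   })
  res
}

#' Fit a 1:1 binding model to an ITC thermogram
#'
#' Levenberg-Marquardt least squares of the [predict_itc_heats()] forward
#' model against the measured heats, over \eqn{(\log_{10}K, \Delta H)} with
#' the stoichiometry n fixed at 1 by default, or \eqn{(\log_{10}K, \Delta H,
#' n)} when `float_n = TRUE`. Multi-start over a log-spaced K grid. The
#' first injection is excluded by default (syringe-tip diffusion artefact
#' convention); reference/dilution heats are assumed already subtracted.
#'
#' A warning is issued when the Wiseman c-parameter falls outside [1, 1000],
#' where the isotherm shape carries little information about K. Floating n
#' with a titration that does not reach the equivalence point leaves (n, K)
#' jointly poorly determined; fixing the known stoichiometry is recommended
#' in that regime.
#'
#' @param exp an [itc_experiment()] with measured `heats`.
#' @param float_n fit the stoichiometry n as a free parameter.
#' @param exclude_first drop injection 1 from the fit.
#' @param init optional named list with any of `K`, `dH`, `n` start values.
#' @param host_id,guest_id labels carried into the result.
#' @param const [thermo_constants()] for the dG conversion (reporting
#'   temperature; the experiment temperature stays on `exp`).
#' @return A `binding_result` with `n`, `dH` and their uncertainties.
#' @export
fit_itc <- function(exp, float_n = FALSE, exclude_first = TRUE, init = NULL,
                    host_id = NA_character_, guest_id = NA_character_,
                    const = thermo_constants()) {
  stopifnot(inherits(exp, "itc_experiment"))
  if (is.null(exp$heats)) stop("experiment has no measured heats", call. = FALSE)
  heats <- exp$heats
  use <- seq_along(heats)
  if (exclude_first) use <- use[-1L]
  if (length(use) < 5L) {
    stop("need at least 5 usable injections", call. = FALSE)
  }

  if (max(abs(heats[use])) < 1e-15) {
    return(binding_result(host_id, guest_id, K = NA_real_, K_sigma = NA_real_,
                          method = "ITC", temperature = const$T,
                          n = if (float_n) NA_real_ else 1,
                          dH = 0, dH_sigma = 0, rms = 0, converged = FALSE,
                          const = const))
  }

  mol_inj <- exp$injection_volumes * exp$syringe_conc
  dH0 <- if (!is.null(init$dH)) init$dH else sum(heats) / sum(mol_inj)
  n0 <- if (!is.null(init$n)) init$n else 1
  resid_fn <- function(p) {
    K <- 10^p[1]; dH <- p[2]; n <- if (float_n) p[3] else 1
    if (n <= 0) return(rep(1e6, length(use)))
    predict_itc_heats(exp, n = n, K = K, dH = dH)[use] - heats[use]
  }
  starts <- seq(-1, 8, length.out = 8L)
  if (!is.null(init$K)) starts <- c(log10(init$K), starts)
  best <- NULL
  for (lk in starts) {
    p0 <- c(lk, dH0, if (float_n) n0)
    f <- try(minpack.lm::nls.lm(p0, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) {
    return(binding_result(host_id, guest_id, NA_real_, NA_real_, "ITC",
                          temperature = const$T, converged = FALSE,
                          const = const))
  }
  par <- best$par
  K <- 10^par[1]; dH <- par[2]; n <- if (float_n) par[3] else 1
  converged <- best$info %in% 1:4

  cpar <- wiseman_c(exp, n = n, K = K)
  if (cpar < 1 || cpar > 1000) {
    warning(sprintf(
      "Wiseman c-parameter %.3g outside [1, 1000]: isotherm poorly conditioned for K",
      cpar), call. = FALSE)
  }

  r <- resid_fn(par)
  dof <- length(r) - length(par)
  s2 <- sum(r^2) / max(dof, 1L)
  J <- .num_jacobian(resid_fn, par)
  cv <- try(s2 * solve(crossprod(J)), silent = TRUE)
  se <- if (inherits(cv, "try-error")) rep(NA_real_, length(par))
        else sqrt(pmax(diag(cv), 0))
  res <- binding_result(host_id, guest_id, K,
                        K_sigma = log(10) * K * se[1],
                        method = "ITC", temperature = const$T,
                        n = n, n_sigma = if (float_n) se[3] else 0,
                        dH = dH, dH_sigma = se[2],
                        rms = sqrt(mean(r^2)), converged = converged,
                        const = const)
  res$boot <- list(fitted = heats[use] - r, residuals = r,
                   refit = function(ynew) {
                     rf <- function(p) {
                       Kp <- 10^p[1]; dHp <- p[2]
                       np <- if (float_n) p[3] else 1
                       if (np <= 0) return(rep(1e6, length(use)))
                       predict_itc_heats(exp, n = np, K = Kp, dH = dHp)[use] - ynew
                     }
                     f <- minpack.lm::nls.lm(par, fn = rf,
                                             control = minpack.lm::nls.lm.control(maxiter = 200))
                     10^f$par[1]
                   })
  res
}

#' Bootstrap uncertainty for a fitted association constant
#'
#' Residual-resampling bootstrap: synthetic observation vectors are drawn as
#' fitted + resampled residuals (with replacement) and refit; the empirical
#' sd and percentile interval of the refitted K are returned. Deterministic
#' under a fixed seed.
#'
#' @param result a converged `binding_result` from [fit_nmr_titration()] or
#'   [fit_itc()].
#' @param n_boot number of bootstrap replicates (>= 10).
#' @param seed integer RNG seed.
#' @param level confidence level for the percentile interval.
#' @return List with `K_sigma` (bootstrap sd), `ci` (percentile interval),
#'   and `K_boot` (the replicate estimates).
#' @export
bootstrap_uncertainty <- function(result, n_boot = 200L, seed = 1L,
                                  level = 0.95) {
  stopifnot(inherits(result, "binding_result"))
  if (n_boot < 10L) stop("n_boot must be >= 10", call. = FALSE)
  if (is.null(result$boot)) {
    stop("result carries no refit information (was the fit flagged?)",
         call. = FALSE)
  }
  if (!isTRUE(result$fit_diagnostics$converged)) {
    stop("refusing to bootstrap a non-converged fit", call. = FALSE)
  }
  rng <- .seeded_rng(seed)
  fitted <- result$boot$fitted
  res <- result$boot$residuals
  Ks <- vapply(seq_len(n_boot), function(b) {
    ynew <- fitted + rng$sample(res)
    result$boot$refit(ynew)
  }, 0)
  a <- (1 - level) / 2
  list(K_sigma = stats::sd(Ks),
       ci = stats::quantile(Ks, c(a, 1 - a), names = FALSE),
       K_boot = Ks)
}

# local RNG that never touches the global .Random.seed
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  with_state <- function(fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- fn()
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample = function(x) with_state(function() sample(x, length(x), replace = TRUE))
  )
}
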