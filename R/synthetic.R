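#' NMR titration scenario
#'
#' Defaults emulate the bench protocol for these systems: a 1.6 mM host
#' solution titrated with guest to 12 equivalents over 14 points (saturation
#' needs > 10 equivalents at K ~ 5e3), a pyrrole NH signal moving 2 ppm
#' downfield on binding, and 0.005 ppm Gaussian shift noise (routine 400 MHz
#' readout precision).
#'
#' @param K_true true association constant, M^-1.
#' @param H0 initial total host concentration, M.
#' @param equivalents non-decreasing guest/host molar ratios, one per point.
#' @param signals named list; each element
#'   `list(owner = "host"|"guest", delta_free =, delta_bound =)` in ppm.
#' @param noise_sd Gaussian shift noise, ppm.
#' @param dilution if TRUE, host dilution by the added guest stock is
#'   modelled explicitly (requires `guest_stock`); if FALSE the host total
#'   is held constant (guest added as solid or from a host-matched stock).
#' @param guest_stock guest stock concentration, M (dilution schedule only).
#' @param temperature K.
#' @param seed integer seed owned by the scenario.
#' @return An `nmr_scenario`.
#' @export
nmr_scenario <- function(K_true, H0 = 1.6e-3,
                         equivalents = seq(0, 12, length.out = 14),
                         signals = list(NH = list(owner = "host",
                                                  delta_free = 8.0,
                                                  delta_bound = 10.0)),
                         noise_sd = 0.005, dilution = FALSE,
                         guest_stock = NULL, temperature = 298.0, seed = 1L) {
  stopifnot(K_true > 0, H0 > 0, noise_sd >= 0, length(equivalents) >= 2L)
  if (is.unsorted(equivalents)) {
    stop("equivalents must be non-decreasing", call. = FALSE)
  }
  if (dilution && is.null(guest_stock)) {
    stop("dilution schedule needs a guest_stock concentration", call. = FALSE)
  }
  structure(list(K_true = K_true, H0 = H0, equivalents = equivalents,
                 signals = signals, noise_sd = noise_sd, dilution = dilution,
                 guest_stock = guest_stock, temperature = temperature,
                 seed = as.integer(seed)),
            class = "nmr_scenario")
}

#' Simulate an NMR titration from a scenario
#'
#' Applies the fast-exchange forward model ([predict_shift()]) at the
#' scenario's true K and adds iid Gaussian noise. Pure function of the
#' scenario (including its seed); the global RNG state is not touched.
#'
#' @param scenario an [nmr_scenario()].
#' @param path optional CSV path; when given the series is also written via
#'   [write_nmr_titration()].
#' @return A [titration_series()].
#' @export
generate_nmr_titration <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "nmr_scenario"))
  V0 <- 1  # arbitrary; only ratios matter
  n_host0 <- scenario$H0 * V0
  if (scenario$dilution) {
    v_add <- scenario$equivalents * n_host0 / scenario$guest_stock
    H0 <- n_host0 / (V0 + v_add)
    G0 <- scenario$equivalents * n_host0 / (V0 + v_add)
  } else {
    H0 <- rep(scenario$H0, length(scenario$equivalents))
    G0 <- scenario$equivalents * scenario$H0
  }
  rng <- .seeded_rng(scenario$seed)
  shifts <- lapply(scenario$signals, function(sg) {
    keep <- sg$owner == "host" | G0 > 0
    d <- rep(NA_real_, length(G0))
    d[keep] <- predict_shift(H0[keep], G0[keep], scenario$K_true,
                             sg$delta_free, sg$delta_bound, sg$owner)
    d + rng$norm(length(d), 0, scenario$noise_sd)
  })
  series <- titration_series(H0, G0, as.data.frame(shifts),
                             owners = vapply(scenario$signals, `[[`, "", "owner"),
                             temperature = scenario$temperature)
  if (!is.null(path)) write_nmr_titration(series, path)
  series
}

#' ITC scenario
#'
#' Defaults emulate the calorimetric protocol for the strongly bound
#' four-wall complexes: a 0.2 mM host solution in a 1.4 mL cell titrated
#' with 25 x 3 uL injections of guest at 7x the cell concentration, with
#' 0.1 ucal Gaussian heat noise (VP-ITC-scale readout noise).
#'
#' @param K_true,dH_true,n_true true 1:1 parameters (K in M^-1, dH in
#'   kcal mol^-1).
#' @param cell_conc host concentration in the cell, M.
#' @param syringe_factor syringe/cell concentration ratio.
#' @param injection_volume per injection, L.
#' @param n_injections number of injections.
#' @param cell_volume L.
#' @param noise_sd Gaussian heat noise per injection, kcal
#'   (1e-10 kcal = 0.1 ucal).
#' @param temperature K.
#' @param seed integer seed owned by the scenario.
#' @return An `itc_scenario`.
#' @export
itc_scenario <- function(K_true, dH_true = -5, n_true = 1,
                         cell_conc = 2e-4, syringe_factor = 7,
                         injection_volume = 3e-6, n_injections = 25L,
                         cell_volume = 1.4e-3, noise_sd = 1e-10,
                         temperature = 298.0, seed = 1L) {
  stopifnot(K_true > 0, n_true > 0, syringe_factor > 0, noise_sd >= 0,
            injection_volume > 0, n_injections >= 1L, cell_volume > 0)
  structure(list(K_true = K_true, dH_true = dH_true, n_true = n_true,
                 cell_conc = cell_conc, syringe_factor = syringe_factor,
                 injection_volume = injection_volume,
                 n_injections = as.integer(n_injections),
                 cell_volume = cell_volume, noise_sd = noise_sd,
                 temperature = temperature, seed = as.integer(seed)),
            class = "itc_scenario")
}

#' Simulate an ITC thermogram from a scenario
#'
#' Applies the Wiseman-type perfusion forward model
#' ([predict_itc_heats()]) at the scenario's true parameters and adds iid
#' Gaussian heat noise. Pure function of the scenario (including its seed).
#'
#' @param scenario an [itc_scenario()].
#' @param path optional CSV path; when given the experiment is also written
#'   via [write_itc()].
#' @return An [itc_experiment()] with simulated `heats`.
#' @export
generate_itc <- function(scenario, path = NULL) {
  stopifnot(inherits(scenario, "itc_scenario"))
  exp <- itc_experiment(
    cell_conc = scenario$cell_conc,
    syringe_conc = scenario$syringe_factor * scenario$cell_conc,
    cell_volume = scenario$cell_volume,
    injection_volumes = rep(scenario$injection_volume, scenario$n_injections),
    temperature = scenario$temperature)
  h <- predict_itc_heats(exp, n = scenario$n_true, K = scenario$K_true,
                         dH = scenario$dH_true)
  rng <- .seeded_rng(scenario$seed)
  exp$heats <- h + rng$norm(length(h), 0, scenario$noise_sd)
  if (!is.null(path)) write_itc(exp, path)
  exp
}

#' Bundled host-guest study scenarios
#'
#' The 12 host x guest systems of the study — six receptors (the wall-free
#' octamethyl reference 1a, two-wall 1b-1d, four-wall 1e-1f) against the
#' N-oxide (2a) and P-oxide (2b) guests — with their reported association
#' constants as the true values, ring ESP values, wall counts, and the
#' measurement protocol appropriate to each affinity (NMR titration below
#' K = 1e4 M^-1, ITC above, where host exchange is slow on the NMR
#' timescale).
#'
#' @param path scenario CSV (default: bundled copy).
#' @return A named list (`"<guest>@<host>"`) of scenario records; each has
#'   `host_id`, `guest_id`, `K_true`, `K_err`, `esp`, `n_walls`,
#'   `substituent`, `method`, printed reference columns, and a ready-made
#'   `nmr` ([nmr_scenario()]) or `itc` ([itc_scenario()]) design.
#' @export
study_scenarios <- function(path = system.file("extdata", "binding_scenarios.csv",
                                               package = "calixchpi")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, ])
    # free NH at 7.4 ppm for the octamethyl reference, ~8 ppm for the
    # aryl-extended hosts; binding moves it ~2 ppm downfield
    d_free <- if (r$n_walls == 0) 7.4 else 8.0
    sc <- list(host_id = r$host_id, guest_id = r$guest_id,
               K_true = r$K, K_err = r$K_err,
               esp = if (is.na(r$esp)) NA_real_ else r$esp,
               n_walls = r$n_walls, substituent = r$substituent,
               method = r$method,
               minus_dG_printed = r$minus_dG_printed,
               minus_ddG_printed = r$minus_ddG_printed,
               ddG_err_printed = r$ddG_err_printed)
    if (r$method == "ITC") {
      sc$itc <- itc_scenario(K_true = r$K)
    } else {
      sc$nmr <- nmr_scenario(K_true = r$K,
                             signals = list(NH = list(owner = "host",
                                                      delta_free = d_free,
                                                      delta_bound = d_free + 2.0)))
    }
    sc
  })
  names(out) <- paste0(df$guest_id, "@", df$host_id)
  out
}

#' Generate a synthetic inclusion-complex geometry
#'
#' Builds an idealised walled receptor-guest contact geometry: a central
#' guest heteroatom with `n_walls` methyl carbons pointing at `n_walls`
#' hexagonal aromatic rings, each ring centroid at `d_contact` from its
#' methyl carbon along the ring normal, with one methyl H on the axis.
#' Optional isotropic Gaussian coordinate jitter emulates thermal/model
#' disorder. Entirely synthetic — a topological stand-in for a real
#' inclusion complex, intended for exercising the geometry code.
#'
#' @param n_walls 2 or 4 aromatic walls.
#' @param d_contact methyl-C-to-centroid distance, Angstrom.
#' @param perturbation Gaussian sd added to every coordinate, Angstrom.
#' @param seed integer seed.
#' @return List with `structure` ([structure_coordinates()]),
#'   `methyl_atoms` (carbon ids), and `rings` (list of ring-atom-id sets).
#' @export
generate_complex_geometry <- function(n_walls, d_contact = 3.5,
                                      perturbation = 0, seed = 1L) {
  stopifnot(n_walls %in% c(2L, 4L), d_contact > 0, perturbation >= 0)
  angles <- seq(0, 2 * pi, length.out = n_walls + 1L)[seq_len(n_walls)]
  r_methyl <- 1.5    # guest C-X bond length scale
  hex_r <- 1.39      # aromatic C-C ring radius
  ids <- el <- character(0)
  xyz <- NULL
  add <- function(id, e, p) {
    ids <<- c(ids, id); el <<- c(el, e); xyz <<- rbind(xyz, p)
  }
  add("X1", "N", c(0, 0, 0))
  add("O1", "O", c(0, 0, 1.36))
  methyl_atoms <- character(n_walls)
  rings <- vector("list", n_walls)
  for (k in seq_len(n_walls)) {
    u <- c(cos(angles[k]), sin(angles[k]), 0)       # wall direction
    e1 <- c(-sin(angles[k]), cos(angles[k]), 0)     # ring in-plane axes
    e2 <- c(0, 0, 1)
    cid <- sprintf("C%d", k)
    add(cid, "C", r_methyl * u)
    add(sprintf("H%d", k), "H", (r_methyl + 1.09) * u)
    centroid <- (r_methyl + d_contact) * u
    ring_ids <- sprintf("R%d_%d", k, 1:6)
    for (j in 1:6) {
      th <- 2 * pi * (j - 1) / 6
      add(ring_ids[j], "C", centroid + hex_r * (cos(th) * e1 + sin(th) * e2))
    }
    methyl_atoms[k] <- cid
    rings[[k]] <- ring_ids
  }
  if (perturbation > 0) {
    rng <- .seeded_rng(seed)
    xyz <- xyz + matrix(rng$norm(length(xyz), 0, perturbation), nrow(xyz))
  }
  st <- structure_coordinates(ids, el, xyz[, 1], xyz[, 2], xyz[, 3],
                              source = "synthetic")
  list(structure = st, methyl_atoms = methyl_atoms, rings = rings)
}
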