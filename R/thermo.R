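#' Thermodynamic constants
#'
#' Bundle of the gas constant and absolute temperature used for all
#' \eqn{\Delta G \leftrightarrow K} conversions. Defaults reproduce the
#' conventional 298 K reporting temperature for binding free energies in
#' acetonitrile.
#'
#' @param T_K absolute temperature in kelvin.
#' @param R_kcal gas constant in kcal mol^-1 K^-1.
#' @return An object of class `thermo_constants`.
#' @export
#' @examples
#' const <- thermo_constants()
#' K_to_free_energy(72.2, const)
thermo_constants <- function(T_K = 298.0, R_kcal = 1.9872e-3) {
  stopifnot(is.numeric(T_K), length(T_K) == 1L, T_K > 0,
            is.numeric(R_kcal), length(R_kcal) == 1L, R_kcal > 0)
  structure(list(R = R_kcal, T = T_K), class = "thermo_constants")
}

#' Convert a binding free energy to an association constant
#'
#' @param dG free energy of association, kcal mol^-1 (negative = favourable).
#' @param const a [thermo_constants()] object.
#' @return Association constant K in M^-1 (strictly positive).
#' @export
free_energy_to_K <- function(dG, const = thermo_constants()) {
  stopifnot(is.numeric(dG), inherits(const, "thermo_constants"))
  exp(-dG / (const$R * const$T))
}

#' Convert an association constant to a binding free energy
#'
#' \eqn{\Delta G = -RT \ln K}. Exact inverse of [free_energy_to_K()].
#'
#' @param K association constant, M^-1; must be > 0.
#' @inheritParams free_energy_to_K
#' @return Free energy in kcal mol^-1.
#' @export
K_to_free_energy <- function(K, const = thermo_constants()) {
  stopifnot(is.numeric(K), inherits(const, "thermo_constants"))
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("association constant K must be finite and > 0", call. = FALSE)
  }
  -const$R * const$T * log(K)
}

#' Hydrogen-bond donor/acceptor descriptor
#'
#' Empirical dimensionless descriptors of hydrogen-bond donor strength
#' (`alpha`) and acceptor strength (`beta`) for a solute. Either may be `NA`
#' when the species is only ever used on one side of the bond.
#'
#' @param species_id text label, unique within a descriptor table.
#' @param alpha donor strength, >= 0 or NA.
#' @param beta acceptor strength, >= 0 or NA.
#' @return An `hb_descriptor` object.
#' @export
hb_descriptor <- function(species_id, alpha = NA_real_, beta = NA_real_) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  if (!is.na(alpha) && alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!is.na(beta) && beta < 0) stop("beta must be >= 0", call. = FALSE)
  structure(list(species_id = species_id, alpha = alpha, beta = beta),
            class = "hb_descriptor")
}

#' Solvent hydrogen-bond descriptor
#'
#' @param solvent_id text label.
#' @param alpha_s solvent donor strength, >= 0.
#' @param beta_s solvent acceptor strength, >= 0.
#' @return A `solvent_descriptor` object.
#' @export
solvent_descriptor <- function(solvent_id, alpha_s, beta_s) {
  stopifnot(is.character(solvent_id), length(solvent_id) == 1L,
            is.numeric(alpha_s), alpha_s >= 0,
            is.numeric(beta_s), beta_s >= 0)
  structure(list(solvent_id = solvent_id, alpha_s = alpha_s, beta_s = beta_s),
            class = "solvent_descriptor")
}

#' Predict the free energy of a single hydrogen bond in a competing solvent
#'
#' Hunter-style prediction
#' \deqn{\Delta\Delta G_{HB} = \frac{-(\alpha-\alpha_s)(\beta-\beta_s) + 6}{4.18}}
#' in kcal mol^-1, where \eqn{\alpha,\beta} describe the donor and acceptor
#' and \eqn{\alpha_s,\beta_s} the solvent. The additive constant 6 is a
#' kJ mol^-1 offset and 4.18 converts kJ to kcal; both are fixed. Not valid
#' for arrays of cooperative hydrogen bonds — single-contact estimates only.
#'
#' @param donor [hb_descriptor()] of the H-bond donor (its `alpha` is used).
#' @param acceptor [hb_descriptor()] of the acceptor (its `beta` is used).
#' @param solvent a [solvent_descriptor()].
#' @return Predicted free energy, kcal mol^-1 (negative = favourable).
#' @export
#' @examples
#' pyrrole <- hb_descriptor("pyrrole", alpha = 3.0)
#' tmao <- hb_descriptor("2a", alpha = 1.2, beta = 12.2)
#' mecn <- solvent_descriptor("acetonitrile", 1.7, 5.1)
#' predict_hb_free_energy(pyrrole, tmao, mecn)  # ~ -0.77
predict_hb_free_energy <- function(donor, acceptor, solvent) {
  stopifnot(inherits(donor, "hb_descriptor"),
            inherits(acceptor, "hb_descriptor"),
            inherits(solvent, "solvent_descriptor"))
  if (is.na(donor$alpha)) {
    stop("no alpha descriptor for donor species '", donor$species_id, "'",
         call. = FALSE)
  }
  if (is.na(acceptor$beta)) {
    stop("no beta descriptor for acceptor species '", acceptor$species_id, "'",
         call. = FALSE)
  }
  (-(donor$alpha - solvent$alpha_s) * (acceptor$beta - solvent$beta_s) + 6) / 4.18
}

#' Read a hydrogen-bond descriptor table
#'
#' CSV with columns `species_id`, `alpha`, `beta` (blank = unknown). The
#' bundled table (`system.file("extdata", "hbond_descriptors.csv",
#' package = "calixchpi")`) carries pyrrole and the trimethylamine-N-oxide /
#' trimethylphosphine-P-oxide guests.
#'
#' @param path CSV file; default is the bundled table.
#' @return Named list of [hb_descriptor()] objects.
#' @export
read_descriptor_table <- function(path = system.file("extdata", "hbond_descriptors.csv",
                                                     package = "calixchpi")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "alpha", "beta")
  if (!all(need %in% names(df))) {
    stop("descriptor table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$species_id)) {
    stop("duplicate species_id in descriptor table", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    hb_descriptor(df$species_id[i], df$alpha[i], df$beta[i])
  })
  names(out) <- df$species_id
  out
}

#' Read a solvent descriptor table
#'
#' CSV with columns `solvent_id`, `alpha_s`, `beta_s`.
#'
#' @param path CSV file; default is the bundled table (acetonitrile).
#' @return Named list of [solvent_descriptor()] objects.
#' @export
read_solvent_table <- function(path = system.file("extdata", "solvents.csv",
                                                  package = "calixchpi")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("solvent_id", "alpha_s", "beta_s")
  if (!all(need %in% names(df))) {
    stop("solvent table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    solvent_descriptor(df$solvent_id[i], df$alpha_s[i], df$beta_s[i])
  })
  names(out) <- df$solvent_id
  out
}

#' Look up a species in a descriptor table
#'
#' @param table named list from [read_descriptor_table()] or
#'   [read_solvent_table()].
#' @param species_id label to look up.
#' @return The descriptor object.
#' @export
lookup_descriptor <- function(table, species_id) {
  if (!species_id %in% names(table)) {
    stop("species '", species_id, "' not found in descriptor table",
         call. = FALSE)
  }
  table[[species_id]]
}
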