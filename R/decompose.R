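#' Host record
#'
#' Metadata for one receptor: number of aromatic walls and the electrostatic
#' surface potential (ESP) at the centre of the wall's phenyl ring. The
#' wall-free reference receptor has no ESP.
#'
#' @param host_id text label.
#' @param n_walls 0, 2 or 4 aromatic walls.
#' @param esp ESP at the ring centroid, kcal mol^-1 (required iff
#'   `n_walls > 0`).
#' @param substituent para-substituent label (optional).
#' @return A `host_record`.
#' @export
host_record <- function(host_id, n_walls, esp = NA_real_,
                        substituent = NA_character_) {
  stopifnot(n_walls %in% c(0, 2, 4))
  if (n_walls > 0 && is.na(esp)) {
    stop("walled host '", host_id, "' needs an ESP value", call. = FALSE)
  }
  if (n_walls == 0 && !is.na(esp)) {
    stop("reference host '", host_id, "' has no aromatic wall, ESP must be absent",
         call. = FALSE)
  }
  structure(list(host_id = host_id, n_walls = n_walls, esp = esp,
                 substituent = substituent), class = "host_record")
}

#' Double-difference free energy of the CH-pi contacts
#'
#' Subtracts the binding free energy of the wall-free reference complex
#' (same guest) from that of the walled complex; what remains is attributed
#' to the guest-methyl/aromatic-wall CH-pi contacts. Uncertainties combine
#' in quadrature.
#'
#' @param target `binding_result` for the walled complex.
#' @param reference `binding_result` for the reference (wall-free) complex;
#'   must share `guest_id` and temperature with `target`.
#' @param n_contacts optional contact count; when given, the per-contact
#'   energy is filled in (see [per_contact_energy()]).
#' @return A `decomposition_result` with `ddG` (negative = walls favourable),
#'   `ddG_sigma`, and optionally `n_contacts`/`per_contact`.
#' @export
delta_delta_G <- function(target, reference, n_contacts = NULL) {
  stopifnot(inherits(target, "binding_result"),
            inherits(reference, "binding_result"))
  if (!identical(target$guest_id, reference$guest_id)) {
    stop("guest mismatch: target has '", target$guest_id,
         "', reference has '", reference$guest_id, "'", call. = FALSE)
  }
  if (!isTRUE(all.equal(target$temperature, reference$temperature))) {
    stop("temperature mismatch between target and reference", call. = FALSE)
  }
  ddG <- target$dG - reference$dG
  sig <- sqrt(.na0(target$dG_sigma)^2 + .na0(reference$dG_sigma)^2)
  out <- structure(list(host_id = target$host_id, guest_id = target$guest_id,
                        ddG = ddG, ddG_sigma = sig,
                        n_contacts = NA_integer_, per_contact = NA_real_),
                   class = "decomposition_result")
  if (!is.null(n_contacts)) {
    out$n_contacts <- as.integer(n_contacts)
    out$per_contact <- per_contact_energy(ddG, n_contacts)
  }
  out
}

.na0 <- function(x) ifelse(is.finite(x), x, 0)

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("CH-pi decomposition %s@%s: ddG = %.3f +/- %.3f kcal/mol",
              x$guest_id, x$host_id, x$ddG, x$ddG_sigma))
  if (is.finite(x$per_contact)) {
    cat(sprintf(" (%d contacts, %.3f each)", x$n_contacts, x$per_contact))
  }
  cat("\n")
  invisible(x)
}

#' Free energy per CH-pi contact
#'
#' @param ddG double-difference free energy, kcal mol^-1.
#' @param n_contacts number of CH-pi contacts (>= 1), e.g. from the crystal
#'   geometry or [count_contacts()].
#' @return `ddG / n_contacts`, kcal mol^-1.
#' @export
per_contact_energy <- function(ddG, n_contacts) {
  if (length(n_contacts) != 1L || is.na(n_contacts) || n_contacts < 1) {
    stop("n_contacts must be a single integer >= 1", call. = FALSE)
  }
  ddG / n_contacts
}

#' Linear free-energy relationship of CH-pi energy vs ring ESP
#'
#' Ordinary (or inverse-variance weighted) least-squares regression of the
#' CH-pi free energies on the electrostatic surface potential at the
#' aromatic ring centre — a pseudo-Hammett plot. A slope statistically
#' indistinguishable from zero indicates that electrostatics does not set
#' the interaction strength (the dispersion-dominated, "typical" CH-pi
#' regime).
#'
#' @param esp ESP values, kcal mol^-1.
#' @param ddG CH-pi free energies, kcal mol^-1 (either sign convention; the
#'   slope test is convention-agnostic).
#' @param ddG_sigma optional uncertainties; used only when `weighted = TRUE`.
#' @param weighted use inverse-variance weights.
#' @return An `lfer_result`: slope, intercept, their standard errors, the
#'   two-sided p-value for slope = 0 (t, df = n - 2), and `n_points`.
#' @export
lfer_regression <- function(esp, ddG, ddG_sigma = NULL, weighted = FALSE) {
  ok <- is.finite(esp) & is.finite(ddG)
  esp <- esp[ok]; ddG <- ddG[ok]
  if (length(esp) < 2L) stop("need at least 2 points", call. = FALSE)
  if (length(unique(esp)) < 2L) {
    stop("rank-deficient LFER: all ESP values identical", call. = FALSE)
  }
  w <- NULL
  if (weighted) {
    if (is.null(ddG_sigma)) stop("weighted fit needs ddG_sigma", call. = FALSE)
    sig <- ddG_sigma[ok]
    if (any(!is.finite(sig)) || any(sig <= 0)) {
      stop("weighted fit needs finite positive ddG_sigma", call. = FALSE)
    }
    w <- 1 / sig^2
  }
  fit <- stats::lm(ddG ~ esp, weights = w)
  # a constant response is a legitimate degenerate input (slope exactly 0);
  # stats::summary.lm warns about the perfect fit, which is expected here
  cf <- suppressWarnings(summary(fit))$coefficients
  n <- length(esp)
  slope <- cf["esp", "Estimate"]
  slope_se <- cf["esp", "Std. Error"]
  p_slope <- if (n > 2L) {
    2 * stats::pt(abs(slope / slope_se), df = n - 2L, lower.tail = FALSE)
  } else NA_real_  # two points: exact interpolation, no residual dof
  structure(list(slope = slope, intercept = cf["(Intercept)", "Estimate"],
                 slope_se = slope_se,
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 p_slope = p_slope, n_points = n, weighted = weighted,
                 lm = fit),
            class = "lfer_result")
}

#' @export
print.lfer_result <- function(x, ...) {
  cat(sprintf(
    "LFER (ddG vs ESP, %s, n = %d):\n  slope = %.4f +/- %.4f kcal/mol per ESP unit (p = %s)\n  intercept = %.3f +/- %.3f kcal/mol\n",
    if (x$weighted) "weighted" else "OLS", x$n_points, x$slope, x$slope_se,
    ifelse(is.na(x$p_slope), "NA", format.pval(x$p_slope, digits = 3)),
    x$intercept, x$intercept_se))
  invisible(x)
}

#' Default CH-pi contact count for a host
#'
#' One guest methyl faces each aromatic wall: 4 contacts for four-wall
#' hosts, 2 for two-wall. Overridable wherever a contact count is accepted
#' (e.g. from [count_contacts()] on a structure).
#'
#' @param n_walls number of aromatic walls.
#' @return Integer contact count (0 for the wall-free reference).
#' @export
default_contact_count <- function(n_walls) {
  stopifnot(n_walls %in% c(0, 2, 4))
  as.integer(n_walls)
}

#' Assemble a Table-1-style binding/decomposition report
#'
#' For each host x guest pair: ESP, K with its uncertainty, -dG, and (for
#' walled hosts) -ddG against the same-guest reference complex with the
#' quadrature-combined uncertainty. Free energies are printed with the
#' favourable sign positive, matching the conventional tabulation.
#'
#' @param results list of `binding_result` objects (one per host x guest).
#' @param hosts list of [host_record()] objects covering every host in
#'   `results`.
#' @param reference_id host id of the wall-free reference (default "1a").
#' @return A data.frame sorted by guest then host, columns `host_id`,
#'   `guest_id`, `n_walls`, `esp`, `K`, `K_sigma`, `minus_dG`, `minus_ddG`,
#'   `ddG_sigma`, `n_contacts`, `per_contact`.
#' @export
build_table1 <- function(results, hosts, reference_id = "1a") {
  stopifnot(length(results) > 0)
  hmap <- stats::setNames(hosts, vapply(hosts, `[[`, "", "host_id"))
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "binding_result"))
    if (!r$host_id %in% names(hmap)) {
      stop("no host record for '", r$host_id, "'", call. = FALSE)
    }
    h <- hmap[[r$host_id]]
    data.frame(host_id = r$host_id, guest_id = r$guest_id,
               n_walls = h$n_walls, esp = h$esp,
               K = r$K, K_sigma = r$K_sigma, minus_dG = -r$dG,
               minus_ddG = NA_real_, ddG_sigma = NA_real_,
               n_contacts = NA_integer_, per_contact = NA_real_)
  })
  tab <- do.call(rbind, rows)
  for (g in unique(tab$guest_id)) {
    ref_i <- which(tab$guest_id == g & tab$host_id == reference_id)
    if (length(ref_i) != 1L) {
      stop("missing reference complex ", g, "@", reference_id,
           " for guest '", g, "'", call. = FALSE)
    }
    ref <- results[[ref_i]]
    for (i in which(tab$guest_id == g & tab$host_id != reference_id)) {
      nc <- default_contact_count(tab$n_walls[i])
      d <- delta_delta_G(results[[i]], ref,
                         n_contacts = if (nc > 0) nc else NULL)
      tab$minus_ddG[i] <- -d$ddG
      tab$ddG_sigma[i] <- d$ddG_sigma
      if (nc > 0) {
        tab$n_contacts[i] <- nc
        tab$per_contact[i] <- d$per_contact
      }
    }
  }
  tab <- tab[order(tab$guest_id, tab$host_id), ]
  rownames(tab) <- NULL
  tab
}

#' Write a binding table as CSV and JSON
#'
#' @param tab data.frame from [build_table1()].
#' @param csv_path,json_path output files (either may be `NULL` to skip).
#' @return `tab`, invisibly.
#' @export
write_table1 <- function(tab, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(tab)
}
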