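#' Write an NMR titration series to CSV
#'
#' Layout: `# key: value` metadata comment lines (temperature_K, and
#' `owner_<signal>: host|guest` per signal), then a header
#' `H0_M,G0_M,<signal columns>` and one row per titration point.
#'
#' @param series a [titration_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nmr_titration <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K: %.6g", series$temperature), con)
  for (s in names(series$owners)) {
    writeLines(sprintf("# owner_%s: %s", s, series$owners[[s]]), con)
  }
  df <- cbind(data.frame(H0_M = series$H0, G0_M = series$G0), series$shifts)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_kv_comments <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3L) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Read an NMR titration series from CSV
#'
#' Inverse of [write_nmr_titration()]. Signals with no `owner_*` metadata
#' default to host-owned.
#'
#' @param path CSV file.
#' @return A [titration_series()].
#' @export
read_nmr_titration <- function(path) {
  kv <- .read_kv_comments(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!all(c("H0_M", "G0_M") %in% names(df))) {
    stop("titration CSV needs H0_M and G0_M columns", call. = FALSE)
  }
  sig <- setdiff(names(df), c("H0_M", "G0_M"))
  if (length(sig) == 0L) stop("no signal columns found", call. = FALSE)
  owners <- vapply(sig, function(s) {
    v <- kv[[paste0("owner_", s)]]
    if (is.null(v)) "host" else v
  }, "")
  temp <- if (!is.null(kv$temperature_K)) as.numeric(kv$temperature_K) else 298.0
  titration_series(df$H0_M, df$G0_M, df[sig], owners, temperature = temp)
}

#' Write an ITC experiment to CSV
#'
#' Columns `injection_volume_uL`, `heat_ucal`; metadata comment lines carry
#' cell_conc_M, syringe_conc_M, cell_volume_mL and temperature_K. Heats are
#' stored in microcalories (instrument convention); the in-memory object
#' keeps kcal.
#'
#' @param exp an [itc_experiment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_itc <- function(exp, path) {
  stopifnot(inherits(exp, "itc_experiment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_conc_M: %.10g", exp$cell_conc),
               sprintf("# syringe_conc_M: %.10g", exp$syringe_conc),
               sprintf("# cell_volume_mL: %.10g", exp$cell_volume * 1e3),
               sprintf("# temperature_K: %.6g", exp$temperature)), con)
  heats <- if (is.null(exp$heats)) rep(NA_real_, length(exp$injection_volumes))
           else exp$heats * 1e9
  df <- data.frame(injection_volume_uL = exp$injection_volumes * 1e6,
                   heat_ucal = heats)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ITC experiment from CSV
#'
#' Inverse of [write_itc()].
#'
#' @param path CSV file.
#' @return An [itc_experiment()].
#' @export
read_itc <- function(path) {
  kv <- .read_kv_comments(path)
  need <- c("cell_conc_M", "syringe_conc_M", "cell_volume_mL")
  if (!all(need %in% names(kv))) {
    stop("ITC CSV metadata must include: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  heats <- df$heat_ucal * 1e-9
  if (all(is.na(heats))) heats <- NULL
  temp <- if (!is.null(kv$temperature_K)) as.numeric(kv$temperature_K) else 298.0
  itc_experiment(cell_conc = as.numeric(kv$cell_conc_M),
                 syringe_conc = as.numeric(kv$syringe_conc_M),
                 cell_volume = as.numeric(kv$cell_volume_mL) * 1e-3,
                 injection_volumes = df$injection_volume_uL * 1e-6,
                 heats = heats, temperature = temp)
}
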