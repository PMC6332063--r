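#' Structure coordinates container
#'
#' @param atom_id unique atom labels.
#' @param element element symbols.
#' @param x,y,z Cartesian coordinates, Angstrom.
#' @param source provenance tag ("XYZ", "PDB", or "synthetic").
#' @return A `structure_coordinates` data.frame.
#' @export
structure_coordinates <- function(atom_id, element, x, y, z,
                                  source = "synthetic") {
  atom_id <- as.character(atom_id)
  if (anyDuplicated(atom_id)) stop("atom ids must be unique", call. = FALSE)
  if (any(!is.finite(c(x, y, z)))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  out <- data.frame(atom_id = atom_id, element = as.character(element),
                    x = x, y = y, z = z, stringsAsFactors = FALSE)
  attr(out, "source") <- source
  class(out) <- c("structure_coordinates", "data.frame")
  out
}

.coords <- function(structure, ids) {
  i <- match(as.character(ids), structure$atom_id)
  if (anyNA(i)) {
    stop("atom(s) not found: ",
         paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
  }
  unname(as.matrix(structure[i, c("x", "y", "z")]))
}

#' Read an XYZ coordinate file
#'
#' Standard dialect: atom count on line 1, free comment on line 2, then
#' `element x y z` per atom. Atom ids are `<element><serial>`.
#'
#' @param path XYZ file.
#' @return A [structure_coordinates()] object.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 2L) {
    stop("malformed XYZ file: ", path, call. = FALSE)
  }
  tok <- strsplit(trimws(lines[3:(n + 2L)]), "\\s+")
  el <- vapply(tok, `[[`, "", 1L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
  structure_coordinates(paste0(el, seq_len(n)), el,
                        xyz[, 1], xyz[, 2], xyz[, 3], source = "XYZ")
}

#' Write an XYZ coordinate file
#'
#' @param structure a [structure_coordinates()] object.
#' @param path output file.
#' @param comment the free-text second line.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(structure, path, comment = "") {
  body <- sprintf("%-2s %14.8f %14.8f %14.8f",
                  structure$element, structure$x, structure$y, structure$z)
  writeLines(c(nrow(structure), comment, body), path)
  invisible(path)
}

#' Read coordinates from a PDB file
#'
#' ATOM/HETATM records of the first model; alternate locations other than
#' "A" are dropped. Parsing is delegated to bio3d.
#'
#' @param path PDB file.
#' @return A [structure_coordinates()] object with atom ids
#'   `<atom name>_<residue serial>_<atom serial>`.
#' @export
read_pdb_coords <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$alt %in% c("", "A", NA)
  a <- a[keep, ]
  el <- a$elesy
  if (is.null(el) || all(!nzchar(trimws(el)))) {
    el <- substr(trimws(a$elety), 1, 1)
  }
  structure_coordinates(
    atom_id = paste(trimws(a$elety), a$resno, a$eleno, sep = "_"),
    element = trimws(el), x = a$x, y = a$y, z = a$z, source = "PDB")
}

#' Centroid and least-squares plane normal of an aromatic ring
#'
#' The centroid is the mean of the ring atom positions; the normal is the
#' unit eigenvector of the smallest principal component of the centred ring
#' coordinates (the least-squares plane). With `toward` given, the normal's
#' sign is chosen to point at that atom.
#'
#' @param structure a [structure_coordinates()] object.
#' @param ring_atom_ids >= 3 atom ids defining the ring.
#' @param toward optional atom id fixing the normal's sign.
#' @return List with `centroid` (length-3), `normal` (unit length), and
#'   `max_dev` (largest out-of-plane deviation, Angstrom).
#' @export
ring_centroid_normal <- function(structure, ring_atom_ids, toward = NULL) {
  P <- .coords(structure, ring_atom_ids)
  if (nrow(P) < 3L) stop("a ring needs at least 3 atoms", call. = FALSE)
  centroid <- unname(colMeans(P))
  Q <- sweep(P, 2, centroid)
  ev <- eigen(crossprod(Q), symmetric = TRUE)
  # collinear atoms: the two smallest principal variances both vanish
  if (ev$values[2] <= 1e-10 * max(ev$values[1], 1e-300)) {
    stop("degenerate ring plane: atoms are (near-)collinear", call. = FALSE)
  }
  normal <- ev$vectors[, 3]
  normal <- normal / sqrt(sum(normal^2))
  if (!is.null(toward)) {
    q <- drop(.coords(structure, toward)) - centroid
    if (sum(normal * q) < 0) normal <- -normal
  }
  list(centroid = centroid, normal = normal,
       max_dev = max(abs(Q %*% normal)))
}

#' Geometric parameters of one CH-pi contact
#'
#' The conventional descriptors of a C-H group over an aromatic ring:
#' \itemize{
#'   \item `d` — distance from the H atom (or from C in heavy-atom mode) to
#'     the ring centroid, Angstrom;
#'   \item `theta` — the C-H...centroid angle at H, degrees (180 = linear);
#'   \item `phi` — the displacement of the (H or C) atom from the ring
#'     normal erected at the centroid, degrees (0 = directly above the
#'     centre), folded into [0, 90].
#' }
#' When `H_id` is `NULL` the contact is measured from the carbon
#' (heavy-atom mode, `theta` undefined) and the result is flagged.
#'
#' @param structure a [structure_coordinates()] object.
#' @param C_id methyl carbon atom id.
#' @param H_id hydrogen atom id, or `NULL` for heavy-atom mode.
#' @param ring_atom_ids ring definition, as in [ring_centroid_normal()].
#' @return A `chpi_geometry` list: `d`, `theta`, `phi`, `heavy_atom_mode`,
#'   `degenerate` (TRUE when the query atom sits on the centroid and phi is
#'   undefined).
#' @export
chpi_parameters <- function(structure, C_id, H_id = NULL, ring_atom_ids) {
  rcn <- ring_centroid_normal(structure, ring_atom_ids, toward = C_id)
  C <- drop(.coords(structure, C_id))
  heavy <- is.null(H_id)
  theta <- NA_real_
  if (!heavy) {
    H <- drop(.coords(structure, H_id))
    if (sqrt(sum((C - H)^2)) >= 1.3) {
      stop("atoms '", C_id, "' and '", H_id,
           "' are not bonded (C-H distance >= 1.3 A)", call. = FALSE)
    }
    q <- H
    v1 <- C - H; v2 <- rcn$centroid - H
    theta <- .angle_deg(v1, v2)
  } else {
    q <- C
  }
  u <- q - rcn$centroid
  d <- sqrt(sum(u^2))
  degenerate <- d < 1e-9
  phi <- if (degenerate) NA_real_ else {
    # fold onto [0, 90]: displacement from the normal axis, side-agnostic
    ang <- .angle_deg(u, rcn$normal)
    min(ang, 180 - ang)
  }
  structure(list(d = d, theta = theta, phi = phi,
                 heavy_atom_mode = heavy, degenerate = degenerate),
            class = "chpi_geometry")
}

.angle_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, ca))) * 180 / pi
}

#' @export
print.chpi_geometry <- function(x, ...) {
  cat(sprintf("CH-pi contact: d = %.3f A, theta = %s, phi = %s%s\n",
              x$d,
              ifelse(is.na(x$theta), "NA (heavy-atom mode)",
                     sprintf("%.1f deg", x$theta)),
              ifelse(is.na(x$phi), "NA (degenerate)",
                     sprintf("%.1f deg", x$phi)),
              if (x$heavy_atom_mode) " [C-based]" else ""))
  invisible(x)
}

#' Count CH-pi contacts between methyl groups and aromatic rings
#'
#' A contact is any (methyl, ring) pair whose methyl-carbon-to-centroid
#' distance (mode "C", the default criterion) or hydrogen-to-centroid
#' distance (mode "H") does not exceed `cutoff`. Contacts are returned
#' sorted by distance.
#'
#' @param structure a [structure_coordinates()] object.
#' @param methyl_atoms character vector of methyl carbon ids (mode "C") or
#'   hydrogen ids (mode "H").
#' @param rings list of ring-atom-id vectors.
#' @param cutoff distance cutoff, Angstrom (default 4.0, a conventional
#'   upper bound for methyl CH-pi contacts).
#' @param mode measure from the carbon ("C") or the hydrogen ("H").
#' @return List with `n_contacts` and `contacts`, a data.frame
#'   (`methyl`, `ring`, `d`, `phi`) sorted by `d`.
#' @export
count_contacts <- function(structure, methyl_atoms, rings, cutoff = 4.0,
                           mode = c("C", "H")) {
  mode <- match.arg(mode)
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  if (length(rings) == 0L) stop("empty ring list", call. = FALSE)
  rows <- list()
  for (m in methyl_atoms) {
    for (ri in seq_along(rings)) {
      g <- if (mode == "C") {
        chpi_parameters(structure, C_id = m, H_id = NULL,
                        ring_atom_ids = rings[[ri]])
      } else {
        # H mode: distance measured from the hydrogen itself
        rcn <- ring_centroid_normal(structure, rings[[ri]], toward = m)
        u <- drop(.coords(structure, m)) - rcn$centroid
        dd <- sqrt(sum(u^2))
        ang <- .angle_deg(u, rcn$normal)
        list(d = dd, phi = min(ang, 180 - ang))
      }
      if (g$d <= cutoff) {
        rows[[length(rows) + 1L]] <-
          data.frame(methyl = m, ring = ri, d = g$d,
                     phi = if (is.null(g$phi)) NA_real_ else g$phi)
      }
    }
  }
  contacts <- if (length(rows)) do.call(rbind, rows) else
    data.frame(methyl = character(), ring = integer(),
               d = numeric(), phi = numeric())
  contacts <- contacts[order(contacts$d, contacts$methyl, contacts$ring), ]
  rownames(contacts) <- NULL
  list(n_contacts = nrow(contacts), contacts = contacts)
}

#' Hydrogen-bond donor-acceptor distances
#'
#' Euclidean distances between paired donor (H or N) and acceptor (O)
#' atoms; vectorised over pairs, e.g. the four pyrrole NH...O contacts of
#' an inclusion complex.
#'
#' @param structure a [structure_coordinates()] object.
#' @param donor_ids,acceptor_ids equal-length atom id vectors.
#' @return Numeric vector of distances, Angstrom.
#' @export
hydrogen_bond_distances <- function(structure, donor_ids, acceptor_ids) {
  if (length(donor_ids) != length(acceptor_ids)) {
    stop("donor and acceptor id vectors must have equal length", call. = FALSE)
  }
  D <- .coords(structure, donor_ids)
  A <- .coords(structure, acceptor_ids)
  unname(sqrt(rowSums((D - A)^2)))
}
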