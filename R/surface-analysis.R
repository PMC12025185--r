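#' Golden-spiral quadrature points on the unit sphere
#'
#' Deterministic quasi-uniform point set used by the Shrake-Rupley
#' quadrature; no RNG is involved, so SASA values are reproducible for a
#' fixed `n`.
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Distributes `n_points` quasi-uniform quadrature points on each atom's
#' expanded sphere (vdW radius + probe); a point is accessible when it
#' lies outside every neighbour's expanded sphere. Atom SASA is
#' `4*pi*(r+probe)^2` times the accessible fraction. Deterministic for a
#' fixed `n_points`.
#'
#' @param structure a `protein_structure`.
#' @param probe_radius solvent probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom (>= 92; default 960).
#' @return object of class `sasa_result`: list with `per_atom` (numeric,
#'   one value per atom in structure order), `per_residue` (named by
#'   residue key), `total`, `probe_radius`, `n_points`.
#' @export
shrake_rupley <- function(structure, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "protein_structure"))
  if (n_points < 92) stop("n_points must be >= 92")
  a <- structure$atoms
  if (nrow(a) == 0L) stop("structure has no atoms")
  coords <- cbind(a$x, a$y, a$z)
  if (!all(is.finite(coords))) stop("non-finite atom coordinate")
  pts <- golden_spiral_points(n_points)
  per_atom <- .sasa_per_atom(coords, a$radius, probe_radius, pts)
  per_residue <- tapply(per_atom, factor(a$key, levels = unique(a$key)),
                        sum)
  out <- list(per_atom = as.numeric(per_atom),
              per_residue = setNames(as.numeric(per_residue),
                                     names(per_residue)),
              total = sum(per_atom),
              probe_radius = probe_radius,
              n_points = as.integer(n_points))
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.2f A^2 over %d atoms (probe %.2f A, %d points/atom)\n",
              x$total, length(x$per_atom), x$probe_radius, x$n_points))
  invisible(x)
}

#' Per-residue relative exposure classification
#'
#' Normalizes each residue's SASA by its theoretical maximum in an
#' extended Gly-X-Gly tripeptide and classifies residues as exposed when
#' relative SASA is at or above `threshold` (default 20%). Residues whose
#' name is missing from the reference table are reported as "unscored",
#' never dropped.
#'
#' @param sasa a `sasa_result` computed on `structure`.
#' @param structure the `protein_structure` the SASA belongs to.
#' @param reference named residue -> max-ASA table,
#'   see [max_asa_reference()].
#' @param threshold relative-SASA exposure threshold (fraction).
#' @return data.frame (one row per residue in structure order): chain,
#'   resnum, icode, resname, key, sasa, max_reference, relative_sasa,
#'   exposure_class ("exposed" / "buried" / "unscored").
#' @export
residue_exposure <- function(sasa, structure,
                             reference = max_asa_reference(),
                             threshold = 0.20) {
  stopifnot(inherits(sasa, "sasa_result"),
            inherits(structure, "protein_structure"),
            threshold > 0)
  res <- structure$residues
  out <- res
  out$sasa <- unname(sasa$per_residue[res$key])
  out$max_reference <- unname(reference[res$resname])
  out$relative_sasa <- out$sasa / out$max_reference
  bad <- is.na(out$max_reference) | out$max_reference <= 0
  out$relative_sasa[bad] <- NA_real_
  out$exposure_class <- ifelse(bad, "unscored",
                               ifelse(out$relative_sasa >= threshold,
                                      "exposed", "buried"))
  rownames(out) <- NULL
  out
}

#' Hydrophobic/hydrophilic partition of the accessible surface
#'
#' Assigns each atom's SASA to the hydrophobic (carbon, sulfur) or
#' hydrophilic (nitrogen, oxygen) side, the POPS convention. Elements
#' outside both sets are counted on the `other_side` with a warning.
#'
#' @param sasa a `sasa_result` computed on `structure`.
#' @param structure matching `protein_structure`.
#' @param hydrophobic_elements,hydrophilic_elements element sets.
#' @param other_side side for unclassified elements ("hydrophilic" or
#'   "hydrophobic").
#' @return object of class `surface_partition`: list with
#'   hydrophobic_area, hydrophilic_area, total,
#'   ratio_hydrophilic_to_hydrophobic (Inf when hydrophobic area is 0).
#' @export
surface_partition <- function(sasa, structure,
                              hydrophobic_elements = c("C", "S"),
                              hydrophilic_elements = c("N", "O"),
                              other_side = c("hydrophilic",
                                             "hydrophobic")) {
  stopifnot(inherits(sasa, "sasa_result"),
            inherits(structure, "protein_structure"))
  other_side <- match.arg(other_side)
  elem <- structure$atoms$element
  stopifnot(length(elem) == length(sasa$per_atom))
  phob <- elem %in% hydrophobic_elements
  phil <- elem %in% hydrophilic_elements
  other <- !phob & !phil
  if (any(other)) {
    warning("element(s) ", paste(unique(elem[other]), collapse = ", "),
            " outside hydrophobic/hydrophilic sets; counted as ",
            other_side)
    if (other_side == "hydrophilic") phil <- phil | other
    else phob <- phob | other
  }
  hb <- sum(sasa$per_atom[phob])
  hl <- sum(sasa$per_atom[phil])
  out <- list(hydrophobic_area = hb, hydrophilic_area = hl,
              total = hb + hl,
              ratio_hydrophilic_to_hydrophobic =
                if (hb > 0) hl / hb else Inf)
  class(out) <- "surface_partition"
  out
}

#' @export
print.surface_partition <- function(x, ...) {
  cat(sprintf("surface_partition: hydrophobic %.2f A^2, hydrophilic %.2f A^2, ratio %.3f\n",
              x$hydrophobic_area, x$hydrophilic_area,
              x$ratio_hydrophilic_to_hydrophobic))
  invisible(x)
}
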