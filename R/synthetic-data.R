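# run code with a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# minimal ideal side-chain fragments; offsets are relative to the residue's
# placed key atom (the charged/terminal side-chain atom), in Angstrom
.residue_templates <- list(
  LYS = data.frame(name = c("NZ", "CB", "CA"),
                   dx = c(0, 0, 0), dy = c(0, 0, 0), dz = c(0, 2.8, 4.0)),
  ASP = data.frame(name = c("OD1", "OD2", "CG", "CB", "CA"),
                   dx = c(0, 0.7, 0.4, 0.4, 0.4),
                   dy = c(0, 2.0, 1.0, 1.0, 1.0),
                   dz = c(0, 0, 0.9, 2.4, 3.9)),
  GLU = data.frame(name = c("OE1", "OE2", "CD", "CB", "CA"),
                   dx = c(0, 0.7, 0.4, 0.4, 0.4),
                   dy = c(0, 2.0, 1.0, 1.0, 1.0),
                   dz = c(0, 0, 0.9, 2.4, 3.9)),
  ARG = data.frame(name = c("NH1", "NH2", "NE", "CA"),
                   dx = c(0, 0.7, 0.4, 0.4),
                   dy = c(0, 2.0, 1.0, 1.0),
                   dz = c(0, 0, 1.1, 4.0)),
  HIS = data.frame(name = c("NE2", "ND1", "CA"),
                   dx = c(0, 0.7, 0.4), dy = c(0, 2.0, 1.0),
                   dz = c(0, 0, 3.9)),
  ALA = data.frame(name = c("CA", "CB"),
                   dx = c(0, 0), dy = c(0, 0), dz = c(0, 1.5)),
  GLY = data.frame(name = "CA", dx = 0, dy = 0, dz = 0))

.template_for <- function(resname) {
  tpl <- .residue_templates[[resname]]
  if (is.null(tpl)) tpl <- .residue_templates[["GLY"]]
  tpl
}

#' Specification of a synthetic toy structure
#'
#' @param placements data.frame with columns resname, resnum, chain, x, y,
#'   z: the coordinate of each residue's key side-chain atom (NZ for LYS,
#'   OD1 for ASP, OE1 for GLU, NH1 for ARG, NE2 for HIS, CA otherwise).
#' @param decoy_shells optional list of shells, each
#'   `list(chain=, resnum=, count=, radius=)`: `count` occluding carbon
#'   atoms on a sphere of `radius` Angstrom around the target residue's
#'   centroid, burying it.
#' @param seed integer recorded in the spec (generators are fully
#'   deterministic; the seed matters only for downstream noisy
#'   simulations).
#' @return object of class `structure_spec`.
#' @export
structure_spec <- function(placements, decoy_shells = NULL, seed = 1L) {
  stopifnot(is.data.frame(placements),
            all(c("resname", "resnum", "chain", "x", "y", "z") %in%
                  names(placements)))
  if (anyDuplicated(paste(placements$chain, placements$resnum))) {
    stop("residue numbers must be unique per chain")
  }
  if (!all(is.finite(placements$x) & is.finite(placements$y) &
             is.finite(placements$z))) {
    stop("placement coordinates must be finite")
  }
  out <- list(placements = placements, decoy_shells = decoy_shells,
              seed = as.integer(seed))
  class(out) <- "structure_spec"
  out
}

#' Build a synthetic structure with ground-truth annotations
#'
#' Emits minimal ideal residue fragments (backbone CA plus named
#' side-chain atoms) at the requested key-atom coordinates, plus optional
#' occluding decoy shells (carbon atoms on a deterministic golden-spiral
#' sphere, chain "Z"). Ground truth reports which residues are buried by
#' a shell, which basic-acidic pairs sit within the salt-bridge cutoff,
#' and all pairwise lysine NZ-NZ distances.
#'
#' @param spec a `structure_spec`.
#' @param bridge_cutoff Angstrom cutoff used for the ground-truth bridge
#'   annotation (default 4.0).
#' @return list with `structure` (a `protein_structure`) and
#'   `annotations` (list: buried_keys, bridges, nz_distances).
#' @export
make_structure <- function(spec, bridge_cutoff = 4.0) {
  stopifnot(inherits(spec, "structure_spec"))
  pl <- spec$placements
  rows <- vector("list", nrow(pl))
  for (i in seq_len(nrow(pl))) {
    tpl <- .template_for(pl$resname[i])
    rows[[i]] <- data.frame(
      name = tpl$name, resname = pl$resname[i], chain = pl$chain[i],
      resnum = pl$resnum[i],
      x = pl$x[i] + tpl$dx, y = pl$y[i] + tpl$dy, z = pl$z[i] + tpl$dz,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)

  buried_keys <- character(0)
  if (!is.null(spec$decoy_shells)) {
    shells <- spec$decoy_shells
    if (!is.null(shells$resnum)) shells <- list(shells)
    shell_rows <- list()
    next_num <- 9000L
    for (sh in shells) {
      ch <- if (is.null(sh$chain)) "A" else sh$chain
      target <- atoms$chain == ch & atoms$resnum == sh$resnum
      if (!any(target)) stop("decoy shell targets unknown residue ",
                             ch, ":", sh$resnum)
      ctr <- c(mean(atoms$x[target]), mean(atoms$y[target]),
               mean(atoms$z[target]))
      pts <- golden_spiral_points(sh$count) * sh$radius
      shell_rows[[length(shell_rows) + 1L]] <- data.frame(
        name = "CA", resname = "DUM", chain = "Z",
        resnum = next_num + seq_len(sh$count) - 1L,
        x = ctr[1] + pts[, 1], y = ctr[2] + pts[, 2],
        z = ctr[3] + pts[, 3], stringsAsFactors = FALSE)
      next_num <- next_num + sh$count
      buried_keys <- c(buried_keys,
                       residue_key(ch, sh$resnum, "",
                                   atoms$resname[target][1]))
    }
    atoms <- rbind(atoms, do.call(rbind, shell_rows))
  }

  # collision guard on distinct atoms
  n <- nrow(atoms)
  if (n > 1L) {
    d2 <- as.matrix(stats::dist(cbind(atoms$x, atoms$y, atoms$z)))
    diag(d2) <- Inf
    if (min(d2) < 0.5) {
      stop("coordinate collision: atoms closer than 0.5 Angstrom")
    }
  }

  atoms$serial <- seq_len(n)
  atoms$altloc <- ""
  atoms$icode <- ""
  atoms$occupancy <- 1.0
  atoms$element <- substr(sub("^[0-9]*", "", atoms$name), 1, 1)
  radii <- default_element_radii()
  atoms$radius <- unname(radii[atoms$element])
  atoms$radius[is.na(atoms$radius)] <- .radius_fallback
  atoms$key <- residue_key(atoms$chain, atoms$resnum, atoms$icode,
                           atoms$resname)
  atoms <- atoms[, c("serial", "name", "altloc", "resname", "chain",
                     "resnum", "icode", "x", "y", "z", "occupancy",
                     "element", "radius", "key")]
  st <- new_protein_structure(atoms)

  annotations <- list(
    buried_keys = buried_keys,
    bridges = .annotate_bridges(atoms, bridge_cutoff),
    nz_distances = .annotate_nz(atoms))
  list(structure = st, annotations = annotations)
}

# ground-truth bridge annotation: plain double loop over charged residues
.annotate_bridges <- function(atoms, cutoff) {
  bk <- unique(atoms$key[atoms$resname %in% names(.basic_atoms)])
  ak <- unique(atoms$key[atoms$resname %in% names(.acidic_atoms)])
  out <- list()
  for (b in bk) {
    brow <- atoms[atoms$key == b &
                    atoms$name %in%
                    .basic_atoms[[atoms$resname[atoms$key == b][1]]], ,
                  drop = FALSE]
    for (a in ak) {
      arow <- atoms[atoms$key == a &
                      atoms$name %in%
                      .acidic_atoms[[atoms$resname[atoms$key == a][1]]], ,
                    drop = FALSE]
      dmin <- Inf
      for (i in seq_len(nrow(brow))) {
        for (j in seq_len(nrow(arow))) {
          d <- sqrt((brow$x[i] - arow$x[j])^2 +
                      (brow$y[i] - arow$y[j])^2 +
                      (brow$z[i] - arow$z[j])^2)
          if (d < dmin) dmin <- d
        }
      }
      if (dmin <= cutoff) {
        out[[length(out) + 1L]] <- data.frame(
          basic_key = b, acidic_key = a, min_distance = dmin,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(basic_key = character(0),
                      acidic_key = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$basic_key, out$acidic_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.annotate_nz <- function(atoms) {
  nz <- atoms[atoms$resname == "LYS" & atoms$name == "NZ", , drop = FALSE]
  nz <- nz[order(nz$chain, nz$resnum), , drop = FALSE]
  if (nrow(nz) < 2L) {
    return(data.frame(lys_a = character(0), lys_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(nrow(nz), 2)
  i <- idx[1, ]; j <- idx[2, ]
  data.frame(lys_a = nz$key[i], lys_b = nz$key[j],
             distance = sqrt((nz$x[i] - nz$x[j])^2 +
                               (nz$y[i] - nz$y[j])^2 +
                               (nz$z[i] - nz$z[j])^2),
             stringsAsFactors = FALSE)
}

#' Random synthetic structure with well-separated residues
#'
#' Places `n_residues` key atoms by rejection sampling in a cube with a
#' minimum pairwise separation (default 6 Angstrom, which guarantees no
#' atom collisions given the fragment templates), then builds the
#' structure via [make_structure()]. Reproducible under `seed`.
#'
#' @param n_residues number of residues.
#' @param seed RNG seed.
#' @param pool residue names to sample from.
#' @param min_separation minimum key-atom separation, Angstrom.
#' @return as [make_structure()], plus `$spec`.
#' @export
random_structure <- function(n_residues, seed = 1L,
                             pool = c("LYS", "ASP", "GLU", "ARG", "HIS",
                                      "GLY", "ALA"),
                             min_separation = 6.0) {
  stopifnot(n_residues >= 1)
  with_seed(seed, {
    side <- max(min_separation * (3 * n_residues)^(1 / 3), min_separation)
    pts <- matrix(NA_real_, n_residues, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n_residues) {
      cand <- stats::runif(3, 0, side)
      ok <- placed == 0L ||
        min(sqrt(colSums((t(pts[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= min_separation
      if (ok) {
        placed <- placed + 1L
        pts[placed, ] <- cand
      }
      tries <- tries + 1L
      if (tries > 20000L * n_residues) {
        side <- side * 1.3  # box too dense: expand and continue
        tries <- 0L
      }
    }
    placements <- data.frame(
      resname = sample(pool, n_residues, replace = TRUE),
      resnum = seq_len(n_residues), chain = "A",
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      stringsAsFactors = FALSE)
    spec <- structure_spec(placements, seed = seed)
    out <- make_structure(spec)
    out$spec <- spec
    out
  })
}

#' Simulate a first-order activity decay series
#'
#' `A(t) = A0 * exp(-kd * t) * (1 + e_t)` with
#' `e_t ~ N(0, noise_sd_fraction)` (multiplicative noise, matching
#' percent-scale activity assays); negative draws are truncated at 0.
#'
#' @param kd_true positive decay constant, min^-1.
#' @param times sampling times, minutes.
#' @param A0 initial activity.
#' @param noise_sd_fraction fractional noise SD (0 = noiseless).
#' @param seed RNG seed.
#' @param temperature label stored on the series.
#' @return a `decay_series` with attribute `kd_true`.
#' @export
simulate_decay <- function(kd_true, times, A0 = 100,
                           noise_sd_fraction = 0, seed = 1L,
                           temperature = 60) {
  stopifnot(kd_true > 0, noise_sd_fraction >= 0)
  a <- A0 * exp(-kd_true * times)
  if (noise_sd_fraction > 0) {
    a <- with_seed(seed, a * (1 + rnorm(length(times), 0,
                                        noise_sd_fraction)))
    a <- pmax(a, 0)
  }
  out <- decay_series(times, a, temperature)
  attr(out, "kd_true") <- kd_true
  out
}

#' Simulate a TNBS absorbance reading
#'
#' Forward model of the lysine standard curve:
#' `absorbance = slope * conc + intercept + N(0, noise_sd)`.
#'
#' @param n_free_lys_mM free-lysine concentration(s), mM.
#' @param curve a `standard_curve` (or list with slope/intercept).
#' @param noise_sd absorbance noise SD.
#' @param seed RNG seed.
#' @return numeric absorbance(s).
#' @export
simulate_tnbs <- function(n_free_lys_mM, curve, noise_sd = 0, seed = 1L) {
  stopifnot(curve$slope > 0, noise_sd >= 0)
  ab <- curve$slope * n_free_lys_mM + curve$intercept
  if (noise_sd > 0) {
    ab <- with_seed(seed, ab + rnorm(length(ab), 0, noise_sd))
  }
  ab
}
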