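#' Henderson-Hasselbalch lysine reactivity score
#'
#' The reactivity index of a lysine epsilon-amine at the modification pH
#' is the fraction-deprotonated ratio `10^(pH - pKa)`. Residues score
#' "low" below 0.1, "semi" between 0.1 and 1.0 (boundaries inclusive) and
#' "high" above 1.0.
#'
#' @param pka predicted pKa value(s).
#' @param ph modification pH (scalar or vector recycled against `pka`).
#' @param thresholds length-2 increasing vector (low/semi, semi/high).
#' @return data.frame with pka, ph, lys_re, reactivity_class.
#' @export
lys_reactivity <- function(pka, ph, thresholds = c(0.1, 1.0)) {
  stopifnot(is.numeric(pka), is.numeric(ph),
            all(is.finite(pka)), all(is.finite(ph)),
            length(thresholds) == 2L, thresholds[1] < thresholds[2])
  lys_re <- 10^(ph - pka)
  cls <- ifelse(lys_re < thresholds[1], "low",
                ifelse(lys_re > thresholds[2], "high", "semi"))
  data.frame(pka = pka, ph = ph, lys_re = lys_re, reactivity_class = cls,
             stringsAsFactors = FALSE)
}

# coordinates of named side-chain atoms for the given residue rows
.charged_group_atoms <- function(atoms, atom_table) {
  sel <- logical(nrow(atoms))
  for (rn in names(atom_table)) {
    sel <- sel | (atoms$resname == rn & atoms$name %in% atom_table[[rn]])
  }
  atoms[sel, , drop = FALSE]
}

#' Detect salt bridges between basic and acidic side chains
#'
#' Reports a bridge when any charged-group nitrogen of LYS (NZ), ARG
#' (NH1/NH2/NE) or HIS (ND1/NE2) lies within `cutoff` of any carboxylate
#' oxygen of ASP (OD1/OD2) or GLU (OE1/OE2); the minimum over atom pairs
#' is reported. Charged residues missing all relevant side-chain atoms
#' are skipped with a warning.
#'
#' @param structure a `protein_structure`.
#' @param cutoff N...O distance cutoff in Angstrom (default 4.0,
#'   Barlow-Thornton criterion).
#' @return data.frame: basic_key, acidic_key, min_distance; zero rows when
#'   no bridge is present.
#' @export
detect_salt_bridges <- function(structure, cutoff = 4.0) {
  stopifnot(inherits(structure, "protein_structure"), cutoff > 0)
  a <- structure$atoms
  basic <- .charged_group_atoms(a, .basic_atoms)
  acidic <- .charged_group_atoms(a, .acidic_atoms)

  charged <- structure$residues
  charged <- charged[charged$resname %in% c(names(.basic_atoms),
                                            names(.acidic_atoms)), ,
                     drop = FALSE]
  present <- c(unique(basic$key), unique(acidic$key))
  missing_sc <- setdiff(charged$key, present)
  if (length(missing_sc) > 0L) {
    warning("charged residue(s) without charged-group side-chain atoms ",
            "skipped: ", paste(missing_sc, collapse = ", "))
  }
  empty <- data.frame(basic_key = character(0), acidic_key = character(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(basic) == 0L || nrow(acidic) == 0L) return(empty)

  # all-pairs atom distances between the two (small) charged-atom sets
  d2 <- outer(basic$x, acidic$x, "-")^2 +
    outer(basic$y, acidic$y, "-")^2 +
    outer(basic$z, acidic$z, "-")^2
  d <- sqrt(d2)
  pair_id <- paste(basic$key[row(d)], acidic$key[col(d)], sep = "\r")
  dmin <- tapply(as.vector(d), pair_id, min)
  hit <- dmin <= cutoff
  if (!any(hit)) return(empty)
  keys <- strsplit(names(dmin)[hit], "\r", fixed = TRUE)
  out <- data.frame(basic_key = vapply(keys, `[`, "", 1),
                    acidic_key = vapply(keys, `[`, "", 2),
                    min_distance = unname(dmin[hit]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$basic_key, out$acidic_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lysine pair distances and crosslinker span feasibility
#'
#' For every unordered pair of lysines computes the NZ-NZ and CA-CA
#' distances and lists the bifunctional agents whose span covers the
#' NZ-NZ distance. Pairs bridgeable by no agent are still listed (empty
#' agent string). Monofunctional agents never appear here.
#'
#' @param structure a `protein_structure`.
#' @param agents agent table as from [default_agents()]; only rows with
#'   `bifunctional == TRUE` and finite spans are used.
#' @return data.frame: lys_a, lys_b, nz_nz_distance, ca_ca_distance,
#'   compatible_agents (comma-separated). Fewer than two lysines with NZ
#'   atoms yields zero rows.
#' @export
crosslink_pairs <- function(structure, agents = default_agents()) {
  stopifnot(inherits(structure, "protein_structure"))
  span <- agents[isTRUE_vec(agents$bifunctional) &
                   is.finite(agents$span_min) &
                   is.finite(agents$span_max), , drop = FALSE]
  a <- structure$atoms
  nz <- a[a$resname == "LYS" & a$name == "NZ", , drop = FALSE]
  ca <- a[a$resname == "LYS" & a$name == "CA", , drop = FALSE]
  nz <- nz[order(nz$chain, nz$resnum, nz$icode), , drop = FALSE]
  empty <- data.frame(lys_a = character(0), lys_b = character(0),
                      nz_nz_distance = numeric(0),
                      ca_ca_distance = numeric(0),
                      compatible_agents = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(nz) < 2L) return(empty)
  idx <- utils::combn(nrow(nz), 2)
  i <- idx[1, ]; j <- idx[2, ]
  dnz <- sqrt((nz$x[i] - nz$x[j])^2 + (nz$y[i] - nz$y[j])^2 +
                (nz$z[i] - nz$z[j])^2)
  camap <- setNames(seq_len(nrow(ca)), ca$key)
  dca <- rep(NA_real_, length(i))
  ai <- camap[nz$key[i]]; aj <- camap[nz$key[j]]
  ok <- !is.na(ai) & !is.na(aj)
  dca[ok] <- sqrt((ca$x[ai[ok]] - ca$x[aj[ok]])^2 +
                    (ca$y[ai[ok]] - ca$y[aj[ok]])^2 +
                    (ca$z[ai[ok]] - ca$z[aj[ok]])^2)
  compat <- vapply(dnz, function(d) {
    paste(span$agent[span$span_min <= d & d <= span$span_max],
          collapse = ",")
  }, "")
  data.frame(lys_a = nz$key[i], lys_b = nz$key[j],
             nz_nz_distance = dnz, ca_ca_distance = dca,
             compatible_agents = compat, stringsAsFactors = FALSE)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Integrated triage of candidate lysine modification sites
#'
#' Combines relative exposure, salt-bridge membership and (optionally)
#' pKa-based reactivity at the modification pH into a ranked candidate
#' list. A lysine is a candidate when it is exposed and not a member of
#' any salt bridge. Ranking: reactivity class (high > semi > low), then
#' LysRe descending, then relative SASA descending, ties broken by
#' (chain, residue number). Lysines without a pKa entry are ranked by
#' exposure only and flagged (`has_pka = FALSE`).
#'
#' @param exposure residue exposure table from [residue_exposure()]
#'   (non-lysine rows are ignored).
#' @param bridges salt-bridge table from [detect_salt_bridges()].
#' @param ph modification pH (required; no default is guessed).
#' @param pka_table optional `pka_table`; lysine entries must exist in the
#'   structure (unknown lysine keys are an input-consistency error).
#' @param thresholds reactivity class boundaries, see [lys_reactivity()].
#' @return data.frame of lysine profiles ordered by rank: chain, resnum,
#'   key, relative_sasa, exposure_class, pka, lys_re, reactivity_class,
#'   has_pka, in_salt_bridge, salt_bridge_partners, candidate, rank.
#' @export
triage_sites <- function(exposure, bridges, ph, pka_table = NULL,
                         thresholds = c(0.1, 1.0)) {
  stopifnot(is.data.frame(exposure), is.data.frame(bridges))
  if (missing(ph) || is.null(ph) || !is.finite(ph)) {
    stop("a modification pH is required")
  }
  lys <- exposure[exposure$resname == "LYS", , drop = FALSE]
  if (anyDuplicated(lys$key)) stop("duplicate lysine key in exposure input")
  if (nrow(lys) == 0L) {
    out <- lys[, c("chain", "resnum", "key", "relative_sasa",
                   "exposure_class")]
    out$pka <- numeric(0); out$lys_re <- numeric(0)
    out$reactivity_class <- character(0); out$has_pka <- logical(0)
    out$in_salt_bridge <- logical(0)
    out$salt_bridge_partners <- character(0)
    out$candidate <- logical(0); out$rank <- integer(0)
    return(out)
  }

  prof <- lys[, c("chain", "resnum", "key", "relative_sasa",
                  "exposure_class")]
  prof$pka <- NA_real_
  if (!is.null(pka_table)) {
    pk <- pka_table[pka_table$resname == "LYS", , drop = FALSE]
    unknown <- setdiff(pk$key, prof$key)
    if (length(unknown) > 0L) {
      stop("pKa table lists lysine(s) absent from the structure: ",
           paste(unknown, collapse = ", "))
    }
    prof$pka <- pk$pka[match(prof$key, pk$key)]
  }
  prof$has_pka <- !is.na(prof$pka)
  prof$lys_re <- ifelse(prof$has_pka, 10^(ph - prof$pka), NA_real_)
  prof$reactivity_class <- NA_character_
  scored <- prof$has_pka
  if (any(scored)) {
    prof$reactivity_class[scored] <-
      lys_reactivity(prof$pka[scored], ph, thresholds)$reactivity_class
  }

  partners <- lapply(prof$key, function(k) {
    bridges$acidic_key[bridges$basic_key == k]
  })
  prof$in_salt_bridge <- vapply(partners, length, 0L) > 0L
  prof$salt_bridge_partners <- vapply(partners, paste, "", collapse = ",")
  prof$candidate <- prof$exposure_class == "exposed" & !prof$in_salt_bridge

  cls_rank <- match(prof$reactivity_class, c("high", "semi", "low"))
  cls_rank[is.na(cls_rank)] <- 4L  # no pKa: exposure-only ranking, last
  ord <- order(cls_rank, -ifelse(is.na(prof$lys_re), -Inf, prof$lys_re),
               -ifelse(is.na(prof$relative_sasa), -Inf,
                       prof$relative_sasa),
               prof$chain, prof$resnum)
  prof <- prof[ord, , drop = FALSE]
  prof$rank <- seq_len(nrow(prof))
  rownames(prof) <- NULL
  prof
}
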