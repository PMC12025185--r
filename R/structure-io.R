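#' Parse a PDB coordinate file into a protein structure
#'
#' Reads ATOM records from PDB-format text. Only the first MODEL is kept;
#' HETATM records, hydrogens/deuteriums and waters are excluded by default.
#' For alternate locations the highest-occupancy conformer is retained
#' (ties resolved toward altloc "A"). The element is taken from columns
#' 77-78 when present, otherwise inferred from the atom name. Every
#' retained atom is assigned a van der Waals radius from `radii` (unknown
#' elements fall back to 1.80 Angstrom with a warning).
#'
#' @param file path to a PDB file. Ignored when `text` is given.
#' @param text character vector of PDB lines (or a single string with
#'   embedded newlines).
#' @param keep_hetatm keep HETATM records (waters are still dropped).
#' @param radii named element -> radius table, see [default_element_radii()].
#' @return an object of class `protein_structure`: a list with `atoms`
#'   (data.frame: serial, name, altloc, resname, chain, resnum, icode,
#'   x, y, z, occupancy, element, radius, key) and `residues` (data.frame
#'   of unique residue keys in file order).
#' @export
parse_pdb <- function(file = NULL, text = NULL, keep_hetatm = FALSE,
                      radii = default_element_radii()) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L, file.exists(file))
    text <- readLines(file, warn = FALSE)
  }
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  # restrict to the first model when MODEL records are present
  model_starts <- grep("^MODEL ", text)
  if (length(model_starts) > 0L) {
    endmdl <- grep("^ENDMDL", text)
    stop_at <- if (length(endmdl)) endmdl[1] else length(text)
    text <- text[seq(model_starts[1], stop_at)]
  }
  rec <- substr(text, 1, 6)
  take <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  lineno <- which(take)
  if (length(lineno) == 0L) stop("no ATOM records found in PDB input")
  ln <- text[take]

  fx <- function(from, to) trimws(substr(ln, from, to))
  serial <- suppressWarnings(as.integer(fx(7, 11)))
  name <- fx(13, 16)
  altloc <- substr(ln, 17, 17)
  resname <- fx(18, 20)
  chain <- substr(ln, 22, 22)
  resnum <- suppressWarnings(as.integer(fx(23, 26)))
  icode <- trimws(substr(ln, 27, 27))
  xs <- suppressWarnings(as.numeric(fx(31, 38)))
  ys <- suppressWarnings(as.numeric(fx(39, 46)))
  zs <- suppressWarnings(as.numeric(fx(47, 54)))
  occ <- suppressWarnings(as.numeric(fx(55, 60)))
  occ[is.na(occ)] <- 1.0
  elem <- toupper(fx(77, 78))

  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(resnum)
  if (any(bad)) {
    stop("malformed ATOM record at line ", lineno[which(bad)[1]],
         ": ", ln[which(bad)[1]])
  }
  # element fallback: first non-digit character of the atom name
  miss <- elem == ""
  if (any(miss)) {
    guess <- sub("^[0-9]*", "", name[miss])
    elem[miss] <- substr(guess, 1, 1)
  }

  atoms <- data.frame(serial = serial, name = name, altloc = altloc,
                      resname = resname, chain = chain, resnum = resnum,
                      icode = icode, x = xs, y = ys, z = zs,
                      occupancy = occ, element = elem,
                      stringsAsFactors = FALSE)
  atoms <- atoms[!(atoms$element %in% c("H", "D")) &
                   !(atoms$resname %in% c("HOH", "WAT", "DOD")), ,
                 drop = FALSE]
  if (nrow(atoms) == 0L) stop("no heavy atoms retained from PDB input")

  # altloc resolution: highest occupancy wins, ties go to altloc "A"
  id <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$resname,
              atoms$name, sep = "\r")
  if (anyDuplicated(id)) {
    pref <- order(id, -atoms$occupancy, atoms$altloc != "A", atoms$altloc)
    atoms <- atoms[pref, , drop = FALSE]
    keep <- !duplicated(id[pref])
    atoms <- atoms[keep, , drop = FALSE]
    atoms <- atoms[order(match(atoms$serial, serial)), , drop = FALSE]
    id <- id[pref][keep]
    if (anyDuplicated(paste(atoms$chain, atoms$resnum, atoms$icode,
                            atoms$name, sep = "\r"))) {
      stop("duplicate atom (same chain/residue/atom name) after altloc ",
           "resolution")
    }
  }

  atoms$radius <- unname(radii[atoms$element])
  unknown <- is.na(atoms$radius)
  if (any(unknown)) {
    warning("element(s) ", paste(unique(atoms$element[unknown]),
                                 collapse = ", "),
            " not in radius table; using fallback ", .radius_fallback,
            " Angstrom")
    atoms$radius[unknown] <- .radius_fallback
  }
  atoms$key <- residue_key(atoms$chain, atoms$resnum, atoms$icode,
                           atoms$resname)
  rownames(atoms) <- NULL
  new_protein_structure(atoms)
}

residue_key <- function(chain, resnum, icode, resname) {
  paste0(chain, ":", resnum, ifelse(icode == "", "", icode), ":", resname)
}

new_protein_structure <- function(atoms) {
  first <- !duplicated(atoms$key)
  residues <- data.frame(chain = atoms$chain[first],
                         resnum = atoms$resnum[first],
                         icode = atoms$icode[first],
                         resname = atoms$resname[first],
                         key = atoms$key[first],
                         stringsAsFactors = FALSE)
  rownames(residues) <- NULL
  structure(list(atoms = atoms, residues = residues),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Write a protein structure to a PDB file
#'
#' @param structure a `protein_structure`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_pdb <- function(structure, file) {
  stopifnot(inherits(structure, "protein_structure"))
  a <- structure$atoms
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial, nm, a$altloc, a$resname, a$chain, a$resnum,
    ifelse(a$icode == "", " ", a$icode), a$x, a$y, a$z, a$occupancy, 0,
    a$element)
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Read a per-residue pKa table
#'
#' Tab-separated table with a header row and columns chain, residue
#' number, residue name, pKa (as produced by PROPKA-class predictors).
#' Lines starting with `#` are ignored. Non-lysine rows are retained;
#' downstream triage filters by residue name.
#'
#' @param file path to the TSV file. Ignored when `text` is given.
#' @param text character scalar/vector with the TSV content.
#' @return object of class `pka_table`: data.frame with chain, resnum,
#'   resname, pka, key.
#' @export
read_pka_table <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    if (length(text) > 1L) text <- paste(text, collapse = "\n")
    df <- read.delim(text = text, comment.char = "#",
                     stringsAsFactors = FALSE)
  }
  if (ncol(df) < 4L) stop("pKa table needs >= 4 columns: ",
                          "chain, resnum, resname, pKa")
  out <- data.frame(chain = as.character(df[[1]]),
                    resnum = as.integer(df[[2]]),
                    resname = toupper(as.character(df[[3]])),
                    pka = suppressWarnings(as.numeric(df[[4]])),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) {
    out$key <- character(0)
    class(out) <- c("pka_table", "data.frame")
    return(out)
  }
  if (anyNA(out$pka)) {
    stop("unparsable pKa value in row ", which(is.na(out$pka))[1])
  }
  if (any(out$pka <= 0 | out$pka >= 20)) {
    stop("pKa values must lie in (0, 20)")
  }
  out$key <- residue_key(out$chain, out$resnum, "", out$resname)
  if (anyDuplicated(out$key)) {
    stop("duplicate residue key in pKa table: ",
         out$key[anyDuplicated(out$key)])
  }
  rownames(out) <- NULL
  class(out) <- c("pka_table", "data.frame")
  out
}

#' Read a condition-vs-activity assay table
#'
#' Tab-separated, header row, columns condition and activity (an optional
#' third replicate column is averaged over). `#` comment lines ignored.
#'
#' @param file path to TSV. Ignored when `text` is given.
#' @param text TSV content.
#' @param metadata free-text condition descriptor.
#' @return an `assay_table`: list with condition_labels, activities,
#'   metadata.
#' @export
read_assay_table <- function(file = NULL, text = NULL, metadata = "") {
  if (is.null(text)) {
    df <- read.delim(file, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    if (length(text) > 1L) text <- paste(text, collapse = "\n")
    df <- read.delim(text = text, comment.char = "#",
                     stringsAsFactors = FALSE)
  }
  if (ncol(df) < 2L) stop("assay table needs condition and activity columns")
  cond <- df[[1]]
  act <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(act)) stop("unparsable activity value in assay table")
  if (ncol(df) >= 3L && !anyNA(suppressWarnings(as.numeric(df[[3]])))) {
    # replicate column present: average replicates per condition
    agg <- tapply(act, cond, mean)
    cond <- names(agg)
    act <- unname(agg)
  }
  assay_table(cond, act, metadata)
}

#' Construct an assay table
#'
#' @param condition_labels condition labels (pH, temperature, mM, ...).
#' @param activities matching non-negative activities.
#' @param metadata free-text descriptor.
#' @return an `assay_table` list.
#' @export
assay_table <- function(condition_labels, activities, metadata = "") {
  if (length(condition_labels) != length(activities)) {
    stop("condition_labels and activities must have equal length")
  }
  if (any(activities < 0)) stop("activities must be non-negative")
  structure(list(condition_labels = condition_labels,
                 activities = as.numeric(activities),
                 metadata = metadata),
            class = "assay_table")
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are reported in file order; residue names outside the 20
#' standard amino acids map to "X".
#'
#' @param structure a `protein_structure`.
#' @param chain single-character chain id.
#' @return one-letter amino-acid string.
#' @export
extract_sequence <- function(structure, chain) {
  stopifnot(inherits(structure, "protein_structure"))
  res <- structure$residues
  res <- res[res$chain == chain, , drop = FALSE]
  if (nrow(res) == 0L) stop("unknown chain: ", chain)
  letters1 <- .aa_three_to_one[res$resname]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}
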