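#' Default van der Waals radii by element
#'
#' Heavy-atom united radii used for SASA: hydrogens are dropped at parse
#' time and their volume is implicitly absorbed by the heavy-atom radii.
#'
#' @param overrides named numeric vector of element -> radius (Angstrom)
#'   merged over the defaults (C 1.70, N 1.55, O 1.52, S 1.80).
#' @return named numeric vector of radii in Angstrom.
#' @export
default_element_radii <- function(overrides = NULL) {
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  if (!is.null(overrides)) {
    stopifnot(is.numeric(overrides), !is.null(names(overrides)),
              all(overrides > 0))
    r[names(overrides)] <- overrides
  }
  r
}

# radius fallback for elements outside the table (P, Se, metals kept by a
# permissive caller); generous so burial is never overstated
.radius_fallback <- 1.80

#' Theoretical maximum accessible surface area per residue
#'
#' Gly-X-Gly extended tripeptide reference values (theoretical scale of
#' Tien et al. 2013), used to normalize residue SASA into relative
#' exposure.
#'
#' @return named numeric vector, Angstrom squared, by 3-letter residue code.
#' @export
max_asa_reference <- function() {
  c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)
}

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

# side-chain atoms carrying the formal charge, used for salt-bridge geometry
.basic_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                     HIS = c("ND1", "NE2"))
.acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Default modifying-agent table
#'
#' Agents used in laccase lysine-modification protocols, with the buffer pH
#' of each protocol and, for bifunctional crosslinkers, the NZ-NZ span
#' (Angstrom) they can bridge. CDI performs zero-length amide coupling and
#' is treated as monofunctional for pair analysis; CA, N-HSP, PS and the
#' saccharides modify single amino groups.
#'
#' @return data.frame with columns agent, ph, bifunctional, span_min,
#'   span_max.
#' @export
default_agents <- function() {
  data.frame(
    agent = c("EGNHS", "CA", "GA", "CDI", "GA-CDI", "N-HSP", "PS"),
    ph = c(7.4, 9.0, 5.5, 5.5, 5.5, 8.0, 8.0),
    bifunctional = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE),
    span_min = c(4, NA, 4, NA, 4, NA, NA),
    span_max = c(18, NA, 11, NA, 11, NA, NA),
    stringsAsFactors = FALSE)
}
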