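# Independent oracles used across tests. These deliberately avoid the
# production code paths: plain nested loops and direct point-in-sphere
# checks instead of the vectorized / compiled implementations.

# brute-force all-pairs salt-bridge scan
bf_salt_bridges <- function(structure, cutoff = 4.0) {
  basic_atoms <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                      HIS = c("ND1", "NE2"))
  acidic_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
  a <- structure$atoms
  res <- structure$residues
  out <- data.frame(basic_key = character(0), acidic_key = character(0),
                    min_distance = numeric(0), stringsAsFactors = FALSE)
  for (b in res$key[res$resname %in% names(basic_atoms)]) {
    brn <- res$resname[res$key == b]
    bi <- which(a$key == b & a$name %in% basic_atoms[[brn]])
    for (ac in res$key[res$resname %in% names(acidic_atoms)]) {
      arn <- res$resname[res$key == ac]
      ai <- which(a$key == ac & a$name %in% acidic_atoms[[arn]])
      dmin <- Inf
      for (i in bi) for (j in ai) {
        d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                    (a$z[i] - a$z[j])^2)
        dmin <- min(dmin, d)
      }
      if (dmin <= cutoff) {
        out <- rbind(out, data.frame(basic_key = b, acidic_key = ac,
                                     min_distance = dmin,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[order(out$basic_key, out$acidic_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pure-R Shrake-Rupley for one atom: direct point-in-sphere test against
# all other atoms (no neighbour pruning, no compiled code)
bf_atom_sasa <- function(structure, atom_index, probe = 1.4,
                         n_points = 960) {
  a <- structure$atoms
  ri <- a$radius[atom_index] + probe
  pts <- golden_spiral_points(n_points) * ri
  pts <- sweep(pts, 2, c(a$x[atom_index], a$y[atom_index],
                         a$z[atom_index]), "+")
  free <- rep(TRUE, n_points)
  for (j in seq_len(nrow(a))) {
    if (j == atom_index) next
    rj <- a$radius[j] + probe
    d2 <- (pts[, 1] - a$x[j])^2 + (pts[, 2] - a$y[j])^2 +
      (pts[, 3] - a$z[j])^2
    free <- free & d2 >= rj^2
  }
  4 * pi * ri^2 * mean(free)
}

# toy structure: n_lys well-separated lysines, the first n_bridged of
# which get an ASP carboxylate 3.2 A from their NZ
bridged_lysine_field <- function(n_lys, n_bridged) {
  stopifnot(n_bridged <= n_lys)
  pl <- data.frame(resname = "LYS", resnum = seq_len(n_lys), chain = "A",
                   x = 40 * (seq_len(n_lys) - 1), y = 0, z = 0,
                   stringsAsFactors = FALSE)
  if (n_bridged > 0) {
    asp <- data.frame(resname = "ASP",
                      resnum = 100 + seq_len(n_bridged), chain = "A",
                      x = 40 * (seq_len(n_bridged) - 1) + 3.2,
                      y = 0, z = 0, stringsAsFactors = FALSE)
    pl <- rbind(pl, asp)
  }
  make_structure(structure_spec(pl))
}

table2_fixture <- function() {
  read.delim(system.file("extdata", "thermostability_60C.tsv",
                         package = "laccmod"),
             comment.char = "#", stringsAsFactors = FALSE)
}
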