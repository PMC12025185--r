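# Shrake-Rupley SASA, exposure classification, surface partition

one_sphere <- function(resname = "GLY", x = 0) {
  make_structure(structure_spec(data.frame(
    resname = resname, resnum = 1, chain = "A", x = x, y = 0,
    z = 0)))$structure
}

test_that("isolated spheres match the closed-form area", {
  st <- one_sphere()  # single carbon, r = 1.70
  s <- shrake_rupley(st, probe_radius = 1.4, n_points = 960)
  expect_equal(s$total, 4 * pi * 3.10^2, tolerance = 0.01)
  # two carbons far apart are independent
  st2 <- make_structure(structure_spec(data.frame(
    resname = "GLY", resnum = 1:2, chain = "A", x = c(0, 100), y = 0,
    z = 0)))$structure
  s2 <- shrake_rupley(st2)
  expect_equal(s2$total, 2 * 4 * pi * 3.10^2, tolerance = 0.01)
  expect_equal(sum(s2$per_atom), s2$total, tolerance = 1e-9)
})

test_that("an atom enclosed by a shell has zero SASA", {
  shell <- golden_spiral_points(30) * 2.0
  m <- make_structure(structure_spec(data.frame(
    resname = "GLY", resnum = 1:31, chain = "A",
    x = c(0, shell[, 1]), y = c(0, shell[, 2]), z = c(0, shell[, 3]))))
  s <- shrake_rupley(m$structure)
  expect_identical(bf_atom_sasa(m$structure, 1), 0)  # oracle agrees
  expect_equal(s$per_atom[1], 0)
})

test_that("per-atom values are non-negative and sum to residue/total", {
  sim <- random_structure(30, seed = 7)
  s <- shrake_rupley(sim$structure)
  expect_true(all(s$per_atom >= 0))
  expect_equal(sum(s$per_atom), s$total, tolerance = 1e-9)
  agg <- tapply(s$per_atom, sim$structure$atoms$key, sum)
  expect_equal(unname(s$per_residue[names(agg)]), as.numeric(agg),
               tolerance = 1e-9)
})

test_that("compiled SASA equals the pure-R point-in-sphere oracle", {
  sim <- random_structure(12, seed = 5, min_separation = 6)
  s <- shrake_rupley(sim$structure, n_points = 272)
  oracle <- vapply(seq_len(nrow(sim$structure$atoms)), function(i) {
    bf_atom_sasa(sim$structure, i, n_points = 272)
  }, 0)
  expect_equal(s$per_atom, oracle, tolerance = 1e-9)
})

test_that("adding an atom never increases another atom's SASA", {
  for (seed in 1:5) {
    sim <- random_structure(10, seed = seed, min_separation = 6)
    s0 <- shrake_rupley(sim$structure, n_points = 272)
    extra <- sim$structure$atoms[1, ]
    extra$serial <- max(sim$structure$atoms$serial) + 1L
    extra$resnum <- 999L
    extra$x <- extra$x + 3.5
    extra$key <- paste0("A:999:", extra$resname)
    st1 <- laccmod:::new_protein_structure(
      rbind(sim$structure$atoms, extra))
    s1 <- shrake_rupley(st1, n_points = 272)
    n <- length(s0$per_atom)
    expect_true(all(s1$per_atom[seq_len(n)] <= s0$per_atom + 1e-9))
  }
})

test_that("quadrature converges and matches an external implementation", {
  sim <- random_structure(50, seed = 42)
  s960 <- shrake_rupley(sim$structure, n_points = 960)
  s3840 <- shrake_rupley(sim$structure, n_points = 3840)
  expect_lt(abs(s960$total - s3840$total) / s960$total, 0.005)
  # frozen oracle: biotite 1.4 struc.sasa() on the identical structure
  # (probe 1.4 A, matching element radii, 2000 points) -> 8481.777 A^2
  expect_equal(s960$total, 8481.777, tolerance = 0.02)
})

test_that("exposure classification follows the 20% threshold", {
  # isolated lysine fragment: maximally exposed
  m <- bridged_lysine_field(1, 0)
  e <- residue_exposure(shrake_rupley(m$structure), m$structure)
  expect_equal(e$exposure_class, "exposed")
  expect_gt(e$relative_sasa, 0.20)

  # boundary convention: rel >= threshold is exposed, below is buried
  st <- m$structure
  s <- shrake_rupley(st)
  s$per_residue["A:1:LYS"] <- 20
  e_at <- residue_exposure(s, st, reference = c(LYS = 100))
  expect_equal(e_at$relative_sasa, 0.20)
  expect_equal(e_at$exposure_class, "exposed")
  s$per_residue["A:1:LYS"] <- 19
  e_below <- residue_exposure(s, st, reference = c(LYS = 100))
  expect_equal(e_below$exposure_class, "buried")

  # shell-buried lysine is classified buried, surface lysine exposed
  sp <- structure_spec(
    data.frame(resname = "LYS", resnum = 1:2, chain = "A",
               x = c(0, 40), y = 0, z = 0),
    decoy_shells = list(resnum = 1, count = 80, radius = 6))
  mb <- make_structure(sp)
  eb <- residue_exposure(shrake_rupley(mb$structure), mb$structure)
  expect_equal(eb$exposure_class[eb$key == "A:1:LYS"], "buried")
  expect_equal(eb$exposure_class[eb$key == "A:2:LYS"], "exposed")
})

test_that("residues missing from the reference table are unscored", {
  m <- bridged_lysine_field(1, 0)
  s <- shrake_rupley(m$structure)
  e <- residue_exposure(s, m$structure, reference = c(GLY = 104))
  expect_equal(e$exposure_class, "unscored")
  expect_true(is.na(e$relative_sasa))
  expect_equal(nrow(e), 1L)  # flagged, never dropped
})

test_that("surface partition conserves total area and computes ratio", {
  st <- one_sphere()
  s <- shrake_rupley(st)
  p <- surface_partition(s, st)
  expect_equal(p$hydrophobic_area, 4 * pi * 3.10^2, tolerance = 0.01)
  expect_equal(p$hydrophilic_area, 0)
  # all-carbon surface: hydrophilic/hydrophobic ratio is zero
  expect_equal(p$ratio_hydrophilic_to_hydrophobic, 0)
  # zero hydrophobic area flags the undefined ratio as Inf
  stN <- one_sphere("LYS")
  stN$atoms <- stN$atoms[stN$atoms$name == "NZ", ]
  stN <- laccmod:::new_protein_structure(stN$atoms)
  sN <- shrake_rupley(stN)
  expect_identical(surface_partition(sN, stN)$ratio_hydrophilic_to_hydrophobic,
                   Inf)

  # carbon + nitrogen far apart
  m2 <- make_structure(structure_spec(data.frame(
    resname = c("GLY", "LYS"), resnum = 1:2, chain = "A",
    x = c(0, 100), y = 0, z = 0)))
  st2 <- m2$structure
  st2$atoms <- st2$atoms[st2$atoms$name %in% c("CA", "NZ") &
                           !(st2$atoms$name == "CA" &
                               st2$atoms$resname == "LYS"), ]
  st2 <- laccmod:::new_protein_structure(st2$atoms)
  s2 <- shrake_rupley(st2)
  p2 <- surface_partition(s2, st2)
  expect_equal(p2$hydrophobic_area, 4 * pi * 3.10^2, tolerance = 0.01)
  expect_equal(p2$hydrophilic_area, 4 * pi * 2.95^2, tolerance = 0.01)
  expect_equal(p2$ratio_hydrophilic_to_hydrophobic, 0.906,
               tolerance = 0.01)

  # conservation on an arbitrary synthetic structure
  sim <- random_structure(25, seed = 9)
  s3 <- shrake_rupley(sim$structure)
  p3 <- surface_partition(s3, sim$structure)
  expect_equal(p3$hydrophobic_area + p3$hydrophilic_area, s3$total,
               tolerance = 1e-6)
})

test_that("SASA input validation", {
  st <- one_sphere()
  expect_error(shrake_rupley(st, n_points = 50), ">= 92")
  st$atoms$x[1] <- NaN
  expect_error(shrake_rupley(st), "non-finite")
})
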