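# reactivity scoring, salt bridges, crosslink spans, integrated triage

test_that("LysRe follows the Henderson-Hasselbalch power law", {
  # pH = pKa: exponent zero, boundary assigned to semi
  r <- lys_reactivity(9.0, 9.0)
  expect_equal(r$lys_re, 1.0)
  expect_equal(r$reactivity_class, "semi")
  # lower boundary 0.1 is also semi
  expect_equal(lys_reactivity(10.0, 9.0)$reactivity_class, "semi")
  # published pKa values at the CA modification pH of 9.0
  expect_equal(lys_reactivity(8.92, 9.0)$lys_re, 1.2023,
               tolerance = 1e-4)
  expect_equal(lys_reactivity(8.92, 9.0)$reactivity_class, "high")
  expect_equal(lys_reactivity(10.05, 9.0)$lys_re, 0.08913,
               tolerance = 1e-4)
  expect_equal(lys_reactivity(10.05, 9.0)$reactivity_class, "low")
})

test_that("LysRe is monotone and scales tenfold per pH unit", {
  pka <- seq(8, 12, by = 0.25)
  sc <- lys_reactivity(pka, 9.0)$lys_re
  expect_true(all(diff(sc) < 0))  # decreasing in pKa
  ph <- seq(5, 10, by = 0.5)
  sc2 <- lys_reactivity(10.4, ph)$lys_re
  expect_true(all(diff(sc2) > 0))  # increasing in pH
  expect_equal(lys_reactivity(10.4, ph + 1)$lys_re, 10 * sc2)
})

test_that("salt bridges are detected within the cutoff only", {
  m <- make_structure(structure_spec(data.frame(
    resname = c("LYS", "ASP"), resnum = 1:2, chain = "A",
    x = c(0, 3.2), y = 0, z = 0)))
  b <- detect_salt_bridges(m$structure)
  expect_equal(nrow(b), 1L)
  expect_equal(b$basic_key, "A:1:LYS")
  expect_equal(b$acidic_key, "A:2:ASP")
  expect_equal(b$min_distance, 3.2, tolerance = 1e-9)

  far <- make_structure(structure_spec(data.frame(
    resname = c("LYS", "ASP"), resnum = 1:2, chain = "A",
    x = c(0, 8.0), y = 0, z = 0)))
  expect_equal(nrow(detect_salt_bridges(far$structure)), 0L)
  # a wider cutoff recovers the pair
  expect_equal(nrow(detect_salt_bridges(far$structure, cutoff = 9)), 1L)
})

test_that("salt-bridge detection equals the brute-force oracle", {
  for (seed in 1:20) {
    sim <- random_structure(20, seed = seed,
                            pool = c("LYS", "ARG", "HIS", "ASP", "GLU"),
                            min_separation = 6)
    got <- detect_salt_bridges(sim$structure, cutoff = 8.0)
    want <- bf_salt_bridges(sim$structure, cutoff = 8.0)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("crosslink pairs report spans and compatible agents", {
  m <- make_structure(structure_spec(data.frame(
    resname = "LYS", resnum = 1:2, chain = "A",
    x = c(0, 12), y = 0, z = 0)))
  p <- crosslink_pairs(m$structure)
  expect_equal(nrow(p), 1L)
  expect_equal(p$nz_nz_distance, 12, tolerance = 1e-9)
  expect_equal(p$ca_ca_distance, 12, tolerance = 1e-9)
  agents <- strsplit(p$compatible_agents, ",")[[1]]
  expect_true("EGNHS" %in% agents)   # span 4-18
  expect_false("GA" %in% agents)     # span 4-11

  far <- make_structure(structure_spec(data.frame(
    resname = "LYS", resnum = 1:2, chain = "A",
    x = c(0, 25), y = 0, z = 0)))
  pf <- crosslink_pairs(far$structure)
  expect_equal(pf$compatible_agents, "")  # listed with empty agent set

  three <- make_structure(structure_spec(data.frame(
    resname = "LYS", resnum = 1:3, chain = "A",
    x = c(0, 12, 30), y = 0, z = 0)))
  expect_equal(nrow(crosslink_pairs(three$structure)), 3L)

  single <- bridged_lysine_field(1, 0)
  expect_equal(nrow(crosslink_pairs(single$structure)), 0L)
})

test_that("crosslink pairs are invariant under atom-order permutation", {
  sim <- random_structure(15, seed = 8, pool = c("LYS", "GLY"))
  p1 <- crosslink_pairs(sim$structure)
  perm <- sim$structure$atoms[rev(seq_len(nrow(sim$structure$atoms))), ]
  p2 <- crosslink_pairs(laccmod:::new_protein_structure(perm))
  key <- function(p) paste(p$lys_a, p$lys_b)
  expect_setequal(key(p1), key(p2))
  expect_equal(p1$nz_nz_distance[order(key(p1))],
               p2$nz_nz_distance[order(key(p2))])
})

triage_on <- function(m, ph = 7.4, pka_table = NULL, cutoff = 4.0) {
  s <- shrake_rupley(m$structure)
  e <- residue_exposure(s, m$structure)
  b <- detect_salt_bridges(m$structure, cutoff)
  triage_sites(e, b, ph = ph, pka_table = pka_table)
}

test_that("candidates are exposed, non-bridged lysines", {
  m <- bridged_lysine_field(8, 4)
  tr <- triage_on(m)
  expect_equal(nrow(tr), 8L)
  expect_equal(sum(tr$candidate), 4L)
  expect_setequal(tr$key[tr$candidate],
                  paste0("A:", 5:8, ":LYS"))
  expect_true(all(tr$exposure_class[tr$candidate] == "exposed"))
  expect_true(all(!tr$in_salt_bridge[tr$candidate]))
})

test_that("buried lysines are never candidates", {
  sp <- structure_spec(
    data.frame(resname = "LYS", resnum = 1:2, chain = "A",
               x = c(0, 60), y = 0, z = 0),
    decoy_shells = list(list(resnum = 1, count = 80, radius = 6),
                        list(resnum = 2, count = 80, radius = 6)))
  m <- make_structure(sp)
  tr <- triage_on(m)
  expect_equal(sum(tr$candidate), 0L)
})

test_that("ranking is deterministic with documented tie-breaks", {
  m <- bridged_lysine_field(3, 0)
  # identical exposure/reactivity: lower residue number first
  pka <- read_pka_table(text = c("chain\tresnum\tresname\tpka",
                                 "A\t1\tLYS\t10.4",
                                 "A\t2\tLYS\t10.4",
                                 "A\t3\tLYS\t9.0"))
  tr <- triage_on(m, ph = 9.0, pka_table = pka)
  # the pKa-9.0 lysine scores semi (1.0) and outranks the two low ones
  expect_equal(tr$key[1], "A:3:LYS")
  expect_equal(tr$key[2:3], c("A:1:LYS", "A:2:LYS"))
  expect_equal(tr$rank, 1:3)
})

test_that("lysines without pKa are flagged and ranked by exposure", {
  m <- bridged_lysine_field(2, 0)
  pka <- read_pka_table(text = c("chain\tresnum\tresname\tpka",
                                 "A\t1\tLYS\t10.4"))
  tr <- triage_on(m, ph = 9.0, pka_table = pka)
  expect_true(tr$has_pka[tr$key == "A:1:LYS"])
  expect_false(tr$has_pka[tr$key == "A:2:LYS"])
  expect_true(is.na(tr$lys_re[tr$key == "A:2:LYS"]))
  # still listed and still a candidate
  expect_true(tr$candidate[tr$key == "A:2:LYS"])
})

test_that("pKa entries for lysines absent from the structure error", {
  m <- bridged_lysine_field(2, 0)
  pka <- read_pka_table(text = c("chain\tresnum\tresname\tpka",
                                 "A\t99\tLYS\t10.4"))
  expect_error(triage_on(m, ph = 9.0, pka_table = pka),
               "absent from the structure")
  # and a missing pH is never guessed
  s <- shrake_rupley(m$structure)
  e <- residue_exposure(s, m$structure)
  expect_error(triage_sites(e, detect_salt_bridges(m$structure),
                            ph = NULL), "pH")
})

test_that("removing a salt bridge never removes a candidate", {
  m_with <- bridged_lysine_field(6, 3)
  m_without <- bridged_lysine_field(6, 2)  # one fewer bridge
  c_with <- triage_on(m_with)
  c_without <- triage_on(m_without)
  expect_true(all(c_with$key[c_with$candidate] %in%
                    c_without$key[c_without$candidate]))
  expect_gte(sum(c_without$candidate), sum(c_with$candidate))
})
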