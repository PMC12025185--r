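# laccmod

Structure-guided planning and assay-side statistics for chemical
modification of lysine residues in enzymes, developed around comparative
work on a bacterial (*Ensifer meliloti*) and a fungal (*Cerrena
unicolor*) laccase.

Chemical modification of surface lysines (crosslinkers such as
glutaraldehyde or EGNHS, acylating agents such as citraconic anhydride,
glycosylation with polymeric sucrose) is a classic route to more
thermostable biocatalysts. Which lysines can actually react is a
structural question: the residue must be solvent-exposed, must not be
locked in a salt bridge, and its epsilon-amine must be deprotonated often
enough at the modification pH. Whether a modification helped is a
kinetics question: the thermal inactivation rate before and after.
`laccmod` implements both sides as a tested, scriptable pipeline.

## What it computes

**Structure side** (input: any PDB file plus an externally predicted
per-residue pKa table):

- Atomistic solvent-accessible surface area by Shrake–Rupley quadrature
  (probe radius 1.4 Å, deterministic golden-spiral point sets, compiled
  core), per-residue relative exposure against theoretical Gly-X-Gly
  maxima, and the hydrophobic (C,S) vs hydrophilic (N,O) surface
  partition.
- Lysine reactivity: LysRe = 10^(pH − pKa), the Henderson–Hasselbalch
  fraction-deprotonated ratio, classed low (< 0.1), semi (0.1–1.0) or
  high (> 1.0).
- Salt bridges: basic side-chain N (Lys NZ, Arg NH1/NH2/NE, His
  ND1/NE2) within 4.0 Å of a carboxylate O (Asp OD1/OD2, Glu OE1/OE2).
- Crosslinker feasibility: NZ–NZ and CA–CA distances for every lysine
  pair against agent span windows (glutaraldehyde 4–11 Å, EGNHS 4–18 Å).
- Integrated triage: candidate ⇔ exposed (relative SASA ≥ 20%) and not
  salt-bridged, ranked by reactivity class, LysRe, then exposure.

**Assay side** (input: tab-separated time/condition vs activity tables):

- TNBS degree of modification: DM% = 100·(1 − C_Lys,sample/C_Lys,control),
  clamped to [0, 100], with the lysine standard-curve fit.
- First-order thermal inactivation: OLS fit of ln A = ln A₀ − k_d·t,
  half-life t½ = ln 2 / k_d, and the stabilization ratio
  R = t½(modified)/t½(control) = k_d,control/k_d,modified.
- pH/temperature optimum summaries (measured grid, median-directed
  tie-break) and residual activity vs inhibitor concentration.

A synthetic-data module generates toy structures with controlled
exposure/bridge/span geometry and decay series with known rate
constants, so every operator is testable against ground truth.

## Worked example

```r
library(laccmod)

# a toy structure: four lysines on a line, one buried under a decoy
# shell, one salt-bridged to an aspartate 3.2 A away
sp <- structure_spec(
  data.frame(resname = c("LYS","LYS","LYS","ASP","LYS"),
             resnum  = c(20, 476, 488, 344, 559), chain = "A",
             x = c(0, 40, 80, 3.2, 120), y = 0, z = 0),
  decoy_shells = list(resnum = 559, count = 80, radius = 6))
m <- make_structure(sp)
write_pdb(m$structure, "demo.pdb")
writeLines(c("chain\tresnum\tresname\tpka",
             "A\t20\tLYS\t10.20", "A\t476\tLYS\t11.44",
             "A\t488\tLYS\t10.55", "A\t559\tLYS\t8.92"), "demo_pka.tsv")

res <- run_profile("demo.pdb", "demo_pka.tsv", agent = "CA")  # pH 9.0
res$triage[, c("key", "relative_sasa", "exposure_class", "lys_re",
               "reactivity_class", "in_salt_bridge", "candidate")]
```

```
        key relative_sasa exposure_class  lys_re reactivity_class in_salt_bridge candidate
1 A:559:LYS        0.0582         buried 1.20226             high          FALSE     FALSE
2  A:20:LYS        0.6082        exposed 0.06310              low           TRUE     FALSE
3 A:488:LYS        0.8127        exposed 0.02818              low          FALSE      TRUE
4 A:476:LYS        0.8127        exposed 0.00363              low          FALSE      TRUE
```

Reading: Lys 559 is the only residue whose lowered pKa (8.92) makes it
nominally reactive at pH 9 (LysRe 1.2 > 1), but it is buried (5.8%
relative SASA) — reactivity scoring alone is not enough. Lys 20 is
exposed but locked in a salt bridge; the two remaining exposed,
unbridged lysines are the modification candidates.

Kinetics, from a simulated two-variant decay experiment:

```r
times <- c(0, 30, 60, 120, 180)
df <- rbind(
  data.frame(variant = "EM_control", time = times,
             activity = simulate_decay(31.55e-4, times)$activities),
  data.frame(variant = "PS-EM", time = times,
             activity = simulate_decay(15.85e-4, times)$activities))
write.table(df, "assay.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
run_stability("assay.tsv", "EM_control")[, c("variant", "kd",
                                             "t_half_round", "R_round")]
```

```
     variant       kd t_half_round R_round
1 EM_control 0.003155        219.7      NA
2      PS-EM 0.001585        437.3       2
```

The polymeric-sucrose-style variant halves the inactivation constant:
half-life 437.3 min vs 219.7 min, stabilization ratio R = 2.0.

## Command line

```sh
Rscript inst/cli/laccmod.R profile --structure model.pdb --pka pka.tsv --agent CA --out report/
Rscript inst/cli/laccmod.R stability --assay assay.tsv --control EM_control --out report/
Rscript inst/cli/laccmod.R dm --sample 0.37 --control 1.0
Rscript inst/cli/laccmod.R simulate --n 30 --seed 7 --out fixtures/
```

All reports embed the resolved configuration (probe radius, thresholds,
cutoffs, agent table) as an audit trail, and identical inputs produce
byte-identical outputs.

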