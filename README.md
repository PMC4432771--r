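# protdescr

General-purpose numerical descriptors for protein sequences and 3D
structures, for machine-learning and similarity studies in structural
bioinformatics.

Pattern-recognition work on proteins needs numeric feature vectors.
`protdescr` generates them combinatorially, the way cheminformatics
descriptor suites do for small molecules, through four hierarchical
levels:

1. **Per-residue indices** `L_i` — amino-acid property scales
   (Kyte–Doolittle hydrophobicity `HP`, the `z1`/`z2`/`z3` principal
   properties, Levitt's `Pa`/`Pb`/`Pt` conformational preferences,
   isoelectric point, mass, plus user-loadable tables), contact-based
   *topographic* indices, and energy-like *thermodynamic* terms.  The
   topographic family redefines classic whole-protein fold descriptors at
   residue level; e.g. the weighted contact order share of residue *i* is

   ```
   wCO_i = 1/(2 N N_c) * Σ_{j≠i} ω_ij δ_ij
   ```

   where `δ_ij` marks a contact (Cα distance < d **and** sequence
   separation > t; defaults d = 8 Å, t = 4), `N_c` is the contact count
   and `ω_ij` is 1, the sequence separation `|i−j|`, or a product of
   per-residue property values.  Summing `wCO_i` over residues recovers
   Plaxco's relative contact order exactly; the same residue-level scheme
   covers long-range order (`wLRO`), total contact distance (`wTCD`),
   contact number (`wNc`) and cliquishness (`wCLQ`).

2. **Weighting operators** — neighbourhood transforms on sequence
   topology (`d_ij = |j−i|`): autocorrelation
   `AC_i^k = Σ_j L_i L_j δ(d_ij − k)`, Kier–Hall-, electrotopological-,
   Ivanciuc–Balaban- and gravitational-like operators.

3. **Residue groups** — amino-acid types, physicochemical classes
   (polar, basic, acidic, aromatic, ...), and structural sets: buried
   (`INT`, relative SASA below an adjustable cutoff) vs superficial
   (`SUP`), helix/sheet/turn from PDB records (`HEX`/`SHT`/`TRN`), coil
   (`RCL`), whole protein (`PRT`).

4. **Aggregation operators** — 20 statistics per group: Minkowski norms
   `N1`/`N2`/`N3`, central tendency (`AM`, `GM`, `HM`, quartiles,
   extremes), dispersion (`V`, `SD`, `CV`, `SK`, `RG`, `IQ`) and
   information content (`TIC`, `MIC`, `SIC`).

Every combination yields one named descriptor,
`<index>[_<weighting><k>]_<group>_<aggregator>` (e.g. `HP_PRT_Q2`: median
Kyte–Doolittle hydropathy of the whole chain), so a handful of selections
already produces thousands of features per protein.  PDB input enables the
full set; FASTA input enables the sequence-based subset.  A
Shannon-entropy variability filter ranks descriptors by their power to
tell proteins apart, and inter-protein distance matrices support
similarity analyses.

## Worked example

The octapeptide worked example bundled with the package (sequence
`HGGGWGQP`, with its per-residue log folding-degree values) run through
the autocorrelation operator at k = 2:

```r
library(protdescr)
fx <- table1_fixture()
ac <- autocorrelation(fx$lnFD, k = 2)
data.frame(residue = strsplit(fx$sequence, "")[[1]],
           lnFD = fx$lnFD$values, lnFD_AC2 = signif(ac$values, 3))
#>   residue     lnFD lnFD_AC2
#> 1       H -0.03530 0.000293
#> 2       G -0.01540 0.000139
#> 3       G -0.00831 0.000372
#> 4       G -0.00901 0.000205
#> 5       W -0.00943 0.000289
#> 6       G -0.00736 0.000309
#> 7       Q -0.02230 0.000210
#> 8       P -0.03300 0.000243
```

Each residue's updated value sums the products `L_i·L_j` over its (at
most two) neighbours at sequence distance 2 — e.g. position 1 has only
position 3, giving `(−0.0353)·(−0.00831) = 2.93e−4`.

A small full pipeline on a two-record FASTA file:

```r
f <- tempfile(fileext = ".fasta")
writeLines(c(">p1", "HGGGWGQP", ">p2", "MKTAYIAKQRQISFVK"), f)
cfg <- project_config(inputs = f, indices = c("HP", "z1"),
                      weightings = c("NONE", "AC2"),
                      groups = c("PRT", "polar"),
                      aggregators = c("AM", "Q2", "SD"),
                      output_prefix = tempfile())
paths <- run_project(cfg)       # writes <prefix>_AA.txt, <prefix>_Prot.txt
tab <- read_descriptor_table(paths[["prot"]])
dim(tab)
#> [1]  2 24                     # 2 indices x 2 weightings x 2 groups x 3 aggregators
round(tab[, c("HP_PRT_Q2", "HP_AC2_PRT_AM", "z1_polar_SD")], 4)
#>    HP_PRT_Q2 HP_AC2_PRT_AM z1_polar_SD
#> p1     -0.65        1.4375      3.3224
#> p2     -0.75       -1.8575      1.3146
round(distance_matrix(tab, "euclidean"), 3)
#>        p1     p2
#> p1  0.000 16.736
#> p2 16.736  0.000
```

`HP_PRT_Q2` is the median hydropathy of each chain (both mildly polar
here); the distance matrix places the two sequences ~16.7 apart in this
24-descriptor space.  `shannon_relevance(tab, n_bins)` ranks the columns
by histogram entropy across the dataset; with only two proteins every
varying descriptor carries 1 bit.

Structure-based runs work the same way from PDB files, and
`synthetic_structure()` generates seeded test structures (ideal helix,
self-avoiding coil, cluster with a known buried core).  A thin CLI with
`run`, `multi`, `relevance`, `distmat`, `fixtures` and `adhoc`
subcommands is installed at `inst/cli/protdescr.R`.

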