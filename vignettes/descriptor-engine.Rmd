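---
title: "The protdescr descriptor engine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The protdescr descriptor engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protdescr)
```

## The model

`protdescr` treats a protein as an ordered chain of residues, position
1..N, optionally carrying atomic coordinates, secondary-structure labels
and solvent accessibilities.  A *descriptor* is produced by a four-stage
pipeline: a per-residue **index** vector $L_i$; an optional
**weighting operator** that mixes each residue's value with its sequence
neighbourhood; a **residue group** selecting a subset of positions; and an
**aggregation operator** collapsing the group's values to one number.  The
descriptor set is the full Cartesian product of the user's selections, so
the number of columns is always
$|I| \times |W| \times |G| \times |A|$ — incompatible combinations
(structure-demanding index on a sequence-only input, empty group) yield
the missing-value sentinel rather than a dropped column, keeping the
table rectangular across heterogeneous inputs.

### Contacts and topographic indices

Two residues are in contact when their spatial distance is below $d$
**and** their sequence separation exceeds $t$ (strict inequalities on
both sides; the pair $|i-j| = t$ is *not* a contact).  Defaults are
$d = 8$ Å and $t = 4$, the conventional contact-order regime.  The
spatial distance is measured between Cα atoms by default — the choice is
exposed (`atom_mode`) because the literature varies between Cα, Cβ and
minimal heavy-atom conventions; Cα is the one that works for
backbone-only models and coarse decoys.

Classic fold descriptors (relative contact order, long-range order,
total contact distance, contact number, cliquishness) are whole-protein
sums over contacts.  The engine redefines each per residue so that the
residue contributions sum back to the original value: every contact's
contribution is split half-and-half between its two members.  For the
weighted contact order,

$$ wCO_i = \frac{1}{2 N N_c} \sum_{j \ne i} \omega_{ij}\,\delta_{ij}, $$

and $\sum_i wCO_i$ equals the classic contact order exactly when
$\omega_{ij} = |i-j|$.  This summation identity is enforced by a
property-style test on seeded synthetic structures at $10^{-12}$
relative tolerance; it is the anchor that pins down the per-residue
normalisation constants of `wLRO` ($1/2N$), `wTCD` ($1/2N^2$) and `wNc`
(no normalisation) as well.  Cliquishness is the clustering coefficient
of the contact graph — the ($\omega$-weighted) fraction of contacting
pairs among a residue's contact neighbours — and is defined as 0 for
degree < 2.  A contact map with no contacts at all leaves the
$1/N_c$-normalised indices undefined; this is an error by default, with
an explicit `zero_on_degenerate` opt-in because batch runs over decoy
sets routinely contain extended chains.

The contact weight $\omega_{ij}$ under property weighting is the raw
product of the two residues' scale values.  Whether the scale should be
normalised first is genuinely open; raw values were frozen because they
keep the identity $\omega_{ij} = \omega_i \omega_j$ interpretable in the
scale's own units, and any rescaling is expressible as a user-registered
scale.

### The folding-degree index

`lnFD` is defined here as the log of a per-residue folding-degree share
built from backbone dihedral cosines,
$c_i = (2 + \cos\varphi_i + \cos\psi_i)/(4N) \in (0, 1/N]$, floored at
$\varepsilon = 10^{-8}$ before the logarithm (missing dihedrals at chain
ends contribute cosine 0; Cα-only models fall back to the Cα
pseudo-dihedral).  The bundled octapeptide worked example stores the
*printed* lnFD values as fixture input, deliberately decoupling all
downstream weighting/aggregation tests from this definition.

### Thermodynamic-style indices

The energy-like family is defined by this package as documented closed
forms behind a registry, so alternative formulations can be plugged in
without API change: a screened Coulomb term over charged side chains
(Debye-like length 10 Å, dielectric-free 332 kcal·Å/mol prefactor,
half-share per pair member), a 12-6 Lennard-Jones sum on Cα pairs with
per-type radii scaled from residue mass, a backbone hydrogen-bond count
at −0.75 per participating partner (N···O < 3.5 Å, $|i-j| \ge 3$), a
3-fold torsion potential on $\varphi/\psi$, and a hydrophobic-burial
term equal to the Kyte–Doolittle value times the buried fraction
$(1 - \text{rel\_sasa})$ — at full burial it equals the bare scale value,
at full exposure it vanishes.  Sequence-only analogues (`HphS`, `ChgS`)
are plain scale lookups, the unfolded-reference-state limit.  These are
descriptor generators, not a force field: only relative magnitudes and
sign conventions (favourable negative) matter downstream.

### Weighting operators

All five operators act on sequence topology, $d_{ij} = |j - i|$, with
*truncated* boundaries: a terminal residue simply sums fewer terms (the
worked example's one-sided products at the chain ends fix this
convention for autocorrelation, and the same rule is applied uniformly
to the other operators).  The autocorrelation at cut-off $k$ is
$AC_i^k = \sum_j L_i L_j\, \delta(d_{ij} - k)$.  The Kier–Hall-,
electrotopological-, Ivanciuc–Balaban- and gravitational-like forms are
classical sequence adaptations; inverse-square-root terms drop
contributions with $|x| < 10^{-12}$ — small enough not to perturb any
real scale value, large enough to avoid infinities from structurally
zero products.  Every operator is checked against a naive $O(N^2)$
reference implementation on random vectors, and for reversal covariance
and (AC) degree-2 homogeneity.

### Solvent accessibility and structure groups

Relative SASA is computed with the Shrake–Rupley rolling-probe method:
960 deterministic golden-spiral points per atom sphere, probe 1.4 Å,
Bondi van der Waals radii, normalised by the Tien et al. theoretical
maximum per residue type and clipped to [0, 1].  The point count is a
compromise: 960 points give ≈0.1 Å² resolution per atom while keeping a
500-residue protein in the seconds range.  The implementation is
verified against the analytic sphere area of an isolated atom and an
independent latitude–longitude brute-force sampler.

Buried residues (`INT`) are those with relative accessibility below an
adjustable cutoff, default 0.25 — the conventional boundary between
buried and exposed in surface-area studies; `SUP` is its complement.
Helix/sheet/turn groups come *only* from HELIX/SHEET/TURN records in the
PDB file — no geometric re-assignment — so files without records yield
empty `HEX`/`SHT` and `RCL` = `PRT`.  Turns are members of the coil
group by definition (coil = neither helix nor sheet).  The
physicochemical class table follows IUPAC-conventional assignments, with
histidine deliberately in both the basic and aromatic classes.

### Aggregation

Twenty operators.  Numerical conventions that had to be frozen for
bit-reproducibility: quartiles use linear interpolation between closest
ranks (`stats::quantile` type 7); variance and skewness are population
moments (these are descriptors of the value distribution, not inference
statistics); the geometric mean uses absolute values with
zero-propagation so it stays defined for energy-like negative indices;
the information measures form equivalence classes by rounding to
`precision` decimals (default 6).  All degenerate cases — empty group,
harmonic mean with a zero, CV at zero mean, skewness at zero variance,
SIC of a singleton — map to a single missing-value sentinel (`NA` in
memory, a configurable token in files), never to an error.

### Relevance and distances

Descriptor variability is ranked by histogram Shannon entropy: values
binned into `n_bins` equal-width bins over [min, max] (default 20; the
binning granularity used in the information-theoretic variability
literature varies, so it is exposed), $H = -\sum p_b \log_2 p_b$,
constant columns defined as $H = 0$, ties broken by descriptor name for
a stable ordering.  Distance matrices (Euclidean/Manhattan) are computed
over the sentinel-free descriptor columns only, so all proteins are
compared in the same complete subspace.

## Output contract

Each run writes `<prefix>_AA.txt` (per-residue weighted indices, rows
labelled `<id>_aa<position>_<TYPE>`) and `<prefix>_Prot.txt` (proteins ×
descriptors), tab-delimited with a header row, numbers in scientific
notation with 6 significant decimals.  The fixed format makes re-runs of
a saved project byte-identical, which the test suite asserts.  Project
configurations are YAML, validated field-by-field, and runnable in batch
with per-project failure isolation.

## What the synthetic generators do and do not emulate

The seeded generators produce: an ideal α-helix Cα trace (rise 1.5
Å/residue, 100°/residue, radius 2.3 Å) with matching HELIX records; a
self-avoiding random coil (bond 3.8 Å, 4.0 Å excluded volume); and a
two-layer cluster whose inner residues are fully occluded by a dense
outer shell — a *constructed* burial oracle (it requires ≥ 14 shell
residues for the occlusion guarantee).  They are Cα-only and make no
attempt at side-chain packing, realistic Ramachandran statistics or
native-like contact topology.  Passing tests on them demonstrates the
*correctness of the formulas* (contact conditions, summation identities,
burial partition, operator algebra) — not predictive value on real
proteins, which depends on full-atom structures and curated datasets.
Test problem sizes (chains of 20–100 residues, 100 structures for the
contact-order identity, 1000 random vectors for the aggregator laws)
were chosen to exercise every boundary case while keeping the default
suite under a minute.

## Known limitations

* Single chain, first NMR model only; no mmCIF; hydrogens are ignored.
* Nonstandard residues: MSE/SEC/PYL map to their standard parents;
  anything else is dropped with a warning, as are FASTA letters outside
  the 20 standard codes.
* Secondary structure is trusted from the file; structures stripped of
  their records lose the HEX/SHT/TRN groups silently (RCL then equals
  PRT).
* The thermodynamic index forms are this package's own documented
  surrogates (see above), chosen for the right qualitative behaviour and
  stable descriptor semantics rather than calibrated energetics.
* The bundled property-scale inventory is intentionally small (nine
  scales); large external sets (e.g. electron-density-derived residue
  scales) are supported through `load_property_table()` rather than
  bundled.
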