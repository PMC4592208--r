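---
title: "Methods: QSAR-driven virtual screening and ligand-efficiency prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR-driven virtual screening and ligand-efficiency prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdacScreen)
```

# Scope and model

`hdacScreen` implements a 2D (topological) lead-discovery workflow for
class I histone deacetylase (HDAC1/2/3/8) inhibitors: descriptor
computation on hydrogen-suppressed molecular graphs, a linear
quantitative structure--activity (QSAR) model for pIC50, active/decoy
screen validation statistics, a feature-count pharmacophore surrogate
for library ranking, and the ligand-efficiency suite used to
prioritize leads.

The activity model is ordinary multiple linear regression,

$$\mathrm{pIC50} = \beta_0 + \beta_1 P + \beta_2 \log P +
\beta_3 \mathrm{TPSA} + \beta_4 \mathrm{HBA} + \beta_5 J + \varepsilon,$$

with $P$ the molar polarizability (Å³), TPSA the topological polar
surface area (Å²), HBA the hydrogen-bond-acceptor count, and $J$ the
Balaban distance-connectivity index. `publishedModel()` freezes the
literature coefficients (intercept 14.48; $-0.13$, $+0.06$, $+0.17$,
$-2.54$, $-2.57$) with their reported standard errors and fit
statistics ($n = 10$, $R^2 = 0.93$, adjusted $R^2 = 0.84$, SEE 0.24,
$p = 0.02$); `fitMLR()` refits the same form on any descriptor table
via `stats::lm`. Note the positive TPSA coefficient is chemically
unusual for potency models; it is kept exactly as published. Activities
convert as $\mathrm{pIC50} = 9 - \log_{10}(\mathrm{IC50}/\mathrm{nM})$,
conversion happens *before* per-isoform averaging (geometric-mean
behaviour on IC50), and compounds classify as active when
IC50 < 2500 nM, with the boundary value resolving to decoy (the
published split defines active and decoy by strict inequalities and
leaves the boundary open; strict-active is the conservative choice).

# Descriptors

All descriptors are deterministic functions of the annotated graph
(`Molecule` objects from `parseSmiles()`/`readMolecules()`).

* **Balaban J** uses unweighted topological distances on the
  hydrogen-suppressed graph (the classic definition, no bond-order
  weighting): $J = \frac{M}{\mu+1}\sum_{(i,j)\in E}(s_i s_j)^{-1/2}$.
  It is undefined (a hard error) for single atoms and disconnected
  graphs.
* **TPSA** is an Ertl-type fragment-additive sum over N/O-centred
  environments; the contribution table is frozen in
  `R/descriptor-tables.R` and atoms in environments outside the table
  fall back to a generic N/O value with a message.
* **clogP** is a Crippen-type atom-additive scheme with a deliberately
  coarse, frozen atom typing (aromatic/aliphatic/carbonyl carbon, four
  oxygen types, amine/amide/aromatic nitrogen, per-element halogen
  values, per-hydrogen terms).
* **Polarizability** and **MW** are element-additive, hydrogens
  included.
* **HBA** defaults to the Lipinski N+O convention excluding positively
  charged atoms; a stricter lone-pair rule (dropping pyrrole-type and
  amide nitrogens) is available by argument. **HBD** counts donor
  heteroatoms once regardless of hydrogen multiplicity, switchable to
  per-hydrogen counting.

The proprietary tools behind published descriptor values are neither
available nor documented, so these frozen open schemes will not
numerically coincide with them; every pipeline stage therefore accepts
externally supplied descriptor values (notably clogP) as authoritative
overrides, and the packaged ten-hit table carries the printed values as
inputs. Predictions made with package-computed polarizability may shift
relative to literature predictions; this is documented rather than
resolved.

# Parsing and molecule handling

SMILES input covers the organic subset with aromatic lowercase
notation, bracket atoms (charge, explicit H), branches, ring closures
and dot-separated fragments. Aromaticity is taken from the notation and
validated structurally (every aromatic atom must carry at least two
aromatic bonds); records whose aromatic system cannot be resolved are
hard errors rather than silently kekulized guesses. Implicit hydrogens
follow standard default valences, with aromatic bonds counted as 1.5
and the total ceiled. Salt/multi-fragment records keep the largest
connected fragment with a warning, since the topological descriptors
are defined on connected graphs (test harnesses can bypass this to
exercise additivity). SDF V2000 records are read with explicit-H
suppression, `M CHG` handling, and bond order 4 mapped to aromatic.
Unsupported elements fail at parse time by name; common counter-ion
metals parse (so salts load) but are rejected by the descriptor tables
if they survive fragment stripping.

# Screen validation

With $D$ library compounds, $A$ actives, $H_t$ hits and $H_a$ active
hits: sensitivity $H_a/A$, specificity $TN/(D-A)$, percent yield
$100H_a/H_t$, enrichment factor $(H_a/H_t)/(A/D)$ and the Güner–Henry
score $\mathrm{GH} = \frac{H_a(3A+H_t)}{4H_tA}\left(1-\frac{H_t-H_a}{D-A}\right)$.
These are the standard composite definitions; the tests verify
GH $\in [0,1]$ and agreement with a literal-formula oracle by
exhaustive enumeration over small counts. Undefined ratios (zero hits,
zero actives) are reported as explicit `NA`s with the metric named,
never silent `NaN`.

# Pharmacophore surrogate

Published ligand-based pharmacophores are 3D objects produced from
docked poses by proprietary alignment and scoring; no coordinates are
available to reproduce them. The package therefore implements a 2D
surrogate that preserves the *pipeline role* of a pharmacophore
(learn shared features from actives, rank a library, threshold,
validate): features are perceived by graph rules (donor, acceptor,
aromatic ring, hydrophobic patch, positive/negative ionizable),
a merged model stores, per feature kind, the count supported by a
consensus fraction $f$ of the training actives ($f = 1$ is the
intersection of per-kind minima), and the query fit is
$\sum_k \min(c_k, r_k) / \sum_k r_k \in [0,1]$. Rule families and
thresholds live in a versioned YAML config
(`inst/extdata/pharmacophore_rules.yaml`); the matchers are code, the
config toggles and parameterises them. Ranking ties resolve to input
order for determinism. Per-model retrieval bars and absolute fit values
from 3D engines are out of scope and not approximated.

# Ligand-efficiency suite

For each compound: $LE = (1.37/HA)\,\mathrm{pIC50}$ (pIC50 units per
heavy atom, standard state 300 K, neutral pH, 1 M),
$LipE = \mathrm{pIC50} - \mathrm{clogP}$,
$LEScale = 0.104 + 0.65e^{-0.037\,HA}$ (the empirical maximal-LE
reference, strictly decreasing towards 0.104), and $FQ = LE/LEScale$.
Optimal-lead flags use clogP < 3, LipE > 5 and $|FQ-1| \le 0.25$ (the
"close to 1" band is not standardized; 0.25 is configurable). The
Rule-of-Five filter passes at MW ≤ 500, clogP ≤ 5, HBD ≤ 5, HBA ≤ 10
with zero violations by default (boundary-inclusive).

**Rounding.** Values are kept at full precision internally; reports
round to two decimals, half away from zero. FQ defaults to
*reproduction mode* — the ratio of 2-decimal-rounded LE and LEScale,
itself rounded — because that is how published tables are assembled
from their printed intermediates (e.g. a printed 0.44/0.36 gives 1.22
where the unrounded ratio gives 1.21); full-precision mode is a flag.
The worst-case difference between the two conventions is bounded by
$0.005\,(1 + 1/LEScale + LE/LEScale^2)$, about 0.02 at these table
magnitudes.

**Errata handling.** Two cells of the packaged literature table are
internally inconsistent with the equations: the C1 FQ (printed 0.95;
its own printed intermediates give 0.94) and the C5 LEScale (printed
0.29; the exponential at HA = 22 gives 0.39, which also propagates into
C5's FQ). `checkEfficiencyTable()` recomputes every cell and flags
exactly these; they are treated as transcription errata, not fitted
around.

# Synthetic data generator

The generator emulates the canonical HDAC-inhibitor architecture — a
capping group, a linker and a zinc-binding group — by seeded uniform
choice from curated fragment lists (10 caps, 10 linkers, 8 zinc-binding
motifs including hydroxamate, carboxylate, carboxamide, 2-aminoanilide,
sulfonamide), concatenated into valid SMILES and parsed through the
molecules module. Activities are simulated from the frozen published
coefficients applied to the *computed* descriptors plus Gaussian noise
with SD 0.24 (the published model's standard error of estimate), then
thresholded at 2500 nM. The RNG is pinned (Mersenne–Twister /
inversion) and seeded per stage (library at `seed`, noise at
`seed + 1`), caller RNG state is restored, and configs echo into output
headers, so runs are bit-reproducible.

What the generator does *not* emulate: realistic chemical-space
coverage, property-matched decoys, correlated assay noise across
isoforms, or the composition of any real vendor library. Passing tests
on synthetic data therefore demonstrate the statistical machinery
(identifiability, calibration, enrichment bookkeeping), not predictive
performance on real HDAC data.

# Problem sizes and numerical choices in the test suite

Tests run at desk scale by design: parameter recovery uses $n = 200$
compounds at noise SD 0.24 (each coefficient recovered within 3
estimated SE; the noiseless run identifies them to $10^{-8}$); the
small-sample regime check uses $n = 10$ over 40 seeds (external
$R^2 \ge 0.9$ in at least half, a distributional analogue of the
published $n = 10$, $R^2 = 0.93$ fit); the enumeration oracle for the
screen metrics covers $D \in \{3, 7, 12, 30\}$ exhaustively; OLS is
cross-checked against an SVD pseudo-inverse oracle on 100 random small
instances; the end-to-end screening property uses 50 planted
feature-complete actives among 450 hydrocarbon fillers, recovered
exactly. Descriptor selection follows classical p-value stepping with
entry 0.05 / removal 0.10 (the common statistical-package defaults,
adopted because the source names the software but no thresholds);
p-value ties resolve to the earlier column, making selection
deterministic in column order.

# Pipeline

`runPipeline()` chains read → pharmacophore screen → descriptors →
predict → filter (Rule of Five, minimum predicted pIC50) → efficiency
profile → rank (predicted pIC50 desc, then LipE desc, then input
order). Every retention step is a declared quantitative filter; the
published funnel's docking and manual-inspection stages are out of
scope, and the report header says so. Reruns with identical config are
byte-identical (timestamps are opt-in). Stage failures abort with the
stage named; no partial report is written.

# Known limitations

* Computed descriptors are open reimplementations; absolute agreement
  with proprietary descriptor servers is not expected, which is why
  printed descriptor values act as overrides wherever they exist.
* The pharmacophore surrogate carries no geometry; it cannot express
  excluded volumes, feature distances or pose-dependent features.
* The QSAR machinery is deliberately plain OLS — no regularization or
  cross-validation schemes beyond the external residual check.
* Kekulization is never performed; aromaticity must be notated (SMILES
  lowercase, SDF bond order 4). Kekulé-only SDF input yields
  non-aromatic typing for those rings.
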