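---
title: "Interface footprints, antibody mimicry and 1:1 binding kinetics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface footprints, antibody mimicry and 1:1 binding kinetics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimimic)
```

# What the package measures

`epimimic` characterizes binary protein-protein interfaces from atomic
coordinates and scores how faithfully a therapeutic antibody's paratope
reproduces the footprint of a natural receptor/ligand interaction — the
situation of immune-checkpoint complexes such as ICOS/ICOS-L, where blocking
antibodies (STIM003 against ICOS, prezalumab against ICOS-L) compete with the
natural partner by binding overlapping surfaces. It also simulates and fits
the 1:1 biolayer-interferometry (BLI) kinetics used to characterize such
interactions, including the affinity-versus-avidity contrast that arises when
a dimeric receptor binds an arrayed ligand surface.

Everything is testable offline: the synthetic-data module builds two-sphere
systems with closed-form areas, toy complexes with a designed number of
interface residues, natural/antibody complex pairs with a known shared
fraction, and sensorgrams with known rate constants.

# Structure handling

Models are parsed from PDB (fixed-column) or mmCIF (`atom_site` loop) text
into a flat atom table (parsing is delegated to `bio3d`; record-level
validation reports the offending line for malformed PDB input). Three
normalizations are applied at load and are deliberate design choices:

* **Waters are always removed.** Interface statistics here are direct
  protein-protein (and protein-glycan) quantities; water-mediated contacts
  are out of scope.
* **Alternate locations are collapsed** to the highest-occupancy conformer,
  ties broken in favour of altloc `A`, so all geometry is computed on a
  single deterministic conformer.
* **Hydrogens are dropped.** The intended inputs are moderate-resolution
  (2.4–3.3 Å) crystal structures without hydrogens, so every geometric
  criterion is heavy-atom based.

Author (deposited) residue numbering is preserved and authoritative: residue
labels like N110 or F114 refer to author numbering. When the same molecule
appears in two crystal forms with different numbering, residues are put in
correspondence by global Needleman–Wunsch alignment (`map_residues`, via
`Biostrings`) under identity scoring; non-standard residues become `X` and
glycan residues are excluded from sequences.

# Solvent-accessible surface area

SASA is computed with the Shrake–Rupley method: each atom's sphere (van der
Waals radius + 1.4 Å probe) carries `n_points` quasi-uniform points; a point
is accessible iff it lies outside every neighbour's expanded sphere; the
atom's area is the accessible fraction of $4\pi(r + r_p)^2$.

Numerical choices:

* **Deterministic sampling.** Points come from a golden-section spiral, not a
  random generator, so identical inputs give bit-identical output and reports
  are reproducible byte for byte.
* **`n_points = 960` by default**, which puts an isolated sphere within 0.5%
  of the closed form and, in the convergence check, moves a 100-atom total by
  less than 0.5% when doubled.
* **Radii.** A NACCESS/Chothia-style single-value-per-element table:
  C 1.80, N 1.65, O 1.40, S 1.85 Å (saccharide C/O as protein). Published
  interface areas are often computed with PISA, whose internal
  parameterization is not published; a simple documented table was chosen for
  reproducibility, and comparisons against published buried areas must allow
  roughly ±15% for radii/parameter differences.
* **Neighbour search** uses a cell list with cell size $2(r_{max}+r_p)$,
  contractually identical to the all-pairs scan (tested against an
  independent brute force with a different point set, and against an external
  implementation).

The analytic two-sphere system is the engine's primary oracle: for expanded
radii $R_1, R_2$ at separation $d$, the buried cap of sphere 1 has area
$2\pi R_1 h_1$ with $h_1 = R_1 - (d^2 + R_1^2 - R_2^2)/2d$, going to full
engulfment for $d \le |R_1 - R_2|$. Agreement is stated as a fraction of the
isolated-sphere area $4\pi R_1^2$ (the natural scale of the sampling error; a
relative-to-cap criterion would be ill-posed as the cap vanishes).

# Buried surface area and footprints

Per-atom BSA across an interface is `SASA(side alone) − SASA(side in
complex)`, from three SASA evaluations with identical parameters. **Each
side's total is reported separately** — the per-ectodomain convention behind
statements of the form "X buries N Å²" — never summed or halved (the halved
"interface area" convention of PISA is not used). Tiny negative per-atom
differences (sampling noise) are clamped to zero.

A molecule's *footprint* at threshold $\tau$ is the set of its residues with
BSA strictly greater than $\tau$; the default $\tau = 1$ Å² is the threshold
used in the mimicry definition. Footprints shrink monotonically in $\tau$,
and swapping the two sides swaps the footprints exactly.

Glycans belong to the side they are covalently attached to: an N-linked
glycan on the receptor is part of the receptor's selection by default, which
is what makes "area the receptor's glycan buries on the ligand" a
well-defined region contribution. Whether published per-side totals include
glycan atoms is usually not stated, so the deposited-structure driver reports
totals in the glycan-inclusive convention while protein-only selections are
one flag away (`hetero = FALSE`).

`region_contribution` sums per-residue BSA over a selection (a motif such as
the FG-loop FDPPPF, a strand, or a glycan) and reports it with its fraction
of the side total; contributions over a partition of a side reconstruct the
total exactly.

# The mimicry fraction

The headline statistic is
$$f = \frac{|\{r \in F_{nat} : m(r) \in F_{ab}\}|}{|F_{nat}|}$$
where $F_{nat}$ is the molecule's footprint in the natural complex, $F_{ab}$
its footprint in the antibody complex (both at $\tau = 1$ Å²), and $m$ the
residue correspondence between the two crystal forms. Natural-footprint
residues without a mapped counterpart stay in the denominator and can never
count in the numerator, so missing density in the antibody structure can only
lower $f$, never inflate it.

Two decisions were genuinely open and are resolved as follows:

* **The antibody-side contact criterion** is the same BSA > 1 Å² rule as the
  natural footprint. "Contacted by the antibody" could also have been defined
  by a distance cutoff; symmetry with the stated footprint definition is the
  cleanest reading and keeps $f$ a pure function of two footprints.
* **The denominator** is per-molecule: the receptor's mimicry and the
  ligand's mimicry are separate numbers (`mimicry_f_icos`,
  `mimicry_f_icosl` in the study output), not pooled. Callers can pool the
  two footprints themselves if a single number is wanted.

$f$ is exactly $n_{shared}/n_{interface}$ on constructed scenarios and is
invariant to rigid motion of either structure. It is *not* monotone in
$\tau$: raising the threshold can add or remove residues from numerator and
denominator independently, so no such property is asserted.

# Geometry

Superposition is the Kabsch least-squares fit via SVD with determinant
correction, guaranteeing a proper rotation. Backbone r.m.s.d. between mapped
chains pools N, CA, C, O atoms over all mapped residue pairs, dropping atoms
missing on either side pairwise (carbonyl O is often absent at termini), then
reports the post-fit r.m.s.d. Published r.m.s.d. values rarely state their
exact atom set (whole domain vs aligned core), so cross-structure comparisons
use a generous ±0.3 Å band and this package's choice — all mapped backbone
atoms, no outlier rejection — is stated here once.

A domain's axis is the first principal component of its Cα cloud, sign-fixed
to point N→C (non-negative dot product with the first-to-last Cα vector).
The crossing angle between two domains is $\arccos$ of the dot product of
their axes over the full 0–180° range: because both axes are N→C oriented,
parallel and antiparallel packings are distinguished, which is what makes a
"receptors cross their ligands at 150° vs 110° vs 90°" comparison meaningful.
The published angles were produced with an unstated PyMOL recipe; this
deterministic definition is the package's own and is validated within ±10°.
Inter-domain (elbow) angles use the same machinery on the two domains of one
molecule (for ICOS-L, D1 defaults to author residues 19–128 and D2 to
129–248, both configurable), and conformational flexibility between crystal
forms is reported as the absolute elbow difference.

# Contacts

Hydrogen bonds are donor/acceptor heavy-atom pairs with distance ≤ 3.5 Å and
antecedent–donor–acceptor angle ≥ 90°, the standard practice when structures
carry no hydrogens. Donors: backbone amide N (except proline), Arg NE/NH1/2,
Lys NZ, Asn ND2, Gln NE2, His ND1/NE2, Trp NE1, Ser OG, Thr OG1, Tyr OH, Cys
SG, and saccharide hydroxyl O (the ring O5 excluded). Acceptors:
carbonyl/carboxyl/hydroxyl O, Asn/Gln side-chain O, His ring N, Met SD, and
saccharide O — glycan hydroxyls must both donate and accept for
glycan-mediated interface bonds to be countable. His is both donor and
acceptor at ND1/NE2 because protonation is unknown at these resolutions. The
donor's antecedent is its nearest intra-residue heavy atom; single-atom
donors (no antecedent) are accepted on distance alone. Salt bridges are
Lys/Arg basic N vs Asp/Glu carboxylate O pairs with minimum N–O distance
≤ 4 Å, counted once per residue pair.

The criteria behind published bond counts are typically unstated, hence the
±2 posture when comparing counts. Aromatic (π) interactions are qualitative
descriptions in the literature and are deliberately not detected.

# Kinetics

The 1:1 Langmuir model: association
$R(t) = R_{eq}(1 - e^{-k_{obs}t})$ with $k_{obs} = k_{on}C + k_{off}$ and
$R_{eq} = R_{max}C/(C + K_D)$; dissociation decays single-exponentially at
$k_{off}$. $K_D \equiv k_{off}/k_{on}$ always — it is never an independent
parameter. Fitting is global nonlinear least squares over all concentrations
with shared $k_{on}, k_{off}, R_{max}$ (log-parameterized for positivity, via
`minpack.lm`), initialized from the pooled log-linear dissociation decay and
a $k_{obs}$-vs-$C$ regression. Designs that cannot identify the parameters
(fewer than two concentrations, span under 4-fold, no dissociation phase)
return flagged non-converged results rather than errors.

The simulator mirrors a standard Octet-style design: 1:2 serial dilutions
(default six concentrations from 500 nM), 180 s association and dissociation,
i.i.d. Gaussian noise from R's seeded Mersenne-Twister stream. Under that
design at 2% of $R_{max}$ noise, the fit recovers $k_{on}$ and $k_{off}$ with
median relative errors well under 5% (the acceptance script recomputes this
over 100 seeds). Raw published sensorgrams for the ICOS system are not
deposited, so kinetic validation is recovery-based rather than a
re-derivation of published $K_D$ values.

The avidity mode approximates a homodimeric analyte by two-step serial
binding over a surface of capacity $R_{max}$ (free surface $F$):
$$\dot R_1 = 2k_{on}CF - k_{off}R_1 - k_2R_1F + 2k_{off}R_2, \qquad
  \dot R_2 = k_2R_1F - 2k_{off}R_2$$
with rebinding rate $k_2 = k_{on}c_{loc}/R_{max}$, integrated with
`deSolve`. The effective local concentration of the tethered second site
defaults to $c_{loc} = 0.1$ mM, a typical tethered-ligand value; with the
default rate constants this yields an apparent $K_D$ roughly two orders of
magnitude tighter than the intrinsic one when the bivalent traces are fitted
with the monovalent model — the qualitative monomer-vs-dimer contrast seen
experimentally. The mode exists for that qualitative property only; it is not
a calibrated avidity model.

# The synthetic generators, and what passing tests do not show

The generators define the study conditions for everything tested offline:

* `make_two_sphere_model` — the analytic SASA/BSA substrate.
* `make_toy_interface` — poly-alanine strands (minimal N, CA, C, O, CB
  residues at ideal-ish geometry), residues 12 Å apart along the strand so no
  residue occludes its neighbours, contacting pairs at a 6 Å inter-strand gap
  (well inside burial range), others at 30 Å (no burial possible). This makes
  "exactly k residues per side in the footprint" a construction guarantee,
  not an empirical observation.
* `make_mimicry_pair` — a shared target chain plus natural and antibody
  partner chains contacting designed residue sets; the antibody complex gets
  a seeded rigid motion so numbering-by-coincidence cannot fake overlap, and
  two peripheral contacts outside the natural footprint mirror the enlarged
  epitopes of real antibodies.
* `make_bli_dataset` / `make_helix_model` — seeded sensorgrams and coils
  about known axes.

These fixtures validate the *machinery* — thresholds, bookkeeping, optimality
of fits, invariances. They do not emulate packed protein cores, crystal
contacts, missing density, alternate conformations beyond altloc groups, or
real glycan geometry (glycan handling is tested on hand-written NAG/MAN
records, the generator builds none); agreement with published interface
areas additionally depends on the radii convention discussed above. The
deposited-structure driver (`analysis/07_deposited_structures.R`,
`icos_study()`) exists precisely to run the identical code path on the real
crystal structures; it needs the four PDB entries fetched once over the
network, which is an explicit opt-in (`fetch_structure`) and the only
network access in the package.

Problem sizes used throughout the shipped analyses and tests — toy complexes
of 5–10 residues per chain, ~200-atom contact fixtures, 100-seed kinetic
recovery at a 2 s grid — were chosen as the smallest sizes at which every
property is meaningfully exercised.

# Known limitations

* Single-conformer, heavy-atom geometry only; no hydrogen placement, no
  water-mediated or π-stacking contacts.
* SASA uses per-element radii; no Lee–Richards variant, no polar/apolar
  decomposition, no interface energetics or shape complementarity.
* Asymmetric-unit coordinates are used as-is; no symmetry/assembly
  expansion.
* Chain-role identification in `icos_study` is heuristic (motif search,
  length, cross-form alignment); arbitrary complexes should pass explicit
  selections through `analysis_config` instead.
* The bivalent mode is a qualitative approximation, and deposited-structure
  results depend on network-fetched inputs that cannot be bundled.
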