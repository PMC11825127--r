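---
title: "Conformational descriptors and dimer-selectivity analysis of BRAF kinase structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational descriptors and dimer-selectivity analysis of BRAF kinase structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braftools)
```

## The scientific problem

BRAF with the V600E mutation is a major oncogenic driver. Its kinase domain
signals either as a monomer or as a side-by-side dimer, and RAF inhibitors
divide into three pharmacological classes: monomer-selective (vemurafenib
and relatives), equipotent (e.g. LY3009120), and dimer-selective (e.g. the
ponatinib hybrid PHI1). Which class an inhibitor falls into is tightly
coupled to two conformational switches of the kinase domain:

* the **alpha-C helix**, whose inward ("in") position lets the catalytic
  Lys483 form a salt bridge with the helix-centre Glu501, and
* the **DFG motif** (Asp594-Phe595-Gly596 region at the start of the
  activation loop), whose "out" flip vacates the back pocket that type-II
  inhibitors occupy.

`braftools` implements the quantitative descriptors of these switches, the
protein-ligand interaction fingerprints that summarise how an inhibitor
engages the pocket, an empirical co-crystal-based classifier of dimer
selectivity, trajectory-level statistics for molecular-dynamics (MD)
ensembles, and a difference contact-network analysis for comparing apo and
holo ensembles. A synthetic structure/trajectory generator makes the whole
pipeline testable with no downloads.

## Descriptors and their cutoffs

All cutoffs are heavy-atom distances in Angstrom; crystal structures
usually lack hydrogens, and all criteria here are defined so that they work
identically with and without them (hydrogens are dropped on input).

| descriptor | definition | boundary |
|---|---|---|
| alpha-C position | distance from the Ile582 C-alpha (a stable beta-7 reference) to the unweighted centroid of the C-alpha atoms of Asn500, Glu501, Val502 | in `< 19.6` A, out otherwise |
| K-E salt bridge | Lys483 NZ to nearest Glu501 carboxylate O (OE1/OE2) | bridged at `<= 4.0` A |
| K-E (alternative) | minimum over all sidechain heavy-atom pairs of Lys483 and Glu501 | bridged at `<= 4.5` A |
| DFG pseudo-dihedral | torsion of the C-alpha atoms of Ile592, Gly593, Asp594, Phe595, wrapped to `[0, 360)` | out at `>= 140` degrees |

Conventions worth stating precisely:

* **Centroid, not mass-weighted centre.** The three helix-centre atoms are
  all C-alpha carbons, so the unweighted centroid and the centre of mass
  coincide; we compute the centroid.
* **Boundary conventions.** The in/out boundaries are measure-zero choices:
  alpha-C "in" is strict (`< 19.6`) and DFG "out" is closed (`>= 140`).
  Observed values essentially never sit exactly on a boundary; the choice is
  documented so that results are reproducible bit for bit.
* **Dihedral range and sign.** Reported DFG dihedrals exceed 180 degrees
  (apo ensembles peak near 210, doubly-inhibited dimers near 290), which
  fixes the `[0, 360)` wrapping. The sign before wrapping follows the IUPAC
  right-hand torsion rule; the test suite cross-checks against two
  independently coded torsion implementations (including `bio3d`, which uses
  the opposite sign convention).
* **Sidechain definition.** For the 4.5 A minimum-sidechain criterion,
  "sidechain" means heavy atoms beyond the C-alpha (C-beta onward). Whether
  C-beta should count is genuinely ambiguous in the field's usage; including
  it is the more permissive reading and is what we ship. Both salt-bridge
  metrics are always computed and reported side by side; the NZ-carboxylate
  form is the default for probability analyses and for the classifier.

Missing residues - unresolved activation loops are common in BRAF crystal
structures - degrade descriptor records per-descriptor: the affected field
becomes unavailable (`NA`) while the rest of the record is computed.

## Interaction fingerprints

Fingerprints are per-residue category sets from the ligand's perspective:
`h_donor` (ligand donates a hydrogen bond to the residue), `h_acceptor`
(ligand accepts), `hydrophobic` (carbon-carbon contact). The numeric
criteria: donor-acceptor heavy-atom distance `<= 3.5` A for hydrogen bonds;
carbon-carbon distance `<= 4.0` A when both atoms are aromatic and
`<= 4.5` A otherwise. Aromatic face-to-face stacking is deliberately folded
into the hydrophobic category - no separate pi-stacking geometry test.

Protein-side donor/acceptor typing is a fixed documented table (backbone N
donates except proline, backbone O accepts, sidechains per residue
chemistry; histidine ring nitrogens count as both donor and acceptor since
protonation is unknown in a crystal). Ligand-side typing comes from a
shipped annotation table for the three exemplar inhibitors (keyed `PHI`,
`LY`, `VEM`, with `PHI1` accepted as an alias) and is user-extensible via
TSV; an element-based heuristic (N donors, N/O acceptors) is available as a
fallback and can be disabled.

Three hydrogen bonds get dedicated flags because the selectivity analysis
keys on them: the ligand-to-Glu501-carboxylate bond, the Asp594 backbone
bond (with direction: type-II amide carbonyls *accept* from the backbone
amide, vemurafenib's sulfonamide *donates*), and the ligand-to-His574
backbone-carbonyl bond.

Back-pocket occupancy (BP-I through BP-IV) is configuration, not code: the
shipped residue map (`inst/extdata/backpockets.tsv`) follows the standard
back-pocket nomenclature mapped onto BRAF numbering, and a pocket counts as
occupied when any ligand heavy atom comes within 4.5 A of any heavy atom of
the pocket's residues. BP-III is the subpocket filled by the Phe595
sidechain in DFG-in structures, which is why monomer-selective (DFG-in)
inhibitors do not occupy it.

## The empirical selectivity classifier

The decision rule operates on a dimeric co-crystal structure and reflects a
simple mechanistic chain: a stable ligand-Glu501 hydrogen bond restrains
the alpha-C helix; a restrained helix shows (nearly) identical geometry in
the two crystallographically independent protomers.

1. no ligand hydrogen bond to the Glu501 carboxylate ->
   `monomer_selective`;
2. hydrogen bond present, but the alpha-C position **and/or** the
   NZ-carboxylate K-E distance differ between the protomers by >= 0.3 A
   (after rounding to 0.1 A) -> `equipotent`;
3. hydrogen bond present and both metrics identical within the threshold ->
   `likely_dimer_selective`.

The deviations are rounded to 0.1 A before comparison because that is the
precision at which such differences can be meaningfully read off 2-3 A
resolution structures; raw values are retained in the returned record, and
`evidence_notes` names the branch that fired so borderline calls can be
audited. The "and/or" is important: known equipotent cases fire on the
alpha-C deviation alone or on the K-E deviation alone. The rule is a
screen, not a potency predictor: dimer-compatible exceptions with small
deviations exist, which is why branch 3 is labelled *likely*.

## Trajectory statistics

`extract_series()` computes per-frame descriptor series per protomer. The
default `trim_fraction = 0.4` discards the first 40 percent of frames,
matching the convention of analysing the final 3 microseconds of 5
microsecond production runs; the trim is fraction-based because a frame
index carries no absolute timebase - the frame-to-time mapping is the
user's configuration.

Distribution summaries use 50 equal-width density-normalised bins spanning
the pooled data range (shared edges can be supplied to compare conditions);
the density integral is exactly 1 and the suite enforces this to 1e-9.
State probabilities (e.g. salt-bridge occupancy, predicate
`ke_no_distance <= 4`) are computed per replica and summarised as the mean
and the n-replica sample standard deviation - replica spread is the only
error estimate used; no autocorrelation analysis is attempted. Paired
descriptors (alpha-C position against the minimum distance from the
ligand's donor group to the Glu501 carboxylate oxygens) feed a normalised
2-D binned density whose marginals equal the 1-D histograms exactly when
edges are shared. The "amide group" side of that distance is
operationalised as the ligand's annotated donor atoms and is configurable
per het-code.

## Difference contact networks

Residue-pair contact probability is the fraction of frames in which any
heavy-atom pair of two residues lies within 4.5 A (closed). Same-chain
pairs within two sequence positions are excluded by default - they are
trivially in contact through the backbone; standard contact-network
practice, and configurable (`exclude_within = 0` keeps everything).

A stable-contact graph keeps pairs with probability >= 0.7 (closed).
Communities are found by divisive Girvan-Newman partitioning run until the
requested number of components (default 4, matching the N-lobe/C-lobe x
two-protomer architecture of the kinase dimer). Among equal-betweenness
edges the lexicographically smallest endpoint pair is removed, which makes
the partition deterministic - the contract here is the partition interface,
not a bit-match to any particular external implementation of the same idea.
Isolated residues join the community of their nearest-in-sequence assigned
neighbour.

Community-level "average contacts" are sums of pairwise contact
probabilities between community members, i.e. the expected number of
simultaneous inter-community contacts. That summed-probability reading (as
opposed to counting frames with at least one contact) is a deliberate,
flagged choice: it is additive across pairs, antisymmetric under
holo/apo exchange, and recovers planted scenario parameters exactly in
expectation. The difference network is holo minus apo per community pair,
and the inter-protomer sum adds the deltas over community pairs whose
members lie in different protomers, each unordered pair counted once.

## The synthetic generator: what it emulates, and what it does not

`make_structure()` builds minimal protomers containing exactly the atoms
the descriptors need, placed so computed descriptors equal their targets to
machine precision. The three descriptor regions are geometrically
independent by construction - the alpha-C centroid slides along a fixed
axis from the Ile582 C-alpha, the Phe595 C-alpha rotates about the
Gly593-Asp594 axis, and the Glu501 carboxylate slides along the Lys483 NZ
direction - so tests can vary one target and assert the others unchanged.
`make_trajectory()` realises frames whose descriptors are draws from stated
distributions: normal alpha-C positions, wrapped-normal (mixture) DFG
dihedrals, Bernoulli salt-bridge and hydrogen-bond occupancies. Replicas
differ only by sub-seed; the same seed reproduces output bit for bit.

Generator defaults are the study conditions the package is exercised
under: an apo-dimer-like ensemble (alpha-C ~ Normal(22.0, 0.6) A, broad
DFG-out dihedral around 210 degrees, 25 percent salt-bridge occupancy,
three replicas), and a contact scenario whose planted holo-minus-apo
inter-protomer deltas sum to +0.3 - carried by the N-lobe:A to C-lobe:B
pair and partially offset by a C-lobe:A to C-lobe:B decrease, the
stabilisation pattern characteristic of dimer-compatible inhibitor
binding. The standard deviations (0.6 A for the alpha-C position, 12-15
degrees for the DFG dihedral) are our choice of realistic single-basin
fluctuation scales for a folded kinase domain at 300 K.

What the generator does **not** emulate: physically realistic protein
geometry (no covalent continuity between the descriptor regions, no force
field, no solvent), correlated descriptor dynamics, slow conformational
transitions, or autocorrelated frames (draws are i.i.d., so binomial error
bounds apply exactly). Consequently, passing tests demonstrate that the
*analysis* is correct - parameter recovery, invariances, determinism - not
that any particular biological ensemble has particular properties.
Real-structure regression values used in the acceptance checks are carried
by synthetic stand-ins constructed to the reference geometry of the
corresponding deposited structures; they verify the computation path
end-to-end (PDB text in, numbers out), not the deposited coordinates
themselves.

## Numerical and design choices

* **Alt-locs**: highest occupancy wins, ties broken by alt-loc identifier
  order - deterministic single-conformer geometry.
* **Waters and monoatomic ions** are never ligands; fingerprints are
  protein-inhibitor only. Hydrogens are ignored throughout.
* **Degenerate dihedrals** (three collinear points) raise an error rather
  than returning an arbitrary value.
* **Histogram edges** span the pooled data min/max unless supplied; a
  single repeated value widens its range by +-0.5 to avoid a zero-width
  axis.
* **Problem sizes** in the shipped tests and acceptance script: 3 replicas
  x 10,000 frames for occupancy recovery (binomial 3-SD tolerance), 2,000
  frames per condition for the contact scenario (planted-sum tolerance
  0.1), 100 random quadruples for the torsion cross-check at 1e-6 degrees.
  These sizes make every statistical tolerance an explicit function of n.
* **Trajectory formats**: multi-model PDB and DCD (with a separate
  topology) are read; the synthetic module emits multi-model PDB so the
  pipeline consumes only standard formats.

## Known limitations

* The fingerprint typing of ligands not in the shipped annotation table
  relies on an element heuristic that cannot distinguish, e.g., tertiary
  amines (non-donors) from amides; curate a TSV for production use.
* Back-pocket membership is a pragmatic BRAF-numbered approximation of the
  standard pocket nomenclature; users with a preferred definition should
  supply their own table.
* The classifier encodes an empirical screen whose known exceptions
  (dimer-compatible inhibitors with small inter-protomer deviations) are
  reported as evidence, not resolved.
* The contact-network stage assumes residue identity is stable across
  frames (a fixed topology); it does not handle variable atom counts.

## A worked example

```{r example}
spec <- synthetic_spec(n_protomers = 2, alpha_c = c(19.1, 19.0), dfg = 210,
                       ke = 2.8, ligand = "PHI", glu501_hbond = TRUE)
s <- make_structure(spec)
descriptor_table(s)[, c("chain", "alpha_c_distance", "alpha_c_state",
                        "ke_no_distance", "dfg_pseudo_dihedral", "dfg_state")]
classify_structure(s, "PHI")
```
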