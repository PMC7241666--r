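---
title: "Methods: thermostability profiling of MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermostability profiling of MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotraj)
```

## Scope and model

`thermotraj` analyzes finished MD trajectories of proteins simulated under
several conditions — typically a temperature series with and without a
structural divalent ion — and quantifies what changes: global deviation and
compactness (RMSD, Rg), solvent exposure (SASA), the time-resolved inventory
of non-covalent interactions (hydrogen bonds, salt bridges, hydrophobic
contacts) with occupancy statistics, and the localization of flexibility
changes (RMSF-based region calling). Running the simulations themselves,
force-field assignment and protonation-state prediction are out of scope;
the package starts from a protonated PDB topology and a coordinate
trajectory (multi-model PDB or the plain-text `xyz_frames` dialect — binary
MD formats are deliberately unsupported and should be converted externally).

## Deviation metrics

**Superposition.** All deviation metrics rest on optimal rigid
superposition, computed by the Kabsch algorithm (SVD of the weighted
covariance matrix with reflection correction, so the rotation is always
proper). RMSD uses unweighted backbone atoms, the common convention of
trajectory-analysis tools; Rg is mass-weighted, the common convention of
visualization tools. Both conventions are flags.

**RMSD series.** Each frame's selection (default: the backbone heavy atoms
N, CA, C, O) is superposed onto the same selection of the reference (default:
frame 1, the "initial structure") and the post-fit RMSD recorded.
Time-series summaries are means ± sd over a *converged window*, expressed as
a fraction of simulation time and defaulting to `c(0.25, 1)` — production
runs typically equilibrate within the first quarter; the window is
configurable because convergence must be judged per system.

**RMSF profile.** Frames are aligned on the backbone, then each atom's RMS
deviation over time is computed. The deviation reference is the atom's
*time-mean position* by default (the convention of standard fluctuation
analyses, and the choice that makes RMSF of isotropic Gaussian jitter with
standard deviation σ per coordinate converge to σ√3); deviations from the
initial structure are available by flag. The per-residue value is the mean
over the residue's selected atoms, which is what region calling consumes.

## Solvent-accessible surface area

SASA uses the Shrake–Rupley construction: each atom's van der Waals sphere
(Bondi radii by element, 1.7 Å fallback, 1.2 Å for hydrogens) is inflated by
the probe radius (default 1.4 Å, a water molecule) and covered with a
deterministic golden-spiral point set (default 960 points — the relative
error against the closed form for an isolated sphere is below 1 %, and
doubling the count twice changes a 50-atom system by under 1 %). A point is
accessible when outside every neighbor's inflated sphere; neighbors come
from a cell-list search. Waters and ions are excluded from both the surface
and the occlusion set. Hydrogens are included when present (protonated
AMBER-style inputs), with a flag to drop them for cross-tool comparison.

Aggregation splits the protein area into *hydrophobic* (Ala, Ile, Leu, Phe,
Val, Pro, Gly, Met, Trp) and *hydrophilic* — defined as every protein
residue that is **not** hydrophobic, so the two components add exactly to the
total. Histidine, which belongs to none of the three chemistry classes used
here (charged: Arg, Lys, Asp, Glu; polar: Gln, Asn, Ser, Thr, Tyr, Cys),
counts as hydrophilic under this definition, preserving additivity. The
catalytic-set area (default residues 473, 510 and 642, the
nucleophile/acid-base/transition-state-stabilizer triad of the enzyme the
defaults target) is reported in Å² while the class sums are in nm², because
a three-residue area is of order tens of Å² and would vanish in nm².

The SASA distribution histogram uses 2-nm² bins anchored so centers fall on
odd integers, with the modal bin (center and % of frames) reported; ties
resolve to the lowest center and are flagged.

## Hydrogen bonds

Donors are N/O atoms with at least one covalently bonded hydrogen (one
candidate per hydrogen), acceptors all N/O atoms; water oxygens are both.
A bond is present in a frame iff the donor–acceptor distance is **at most
3.5 Å** (the stated maximum is read as inclusive) **and** the
donor–hydrogen–acceptor angle, measured at the hydrogen, is **strictly
greater than 120°**. Intra-residue pairs are excluded (sequential backbone
neighbors are kept); water–water pairs are excluded.

Candidates sharing the same (donor atom, acceptor atom) through different
hydrogens are redundant: only the highest-occupancy one is kept, with exact
ties resolved to the lowest hydrogen index for determinism.

Records are classified three ways: main-chain/side-chain role of donor and
acceptor heavy atoms (MM / MS / SS; the main-chain set is N, C, O, OXT);
residue-chemistry pairs (chr–chr, pho–pho, phi–phi, pho–phi; any pair
involving His/"other", or charged with non-charged, falls into *other*, so
the named classes plus *other* partition the total); and partner kind, where
protein–water bonds are labelled M-water or S-water by the protein atom's
role and chr/pho/phi-water by the protein residue's class. Category tables
report the *mean per-frame count*: the sum of all per-frame presences in the
category divided by the number of frames.

## Salt bridges and hydrophobic contacts

A salt-bridge event requires a side-chain carboxylate oxygen (Asp OD1/OD2,
Glu OE1/OE2) within **strictly** 4 Å of a side-chain basic nitrogen (Arg
NE/NH1/NH2, Lys NZ); every atom combination of a residue pair is evaluated,
and the pair is represented by its highest-occupancy atom pair, whose mean ±
sd distance over present frames is recorded. A union-of-atom-pairs occupancy
is reported alongside, since either convention is defensible; the best-pair
number is primary, matching the uniqueness-by-highest-occupancy rule.

Hydrophobic contacts consider the designated carbon set (backbone C/CA plus
the CB/CG/CD/CE/CZ/CH side-chain families, i.e. the PDB spellings of the
Greek-letter carbon list); a residue pair is in contact when any carbon pair
across it is within 4 Å (inclusive), and one presence record is kept per
residue pair. Same-residue and sequence-adjacent (|Δseq| ≤ 1) pairs are
excluded — neighboring backbones are trivially within range and would swamp
the statistics; this exclusion is a package decision the user can audit in
the code, as the convention is rarely stated explicitly. A flag restricts
the analysis to hydrophobic-class residues; by default all residues carry
the designated carbons, as backbone C/CA exist everywhere. The literature
alternative cutoff 3.9 Å is a configuration away.

Both detectors, and the hydrogen-bond detector, have two interchangeable
engines — a frame-vectorized all-pairs scan and a per-frame cell-list
search — asserted bit-identical in the test suite; the all-pairs engine is
the default at desk scale, where candidate sets are small and vectorization
over frames dominates.

## Occupancy bookkeeping and differential classification

Occupancy is 100 × frames-present / frames, computable over a window.
Lifetime bins are right-inclusive: short-lived (0, 10], substantially live
(10, 90], long-lived (90, 100]; the fine histogram uses ten 10-point bins.
The occupancy filter keeps records **strictly above** the threshold
(default 50 %).

Across an ordered condition series (reference first), matched interactions
are called: *comparable* (above the filter everywhere, spread ≤ 10
percentage points), *maintained* (everywhere, minimum ≥ 80 %), *weakened*
(everywhere, strictly decreasing with total drop > 10 points), *variable*
(everywhere, none of the above), *lost* / *gained* (above the filter only
in, or only outside, the reference), and *partial* for the remaining mixed
patterns. The 10-point comparability tolerance and the 80 % maintained
floor quantify qualitative notions and are configurable. The checks apply
in the order listed: the categories overlap (a 94/93/92 profile has both a
tight spread and a high floor), and giving *comparable* precedence makes
tight spreads win over high floors, which matches how the two words are
naturally used; *maintained* precedes *weakened* so a high-floor strictly
decreasing profile reads as maintained rather than weakened.

## Thermal-sensitive regions and ANOVA

Region calling operates on per-residue ΔRMSF (condition minus reference) by
default — overlaying absolute profiles is supported by flag, but differences
are what identify *thermally induced* mobility rather than intrinsic
flexibility. Residues at or above the lower threshold (default 0.5 Å) form
maximal runs; runs separated by at most one sub-threshold residue merge;
merged runs shorter than 3 residues are discarded; the first and last 5
profile positions are ignored because free termini fluctuate for reasons
unrelated to thermal sensitivity. A region whose maximum reaches the upper
threshold (default 1.0 Å) is flagged *high*, otherwise *moderate*.

The condition comparison runs a classical one-way fixed-effects ANOVA
(via `stats::oneway.test` with equal variances) on per-frame RMSD, Rg and
SASA values, flagging p < 0.05. Per-frame values are serially correlated,
so treating frames as independent observations is pseudo-replication; the
package reproduces this conventional usage and documents the caveat rather
than replacing the test, since the metric series are also exported for any
more careful treatment.

## Synthetic data: what it emulates and what it does not

The generator builds extended-chain toy peptides with PDB-standard atom
names, explicit hydrogens on donor heteroatoms, an optional water shell
placed ≥ 4 Å from the protein, and an optional Ca²⁺ ion. Frames are the
reference plus independent isotropic Gaussian jitter with per-residue
standard deviations; a condition's "temperature" scales the jitter (defaults
1.0 / 1.2 / 1.5 across the series, ×1.2 when the ion is absent — chosen once
as a realistic-looking destabilization pattern for a strongly
temperature-sensitized enzyme, not fitted to anything). Planted interaction
schedules toggle designed donor/acceptor, salt-bridge and contact pairs in
and out of geometric range; in-range frames are an exact-count seeded
permutation, so recovered occupancies are exact rather than binomial (a
Bernoulli mode exists for stress testing). Only the mobile tip (partner atom
plus bonded hydrogens, or the whole water) moves, parked along a direction
that points into empty space so unrelated metrics stay unperturbed.

This validates the *bookkeeping*: detection criteria, deduplication,
occupancy arithmetic, classification, region boundaries, determinism. It
does **not** emulate real protein physics — no correlated motions, no
realistic water dynamics, no physically consistent conformations in
scheduled frames — so passing tests certify the analysis machinery, not any
claim about what a particular real trajectory contains. Default problem
sizes (16-residue interaction systems, 60-residue fluctuation chains, 400 to
2000 frames) were chosen as the smallest sizes at which recovery tolerances
(occupancies exact; fluctuation ratios within 5 %; region boundaries exact)
are comfortably met.

## Numerical and engineering choices

* Bonds are perceived geometrically from the reference frame (hydrogen to
  nearest in-residue heavy atom ≤ 1.3 Å; in-residue heavy pairs ≤ 1.9 Å;
  peptide C–N across consecutive residues ≤ 1.9 Å) rather than from residue
  templates: donors are matched by bonded-hydrogen lookup, never by name
  patterns, so both PDB-v3 and AMBER hydrogen names work, as do modified
  residues.
* Unknown residues classify as "other" with a warning, never an error;
  missing element symbols are inferred from digit-stripped atom names, with
  monoatomic ions identified by residue name; duplicate alternate locations
  keep 'A'/blank with a warning.
* Boundary conventions are explicit and tested: hydrogen-bond distance
  inclusive, angle strict; salt bridge strict; contact inclusive; lifetime
  bins right-inclusive; occupancy filter strict.
* CSV outputs are written with 4-decimal floats in fixed row orders, making
  whole report bundles byte-reproducible; the fully resolved configuration
  is embedded in every report as JSON, so each gap-filling default actually
  used is visible per run.
* The package's interface is function-first (`run_analysis`,
  `compare_runs`, `write_report`, the generator), in the style of R
  structural-bioinformatics libraries; orchestration from shell scripts is a
  thin `Rscript -e` away, as `scripts/acceptance.R` demonstrates.

## Known limitations

Direct parsing of binary trajectory formats is unsupported. Protein–water
hydrogen-bond counts consider direct pairs only, not water-mediated bridges.
The catalytic-area unit mix (Å² vs nm²) follows the magnitude argument given
above. ANOVA significance inherits the pseudo-replication caveat. The
cell-list engines are reference implementations validated for correctness,
not tuned for very large systems.
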