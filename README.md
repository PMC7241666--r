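# thermotraj

Post-simulation analysis of molecular dynamics (MD) trajectories for
**protein thermostability profiling**, written for structural biologists and
enzyme engineers who run multi-temperature simulations (e.g. of industrial
enzymes such as the barley starch-debranching enzyme limit dextrinase, whose
activity is lost during high-temperature mashing) and need to ask: *which
interactions and which regions give way as the temperature rises?*

The package implements the complete downstream methodology as reusable,
tested R functions:

* **Structural deviation metrics.** Backbone RMSD against the initial
  structure after optimal rigid (Kabsch) superposition,
  `RMSD = sqrt( (1/N) * sum_i |r_i - r_i^ref|^2 )`; per-residue RMSF,
  `RMSF_i = sqrt( <|r_i(t) - <r_i>|^2> )` after frame-wise alignment;
  mass-weighted radius of gyration
  `Rg = sqrt( sum_i m_i |r_i - r_cm|^2 / sum_i m_i )` — each with
  converged-window mean ± sd summaries.
* **Solvent-accessible surface area.** Shrake–Rupley numerical SASA
  (probe 1.4 Å, 960 deterministic golden-spiral points per atom), aggregated
  as hydrophobic / hydrophilic / total / catalytic-residue areas and a
  2-nm² histogram with modal-peak reporting.
* **Non-covalent interaction fingerprints with occupancy bookkeeping.**
  Hydrogen bonds (donor–acceptor ≤ 3.5 Å *and* donor–H–acceptor angle
  > 120°, redundant hydrogens deduplicated by highest occupancy), salt
  bridges (Asp OD1/OD2, Glu OE1/OE2 to Arg NE/NH1/NH2, Lys NZ, strictly
  < 4 Å, one record per residue pair), and hydrophobic contacts (designated
  carbon atoms within 4 Å, without redundancy). Occupancy = % of frames in
  which the geometric criterion holds; records are binned into short-lived
  (0–10%], substantially live (10–90%] and long-lived (90–100%] classes and
  filtered at the strict 50% threshold.
* **Cross-condition comparison.** Differential classification of matched
  interactions (weakened / comparable / maintained / lost / gained), one-way
  ANOVA of per-frame RMSD/Rg/SASA between conditions, and thermal-sensitive
  region calling from ΔRMSF profiles at the 0.5 / 1.0 Å thresholds.
* **Synthetic-data generator.** Toy peptides with PDB-standard atom names
  and designed ground truth — per-residue jitter amplitudes, planted
  interaction schedules with exact-count occupancies, water shells, optional
  divalent ions — so every stage of the pipeline is validated against known
  answers without cluster-scale inputs.

Inputs are PDB structures (hydrogens required for hydrogen-bond analysis)
plus multi-model PDB or plain-text `xyz_frames` trajectories; binary MD
formats should be converted externally.

## Worked example

```r
library(thermotraj)

## six synthetic conditions (three temperatures, with/without Ca2+),
## 400 frames each, with planted interactions of known occupancy
study <- synthetic_study(synthetic_spec(n_frames = 400, seed = 7))
traj  <- study[["298K"]]$trajectory

rmsd_series(traj)
#> <metric_series> rmsd (Angstrom), 400 frames; window [0.25, 1] mean 0.6725 +/- 0.137
radius_of_gyration(traj)
#> <metric_series> rg (Angstrom), 400 frames; window [0.25, 1] mean 18.57 +/- 0.0244

hb  <- classify_hbonds(dedupe_hbonds(detect_hbonds(traj)))
rec <- hb$pairs[hb$pairs$occupancy > 50, ]
rec[order(-rec$occupancy),
    c("donor_res", "donor_atom", "acceptor_res", "acceptor_atom",
      "occupancy", "backbone_class", "chem_class")]
#>  donor_res donor_atom acceptor_res acceptor_atom occupancy backbone_class chem_class
#>         15        NE2            9           OE1        95             SS      other
#>         13        ND2            9           OE2        75             SS      other
#>         18          O           12           OG1        60        S-water  phi-water
#>          6         OG           13           OD1        55             SS    phi-phi

unique_salt_bridges(detect_salt_bridges(traj))[,
    c("pair", "acidic_atom", "basic_atom", "occupancy", "mean_dist")]
#>    pair acidic_atom basic_atom occupancy mean_dist
#>   D3-R7         OD1        NH1        95       3.2
#>  D3-K11         OD2         NZ        90       3.2
```

The recovered occupancies (95, 75, 60, 55 % …) are exactly the values the
generator planted, because scheduled interactions are toggled by exact-count
seeded permutations; the RMSD/Rg summaries are converged-window means over
the final 75 % of the run. `run_analysis()` bundles all per-condition
analyses; `compare_runs()` adds differential interaction calls, region
calls and the ANOVA table; `write_report()` emits a deterministic CSV/JSON
bundle.

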