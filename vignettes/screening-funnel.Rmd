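---
title: "Methods: a comparative virtual-screening funnel for selective zinc chelators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a comparative virtual-screening funnel for selective zinc chelators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdacfunnel)
```

# The screening model

`hdacfunnel` implements the decision logic of a stepwise,
*comparative* structure-based virtual screen for hydroxamate inhibitors
of a zinc-dependent deacylase. The target of interest (an HDAC11 pocket
model) supplies a pharmacophore and a catalytic Zn²⁺; a set of
anti-target pockets (HDAC1, HDAC6, HDAC8) supplies negative evidence.
The working assumptions are those of the screening tradition the
package descends from:

* The zinc binding group dominates binding: a ligand is a plausible
  binder iff its deprotonated hydroxamate chelates the catalytic zinc
  *bidentately*, i.e. both the carbonyl and the hydroxylate oxygen sit
  within a contact cutoff of the metal.
* Selectivity can be screened comparatively: a ligand whose docked pose
  chelates an anti-target's zinc is assumed non-selective and removed,
  without requiring affinity estimates for the anti-targets.
* Docking poses, binding scores (MM-GBSA-like) and MD trajectories are
  produced by *external* engines. The funnel consumes exactly one top
  pose per ligand per receptor through a backend contract
  (`function(molecule, receptor) -> DockedPose`), a `ScoreTable` for
  ranking, and multi-model PDB trajectories for the stability analysis.
  Only a deterministic mock backend ships; its purpose is testing the
  funnel's logic, not predicting chemistry.

The stage order is fixed (curation → pharmacophore → target docking →
pose filter → anti-target docking → comparative elimination → alerts →
ranking). The orchestration guarantees three audit invariants, which the
test suite asserts: survivor sets only shrink, per-stage input = output +
removals, and every removal carries exactly one stage and reason.

# Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| rule-of-five thresholds | MW 500, logP 5, HBD 5, HBA 10 | Da / – | classical drug-likeness rule; inequalities **strict**, the form in which the rule is printed in the screening literature this funnel mirrors; `strict = FALSE` gives the ≤ variant |
| chelation cutoff | 2.6 | Å | conventional Zn–O contact limit for hydroxamates; the boundary is *inclusive* because poses are removed only when a distance exceeds the cutoff |
| feature tolerance | 1.5 | Å | matching sphere radius per pharmacophore feature; platform defaults for this are unpublished, so it is a config key |
| excluded-volume radius | 1.2 | Å | sphere around protein heavy atoms that ligand heavy-atom centers may not enter |
| shell distance | 5.0 | Å | protein atoms within this distance of any ligand heavy atom become excluded volumes |
| conformer cap | 50 | – | conformers examined per ligand during matching |
| H-bond criteria | 2.5 Å, 120° | – | donor-H···acceptor distance and D–H···A angle, common simulation-suite convention |
| salt-bridge criterion | 4.0 | Å | charged-group heavy-atom distance |
| termini exclusion | residues 1–14, 321–347 | – | flexible termini excluded from backbone fits on request |
| CompScore weight | 5 | – | `CompScore = PoseScore − 5·PersScore`; verified against both published (PoseScore, PersScore, CompScore) triples |
| stability flags | PoseScore ≤ 2 Å, PersScore ≥ 0.6 | – | conventional pose-stability and contact-maintenance thresholds |

All of these are function arguments or config keys; none is hard-coded.

# Chemistry layer

Molecule parsing, canonical SMILES, SMARTS matching, molecular weight
(average atomic weights) and fragment-additive logP go through Open
Babel (`ChemmineOB`). Three perception choices deserve note:

* **Kekulized queries.** Strict Daylight SMARTS semantics make the
  classical kekulized benzohydroxamate query
  (`C1=CC=C(C(=O)NO)C=C1`) match nothing aromatic. Because such queries
  are invariably *meant* aromatically, `substructureFilter()` normalizes
  SMILES-style patterns to canonical aromatic form by default
  (`canonicalizePattern()`); pure SMARTS expressions pass through
  untouched.
* **Donor/acceptor counting.** Rule-of-five HBD/HBA perception ships as
  editable YAML SMARTS (`extdata/perception_smarts.yaml`): HBD = N/O
  atoms bearing ≥ 1 hydrogen, HBA = all N and O atoms. Proprietary
  descriptor packages use fractional, environment-dependent counts that
  are not reproducible from their publications; integer counts are used
  deliberately, so absolute survivor counts of historical screens are
  not a reproduction target.
* **logP.** Open Babel's published fragment-contribution model. Any
  fragment-additive scheme satisfies the filter's contract; the choice
  is recorded here rather than asserted numerically against hand-summed
  tables, which would merely transcribe the implementation's own data.

Pharmacophore feature perception and hydroxamate-chelator
identification run on the molecular graph directly (charged atoms →
negative/positive; N/O with hydrogens → donor; neutral O and
hydrogen-free, low-degree N → acceptor; six-membered C/N rings with
aromatic or alternating bonds → aromatic centroid; halogens and
C-only-terminal carbons → hydrophobic). These rules are deliberately
small and documented; they are not a general-purpose perception engine.

# The matcher

A hypothesis is a set of typed feature points with tolerances plus
excluded volumes. Matching enumerates kind-compatible injective
assignments of hypothesis features to perceived ligand features, aligns
the chosen anchors by rigid-body least squares (Kabsch, proper rotations
only), and accepts iff every aligned anchor is inside its tolerance
sphere and no ligand heavy atom center is inside an excluded volume.
The best accepted assignment across conformers (lowest anchor RMSD)
wins; ties go to the lower conformer index, making screening
deterministic. When `requiredCount` is below the feature count, all
feature subsets of that size are enumerated — partial-match *scoring* is
intentionally absent. Directional (vector) feature checks are omitted:
whether the original platform's aromatic features carry directions is
unpublished, and the synthetic validation layer does not depend on it.

Degenerate inputs are errors, not silent passes: hypotheses with no
features, matching with fewer than three anchors, superposition of
collinear fit selections, selectors resolving to anything but one atom.

# Trajectory analysis and pose scoring

The reference structure is frame 1 by default (stability plots then
start at zero), configurable to an external pose. RMSD series fit each
frame to the reference on a fit selection (typically the backbone,
optionally minus the termini) and measure over a second selection
(ligand, zinc, ...). RMSF is computed about the time-average position
after per-frame fitting. Persistence is the exact fraction of frames
satisfying all criteria of an interaction spec — no smoothing, which is
what makes planted-mask recovery exact. BPMD aggregation reduces each
trial to its time-averaged ligand RMSD (window configurable), averages
over trials (PoseScore), averages mean per-interaction persistences
(PersScore), and combines them linearly (CompScore); interactions are
those defined at the starting pose.

# What the synthetic data emulate — and what they do not

The generators exist so that every stage has labelled inputs with the
statistical structure that stage assumes:

* `genLibrary()` plants exact subset sizes (`roundHalfUp(n·fraction)`)
  for benzohydroxamates, deprotonated states, rule-of-five violators
  (perchlorinated tails pushing MW past 500), pharmacophore matchers and
  nitro alert bearers, nested the way the funnel consumes them
  (violators are anionic, so they reach and fail the property filter;
  alert bearers are comparative survivors, so the alert stage has work).
  Scaffolds are ortho-substituted benzohydroxamates (methoxy / ethoxy /
  chloro) with aliphatic capping tails, mirroring the chemotypes of
  published selective hits. Default conditions, chosen once: n = 200,
  fractions 0.70 / 0.50 / 0.10 / 0.25 / 0.02, target chelation
  0.70 / 0.10 / 0.20 over matchers, anti-target distributions including
  an `absent` class (failed docking), e.g. 0.10 / 0.10 / 0.60 / 0.20 for
  HDAC1. Every planted label is re-verified by the corresponding real
  filter at generation time.
* `genPocket()` builds the template pose and zinc analytically: the
  metal is placed at exactly the classic bidentate geometry (2.41 Å to
  the carbonyl O, 2.17 Å to the hydroxylate O), pseudo-protein shell
  atoms become the excluded volumes, and two histidine-like partners
  provide salt-bridge/H-bond anchors for trajectories. The four-feature
  hypothesis is derived from this pose through the same
  `buildHypothesis()` code path users call.
* `genTrajectory()` realizes planted interaction persistences as exact
  frame masks by geometric construction (participant atoms are placed
  inside the criteria in masked frames and far outside otherwise, and
  are exempt from jitter); isotropic Gaussian jitter, ligand drift
  schedules and extra "flexible termini" jitter are layered on top.

What they deliberately do **not** emulate: conformational energetics
(non-matcher conformers are made by displacing the ring block, not by
strain), docking physics (the mock backend realizes a requested
chelation class geometrically, with a clearance-maximizing spin and
0.05 Å jitter), force fields, water, and realistic protein geometry
(the backbone is a helical C-α trace). Passing tests therefore
demonstrate that the *decision logic* — filters, matcher, classifier,
eliminator, aggregators — is correct on inputs whose ground truth is
known exactly; they say nothing about docking accuracy or affinity
prediction on real chemistry, which remain the attached engines'
responsibility.

# Numerical choices

* Kabsch superposition via SVD with a determinant correction (never a
  reflection); collinear fit sets are rejected since the rotation is
  undetermined.
* Placement of mock poses uses exact two-sphere intersection for the
  chelator oxygens, so requested chelation distances are met to machine
  precision; infeasible mode/geometry combinations error.
* Ranking ties break lexicographically by id (radix order), making
  reports permutation-invariant; the tests shuffle libraries to confirm.
* Planted-count rounding is round-half-up, so fraction specifications
  translate to asserted integers.
* All generators and the mock backend take explicit seeds, save and
  restore the caller's RNG state, and are bit-reproducible.
* Problem sizes used by the shipped suite: a 200-ligand library for the
  end-to-end funnel check, 1000 random poses for the chelation oracle,
  2000 frames for the RMSF convergence check (√3·σ within 5 %), and a 2°
  Euler grid for the superposition oracle — sizes at which the
  closed-form expectations are sharp while the suite stays quick.

# Known limitations

* State *enumeration* (pKa engines) is out of scope; libraries must
  already contain the protonation states to select among.
* Integer HBD/HBA counts mean historical absolute survivor counts from
  proprietary descriptor pipelines are not reproducible, by design.
* The comparative stage operationalizes "correct pose in an anti-target"
  purely as the chelation class; manual pose triage beyond the distance
  rule is not modelled.
* Aromatic ring perception covers six-membered C/N rings — sufficient
  for the benzohydroxamate/pyridine chemotypes this funnel screens, not
  for five-membered heteroaromatics as aromatic *features*.
* Binary trajectory formats are not read; multi-model PDB is the
  portable baseline (converters exist in every MD suite).
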