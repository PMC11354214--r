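---
title: "Profiling the structural impact of missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the structural impact of missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstruct)
```

## The procedure

varstruct automates a classic structural-bioinformatics workflow for
missense variants of a single-chain protein model. For each substitution it

1. builds a point-mutant model with a rigid backbone,
2. computes a per-residue structural profile of wild type and mutant
   (secondary structure, solvent accessibility, hydrogen bonds, salt
   bridges, disulfides, hydrophobic contacts),
3. diffs the two profiles at and around the mutated site,
4. attaches a stability call from a 3-of-5 consensus over external
   predictor values, a conservation flag, and a chemokine-fold region
   label, and
5. aggregates per-variant reports into cohort counts.

All residue numbering is *precursor* numbering: position 1 is the first
residue of the translated chain including the signal peptide (23 residues
by default). Structures numbered on the mature chain are shifted with the
`offset` argument of `read_pdb()`.

## Geometric operators and their parameters

**Secondary structure** follows the Kabsch–Sander construction: the amide
hydrogen is placed 1.0 Å from N along the preceding carbonyl C→O
direction, and the electrostatic hydrogen-bond energy
$E = 0.084\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})\cdot 332$
kcal/mol defines a bond at $E < -0.5$. Two consecutive i→i+4 turns give
`H`, i→i+3 turns `G`, bridge ladders `E`, remaining turn residues `T`,
everything else `C`. We deliberately reduce the alphabet to these five
letters because the variant diff treats "secondary-structure change" as a
binary outcome at the mutated position; distinguishing, say, bends from
coil would only add noise to that flag. Chain breaks (CA–CA > 4.5 Å or a
numbering gap) split the assignment windows, and chains shorter than four
linked residues are reported as all-coil.

**Solvent accessibility** is Shrake–Rupley sphere sampling with a 1.4 Å
water probe and Chothia van der Waals radii (C 1.87, N 1.65, O 1.40,
S 1.85 Å). Sample points come from a golden-section spiral, so the
computation is deterministic at any point density; the default is 960
points per atom, at which an isolated sphere is recovered to well under
1% and doubling the density moves the total by a fraction of a percent
(both checks are part of the test suite). Relative accessibility divides
by theoretical Gly-X-Gly maxima per residue type. Burial classes use
RSA < 20% = buried, 20–50% = partially exposed, > 50% = exposed; the
literature gives the three classes but no universal cutoffs, so these
conventional thresholds are parameters (`buried_max`, `exposed_min`) and
a value exactly on a boundary is assigned to the more exposed class — a
documented tie-break rather than an accident of floating point.

**Hydrogen bonds** are geometric: donor–acceptor ≤ 3.9 Å, H–acceptor
≤ 2.5 Å, donor-H-acceptor angle ≥ 90°. Input hydrogens are discarded and
rebuilt so wild type and mutant are treated identically: backbone amide H
on the C(i−1)/CA bisector, sp2 side-chain H in idealized planar geometry,
and rotatable donors (hydroxyls, lysine NZ, cysteine SH) oriented toward
the candidate acceptor, which makes their angle criterion trivially
satisfied — the practical convention of geometric H-bond finders for
donors with free torsions.

**Salt bridges** pair any basic side-chain nitrogen (Lys NZ, Arg
NE/NH1/NH2, His ND1/NE2) with any acidic oxygen (Asp OD1/OD2, Glu
OE1/OE2) within 4.0 Å (configurable). Histidine is counted as positively
charged: at physiological pH a buried His adjacent to a carboxylate is
typically protonated, and chemokine worked examples hinge on a
His–Glu pair.

**Disulfides** are SG–SG contacts ≤ 2.5 Å with greedy closest-first
matching so each cysteine joins at most one bond. **Hydrophobic
contacts** pair apolar side-chain carbons (carbons not covalently bonded
to N or O, LigPlot-style) within 3.9 Å.

**Superposition** is the Kabsch SVD solution on CA atoms (with the
reflection guard), and **phi/psi** dihedrals get a coarse
favored/allowed/outlier label from rectangles over the alpha, beta and
left-handed-alpha basins, padded by 20° for "allowed". This is a sanity
classifier, not a replacement for a full Ramachandran analysis.

## The mutation builder

`build_mutant()` substitutes one side chain on a *fixed* backbone: N, CA,
C, O of every residue are bitwise unchanged, which the test suite asserts
for a 105-variant cohort. The new side chain is grown from idealized
internal coordinates (bond lengths, angles and ring torsions tabulated
from ideal residue geometry) and a compact backbone-independent rotamer
library of common chi combinations with prior weights. The rotamer
minimizing a steric clash score — the sum of squared van der Waals
overlaps against all atoms outside the 1-2/1-3 bonded environment — wins;
ties break by prior weight, then library order, so the construction is
fully deterministic. When every rotamer clashes, the least-bad one is
kept and the model is flagged `strained`.

This rigid-backbone design is the package's main modelling approximation:
a restrained-optimization modeller would relax neighbouring side chains
and occasionally the backbone. Interaction differences computed from
rigid-backbone mutants are therefore site-focused by construction —
distal geometry cannot change — and the diff is defined accordingly
(symmetric set difference of interaction pairs, which for these mutants
equals the pairs touching the mutated residue plus any pair whose partner
set changed).

## Stability consensus, conservation and regions

Each of five external stability predictors votes "less stable" when its
(sign-normalized, negative = destabilizing) value is at or below minus
its significance cutoff, "more stable" at or above plus the cutoff, and
abstains otherwise; three agreeing votes decide the call, anything else
is `uncertain`. Published work using this rule cites per-method
significance cutoffs without printing them, so the default is the common
0.5 kcal/mol convention for all methods, overridable per method; the
voting logic is independent of the values, and the test suite checks the
rule against the exhaustive 3^5 vote truth table. Missing values abstain.

Conservation grades on the 1–9 scale are either ingested from a server
export or computed as a stand-in: per reference-ungapped column, the
Shannon entropy of the residue distribution normalized by log 20 is
binned as `9 - floor(9h)` and clipped to [1, 9]. Phylogeny-aware rate
estimation would weight sequences by relatedness; the entropy stand-in is
dependency-free and desk-scale, and the downstream rule — a position is
"highly conserved" at grade ≥ 7 — is applied identically to both
sources. Computed grades are therefore comparable within an alignment,
not across tools.

Fold regions are derived from the model's own secondary structure: the
signal peptide is 1..23 by default, the three strands after it become
beta1–beta3, the loops are named by order (N-loop, 30s, 40s, 50s), the
final helix is the C-helix, and anything after it is "other". Exact loop
boundaries are not standardized in the literature, so every interval can
be overridden, and a strand count other than three is a warning, not an
error.

## What the synthetic generators emulate

`make_structure()` builds ideal-geometry fixtures — helices, registered
antiparallel hairpins, residue pairs at constructed distances, two-chain
complexes, seeded random coils — each carrying its ground truth as an
attribute, so every detector can be tested against constructions whose
answer is known by design, plus brute-force all-pairs scans as
independent oracles.

`synthetic_chemokine_model()` assembles a 94-residue precursor with the
chemokine topology: signal helix, N-loop, three-stranded antiparallel
sheet, 30s/40s/50s loops, C-terminal helix; engineered disulfides
33–57 and 34–73; a histidine at 39 aimed so that mutating Lys78 to Glu
creates exactly one salt bridge; and no other acidic residues, so the
wild type has zero salt bridges by construction. It is labelled synthetic
everywhere because that is what it is: a geometric stand-in with the
fold's ground truth, not an experimentally determined structure. Passing
tests on it demonstrate that the operators and the pipeline recover
engineered features through realistic fold geometry; they do not
demonstrate agreement with any real protein's measured structure, which
would require coordinates this package intentionally does not bundle.
Its loops are threaded on interpolated CA paths with approximate
backbone geometry — adequate for coil assignment and side-chain
placement, not for backbone-sensitive analysis of those loop residues.

`make_variant_cohort()` draws distinct random substitutions and a
predictor table constructed so that preset fractions (default 0.5 / 0.2 /
0.3) resolve to less/more/uncertain; the intended calls are stored, which
is what lets the end-to-end pipeline test compare its consensus counts to
ground truth exactly. The structural half of a random cohort has no
precomputed truth — random substitutions' geometric effects *are* the
computation — so the end-to-end check covers counts the generator can
guarantee: cohort size, consensus calls, conservation flags, and region
partitioning.

## Numerical choices and degenerate inputs

- SASA point density 960/atom by default; profile-level work in the test
  suite uses 240 where only class-level outcomes matter.
- Distances compare with `<=` at every cutoff; class boundaries go to the
  more exposed class; consensus votes include values exactly at the
  cutoff.
- Chain termini have undefined phi (first) and psi (last); proline and
  segment-initial residues donate no amide hydrogen.
- Duplicate variants collapse with a warning; stop/frameshift/synonymous
  rows are skipped with a reported count; a wild-type mismatch against a
  reference sequence is an error naming the position, because public
  variant lists do contain conflicting wild-type codes and silently
  picking one would corrupt every downstream count.
- In the pipeline a mismatching variant is recorded as a failure and
  skipped; only an all-failed cohort is an error.
- Pipeline outputs embed the package version and an MD5 hash of the
  configuration, and rerunning with identical inputs is byte-identical.

## Problem sizes

The bundled checks run at deliberately desk-scale sizes: 15-residue
helices, 8-residue coils (100 seeds) for the detector-vs-brute-force
equivalence, the 94-residue synthetic fold model, and 105-variant
cohorts for backbone invariance and the end-to-end pipeline. These sizes
were chosen so the full suite exercises every operator and the complete
pipeline in a few minutes on a laptop while keeping each oracle exact.

## Known limitations

- Rigid-backbone mutants cannot reproduce relaxation-dependent contact
  changes; diffs are site-focused by construction.
- The entropy conservation stand-in is not a phylogeny-aware rate model.
- The coarse phi/psi classifier is not a full Ramachandran validation.
- Exact numeric parity with specific legacy accessibility or H-bond
  programs is out of scope; agreement is tested at the level of assigned
  labels and detected pairs on fixtures with known ground truth.
- Multi-site variants are not modelled; the pipeline treats each
  substitution independently.
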