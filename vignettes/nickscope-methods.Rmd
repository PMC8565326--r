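---
title: "Geometry and mechanism analysis of nicking endonuclease-DNA complexes"
author: "nickscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and mechanism analysis of nicking endonuclease-DNA complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nickscope)
```

## Scope and model

`nickscope` analyzes protein-DNA complexes of single-metal nicking
endonucleases of the exonuclease-endonuclease-phosphatase (EEP) fold, the
family that contains the LINE-1 retrotransposon endonuclease (L1-EN) and
APE1. These enzymes nick one strand of double-stranded DNA; L1-EN does so
sequence-specifically at 5'-TTTTT/AA-3', and the structural signature of
that specificity is conformational: local helix deformation (minor-groove
widening downstream and narrowing upstream of the scissile bond, large
propeller/roll changes at the cleavage step), a flexible scissile-bond
phosphate that can occupy two conformations related by coordinated
alpha/gamma backbone rotations, and a single Mg(2+) ion whose strong
octahedral-coordination preference shapes the transition state.

The package implements the measurement side of that story:

* base reference frames and CEHS/mid-frame helicoidal parameters
  (intra-base-pair: shear, stretch, stagger, buckle, propeller, opening;
  step: shift, slide, rise, tilt, roll, twist),
* cross-strand phosphate-phosphate groove widths against a canonical
  B-form reference,
* protein-DNA contact maps with moiety (base/sugar/phosphate) and groove
  classification,
* Kabsch least-squares superposition with selection- and shell-based RMSD,
* alpha/gamma torsion driving of the scissile phosphate with restrained
  relaxation,
* pentacoordinate (trigonal-bipyramidal) phosphorane transition-state
  construction and Mg(2+) coordination-shell/water-displacement analysis,
* a synthetic-structure generator that produces full-heavy-atom B-DNA
  duplexes with controllable per-step parameters, two-conformer
  phosphates, hydrated ions, and probe-residue poses.

## Reference frames and parameter conventions

Base frames follow the standard reference frame convention: consensus base
geometries are embedded as package data and fitted to the observed ring
atoms (nine atoms for purines, six for pyrimidines) by least-squares rigid
superposition; the fitted rotation and origin are the base frame, and the
fit RMSD is reported. Pair and step parameters use the mid-frame (CEHS)
decomposition: the two frames are symmetrically rotated onto a common
z-axis about the hinge (the cross product of their z-axes), twist (or
opening) is the remaining in-plane rotation, and roll/tilt (or
propeller/buckle) are the hinge rotation resolved along the mid-frame y
and x axes. Translations are the origin difference projected on the
mid-frame. The decomposition has an exact closed-form inverse, which is
what the duplex builder uses; build-then-analyze therefore recovers
parameter tables to numerical precision, and that roundtrip is the test
suite's master oracle.

Sign conventions follow the standard nucleic acid convention (positive
twist for right-handed winding; dihedrals per IUPAC, verified against an
independent implementation). Propeller of an undistorted pair is 0; the
generator's canonical B-form uses twist 36 deg, rise 3.38 A and all other
parameters 0. Real B-DNA has sequence-dependent propeller near -12 deg;
the reference deliberately omits it so that "bound minus reference"
deltas isolate what binding (or an injected perturbation) did. This is a
declared choice, recorded in output headers.

## Groove widths

Groove widths are cross-strand P...P distances with a fixed index offset:
at pair *i*, the minor width spans P(strand 2, *i* - k) to
P(strand 1, *i* + k) and the major width the mirrored pair, with k = 2 by
default and configurable. A `refined` mode subtracts 5.8 A (two phosphate
van der Waals radii). Published groove-width tools differ in offsets and
interpolation, so absolute values are convention-dependent; deltas against
a same-convention reference are not, which is why the package always
reports the bound and reference profiles together. Positions whose
spanning phosphate is missing (termini) report NA rather than an
extrapolated value.

## The phosphate linkage: rotation and driving

The scissile-bond phosphate is treated in internal coordinates along
C4'(i-1)-C3'(i-1)-O3'(i-1)-P-O5'-C5'-C4'(i)-C3'(i). `rotate_phosphate()`
changes alpha and gamma by exactly the requested amounts, rebuilding the
linkage forward from the fixed upstream sugar with all bond lengths and
angles held at their observed values; the free torsions (epsilon, zeta,
beta) are optimized so the downstream sugar stays in place, and the small
residual rigid motion of the congruent anchor triad is propagated
downstream, so covalent geometry stays exact. The coordinated
alpha/gamma "crankshaft" leaves the flanking deoxyriboses nearly fixed;
the residual is reported in the `"sugar_shift"` attribute and is below
0.2 A for typical coordinated rotation pairs, growing to a few tenths of
an Angstrom for extreme flips (where, conversely, the phosphorus itself
is displaced the most — the two quantities trade off, exactly as in the
crystallographic alternate conformers the operation emulates).

`torsion_drive()` interpolates alpha and gamma linearly (shortest angular
route, ties at exactly 180 deg broken toward positive rotation) between
two conformers in steps of 1/n of the total change (default n = 100,
giving 101 frames including both endpoints). At each step the free
torsions are relaxed under the downstream-anchor restraint plus a
harmonic smoothness restraint to the previous step. One subtlety: the
loop-closure problem has two basins, and torsions *measured* on an
alternate-location conformer (whose sugar atoms are shared with the other
conformer) can sit in the wrong basin. The end conformer is therefore
re-expressed in the start conformer's internal-coordinate system by
fitting its mobile-atom positions before interpolation, which makes the
path endpoints reproduce the input conformers to well under 0.05 A.
Because frames are rebuilt from fixed internal coordinates, bond lengths
and angles are conserved along the whole path by construction, and the
driven torsions are exactly affine in the step index. (Alpha, whose four
defining atoms are all either fixed upstream or mobile, is also exactly
affine when re-measured from the frame coordinates; gamma, measured
against the fixed downstream sugar, additionally carries the small
anchor residual of the compensating relaxation.)

## Phosphorane transition state and Mg coordination

The transition-state model is an ideal trigonal bipyramid at the
phosphorus: axial vertices toward the upstream O3' (leaving group) and
the attacking nucleophile oxygen (by default placed at a
crystallographic-water site), equatorial vertices for O5', OP1 and OP2.
Internal geometry is fixed - axial P-O 1.76 A, equatorial 1.60 A, angles
exactly 180/120/90 deg, values representative of small-molecule
phosphorane crystal structures and configurable - and only the rigid
orientation is optimized (rotation-only Procrustes onto the five target
directions). The TBP angle invariants therefore hold exactly regardless
of how noisy the target vertices are; the placement residual carries the
noise.

`coordination_shell()` lists O/N ligands within a cutoff (default 2.6 A,
standard Mg-O coordination being 2.0-2.2 A) and scores octahedricity as
the RMS angular deviation of the ligand directions from the
best-matching ideal octahedron, minimized over vertex assignments
(enumerated; at most 720) and rigid rotations. A perfect octahedral
fragment scores 0; five ideal vertices also score 0 but are flagged
sub-octahedral by count. Water displacement uses a 2.3 A clash threshold
by default.

## Restrained morph

`restrained_morph()` reproduces the protocol of combining an ion-bound
active site with a DNA-bound conformation: atoms within a fixed radius of
a chosen center are pinned to the source coordinates; all other matched
atoms relax under harmonic tethers to the target plus a simplified
internal-geometry energy (harmonic bonds at source lengths, capped
soft-sphere repulsion between nonbonded heavy atoms). The optimizer is
deterministic steepest descent with backtracking line search, so the
energy is non-increasing and results are bit-reproducible. This energy
model is intentionally a simple surrogate, not a molecular-mechanics
force field: it preserves the protocol (what is constrained, what is
tethered, torsion-only moves elsewhere in the package) while remaining
dependency-free, and results derived from it carry that caveat.

## The synthetic generator and what it does not emulate

`build_duplex()` places base atoms from the embedded standard geometries
by composing pair and step frames from the requested parameter tables,
attaches an idealized B-form sugar-phosphate template oriented by each
base frame, and runs a short per-linkage restrained closure (harmonic
bonds O3'-P 1.607 A, P-O5' 1.593 A, O5'-C5' 1.427 A, P-OP 1.485 A,
C5'-C4' 1.511 A plus tethers) when continuity drifts beyond 0.05 A at
perturbed steps. At strongly perturbed steps (large combined roll, tilt
and shift excursions) the linkage cannot always bridge the gap without
moving sugars, and a residual bond deviation of up to about 0.1 A
remains; this is reported rather than hidden by distorting the sugar. The
backbone template was derived once by restrained optimization of ideal
bond lengths/angles and canonical B-DNA torsion targets under the
helical-continuity constraint, and is frozen as package data; its
torsions sit in the canonical B regions (alpha gauche-, gamma gauche+,
C2'-endo-like delta). Overhang and 5'-terminal nucleotides carry no
phosphate, matching synthetic oligonucleotide substrates. Generation is
deterministic given the spec (seed default 20210923).

The generator emulates the geometric structure of crystallographic
duplexes, not their chemistry: no hydrogens (all criteria are heavy-atom
based, as appropriate for 2.0-2.9 A structures), no solvent beyond the
single hydrated ion, no sequence-dependent baseline geometry, no
crystal-packing neighbors, and probe "proteins" are single side-chain
fragments, not folds. Passing tests on these fixtures demonstrates that
the measurement machinery is exact and self-consistent; it does not by
itself validate conventions against any particular external tool's
output on deposited structures, which is why convention parameters are
explicit and echoed into every report.

## Numerical choices

* Pair detection: C1'-C1' distance 10.4 +/- 1.5 A, base z-axes > 120 deg
  apart, at least one N/O...N/O base-edge contact <= 3.5 A, in-plane
  origin separation <= 2.5 A; greedy assignment by smallest combined
  deviation; all thresholds configurable.
* Contacts: polar 3.5 A over donor/acceptor heavy-atom tables (His N
  atoms donor-or-acceptor, since protonation is unknown), van der Waals
  4.0 A; both configurable. Water-mediated contacts are excluded from
  the protein-DNA map.
* Superposition selections behind RMSD numbers are always named in the
  output (e.g. "calpha", "heavy within a 10-14 A shell of the ion"),
  because printed RMSDs are meaningless without them.
* Degenerate cases: exactly antiparallel frames take the frame-1 x axis
  as the hinge; collinear point sets are rejected rather than fitted;
  missing atoms make a torsion or width NA rather than raising.
* Problem sizes in the tests and the acceptance script (6-12 bp
  duplexes, 50 randomized specs, 101-frame paths, 20-case brute-force
  comparisons) were chosen to exercise every code path at interactive
  runtimes.

## Worked example

```{r example, eval = FALSE}
# consensus-site duplex, numbered relative to the scissile bond
s <- build_duplex("TTTTTAA")
s <- assign_relative_numbering(s, c("A", 6))   # +1 = first A

# two-conformer scissile phosphate and the rotation path between them
s2 <- rotate_phosphate(s, c("A", 6), 100, -90, as_altloc = TRUE)
A <- resolve_altlocs(s2, "label:A")
B <- resolve_altlocs(s2, "label:B")
path <- torsion_drive(A, B, c("A", 6), n_steps = 100)
write_structure(path_to_structure(path), "path.pdb", multi_model = TRUE)

# geometry profile against the canonical B-form reference
gp <- geometry_profile(s, "A", "B")
ref <- geometry_profile(build_duplex("TTTTTAA"), "A", "B")
cmp <- compare_profiles(gp, ref)
cmp$summary
```

## Known limitations

Absolute groove widths (and hence the exact magnitude of
widening/narrowing deltas) depend on the chosen P...P convention; only
same-convention comparisons are meaningful. The pair detector targets
Watson-Crick geometry and flags, rather than classifies, noncanonical
pairs. The morph energy is a surrogate (see above). Sugar pucker
(pseudorotation) analysis and global bend/curvature statistics are out of
scope. mmCIF is read-only; PDB is the only output format.
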