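# nickscope

Structural analysis of nicking endonuclease-DNA complexes in R.

Single-metal nucleases of the exonuclease-endonuclease-phosphatase (EEP)
fold — the LINE-1 retrotransposon endonuclease (L1-EN), APE1, DNase I —
nick one strand of double-stranded DNA. For L1-EN the specificity signal
is conformational rather than a hydrogen-bond code: the enzyme reads and
reinforces local deformability of its 5'-TTTTT/AA-3' target site
(minor-groove widening downstream and narrowing upstream of the scissile
bond, propeller/roll extremes at the cleavage step), the scissile-bond
phosphate can occupy two conformations related by a coordinated
alpha/gamma backbone rotation, and the single catalytic Mg(2+) ion's
strong octahedral-coordination preference shapes a pentacoordinate
(trigonal-bipyramidal) phosphorane transition state. `nickscope`
implements the quantitative side of that analysis for crystallographic
models and for synthetic test structures:

* **structure I/O** — PDB/mmCIF reading (via bio3d), fixed-column PDB
  writing (single- and multi-model), alternate-location policies, and
  scissile-bond-relative residue numbering (-k ... -1, +1 ... +m, no 0);
* **DNA geometry** — standard-reference-frame base fitting, CEHS
  mid-frame base-pair and step parameters (shear ... opening,
  shift ... twist), IUPAC backbone torsions, cross-strand P...P groove
  widths, and bound-vs-canonical-B-form profile comparison;
* **contacts** — polar / van der Waals protein-DNA contact maps with
  moiety (base/sugar/phosphate) and groove-face classification;
* **superposition** — Kabsch least-squares fits, selection- and
  radial-shell-based RMSD;
* **mechanism** — alpha/gamma torsion driving of the scissile phosphate
  (1/n-step schedule, restrained relaxation, torsion-only covalent
  geometry), phosphorane transition-state construction, Mg(2+)
  coordination-shell and water-displacement analysis, restrained morphs;
* **synthetic fixtures** — full-heavy-atom B-DNA duplexes with
  controllable per-step/per-pair parameter tables, two-conformer
  phosphates, hydrated ions, and probe-residue poses. These are the test
  bed and the canonical B-form reference generator.

## Worked example

```r
library(nickscope)

# the consensus target site, numbered relative to the scissile bond
s <- build_duplex("TTTTTAA")
s <- assign_relative_numbering(s, c("A", 6))   # +1 = the first A

geometry_profile(s, "A", "B")[, c("position", "propeller", "roll",
                                  "twist", "minor_width")]
#>   position propeller roll twist minor_width
#> 1       -5         0    0    36          NA
#> 2       -4         0    0    36          NA
#> 3       -3         0    0    36       13.42
#> 4       -2         0    0    36       13.42
#> 5       -1         0    0    36       13.42
#> 6        1         0    0    36          NA
#> 7        2         0   NA    NA          NA
```

An ideal built duplex recovers its construction parameters exactly
(twist 36 deg, rise 3.38 A, zero propeller/roll) and constant interior
minor-groove widths; widths near the termini are NA because no phosphate
spans them. Now give the scissile phosphate a second, rotated conformer
and drive the path between the two:

```r
s2 <- rotate_phosphate(s, c("A", 6), 140, -90, as_altloc = TRUE)
distance_panel(s2, list(c("A:+1:P:A", "A:+1:P:B")))$distance
#> [1] 0.66        # the two P conformers sit 0.66 A apart

A <- resolve_altlocs(s2, "label:A")
B <- resolve_altlocs(s2, "label:B")
path <- torsion_drive(A, B, c("A", 6), n_steps = 100)
path
#> torsion_path: 101 frames; alpha -58.8 -> 81.2 gamma 52.6 -> -56.6
write_structure(path_to_structure(path), "path.pdb", multi_model = TRUE)
```

The path has 101 frames (both endpoints included), the driven torsions
change by exactly 1/100 of their totals per step, and covalent bond
lengths/angles are conserved along the whole path. Finally, a hydrated
magnesium site:

```r
shell <- build_ion_shell("MG", n_waters = 4, distance = 2.1)
coordination_shell(shell, "MG")
#> coordination_shell: 4 ligand(s) within 2.6 A (sub-octahedral) ;
#>   octahedricity deviation 0.00 deg
```

`water_displacement()` then reports which shell waters a modeled
phosphorane oxygen displaces, and `build_phosphorane()` places the ideal
trigonal bipyramid (axial P-O 1.76 A toward the leaving O3' and the
attacking nucleophile, equatorial 1.60 A for O5'/OP1/OP2).

A thin command-line wrapper over the same functions is in
`inst/cli/nickscope.R` (subcommands `convert`, `fixture`, `geometry`,
`contacts`, `superpose`, `distances`, `run`).

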