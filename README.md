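# xnageom

Conformational analysis of nucleic-acid structures whose backbones are not
necessarily DNA's. The package targets the comparison that matters when
engineered polymerases copy DNA into synthetic genetic polymers (XNAs):
how do the sugar pucker, backbone torsions, phosphorus spacing and
Watson–Crick pair geometry of an extension product differ between DNA,
TNA (α-L-threose nucleic acid, five-atom 3'→2' phosphodiester repeat) and
pTNA (its phosphonomethyl variant, six-atom repeat)? It is written for
structural biologists and nucleic-acid chemists who have PDB/mmCIF models
— crystallographic or modeled — and want those measurements as tidy,
scriptable tables rather than one-off viewer sessions.

## What it computes

* **Sugar pucker** — endocyclic torsions ν0–ν4 and the
  Altona–Sundaralingam pseudorotation phase/amplitude, via the
  quadrant-safe atan2 inversion of
  ν_j = ν_max·cos(P + 144°(j−2)):
  P = atan2((ν4+ν1)−(ν3+ν0), 2ν2(sin36° + sin72°)), ν_max = |ν2/cos P|;
  conformers binned on the 20-state pseudorotation wheel
  (C3'-endo at 18°, C2'-endo at 162°, …) with north/east/south/west
  quadrants.
* **Backbone torsions** — chemistry-aware: each backbone chemistry
  declares its own torsion names over its repeat unit in a user-extensible
  registry, with the sugar-coupled δ-analog identified so χ/δ A/B-form
  classification is well defined for DNA, TNA and pTNA alike; glycosidic χ
  uses O4'–C1'–N9–C4 (purines) / O4'–C1'–N1–C2 (pyrimidines).
* **P–P spacings** — distances between consecutive bridging phosphorus
  atoms (phosphate or phosphonate), the direct signature of repeat-unit
  length.
* **Base pairs** — Watson–Crick detection by complementarity, heavy-atom
  H-bond distances (A–T: N6···O4, N1···N3; G–C: O6···N4, N1···N3, N2···O2)
  under a cutoff, and an antiparallelity test; six intra-pair and six step
  parameters from base reference frames fitted to embedded standard
  geometries, combined through the half-rotation mid-frame construction.
* **Superposition** — Kabsch rigid fits (reflections excluded), global
  Cα alignment with iterative outlier rejection, and local alignment on a
  named residue subset with the whole structure transformed for overlays.
* **Synthetic structures** — a generator that builds furanose rings at a
  prescribed (P, ν_max), multi-chemistry duplexes at prescribed base-pair
  and step parameters (including chimeric strands such as a DNA primer
  extended by two pTNA residues), Gaussian coordinate noise and Cα clouds,
  so every stage of the pipeline is verifiable with no external data.

Structures are plain atom tibbles; every analysis returns a tibble, so
calls chain with the pipe. `run_analysis()` orchestrates the full pipeline
from a config; `compare_structures()` joins reports side by side;
`autoplot()` draws the pseudorotation wheel and χ/δ scatter.

## Worked example

Build the system the analysis was designed around — a DNA primer whose
3'-end has been extended by two pTNA adenosines, paired against a DNA
template — and run the pipeline:

```r
library(xnageom)
library(dplyr)

dup <- make_duplex(duplex_spec("ATGCAT",
  chemistry1 = c(rep("DNA", 4), "pTNA", "pTNA")))
report <- run_analysis(run_config(dup,
  primer_chain = "A", template_chain = "B", label = "chimera"))

report
#> <xna_report> 'chimera': pucker (12), torsions (12), spacings (10),
#>   altlocs (0), hbonds (14), pairs (6), steps (5)

report$tables$pucker |> filter(chain == "A") |>
  select(resno, resid, chemistry_id, P, nu_max, conformer)
#>   resno resid chemistry_id   P nu_max conformer
#> 1     1    DA          DNA 162     38  C2'-endo
#> 2     2    DT          DNA 162     38  C2'-endo
#> 3     3    DG          DNA 162     38  C2'-endo
#> 4     4    DC          DNA 162     38  C2'-endo
#> 5     5    PA         pTNA  20     35  C3'-endo
#> 6     6    PT         pTNA  20     35  C3'-endo
```

The DNA residues sit at the C2'-endo phase they were built with (P = 162°,
B-form) and the pTNA extensions in the north C3'-endo region (P = 20°),
exactly as prescribed — the generator's build parameters are the oracle
the analysis is tested against. The backbone spacing table shows the
phosphorus geometry across the junction, including the shorter
phosphonate-linked step:

```r
report$tables$spacings |> filter(chain == "A", status == "measured")
#>   resno_i resno_j p_p_distance
#> 1       2       3        6.725
#> 2       3       4        6.746
#> 3       4       5        6.804
#> 4       5       6        5.962
```

And the pTNA·dT extension pairs are held in canonical Watson–Crick
geometry, with heavy-atom H-bond distances in the hydrogen-bonding range:

```r
hbond_distances(find_basepairs(annotate_chemistry(dup), "A", "B")) |>
  filter(resno_i >= 5)
#>   chain_i resno_i chain_j resno_j atom_i atom_j dist
#> 1       A       5       B       2     N6     O4 3.05
#> 2       A       5       B       2     N1     N3 2.96
#> 3       A       6       B       1     N6     O4 3.05
#> 4       A       6       B       1     N1     N3 2.96
```

For deposited models the entry point is the same: read the file, add the
deposition's ligand codes to the registry
(`registry_add_residue()` — non-standard nucleotide codes live in the
files, not in this package), and point `run_config()` at the right chains.
`concordance_analysis()` bundles the cross-structure comparison (pucker
phases at the extension positions, the 12–13 P–P step, pairwise Cα RMSDs,
the δ drop and extension-pair H-bonds) given local copies of the relevant
structures.

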