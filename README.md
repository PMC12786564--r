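# cifmotif

Batch structural analysis of triatomic R–X–R motifs in Crystallographic
Information Files (CIF).

## The problem

Weakly coordinating anions such as bis(trifluoromethylsulfonyl)imide
(TFSI, [N(SO₂CF₃)₂]⁻) are used throughout organometallic chemistry,
catalysis and battery electrolytes precisely because they tend to stay in a
cation's *outer* coordination sphere. Whether, and how often, such an anion
actually binds a metal is an empirical question that only a survey of many
crystal structures can answer — and inspecting hundreds of deposited
structures one at a time is not practical. `cifmotif` automates that survey:
given a directory of CIF files (e.g. exported from a structure database), it
finds every triatomic core motif — by default the S–N–S core of TFSI —
measures its geometry, and classifies each occurrence by whether a metal is
bound to the central atom. The same machinery handles any R–X–R motif
(C–N–C, F–C–F, the S–N–S core of FSI, …) by changing two element symbols.

## Method

1. **Parsing.** Each CIF is split at the `_atom_site` loop (located via the
   `_atom_site_fract_z` tag). Cell items are read from the header; loop
   columns are mapped by their header tags (with a positional fallback for
   bare five-column files). Only the atoms explicitly listed in the
   asymmetric unit are used; no space-group symmetry expansion is applied.
2. **Coordinates.** Fractional coordinates **s** are converted to Cartesian
   **c** = CM·**s** (Å) through the upper-triangular cell matrix

   ```
        ⎡ a   b·cosγ   c·cosβ      ⎤
   CM = ⎢ 0   b·sinγ   c·sinβ·cosα* ⎥ ,  cosα* = (cosα − cosβ·cosγ)/(sinβ·sinγ)
        ⎣ 0   0        c·sinβ·sinα* ⎦
   ```

   built once per file; det CM equals the cell volume. Cartesian components
   are rounded to six decimals at creation.
3. **Bond perception.** For central element X and edge element R, every
   (X, R) pair with Euclidean distance d ≤ r(X) + r(R) + τ is bonded, where
   r(·) are tabulated single-bond covalent radii (2008 recommended values)
   and τ is an additive tolerance, default 1.0 Å after a 0–3 Å sensitivity
   sweep. Elements missing from the table get radius 0. The boundary case
   counts as bonded.
4. **Motifs.** Every central atom with ≥ 2 bonded edge atoms yields one
   motif, stored as an acyclic undirected graph carrying the central angle
   θ = arccos(v₁·v₂ / |v₁||v₂|) and the mean of the two bond lengths.
5. **Coordination.** A 3 Å spherical "wave" around the central atom collects
   neighbours; a metal M among them with d ≤ r(X) + r(M) + f (f = τ by
   default) marks the motif *metal N-bound*; otherwise a metal anywhere in
   the structure marks it *metal present but unbound*; otherwise *no metal*.
6. **Batch.** Directories are processed deterministically, per-file errors
   are recorded without aborting, results export as CSV tables, and the τ
   sensitivity sweep re-runs the classification over a tolerance grid.

A seeded synthetic-structure generator (`generateCorpus()`) produces valid
CIF text with exactly known planted geometry and a ground-truth ledger, so
the whole pipeline is testable without any database access.

## Worked example

```r
library(cifmotif)

dir <- file.path(tempdir(), "demo")
generateCorpus(dir, 25, seed = 101)          # 25 synthetic TFSI-like CIFs
summary <- analyzeDirectory(dir)             # parse, detect, classify
summary
#> BatchSummary: 50 motifs, 0 file errors, tau=1.00 A
#>   categories: N_BOUND=3 METAL_PRESENT_UNBOUND=13 NO_METAL=34
#>   angle: mean 125.03 deg; mean bond length: 1.5837 A

classificationCounts(summaryReports(summary))$perMetal
#> Au Hg Pd
#>  1  1  1

head(motifTable(summary)[, c("file", "central", "average", "angle", "category")], 3)
#>                 file central  average    angle              category
#> 1 synthetic_0001.cif      N1 1.577697 127.2098              NO_METAL
#> 2 synthetic_0002.cif      N1 1.577350 130.9523 METAL_PRESENT_UNBOUND
#> 3 synthetic_0002.cif      N2 1.590653 117.9318 METAL_PRESENT_UNBOUND
```

The 50 motifs across 25 files carry the TFSI-typical geometry (central
angle near 125°, mean S–N bond near 1.58 Å); three are N-bound to a metal
(one each to Au, Hg, Pd), thirteen sit in structures that contain an
unbound metal, and the rest are metal-free — the outer-sphere preference
the survey is designed to quantify. `exportTables(summary, "out")` writes
the per-motif and count tables as CSV; `tauSweep(dir, ...)` adds the
tolerance sensitivity table; `motifScatter(summary)` plots angle against
bond length coloured by category.

A command-line wrapper with `analyze`, `sweep` and `fixtures` subcommands
is installed at `system.file("cli", "cifmotif.R", package = "cifmotif")`.

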