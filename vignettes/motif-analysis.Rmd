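---
title: "Detecting and classifying triatomic motifs in crystal structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying triatomic motifs in crystal structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifmotif)
```

## The model

`cifmotif` answers a population-level question about weakly coordinating
anions: across a set of crystal structures, how often does the anion's core
motif bind a metal through its central atom, and what does binding do to the
core geometry? The unit of analysis is the triatomic R–X–R motif — by
default S–N–S, the core of the TFSI anion — detected independently in every
input structure.

The pipeline makes three modelling commitments.

**Geometry from the asymmetric unit only.** A CIF lists the
symmetry-unique atoms; applying space-group operations would be required to
reconstruct the full cell. We deliberately do not: a motif straddling a
symmetry element (e.g. a central atom on a two-fold axis with only one edge
atom listed) is not detected. For the flexible anions this tool targets,
such special positions are rare, but the undercount is a known property of
the method, not an accident. A corollary is that no periodic images are
generated either: all distances are between explicitly listed atoms, with no
minimum-image convention.

**Bond perception by covalent radii.** Two atoms are bonded when their
Euclidean separation satisfies

$$ d \le r_1 + r_2 + \tau $$

with single-bond covalent radii from the 2008 recommended compilation and an
additive tolerance $\tau$. The boundary case *is* a bond — this matters
because the criterion is also swept over a grid, and a half-open rule would
make threshold localization ambiguous. Elements absent from the radius table
receive radius 0, so they can never trigger a bond on their own — a
deliberately conservative total-lookup rule rather than an error.

**Two-stage coordination classification.** For each motif, stage one
collects every atom within `searchRadius` (default 3 Å) of the central atom
and marks the motif *N-bound* if any metal of interest among them satisfies
$d \le r(X) + r(M) + f$. Stage two, reached only on failure, asks whether
the structure contains any metal of interest at all (*metal present but
unbound*), else *no metal*. The categories are exhaustive and exclusive by
construction, and classification does not depend on the file's atom order.

## Coordinates and the conversion matrix

Fractional coordinates are mapped to Cartesian ångströms through the
upper-triangular matrix with $a$ along $x$ and $b$ in the $xy$ plane:

$$
CM = \begin{pmatrix}
a & b\cos\gamma & c\cos\beta\\
0 & b\sin\gamma & c\sin\beta\cos\alpha^{*}\\
0 & 0 & c\sin\beta\sin\alpha^{*}
\end{pmatrix},
\qquad
\cos\alpha^{*} = \frac{\cos\alpha - \cos\beta\cos\gamma}{\sin\beta\sin\gamma}.
$$

The sign convention is pinned down by two requirements: an orthogonal cell
must give a diagonal matrix, and the column Gram matrix must reproduce the
cell metric tensor (so $\det CM$ equals the cell volume and all distances
are convention-independent). The implementation is verified in the tests
against an independent crystallographic toolkit's orthogonalization on a
triclinic cell, and against the closed-form volume on random cells. Cells
whose angles admit no three-dimensional lattice ($|\cos\alpha^{*}| \ge 1$,
or $\sin\beta$, $\sin\gamma$ vanishing) are rejected as degenerate.

Trigonometry uses `cospi`/`sinpi`, which are exact at right angles, so
orthogonal cells scale coordinates per axis *exactly* rather than to within
`1e-16` trigonometric residue.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `centralSymbol`, `edgeSymbol` | `"N"`, `"S"` | — | the R–X–R motif; change to `"C"`/`"F"` for F–C–F etc. |
| `tau` | 1.0 | Å | additive bond tolerance in $d \le r_1+r_2+\tau$ |
| `fudge` | = `tau` | Å | additive tolerance of the coordination criterion |
| `searchRadius` | 3.0 | Å | neighbour-search radius around the central atom |
| `metals` | all conventional metals | — | elements counted as metals of interest |

`tau` defaults to 1.0 Å: a deliberately inclusive setting (for comparison,
classic molecular-graphics defaults are nearer 0.5 Å) chosen so that even
long, weak metal–nitrogen contacts are captured; `tauSweep()` exposes the
full 0–3 Å sensitivity analysis (0.1 Å steps) that justifies it on any
given corpus. `fudge` and `tau` express one sliding stringency and default
to the same value; they are stored separately so the sweep can vary them
jointly while leaving both user-overridable.

One interaction deserves attention: for the largest metals the nominal
coordination reach $r(X)+r(M)+f$ exceeds the 3 Å search radius (e.g.
caesium: $0.71 + 2.44 + 1 > 3$), so the wave truncates the criterion. The
package does not silently truncate — `analyzeDirectory()` and
`classifyMotif()` emit a classed warning (`cifmotif_reach_warning`) naming
the affected metals, and `truncatedMetals()` reports them programmatically.
Widening `searchRadius` removes the truncation at a small cost in search
volume.

## Numerical choices

* **Six-decimal rounding.** Cartesian components are rounded to six
  decimals once, at creation — not after every arithmetic step, which would
  compound error. The rounded position triple doubles as the atom identity
  key (no two atoms of a structure may share one).
* **Clamping before `acos`.** Dot-product cosines can exceed 1 by a few
  ulp for collinear arms; the argument is clamped to $[-1, 1]$ so angles of
  0° and 180° are returned instead of `NaN`.
* **Ties and multiplicity.** A central atom bonded to more than two edge
  atoms contributes one motif built from its two *nearest* edges, with
  distance ties broken by file order — the chemically conservative reading,
  and rare at the default tolerance. Two central atoms may share a bridging
  edge atom; both motifs are reported.
* **Standard uncertainties and label suffixes.** `0.1234(5)` parses as
  `0.1234`; labels like `C1A` keep their suffix in the identifier while the
  element comes from the leading letters and the index from the first digit
  run. Element symbols are canonicalized to first-letter-uppercase before
  every comparison.
* **Degenerate inputs.** Missing positional data, missing cell items, and
  unparseable numerics are errors naming the file (and line where
  relevant); in batch runs they are recorded per file and never abort the
  directory. Zero-length angle arms and degenerate cells are errors.
* **Determinism.** Directory iteration sorts filenames with a
  locale-independent radix sort, and exported CSVs format numerics to a
  fixed six decimals, so repeated runs are byte-identical.

## The synthetic-data generator

`fixtureSpec()`/`buildStructure()` plant exact Cartesian geometry — motif
arms at requested lengths and inter-arm angle, metal contacts at requested
distances, decoy atoms kept at least 5 Å from everything planted — and
inverse-transform through the conversion matrix to the fractional
coordinates a CIF stores. `writeCif()` serializes either the tagged-loop
dialect or the bare five-column dialect, exercising both parser paths.
`generateCorpus()` writes seeded corpora whose composition emulates a
surveyed TFSI population: about 1.7 motifs per structure; roughly 64% of
files metal-free, 28% containing an unbound metal and 8% with an N-bound
metal; bound metals drawn Au-heavy with Ag, Cu and traces of Hg, Pd, Fe,
Pt, Ru; central angles near 125° and mean bond lengths near 1.58 Å (longer,
1.625 Å, for bound motifs). Every planted quantity is recorded in a ledger
computed by the generator's own inline arithmetic, independent of the
detection pipeline.

Because stored Cartesian coordinates are rounded to six decimals by
contract, planted positions are snapped to that representable grid first
and the ledger records the geometry *as realized on the grid*. The
nominal-versus-realized gap is of order $10^{-5}$ degrees; recovery of the
ledger by the pipeline is then exact rather than limited by quantization
noise. Boundary-condition tests bypass the generator and write exact
coordinates directly, since snapping could move a distance across a
threshold by $10^{-6}$ Å.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: thermal/positional disorder, partial occupancies,
symmetry-generated atoms, solvent networks, realistic packing densities, or
chemically complete anions (only the triatomic core plus decoys is
planted). The parser-level robustness tests (tag order, uncertainties,
multiple data blocks, case mangling) cover the file-format side of real
inputs, but curated, disorder-free input remains an assumption of the
method.

## Problem sizes

The shipped tests run the oracle-equivalence comparison against a plain
brute-force implementation on 100 seeded random structures of up to 50
atoms, recover a 200-file seeded corpus exactly, and time a 650-file corpus
(a realistic survey size) through the full pipeline — sizes chosen so the
whole suite completes in well under a minute while still exercising every
code path at survey scale. The acceptance script uses a 659-file corpus,
matching the scale of the survey the defaults emulate.

## Known limitations

* κ¹-[N] coordination only: oxygen-mediated modes (κ¹-[O], κ²-[O,O],
  κ²-[O,O′], κ²-[N,O]) are out of scope, as is any check that the detected
  core belongs to a chemically complete anion.
* No disorder handling (`PART`-style assignments are ignored along with all
  other unrecognized loop columns) and no symmetry expansion, as above.
* Tabular export is CSV; spreadsheet (xlsx) output is declined with an
  informative error rather than adding a heavyweight dependency.
* The covalent-radius table ships as editable configuration; analyses of
  elements with multi-valued published radii inherit this package's choices
  (sp³ carbon; high-spin Mn, Fe, Co — the larger, more inclusive values).
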