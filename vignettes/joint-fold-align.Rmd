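---
title: "Joint folding and alignment of RNA homolog pairs with inserted domains"
author: "costruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint folding and alignment of RNA homolog pairs with inserted domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costruct)
```

## The problem and the model

Homologous non-coding RNAs conserve a core secondary structure, but
individual homologs differ: paired positions mutate compensatorily, helices
grow or shrink, bulges and internal loops appear, and — most disruptively
for comparative structure prediction — whole folding domains can be present
in one homolog and absent in the other.  `costruct` predicts the common
pseudoknot-free secondary structure and the structural alignment of two
unaligned homologs by minimizing a joint free energy

$$
\Delta G^\circ_{\mathrm{total}} \;=\; \Delta G^\circ_1 + \Delta G^\circ_2
+ n_{\mathrm{gap}}\,\Delta G^\circ_{\mathrm{gap}}
+ \sum_i \left( \Delta G^\circ_{\mathrm{open}} + x_i\,
  \Delta G^\circ_{\mathrm{elong}} \right),
$$

where $\Delta G^\circ_{1,2}$ are nearest-neighbor folding free energies of
the two structures, $n_{\mathrm{gap}}$ counts alignment gaps outside
inserted domains, and the last sum is an affine penalty for each inserted
domain of length $x_i$ nucleotides.  The affine model *substitutes for* the
per-gap penalty inside an insertion: nucleotides of an inserted domain pay
opening/elongation, never both.  Because opening + elongation grows more
slowly than per-nucleotide gaps, a self-structured insertion that gains
folding energy is recognized instead of being forced into a distorted
"conserved" explanation.

Three move sets are exposed (`mode=`):

* `original` — the classic simultaneous-fold-and-align move set: every
  predicted base pair is conserved (aligned to a pair in the homolog);
  hairpins, internal loops/bulges/stacks, multibranch loops and exterior
  branches, with gaps charged per unaligned nucleotide.
* `no_insert` — adds two structural variations: a run of 2–5 stacked pairs
  in one homolog aligned to a symmetric internal loop in the other (stem
  extension), and stacks/internal loops/bulges inserted wholesale in one
  homolog below a conserved pair (each inserted-side nucleotide paying one
  gap).
* `dynalign2` — additionally allows inserted domains, placed in multibranch
  loops (adjacent to the closing pair or at either end of a branch
  fragment) or in the exterior loop, priced by the affine penalty with the
  domain's content scored by single-sequence folding.

The optima nest by construction:
$E(\texttt{dynalign2}) \le E(\texttt{no\_insert}) \le E(\texttt{original})$.

## Energy model

The shipped bundle (`inst/extdata/params/default.params`) is a reduced,
self-consistent nearest-neighbor parameter set: sequence-dependent stack
energies for all 36 ordered combinations of the six canonical pairs
(strand-symmetric), length-dependent hairpin/bulge/internal-loop
initiations for sizes up to 30 with logarithmic extrapolation beyond, an
internal-loop asymmetry term (0.5 kcal/mol per unit, capped at 3.0), a
0.5 kcal/mol terminal penalty for A-U/G-U helix ends, and a linear
multibranch model (closure 3.4, per-branch 0.4, per-unpaired 0.0 kcal/mol).
There are no dangling ends, coaxial stacks, or special hairpin bonuses;
this keeps the exhaustive rescoring oracle tractable and the decomposition
of every structure unambiguous.  The bundle is a documented plain-text
file, so richer tables can be substituted without touching code.

The three alignment penalties default to the published values: gap
0.4 kcal/mol, domain opening 0.5 kcal/mol, domain elongation
0.1 kcal/mol per nucleotide.  The multibranch constants and the end
penalty are not printed in the literature the alignment penalties come
from; the shipped values are conventional magnitudes and are exposed in
the bundle.

All energies live on a 0.1 kcal/mol grid and are carried internally as
integers, so dynamic-programming minima and ties are exact integer
comparisons — floating-point tie instability would otherwise make the
traceback nondeterministic.

### Conventions worth knowing

* **Terminal A-U/G-U penalties** are charged inside hairpin energies,
  inside internal-loop and multi-nucleotide-bulge motifs (both closing
  pairs), and once per helix end facing a multibranch or exterior loop.
  Single-nucleotide bulges keep their stack term and carry no penalty.
* **Gap counting** is region-wise: between consecutive aligned anchors the
  shorter side's unpaired nucleotides are aligned and the length
  difference is charged.  A motif inserted in one homolog (`no_insert` and
  up) charges one gap per inserted-side nucleotide; a stem extension
  charges none (the extra stacked pairs align to the partner's loop
  nucleotides).
* **The stem-loop-as-branch simplification**: when an inserted domain makes
  a loop multibranch in its host, the aligned loop in the partner is
  scored as a multibranch loop too, even if it retains a single branch.
  The independent rescorer applies the identical convention; otherwise the
  rescoring identity would break.
* **Inserted domains must fold**: a domain interval contains at least one
  base pair (its energy is computed from the single-sequence branch or
  exterior arrays).  Without this, every unpaired stretch of two or more
  nucleotides would be cheaper to label "insertion" than to pay gaps.

## Algorithm and numerical choices

The core is the standard two-sequence Sankoff-style dynamic program: 4D
arrays $V$ (fragments closed by an aligned pair of pairs) and $W$ (aligned
branch fragments), 2D exterior arrays $W5$/$W3$ filled smaller-fragment
first, with the joint optimum at $W5(N_1,N_2) = W3(1,1)$ — an identity the
package asserts on every run.  Inserted domains enter through four $W$
positions, four $V$ positions and the two exterior ends, each enumerating a
single split point, so the additional cost is quadratic while the fill
itself stays $O(N_1^3 d^3)$ under the band.

Two standard accelerations are used, both exact given their premises:

* **Alignment band**: cut points $(i,k)$ are restricted to
  $|k - i N_2/N_1| \le d/2$, evaluated as the exact integer inequality
  $|2(kN_1 - iN_2)| \le dN_1$ (symmetric, no rounding).  The default width
  is $\max(10, \lceil 0.2 \max(N_1,N_2) \rceil)$ rounded up to even, and a
  width too small to reach the endpoints is widened with a warning.
* **Pair filtering**: candidate pairs must occur in some single-sequence
  structure within `window_percent` of that sequence's MFE (interior +
  exterior decomposition; the exterior closure is a full outside
  computation, so nested occurrences count).  `predict_common()` defaults
  to 0.2; in our test corpus this reproduces the unfiltered optimum while
  cutting run time by an order of magnitude.  Set 1 to disable.

The fill stores no traceback tags: the traceback re-derives each cell's
achieving term through the same evaluation code with a fixed priority
(hairpin, conserved motif, stem extension, motif insertion, multibranch,
domain insertion; smallest indices first), which makes tie-breaking
deterministic and biases ties toward conserved explanations.  If no term
reproduces a cell value the traceback raises a hard error rather than
emitting a silently wrong structure.  The traced structure is then
*rescored from scratch* by `total_energy()`, a declarative implementation
that never consults the DP arrays; prediction refuses to return a
structure whose rescored total differs from the DP optimum.

## Validation strategy

The package carries its own brute-force oracles:

* `enumerate_structures()` lists every pseudoknot-free structure of a
  short sequence and scores it by loop decomposition; the count is checked
  against an independent Motzkin-style recurrence, and the single-sequence
  DP must reproduce the enumerated MFE exactly (integer tenths).
* `enumerate_common()` enumerates pairs of structures, all monotone
  nesting-isomorphic matchings of their pairs, and all disjoint
  inserted-domain interval assignments, scoring each configuration with
  the same declarative rescorer.  It shares no recursion code with the
  fill, so recursion-design errors cannot cancel.  The joint DP must equal
  this optimum exactly on randomized suites (200 pairs, lengths 6–10,
  unconstrained band, no filtering).

The synthetic fixture generator emulates homolog pairs with a conserved
multi-hairpin core, compensatory pair mutations (rate 0.15 per pair by
default), loop point mutations, optional helix shortening, and an
optionally planted GC-rich stem-loop spliced into one homolog's exterior
linker (self-checked to fold below 0 kcal/mol).  What these fixtures do
*not* emulate: non-canonical pairs, pseudoknots, sequence-identity signal
in loops, modified bases, and the long-range multidomain architecture of,
say, RNase P.  Passing the recovery tests therefore demonstrates that the
insertion recursions work as designed, not that field accuracy on real
families is reproduced — the published family benchmarks rest on the full
Turner 2004 model and curated databases, both outside this package's
scope.

Default problem sizes in the shipped tests and acceptance script — 200
oracle pairs at 6–10 nt, 100 single-sequence comparisons at 5–12 nt, and
50 planted-insertion fixtures of roughly 60–100 nt at band width 20 — were
chosen so the whole validation corpus runs in a few minutes on one core
while every code path (all three move sets, all insertion positions,
banded and unconstrained runs) is exercised.

## Known limitations

* Only the optimal common structure is traced; no suboptimal structures or
  pair probabilities.
* Two sequences only; no pseudoknots; no coaxial stacking or dangling
  ends; temperature is fixed.
* The original-algorithm mode does not reproduce the historical "single
  inserted base pair" special case; it is the pure conserved move set.
* Inserted domains are modeled in multibranch and exterior loops (where
  they terminate in hairpin stem-loops), not insertions that themselves
  terminate in conserved domains.

## A short session

```{r example, eval = FALSE}
params <- load_params()
fx <- make_fixture(fixture_spec(seed = 3), params)

cs <- predict_common(fx$seq1, fx$seq2, params, mode = "dynalign2",
                     band_width = 20)
cs
cs$domains          # recovered inserted-domain intervals
cat(write_alignment(cs))

kd <- find_inserted_domains(fx$ref$pairs1, fx$ref$pairs2,
                            fx$ref$aln1, fx$ref$aln2)
inserted_domain_accuracy(cs, fx$ref$pairs1, fx$ref$pairs2, kd)
```
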