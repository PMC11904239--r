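---
title: "Methods: folding shape codes, variation matrices and ensemble assembly"
author: "pfvmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folding shape codes, variation matrices and ensemble assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfvmkit)
```

This vignette records the model behind `pfvmkit`, the calibration of its
tunable parameters, the numerical choices made where the design was
genuinely open, and the limits of what the synthetic test bed can show.

## The model

### The folding shape code

The unit of description is the local fold of five consecutive residues.
Five Cα positions have, up to rigid motion, four internal degrees of
freedom along the chain; we summarize them with three descriptors:

* `tau1` — Cα pseudo-torsion over residues *i..i+3* (IUPAC sign, degrees);
* `tau2` — Cα pseudo-torsion over residues *i+1..i+4*;
* `theta` — bend angle at Cα(i+2) over Cα(i), Cα(i+2), Cα(i+4), in [0, 180].

Each descriptor is cut into three bins, giving a 3×3×3 cube of 27 cells.
Twenty-six cells carry letters; the cell that contains degenerate
(near-collinear) geometry is merged with the reserved symbol `$`, which
also marks windows that cannot be measured at all (missing Cα, chain
break). Every code belongs to one of six classes — helix, alike-helix,
strand, alike-strand, irregular, undefined — determined by which tau bins
the window occupies (both helix-like → helix family, both strand-like →
strand family, mixed helix/strand or neither → irregular) and refined by
the theta bin for the pure cells.

The encoding is a function of internal coordinates only, so it is
invariant under translation and rotation, and changing residue *identity*
never changes it. Moving a single Cα can alter at most the five windows
that contain it — the geometric face of the method's locality argument:
one point mutation perturbs exactly the five matrix columns whose
pentamers cover it, never the rest of the matrix. This is what makes the
representation attractive for mutation studies, where whole-model methods
re-predict everything.

### Bin calibration

The bin boundaries are configuration, not physical constants. The
defaults were calibrated **once** against the ideal generator before any
downstream code existed, with two requirements: canonical helix and
strand must land in the interior of distinct pure cells, and a torsional
jitter of a few degrees must not move them across a bin edge.

Measured on the generator, the canonical α-helix window sits at
(τ₁, τ₂, θ) ≈ (51.5°, 51.5°, 71.7°) and the canonical β-strand at
(≈180°, ≈180°, ≈180°). Two facts shaped the defaults:

* strand pseudo-torsions sit exactly on the ±180° wrap, so binning on the
  conventional (−180, 180] branch would put an ideal strand on a bin
  boundary and make its letter flip under infinitesimal noise. The tau
  axis is therefore binned **circularly** with the cut at −30°, i.e. on
  (−30, 330], with breaks at 120 and 240. Helix (51.5°) and strand
  (≈180°) then sit ≥ 60° from every boundary.
* the helix bend angle (71.7°) demands a theta break well above it;
  breaks at 100 and 145 leave ≥ 28° of margin on each side for both
  canonical geometries.

Under these defaults a 5° standard-deviation jitter on every backbone
torsion leaves the encodings of pure helix and pure strand fixtures
unchanged (verified in the test suite over seeded replicates). The `A`
cell is pure helix, `B` pure strand, `$` the degenerate cell
(helix-like torsions with near-collinear bend — the cell a straight line
falls into under the torsion = 0 convention); the remaining 24 cells take
`C`–`Z` in fixed cell order. The letter assignment is arbitrary but
frozen: alphabets are compared only through the class map, never through
letter identities.

### Pentamer database and the backoff

Mining a corpus produces, for every pentamer actually observed, a ranked
table of (code, count). Ranking is by raw count, ties broken
lexicographically by code; no source weighting is applied because none is
specified — counts are evidence, not energies. Pentamers containing `X`
and windows encoded `$` contribute nothing. Conservation (total pattern
mass = number of contributing windows) and invariance to corpus file
order are tested properties.

For pentamers never observed, the original method computes fold patterns
by molecular-dynamics simulation. That stage is outside this package's
scope; instead, unseen pentamers fall back to the **background marginal**
— the corpus-wide code distribution truncated to the top `k_backoff`
(default 5) patterns — and the resulting columns are flagged
`synthetic`, so reports can always distinguish observed from imputed
variability. This is a statistical stand-in with the right interface, not
an approximation of the MD stage's physics; on a desk-scale corpus most
of a random query's columns will be synthetic, and conclusions about
specific fold preferences should only ever be read from observed columns.

### The variation matrix and conformation strings

The PFVM of a sequence of *N* residues has *N−4* columns, one ranked
variant table per window. Columns are labelled by the window's first
residue (1-based); a center-residue label is also printable in reports,
since the literature never fixes which residue a column is "at".

The conformation space is every choice of one code per column; its size
is the exact product of column depths, kept as a big integer (a ~60-line
base-10⁴ implementation, present because no arbitrary-precision
arithmetic package is available in the target environment; it is tested
against an independent long-multiplication oracle, e.g. the full 57-digit
expansion of 25⁴⁰).

Scores: each column is read as a categorical distribution proportional to
its counts; a string's log score is the sum of per-column log
probabilities. `PFVM-01` (rank-1 codes) is the exact maximizer. Two
generators are provided:

* `single_sub`: `PFVM-01` plus all strings differing in exactly one
  column, using ranks 2..`max_rank` (default 3) — the literal reading of
  "replace a letter in the same column";
* `beam` (default): exact top-*k*. Because the score is additive over
  independent columns, keeping the *k* best prefixes at every column is
  provably sufficient, so the "beam" is not a heuristic here; equality
  with brute-force enumeration is a tested property. The published
  method's "optimized coupling with vector features" is not
  reconstructable from the available description; the probability model
  above is this package's formalization of "ranked from higher
  possibility to lower", and the requested ensemble size *k* is an
  ordinary parameter (10, 18, 22, ... are all just values).

Ties everywhere are broken deterministically (column index, then rank),
and `PFVM-01` always leads the member list even when other strings tie
its score.

### PFSA scoring

Position weights: identical codes 1.0; different codes of the same class
0.8; helix↔alike-helix or strand↔alike-strand 0.5; everything else 0.
`$` scores 0 against everything — including itself, resolving a conflict
between the identical-code rule and the undefined-class rule in favor of
the latter: an undefined window carries no conformational evidence, and
two unmeasurable windows are not evidence of agreement. Consequently
self-alignment scores exactly 1.00 precisely for fully defined strings;
strings containing `$` self-score below 1 by design.

Equal-length strings are compared positionwise and the score is the mean
weight. Unequal lengths go through global alignment with affine gaps
(open −0.5, extend −0.1 per position, gaps contributing weight 0) and the
summed weight is normalized by the **longer** length, so a fragment
covering 70 % of a chain can never score above 0.70 on length grounds
alone — this keeps the acceptance threshold meaningful for partial
matches. The 1.0/0.8/0.5/0 ladder itself is calibration, exposed as
`similarity_model()` parameters; only the endpoints (identity 1.00,
acceptance > 0.70) are anchored by the method.

### Fragment search and assembly

Queries are split into fragments of `target_len` 45 residues (within the
method's 40–50 band) stepping by `target_len − overlap` with `overlap` 4
— one encoder window, the minimum that gives the splicing step a
superposable junction; the final span is right-aligned so coverage is
complete. Search scores the query substring against source windows of the
same length. The default is an exhaustive window scan (at desk scale this
is cheap and exactly reproducible by a brute-force oracle); a k-gram
seeded mode (default k = 8) exists for large libraries but can miss hits
whose similarity is purely class-level and never literal — it is tested
as a subset of the exhaustive ranking, not as its equal. Hits must score
strictly above 0.70; when a span finds nothing the threshold relaxes
0.70 → 0.60 → 0.50 and below that the member fails with a recorded
reason — failure handling is unspecified in the source method, and
fabricating geometry for unsupported spans would be worse than an honest
gap.

Assembly chains fragments left to right, rigidly superposing each
incoming fragment onto the growing model over the shared overlap residues
(least squares on ≥ 3 Cα, via `bio3d::fit.xyz`) and appending its new
residues. The least-squares residual of every junction is reported as
`junction_rmsd`, not enforced: adjacent fragments from different source
structures can disagree about the overlap geometry, and the residual is
the honest measure of that disagreement. No loop closure, clash
resolution or refinement is attempted; models are Cα traces.

## What the synthetic test bed shows — and does not

`make_ideal_backbone()` realizes helix (φ = −57°, ψ = −47°), strand
(φ = −139°, ψ = +135°) and coil (seeded uniform draws from broad allowed
torsion regions) through ideal backbone internal coordinates, giving
Cα–Cα virtual bonds of ≈ 3.8 Å; `make_fixture_library()` writes seeded
corpora of 30–120-residue mixed chains. Corpus sequences are drawn from a
reduced 6-letter alphabet (A, E, G, K, L, V): with 20 letters a
desk-scale corpus almost never repeats a pentamer, every matrix column
would have depth 1, and the variation machinery would be vacuously
exercised. The reduced alphabet is a property of the test bed, not of the
method.

The fixtures emulate local geometry faithfully (canonical torsions,
noise bands, chain breaks, missing atoms) but not the statistics of real
proteins: no Ramachandran weighting beyond uniform regions, no
sequence–structure correlation beyond what the corpus itself induces, no
side chains, no experimental noise model. Passing tests therefore
demonstrate the **algorithmic contracts** — encoding laws, conservation,
containment, exact counting, exact top-*k*, score endpoints, round-trip
self-retrieval at RMSD < 0.1 Å, byte-identical reruns — not predictive
accuracy on real proteins, which requires a full-scale structure corpus
that is deliberately out of scope here.

Problem sizes used by the test suite and acceptance script: corpora of
10 chains (≈ 400–500 windows), sequences of 30–120 residues,
enumeration oracles up to 10⁴ strings, 100–200 random fixtures per
property. These sizes were chosen so that every brute-force oracle is
exact and the whole suite stays interactive.

## Known limitations

* The quantizer is a calibrated structural analogue of the published
  27-shape alphabet, not a bit-exact reproduction of it; letter-level
  comparisons with externally produced strings are meaningless, class
  level comparisons are the supported interface.
* Unseen pentamers carry background, not physics; synthetic columns are
  flagged and should be excluded from biological conclusions.
* Ensemble members are Cα traces with unrefined junctions; they are
  conformation-homology collages, not energy-minimized models.
* `$` windows are invisible to scoring; chains dominated by breaks or
  missing atoms yield strings whose PFSA scores are systematically
  depressed, which is intended but worth remembering when comparing
  scores across inputs of very different completeness.
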