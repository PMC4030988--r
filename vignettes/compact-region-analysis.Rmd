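---
title: "Predicting compact regions from average distance maps"
author: "admscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting compact regions from average distance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admscan)
library(tibble)
```

## The problem

Some segments of a protein chain fold into dense, self-contained
substructures — candidate folding units such as the G–H helix pair of the
globin fold.  `admscan` predicts such *compact regions* from the amino-acid
sequence alone, and provides the companion analyses used to characterise
them in helix bundles: hydrophobic packing detection by buried surface
area, conserved-residue calling with a Poisson substitution test, and
helix-local hydrophobic spacing patterns.

## The average distance map (ADM)

The sequence-only oracle is a table of **inter-residue average distances**:
for every unordered pair of residue types and every *range* of sequence
separation $k = |i - j|$ (bins $M = 1$: $1 \le k \le 8$, $M = 2$:
$9 \le k \le 20$, $M = 3$: $21 \le k \le 30$, and width-10 bins upward),
the mean Cα–Cα distance observed in reference structures
(`build_stats_table()`).

A **real distance map** (RDM, `build_rdm()`) plots residue pairs closer
than 15 Å.  An **ADM** (`build_adm()`) plots pair $(i, j)$ when the table's
mean distance for its types at range $M(k)$ falls strictly below a
range-specific cutoff $c_M$.  Cutoffs are calibrated
(`calibrate_cutoffs()`) so that the ADM's overall density matches the
density expected of the protein's RDM:

* the density law $\hat\rho_{av} = \min(1, C/N)$ with $C = 36.12$
  (matching the 15 Å RDM cutoff) predicts the target density for a chain
  of $N$ residues.  The law is a plug-in hook (`law` argument), so an
  alternative functional form can be substituted without touching the
  rest of the pipeline;
* per range, $c_M$ is set so that the fraction of statistically
  significant type pairs (those with at least `min_obs = 10`
  observations) whose mean lies below $c_M$ equals one global parameter
  $D$, i.e. $P(M)_C = D \, P(M)_t$;
* $D$ is found by bisection on the achieved whole-map density.  With a
  finite table the density is a step function of $D$, so the fit stops at
  the closest achievable value; if even $D = 1$ cannot reach the target
  (for instance when some residue types have no significant table
  entries), the calibration returns with a `saturated` flag instead of
  failing.

Both map constructors use strict `<` at every cutoff, never plot the
diagonal, and are fully deterministic.

## Scanning and region calls

At each residue $i$ the map is split in two, in both directions: the
*horizontal* scan's triangle holds all pairs within residues $1..i$, the
*vertical* scan's triangle all pairs within $i..N$; the remainder is the
trapezoid.  The scanning statistic is
$\Delta\rho_i = \rho_\text{triangle} - \rho_\text{trapezoid}$
(`scan_profiles()`).  A vertical peak marks a candidate region start, a
horizontal peak a candidate end; each start is paired with the nearest
admissible end, candidates are accepted greedily by decreasing score, and
the compactness score of a region is
$\eta = (\Delta\rho^v_s + \Delta\rho^h_e)/2$, the mean density contrast at
its two boundaries.

Three numerical choices matter here, all validated by planted-block
recovery on synthetic maps rather than fixed by fiat:

* **edge guard** (default 10 residues): near the profile ends the triangle
  holds so few pairs that its density estimate is noise-dominated and
  spurious high-prominence peaks appear; positions whose triangle spans
  fewer residues than the guard are ineligible as peaks;
* **peak prominence** (default 0.005 density units): the raw
  $\Delta\rho$ statistic is a whole-triangle average and is therefore
  nearly flat on the short-tail side of a block close to a terminus; a
  larger threshold (we first tried 0.02) silently discards true boundary
  peaks in exactly that regime;
* **boundary refinement** (window ±5 residues): for the same reason the
  peak *position* on the flat side is imprecise, so each paired boundary
  is refined by maximising a local band contrast — the density of the
  rows (or columns) kept inside the candidate region minus the density of
  those dropped.  Refinement is local, deterministic, and can be disabled
  (`refine_window = 0`).

Under the package's planted-map conditions (N = 100, one block at
residues 10–40, inside fill 0.8 over background 0.05) the acceptance
suite requires at least 95 % of 100 seeded maps to recover both
boundaries within ±3 residues; the measured rate is 97–99 % depending on
the seed, and $\eta$ ordering follows the planted fill ordering.

## Buried-surface hydrophobic packing

SASA is computed by grid counting (`compute_sasa()`): a deterministic
golden-spiral lattice of `n_points = 960` directions per atom, a sphere
of radius vdW + 1.4 Å (water-sized probe), and the accessible fraction of
lattice points times the sphere area.  Van der Waals radii are a fixed
element table (C 1.70, N 1.55, O 1.52, S 1.80 Å).  On one- and two-sphere
systems the numerical area is within 5 % of the closed forms (isolated
sphere $4\pi(r+1.4)^2$; spherical cap $2\pi R h$), and the error falls as
the point count grows.

The pairwise buried surface (`pair_delta_sasa()`) of residues $a, b$ is
the side-chain SASA of $a$ with all of $b$'s atoms deleted minus its
side-chain SASA in the full structure — a per-pair occluder-deletion
reading, the only one under which a mutual "both exceed 10 Å²" criterion
is well defined per pair.  `find_packing_pairs()` applies it to
hydrophobic residues (A, F, I, L, M, V, W) in different annotated helices,
with the F helix excluded throughout and strict `>` at the 10 Å²
threshold; the ≈5 Å closest-atom check is recorded as a diagnostic, not
applied as a second filter.

## Conservation calling

From a user-supplied protein alignment, `nj_tree()` builds a
neighbor-joining tree on Poisson-corrected p-distances
($d = -\ln(1-p)$ over shared ungapped sites; negative branches are
clamped to zero with the length moved to the sibling so total length is
preserved).  `count_substitutions()` then counts per-column substitutions
by Fitch parsimony on that topology, treating gaps as missing data.
Parsimony replaces likelihood-based ancestral reconstruction here: it
yields the same *statistic* (a per-column substitution count) with no
external dependency, and it agrees exactly with an independent
implementation (phangorn) in the test suite.  Because parsimony cannot
see multiple hits, its counts sit slightly below the branch-length scale
on deep trees; `call_conserved()` therefore accepts either the tree
length (the default estimator) or the empirical mean count as the Poisson
mean $\lambda$.

A column is called conserved when its count lies in the lower 5 % tail:
count $\le q^*$, where $q^*$ is the largest $q$ with
$F_\text{Pois}(q; \lambda) \le \alpha$.  For $\lambda = 10$,
$\alpha = 0.05$ this gives $q^* = 4$
($F(4) \approx 0.029 \le 0.05 < F(5) \approx 0.067$); when
$e^{-\lambda} > \alpha$ no column can be called.  On uniform-rate
simulations (24 taxa, tree length 6, 300 columns) the realised call rate
stays below $\alpha$ plus two binomial standard errors, and planted
invariant columns are always recovered once $\lambda \ge 5$.
`conserved_hydrophobic()` maps conserved columns whose reference residue
is hydrophobic through the reference gap pattern to sequence positions.

## Spacing patterns

`extract_pattern()` encodes a set of (conserved hydrophobic) positions
inside a helix as alternating φ-runs and x-runs — `φx(3)φx(3)φ` for
positions $\{p, p+4, p+8\}$ — and `match_pattern()` compares candidate
positions against a pattern, including the variant notation `x(2,3)`
that admits either run length.  Extraction and parsing are mutually
inverse; patterns depend only on the gap signature, not the absolute
positions.  Patterns by construction begin and end with a φ-run; the
parser enforces this and rejects truncated strings ending in an x-run.

## Synthetic data: what it does and does not show

The seeded generators produce inputs with exactly the statistical
structure each stage assumes:

* `make_stats_table()` plants short mean distances for attractor-type
  pairs in ranges $M \ge 2$ and long distances elsewhere (including all
  of $M = 1$), with deterministic within-group spread so calibration
  quantiles are well defined.  Block fills of ADMs built from it are
  therefore defined over pairs at separations $\ge 9$;
* `make_blocky_sequence()` plants attractor-rich segments whose ADM block
  density approximates the planted fill (within ±0.05);
  `make_planted_map()` plants Bernoulli blocks directly on a map;
* `make_helix_bundle()` builds ideal α-helix Cα traces (rise 1.5 Å, 100°
  per residue, axis radius 2.3 Å) with single-sphere pseudo side chains of
  radius 1.9 Å — deliberately non-physical, sufficient to exercise the
  SASA machinery — placing planted contact spheres ≤ 4 Å apart and
  non-contact inter-helix side chains ≥ 8 Å apart;
* `make_alignment()` evolves a root sequence down a known tree with
  per-column Poisson event counts; planted conserved columns have rate 0.

Passing these tests shows the machinery is correct under its own model:
uniform backgrounds, independent contacts, single-sphere side chains,
rate-homogeneous evolution.  It does not show that real proteins satisfy
those assumptions — real ADMs have composition-dependent textures, real
side chains are articulated, real alignments have rate heterogeneity and
alignment error.  Reproducing the published per-protein region tables
would additionally require the original reference-structure distance
statistics, which are not distributed with the source material; with a
rebuilt table the numbers are approximate by construction.

## Problem sizes and defaults

The test and acceptance workloads use N = 100–120 maps, 100-instance
oracle sweeps, 24-taxon, 300-column alignments and 3 × 18-residue
bundles — sizes at which every stage's behaviour is already
statistically resolved.  Key defaults: RDM cutoff 15 Å; C = 36.12;
calibration tolerance 0.005; `min_obs` 10; minimum region length 10;
prominence 0.005; edge guard 10; refinement window 5; probe 1.4 Å;
`n_points` 960; ΔSASA threshold 10 Å²; α = 0.05.

## Worked example

```{r example, eval = FALSE}
tab <- make_stats_table()
sq  <- make_blocky_sequence(120, tibble(start = 20, end = 70, fill = 0.8),
                            seed = 41)
cal <- calibrate_cutoffs(sq, tab)
adm <- build_adm(sq, tab, cal)
reg <- predict_regions(scan_profiles(adm), adm)
reg
autoplot(adm, regions = reg)
```

The same stages run end to end, with TSV reports, via `run_pipeline()`
on a YAML (or list) configuration; stages whose inputs are absent are
skipped and noted in the summary.

## Known limitations

* The density law and the $P(M)_C = D\,P(M)_t$ calibration relation are
  the simplest forms consistent with their stated roles; both are
  configuration hooks.
* Region pairing is greedy and non-overlapping: nested or interacting
  domain blocks (off-diagonal interaction squares) are reported only
  through the scan profiles, not called as regions.
* Boundary precision on sequence-derived ADMs is lower than on directly
  planted maps because the synthetic table never plots the near-diagonal
  range; tests there assert overlap, not ±3 residues.
* The SASA grid method has no analytic gradient and is not intended for
  per-atom decompositions beyond side-chain sums.
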