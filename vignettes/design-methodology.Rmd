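---
title: "Designing RNA sequences from a shape and physical attributes"
author: "RNAShapeDesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing RNA sequences from a shape and physical attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RNAShapeDesign)
```

## The problem

Classical inverse RNA folding asks for a sequence whose predicted
minimum-free-energy (mfe) structure equals a given secondary structure.
RNAShapeDesign solves an extended version of the problem: the designed
sequence must *strictly* reproduce the coarse-grained **shape** of the
target structure — the tree of helices, hairpins, bulges, interior loops
and multiloops — while its thermodynamic stability (mfe, `dG`, kcal/mol)
and mutational robustness (**neutrality**, a number in [0, 1]) are pulled
toward user-supplied desired values.  Relaxing the structural constraint
from the exact base-pair set to the shape is what makes the physical
attributes attainable at all: a motif may gain or lose a nucleotide at the
expense of another, as long as the global architecture is preserved.  This
is the natural formulation when a functional stem-loop must be kept
exactly but distant motifs are negotiable.

## The objective

A candidate sequence $s$ with predicted structure $S(s)$ and energy
$dG(s)$ is scored by the combined objective

$$F(s) \;=\; w_\eta\,\lvert \eta_d - \eta(s)\rvert
  \;+\; w_{dG}\,\lvert dG_d - dG(s)\rvert
  \;+\; w_{sh}\, d_{tree}\!\big(\sigma(S(s)),\, \sigma(S_d)\big)
  \;+\; w_{bp}\, d_{bp}\!\big(S(s),\, S_d\big),$$

where $\sigma(\cdot)$ is the weighted Shapiro shape, $d_{tree}$ the
ordered tree edit distance (Zhang–Shasha) under the weighted-Shapiro cost
model (insertion/deletion costs the node weight; relabelling costs the
weight difference for equal motif types and the weight sum otherwise),
$d_{bp}$ the base-pair set symmetric difference, $\eta$ the neutrality and
$(\eta_d, dG_d, S_d)$ the design goals.  The neutrality of a sequence of
length $L$ is the exhaustive average over all $3L$ single-point mutants
$m$ of $1 - d_{bp}(S(s), S(m))/L$; normalising by $L$ (not by the pair
count) keeps it in $[0,1]$ for every structure including the open chain.

**Weights.** The defaults are $w_\eta = 500$, $w_{dG} = 2$, $w_{sh} = 50$,
$w_{bp} = 1$.  They encode a deliberate dominance ordering: one tree-edit
unit (50) outweighs any realistic energy or robustness contribution, so
shape violations are effectively lexicographically worse; a neutrality gap
of 0.01 weighs like a 2.5 kcal/mol energy gap; and the base-pair term is a
weak tie-breaker that keeps the search from drifting arbitrarily far from
the literal target among equal-shape structures.  All four are
user-settable (`objectiveWeights()`).

## The search

Each design run chains three stages.

1. **Initialisation (inverse-folding walk).**  A random sequence
   compatible with the target is drawn — paired positions get one of the
   six canonical pair types uniformly (so wobble pairs are admitted from
   the start), unpaired positions a uniform base — and refined by an
   adaptive walk that greedily minimises the base-pair distance of the
   folded sequence to the target.  The walk's neighbourhood contains all
   single-point mutants plus coordinated pair-type swaps (both residues of
   a target pair replaced together), the classical inverse-folding move
   that avoids transiting incompatible intermediates.  Because a single
   greedy walk can end in a local minimum, the walk restarts from fresh
   random sequences until it realises the target exactly (up to
   `maxInitTries`, default 100; individual walks are cheap).  Random,
   rather than deterministic, initialisation matters: consecutive runs
   must sample different basins of the objective landscape.

2. **Simulated annealing with look-ahead.**  For steps $k = 1..n$ the
   temperature follows a geometric schedule $T_k = T_0\,\alpha^k$.  Each
   step samples `samplesPerStep` (default $L$) candidates at Hamming
   distance $1..t$ from the current sequence ($t$ = look-ahead, default
   4, sampled not exhaustive), scores them with the structural terms
   only, promotes one candidate by heat-bath selection (probability
   $\propto e^{-\mathrm{screen}/T_k}$), evaluates its neutrality — the
   dominant cost, $3L$ folds — to complete $F$, and accepts it if $F$
   improves, else with probability $e^{-\Delta F/T_k}$.  $T_0$ is
   calibrated in a warm-up phase (median $|\Delta \mathrm{screen}|$ of 50
   proposals, scaled so a median uphill move is initially accepted with
   probability one half) and $\alpha$ is set so the final temperature is
   $10^{-3}\,T_0$.  The best-so-far sequence is tracked and returned, so
   the reported objective is non-increasing in $k$.  Setting `T0 = 0`
   with look-ahead 1 and exhaustive per-step sampling makes the whole
   procedure collapse, move for move, onto a greedy adaptive walk on the
   full objective — a property the test suite asserts.

3. **Deep greedy polish.**  When the cooled chain stops accepting moves it
   typically still sits a few energy units from $dG_d$: single mutations
   that correct the stability transiently damage the neutrality and are
   rejected.  The final stage is therefore a shape-preserving descent on
   the full objective over the same single-point + pair-swap
   neighbourhood, augmented with a two-move stall breaker: when no single
   move improves, the closest structural intermediates (including
   screen-uphill ones) are expanded one more move, and the best improving
   two-move combination is taken.  Neutrality is evaluated only for moves
   whose structural score could possibly beat the current objective
   (since $F \ge \mathrm{screen}$, moves with
   $\mathrm{screen} \ge F_{cur}$ can never win — an exact filter), capped
   at the 40 best-screened moves per sweep; the descent stops once the
   objective falls below half a base-pair unit (0.25 kcal/mol or a 0.001
   neutrality gap), which is beneath any meaningful attribute
   difference.  The polish runs from both
   the annealing optimum and the stage-1 sequence — the annealing chain
   occasionally migrates into a structure-shifted basin of equal shape
   that it cannot leave — and the run reports the better endpoint, with
   exact-shape candidates taking strict precedence (shape conformity is
   the method's hard contract).

Because the composition landscape at fixed structure is rugged — the
stability and robustness targets couple through the same base pairs — a
single pass occasionally converges into a basin whose best objective
remains a few units above zero.  Each run therefore repeats the
three-stage pipeline from fresh random starts, up to three rounds,
keeping the best result (exact-shape results taking strict precedence)
and stopping as soon as the objective converges below the polish floor;
converged runs pay for a single round.

`designSequences()` repeats this `nRuns` times with independent seeds
derived from the master seed and returns the results sorted by the
tree-edit distance between each design's predicted shape and the target
shape (ties: objective, then seed), mirroring the ranked list a user
inspects.

## Folding backends

All predictions go through a pluggable backend.

* **`toy`** — a hermetic dynamic programme over stacking bonuses: pair
  strengths GC/CG = 3, AU/UA = 2, GU/UG = 1, and each stacked adjacency
  contributes minus the sum of the two pair strengths (pseudo-kcal/mol).
  Minimum hairpin loop 3; no isolated pairs (every helix holds at least
  two stacked pairs); the open chain scores 0.  It is exactly optimal
  under its own model (the tests compare it against exhaustive
  enumeration up to 14 nt), deterministic, and fast enough that a
  neutrality evaluation — hundreds of folds — takes milliseconds.
* **`vienna`** — RNAfold from the ViennaRNA package via subprocess, the
  production engine with the full nearest-neighbour thermodynamic model.
  Temperature and dangles are left at RNAfold defaults; `backendInfo()`
  returns a descriptor (program version and parameter note) embedded in
  every report, because absolute energies — and therefore any reproduction
  of published attribute values — depend on the backend version.

The toy model reproduces the *logic* of the design problem (competing
structures, stability/robustness coupling, shape preservation) but not
real thermodynamics: loop entropies, dangling ends and coaxial stacking
are absent, and its energies move in integer steps of about 2
pseudo-kcal/mol, which is coarse next to RNAfold's 0.1 kcal/mol.  Tests
passing under the toy backend therefore validate the search machinery and
the distance/robustness mathematics, not the biophysical accuracy of any
designed sequence; design work on real RNAs should use the vienna
backend.

## The Shapiro shape dialect

`toShapiro()` follows the coarse-grain grammar of ViennaRNA's
`b2shapiro`: maximal stacked runs become `S` nodes weighted by their pair
count; the loop closed by each helix becomes `H` (hairpin), `B` (bulge —
unpaired bases on exactly one strand), `I` (interior — both strands) or
`M` (multiloop, which may carry weight 0); external unpaired bases are
pooled into a single exterior node `E` that carries the exterior helices
as children.  Children are ordered 5'→3'.  Our canonical rendering drops
ViennaRNA's outermost parenthesis wrap (`"((H3)S3)R"`, not
`"(((H3)S3)R)"`); the test suite pins the dialect to strings generated
with ViennaRNA 2.7.2 on a panel of structures.  Whether the objective
compares weighted or unweighted shapes is configurable; the default is
weighted, which is the stricter reading of "the shape remained exactly
the same".

## The fixture generator and the sensitivity benchmark

`genStructure()` builds seeded-deterministic targets of three topology
classes — single hairpin, two helices separated by a bulge or interior
loop, and an outer helix enclosing a two-branch multiloop — with all
parser constraints respected and no lonely pairs, distributing the slack
length randomly over helices, loops and external bases.  Minimum lengths
are 8, 12 and 18 respectively.

`generateBenchmarkPanel()` turns the generator into a benchmark: a
candidate target is admitted only if an adaptive walk (same operator as
the design's first stage) realises it exactly from a random start within
three attempts, which certifies achievability under the selected backend;
the first such walk product becomes the *reference sequence*, and its
measured energy and neutrality become the desired values.  Using the same
walk operator for the reference and for the design initialisation is
deliberate: it makes the desired values typical of the composition family
the search actually visits, which is the regime the sensitivity claim
speaks to — desired values realised by actual sequences, not adversarial
corners of the attribute space.

The shipped sensitivity benchmark (`scripts/acceptance.R`, mirrored by
the acceptance tests) uses 10 panel targets of 30–60 nt, five design runs
each with default parameters under the toy backend, and reports the
worst-case relative deviation of achieved neutrality and energy from
their desired values.  These problem sizes keep the full sweep within
minutes on one core while still covering all three topology classes at
realistic small-RNA lengths.

## Numerical and design choices

* **Coordinates** are 0-based internally, 1-based in all messages.
* **Pseudoknots are rejected** at parse time (single bracket alphabet);
  hairpin loops under 3 nt are parse errors, matching the folding
  backends so targets are never unattainable by construction.  `T` input
  is converted to `U` with a warning.
* **Tie-breaks** are deterministic everywhere: the adaptive walk scans
  mutants in position order with residues `A<C<G<U` and takes the first
  best; the toy fold's traceback prefers unpaired ends, then the lowest
  helix start, then helix termination over extension; candidate batches
  resolve score ties by enumeration order.
* **Tree-edit costs**: the weighted-Shapiro model above is our declared
  default (`defaultCosts()`), override-able per call.  It is *not*
  numerically identical to `RNAdistance -Dw`, whose internal cost table
  differs (it appears to charge stack nodes twice); the implementation is
  instead verified against an independent naive forest-distance oracle.
* **`-e` (tie the ends)** biases proposals so the residues at the
  target's outermost pair (5'-most with 3'-most paired position) are
  resampled to a complementary pair; it is a no-op when the target has no
  such exterior pair.
* **Determinism**: a master seed fixes the whole multi-run output
  byte-for-byte; per-run seeds are drawn from the master stream and
  recorded in every result row.
* **Degenerate inputs**: an all-unpaired target makes every compatible
  sequence structurally perfect, so the search reduces to attribute
  tuning; sequences shorter than 7 nt always fold open in the toy model.

## Known limitations

* The toy backend's integer energy lattice limits how closely a design
  can approach an arbitrary desired energy (about one lattice unit, i.e.
  roughly 2 pseudo-kcal/mol); on short targets this granularity, not the
  search, can dominate the relative deviation.
* Neutrality evaluation is exhaustive by design ($3L$ folds per
  evaluation); with the vienna backend this is the runtime bottleneck and
  makes 100 nt designs a minutes-scale computation per run.
* The shape relaxation means the designed structure may differ from the
  literal target (shifted helices of identical weighted shape); the
  base-pair term damps but does not forbid this.
* Only pseudoknot-free, single-strand structures are supported.
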