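---
title: "Assessing predicted leucine-zipper dimers with ZipperQC"
author: "ZipperQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted leucine-zipper dimers with ZipperQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ZipperQC)
```

## The problem

Leucine zippers (L-zips) are parallel two-helix coiled coils in which a
seven-residue (heptad) repeat, labelled *a*-*g*, packs leucines at the *d*
position and hydrophobic residues at *a* into a knobs-into-holes core, while
the flanking *e* and *g* positions carry the charged residues that decide
*which* partners may pair.  Deep-learning structure predictors recognise the
heptad pattern extremely well — so well that they fold almost any pair of
heptad-patterned helices into a confident-looking dimer, including pairs
whose *g*-*e'* electrostatics forbid association in vitro.  Confidence
metrics (pLDDT, PAE, ipTM) report how reproducible the fold is, not whether
the complex is physical.

ZipperQC provides the downstream screens a structural biologist would apply
by hand: a geometric classifier of predicted dimers, the standard interface
confidence metrics plus the PAE-gated ipSAE score, a discrete charge
complementarity screen over the registered *g*-*e'* pairs, superposition
with outlier rejection, and ROC/AUC benchmarking against experimental
dimerization ranks.  A Crick-parameterized generator produces ideal
coiled-coil fixtures with known ground truth, so every stage of the
pipeline is testable without running any predictor.

## The classifier

`classifyLzip()` applies, in order:

1. **Helix detection** — residues where CA(i)-CA(i+3) falls in 4.5-6.0 Å and
   CA(i)-CA(i+4) in 5.5-7.0 Å (the canonical alpha-helical spacings) are
   merged into maximal runs; runs under 7 residues (one heptad) are
   discarded.
2. **Pair selection** — among all interchain helix pairs, the pair with the
   most CB-CB contacts (< 8 Å; CA stands in for glycine) is classified.
   Additional helices are ignored for the verdict.
3. **Orientation** — the angle between the fitted helix axes; below 90° is
   parallel, 90° or above is antiparallel.  The tie at exactly 90° goes to
   antiparallel deliberately: a broken verdict is the conservative call for
   a screen whose purpose is flagging implausible models.
4. **Register assignment** — described below.
5. **Failure checks** — the verdict is *broken* with reason codes when the
   model shows antiparallel packing, fewer than `contactsMin = 4` contacts
   (`minimal_contact`), a registered interface under one heptad
   (`too_short`), no contacting helix pair at all, or when more than half of
   the *d*-position Leu/Ile side chains point away from the partner axis
   (`wrong_leu_orientation`).

The source study never quantifies "very minimal interchain interaction" or
"incorrectly oriented" leucines; `contactsMin` and the contact cutoff are
therefore declared, configurable operationalizations, not published values.
Isoleucine at *d* counts as a core residue throughout, so Leu-to-Ile mutant
designs remain classifiable.

**Interface heptads.** The interface length is counted in heptads: the
longest contiguous run of heptads containing at least one contacting,
registered *a*/*d* residue, minimised over the two chains.  A five-heptad
ideal dimer scores exactly 5; a single shared heptad satisfies the
"at least one heptad" rule.  We count heptads rather than dividing the
contact span by seven because a span that starts at an *a* and ends at a
*d* covers five heptads in 32 residues — integer division would undercount.

## Heptad register assignment

For each helix, the local axis is the running mean of three consecutive CA
positions (for an ideal helix this cancels the 100° winding to within
~0.5 Å of the true axis); the axis direction is the first-to-last axis
vector.  A residue is a *core candidate* when its side-chain direction
(CA→CB) has a positive cosine against the inter-axis vector and its CB lies
within the contact shell of the partner.  Because the *e* and *g* positions
flank the core, their side chains also project weakly inward (cosine
≈ 0.26 versus ≈ 0.9 for *a*/*d*), so the seven candidate register phases
are scored by the *sum of cosines* of the candidates they place on *a*/*d*
— the buried positions dominate the vote, and the 3-4 spacing of *a* and
*d* falls out of the same vote.  Ties prefer the phase that puts Leu/Ile on
*d*.  On generated fixtures the assignment recovers 100% of core positions
across all seven register offsets; the test suite asserts at least 95% over
50 randomized builds.

## Confidence metrics

For a two-chain bundle the package computes:

* **mean pLDDT** over any residue region (0-100);
* **mean interchain PAE**, averaging *both* off-diagonal chain blocks so
  matrix orientation conventions cannot flip the result;
* **ipTM**, extracted from predictor output, never recomputed;
* **ipSAE**: for every residue *i* with qualifying interchain partners
  (`pae[i, j] <` 3 Å and side-chain distance `<` 5 Å by default),

    d0_i = max(1, 1.24 * (max(n_i, 19) - 15)^(1/3) - 1.8)
    s_i  = mean_j 1 / (1 + (pae[i, j] / d0_i)^2)

  and the score is the maximum of s_i over both chains (the by-residue d0
  variant, with the maximising residue reported for auditability).  When no
  pair qualifies the score is 0: no supported interface is the worst
  answer, not a missing one.

Two numerical choices deserve a note.  First, the **distance gate uses CB**
(CA for glycine), not CA: the backbone CA atoms of even an ideal dimeric
coiled coil sit ≈ 5.3 Å apart at closest approach, so a 5 Å CA gate would
pass zero pairs on a perfect interface, while the CB atoms — which carry
the knobs-into-holes contacts — come within 2-4 Å.  Setting
`distCutoff = Inf` removes the structural gate entirely, making the score a
function of the PAE matrix alone.  Second, ipSAE is **not monotone in the
PAE cutoff**: widening the cutoff can admit a poor-but-qualifying pair that
drags down a residue's mean.  The score is, however, monotonically
non-increasing when any qualifying PAE entry grows (while staying under the
cutoff), and always lies in [0, 1]; those are the invariants the tests
assert.

## The g-e' charge screen

In the canonical bZIP pairing the *g* residue of heptad *k* on one helix
contacts the *e* residue of heptad *k + 1* on the partner, in both
directions.  `enumerateGePairs()` generates exactly these pairs from the
register assignments (heptads are *a*..*g* blocks, indexed at each *a*),
truncating at the termini.  `chargeComplementarity()` then scores each pair
+1 when both residues carry like charge (D/E with D/E, or K/R with K/R),
-1 for opposite charges, 0 otherwise; a positive net flags a repulsive,
implausible interface.  Histidine is treated as neutral (configurable) —
its protonation state is context-dependent and the screen should not guess.

Quantitative coupling energies (interaction free energies of *g*-*e'*
pairs relative to Ala-Ala) are supported through a user-supplied TSV table
(`readCouplingTable()`); no energy values ship with the package, because
the published tables cover only the common residues at these positions and
embedding a partial transcription would invent data.  Pairs missing from a
supplied table are excluded and counted, and a coverage fraction is always
reported.

Antiparallel interfaces are refused by the chemistry module rather than
scored: their *g*-*e'* geometry differs and no convention is established
for it here.

## Benchmarking against dimerization arrays

Experimental Z-scores from protein-array dimerization data are converted
to 0-6 ordinal ranks with strict thresholds (> 20 → 6, > 10 → 5, > 5 → 4,
> 2.5 → 3, > 1.5 → 2, > 1 → 1, else 0).  Rank 0 means insufficient or
inconsistent array data and is excluded.  Ranks 4-6 label a pair a likely
("true") dimer and 1-3 an unlikely ("false") one; this ≥ 4 / ≤ 3 split is
the default because it reproduces the published class sizes of the
reference array data (286 true, 1642 false), while the stricter
"> 4 / < 3" split seen in some figure captions is available behind
`split = "strict"`.  Synonymous A-B and B-A pairs are scored as separate
rows, mirroring how the arrays were analysed.

`rocAuc()` computes AUC as the Mann-Whitney concordance probability via
midranks (ties count one half) and builds the ROC polyline from a
threshold sweep over unique values; the trapezoidal area of that polyline
equals the concordance AUC exactly, which the tests assert along with
agreement with an O(n²) brute-force oracle and with the pROC package.
`runBenchmark()` restricts ROC computation to pairs whose prediction
formed an L-zip — a model that never formed the motif has no meaningful
interface score — but always emits the formed-by-rank-class
cross-tabulation, because the *failure* to form an L-zip is itself the
strongest negative signal in this domain.

## Superposition

`iterativeAlign()` reproduces the common refinement protocol: superpose on
the retained CA pairs (Kabsch, SVD with a determinant guard against
reflections), drop pairs deviating by more than 2.0 Å, repeat up to 5
cycles or until stable.  Residues are paired 1:1 by position within
explicit ranges; there is no sequence-alignment step, so the ranges must
select equal residue counts.  Because the superposition is CA-only while
interactive tools typically match all atoms with their own pairing
heuristics, agreement with published alignment RMSDs should be expected at
the ±0.1-0.2 Å level, not bit-exactly.

## The synthetic generator

`crickBackbone()` places both chains on a common left-handed superhelix
(radius 4.9 Å, pitch 148 Å, rise 1.51 Å/residue, minor helix radius
2.26 Å, 3.6 residues/turn — canonical dimeric coiled-coil values) using
the Frenet frame of the superhelical axis, with the minor-helix phase
anchored so the *a*/*d* positions face the partner by construction.
Consecutive CA distances stay within 3.8 ± 0.015 Å on all builds,
parallel and antiparallel.  CB atoms are placed 1.53 Å along the local
radial direction, which is what the register and orientation checks
consume; N, C and O are idealized interpolations sufficient for format
round-trips.  Sequences follow the synthetic-peptide design grammar:
five-heptad repeats with the *e*/*g* positions filled by one charged
residue type and a Leu/Ile pattern at *d* (`synthSequence()`,
`parsePairPattern()`); the non-specificity positions default to Val at *a*
and Ala elsewhere, chosen once as unremarkable helix formers.

`synthConfidence()` emulates the confidence signature of a well-supported
interface (pLDDT 90-98 in helices versus 20-40 outside; PAE 0.5-2.5 Å
within and between helix blocks versus 15-30 Å elsewhere; ipTM 0.7-0.95)
or a poorly supported one (every interchain PAE 10-30 Å, ipTM 0.1-0.4).
`synthZscores()` draws labelled score populations whose expected AUC is
known in closed form (`pnorm(delta / sqrt(2))`).

What the generator does **not** emulate: side-chain rotamers, sequence-
dependent helix propensity, partially disordered termini, register
slippage, stutters/stammers in the heptad pattern, or any correlation
between sequence chemistry and the synthetic confidence values.  Passing
tests therefore demonstrate that the geometry, register, metric and ROC
machinery is correct on idealized inputs — they do not demonstrate
discrimination performance on real predictor output, which is what the
benchmark module is for.

## Problem sizes and determinism

The test and acceptance runs use five-heptad (35-residue) chains for
single-model checks, a factorial grid of 8 fixtures for the classifier, 50
randomized builds for register recovery, and Z-score populations of
1000 + 1000 for the closed-form AUC comparison (tolerance three binomial
standard errors) — sizes at which every statistical assertion is stable
across seeds while the whole suite completes in well under a minute.  All
stochastic generators take an explicit seed and restore the caller's RNG
state.

## Known limitations

* Only dimers are classified; trimeric and higher coiled coils are out of
  scope, as is DNA-bound bZIP modelling.
* The classifier's thresholds are operational choices; borderline models
  (e.g. splayed but contacting helices) inherit their sensitivity.
* The chemistry screen is a discrete sign test, not an electrostatics
  calculation; it flags archetypal charge clashes, not subtle ones.
* ipTM cannot be recomputed from PAE here; bundles lacking it simply drop
  out of ipTM benchmarks, with the count reported.
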