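# ZipperQC

Quality assessment of predicted leucine-zipper (L-zip) dimer structures.

## Why

Leucine zippers are parallel two-helix coiled coils: a heptad repeat
(*a*-*g*) buries Leu at *d* and hydrophobics at *a* in a knobs-into-holes
core, while charged residues at *e* and *g* decide which partners may pair
(the *g* of one heptad contacts the *e'* of the next heptad on the partner
helix).  Structure predictors recognise the heptad pattern so reliably
that they fold nearly any such pair into a confident dimer — including
pairs whose *g*-*e'* electrostatics forbid association in vitro.  pLDDT,
PAE and ipTM report reproducibility of the fold, not plausibility of the
complex.

ZipperQC is for structural biologists and protein designers who consume
predictor output (AlphaFold/ColabFold JSON, Boltz-style JSON + `.npz` PAE
archives, PDB/mmCIF models) and need the downstream screens:

* **`classifyLzip()`** — valid parallel L-zip, or broken with reason codes
  (`antiparallel`, `minimal_contact`, `too_short`,
  `wrong_leu_orientation`, `no_helix_pair`), plus the heptad register of
  both chains recovered from geometry.
* **`interfaceScores()`** — ipTM (extracted), mean pLDDT, mean interchain
  PAE, and ipSAE: for residue *i* with interchain partners *j* passing
  `pae[i,j] < 3` Å and a 5 Å side-chain distance gate,
  `s_i = mean_j 1/(1 + (pae[i,j]/d0_i)^2)` with
  `d0_i = max(1, 1.24 (max(n_i,19) - 15)^{1/3} - 1.8)`, maximised over
  residues.
* **`enumerateGePairs()` / `chargeComplementarity()` /
  `couplingEnergy()`** — the discrete *g*-*e'* charge screen (+1 repulsive
  like-charge pair, -1 attractive, 0 neutral) and optional user-supplied
  coupling-energy tables.
* **`newmanRank()` / `labelPairs()` / `rocAuc()` / `runBenchmark()`** —
  Z-score → 0-6 rank conversion (strict thresholds at 20/10/5/2.5/1.5/1),
  true/false labelling (rank ≥ 4 vs 1-3; rank 0 excluded), and
  Mann-Whitney AUC with exact tie handling.
* **`kabsch()` / `iterativeAlign()`** — CA superposition with iterative
  outlier rejection (5 cycles, 2.0 Å cutoff by default).
* **`crickBackbone()` / `synthSequence()` / `synthConfidence()` /
  `synthZscores()`** — Crick-parameterized ideal coiled-coil fixtures with
  known orientation/register ground truth, matched synthetic confidence
  bundles, and labelled score populations with closed-form expected AUC —
  so the entire pipeline runs and is tested with no downloads.

## Worked example

A five-heptad synthetic peptide pair with every *e* and *g* position
glutamate — the archetype of a geometrically perfect but electrostatically
forbidden homotypic interface:

```r
library(ZipperQC)

mod    <- crickBackbone(synthSequence(5), synthSequence(5))
bundle <- synthConfidence(mod, "high", seed = 7)
runAssess(mod, bundle, pairId = "allglu_pair")
#> AssessmentRecord: allglu_pair
#> LzipVerdict: VALID parallel L-zip (5 interface heptads, 58 contacts)
#>   ipTM 0.854 | ipSAE 0.786 | mean pLDDT 94.1 | mean PAE 1.52
#>   g-e' net charge score +10 (repulsive interface)
```

Read bottom-up: the geometry is a textbook L-zip (parallel, five
registered interface heptads, dense core contacts) and every confidence
metric looks excellent — yet all ten *g*-*e'* pairs are Glu-Glu clashes,
so the net charge score of +10 flags the interface as repulsive and
implausible.  Confidence and plausibility are different questions; the
chemistry screen answers the one the metrics cannot.

The same sequences built antiparallel are caught geometrically:

```r
anti <- crickBackbone(synthSequence(5), synthSequence(5),
                      crickParams(orientation = "antiparallel"))
classifyLzip(anti)
#> LzipVerdict: BROKEN [antiparallel]
#>   orientation antiparallel; contacts 53; interface heptads 5
```

Real predictor output works the same way:
`runAssess("model.cif", "confidence.json", paePath = "pae_model.npz")`.

## Documentation

The methods vignette
(`vignettes/assessing-lzip-predictions.Rmd`) describes the classifier
thresholds, the register-assignment vote, the ipSAE numerics (including
why the distance gate uses CB positions and why the score is not monotone
in the PAE cutoff), the rank-split convention, what the synthetic
generator does and does not emulate, and known limitations.
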