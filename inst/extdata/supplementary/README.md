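# Supplementary benchmark data (not shipped)

The acceptance blocks in `tests/testthat/test-acceptance.R` recompute the
published benchmark numbers from the source study's supplementary
materials.  Those files are third-party data, too large to ship with the
package; to run the checks, place them here:

- `L-zip dimer pairs Newman Ranks and structures.xlsx` — per-pair Newman
  ranks and structural characterization (needs columns `pair_a`, `pair_b`,
  a rank column, and a formed-L-zip column).
- `L-zip dimer pairs AlphaFold confidence metrics.xlsx` — per-pair
  ipTM/ipSAE metrics for the AlphaFold2 and Boltz-1 runs.
- `leucine_zippers_Boltz_predictions/` — the 1274 deposited Boltz `.cif`
  dimer models, unpacked.
- `synthetic_peptide_pair.pdb` — the deposited synthetic-peptide dimer
  model.
- `5vpf.pdb` — the FosB-JunD heterodimer crystal structure (PDB 5VPF).

Everything else in the test suite is self-contained and generates its own
fixtures.
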