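# Reference crystal structures (not redistributed)

The crystal-comparison checks in `tests/testthat/test-acceptance.R` and the
corresponding quantities in `scripts/acceptance.R` compare the deposited
Tpm3.1 N-terminal peptide structure against two published coiled-coil
structures. Deposited PDB coordinates are not redistributed with this
package; to enable those checks, download the entries from the Protein
Data Bank (https://files.rcsb.org/download/<ID>.pdb) and save them here
before installing:

- `6otn.pdb`  — Tpm3.1 N-terminal peptide (four chains, two coiled coils)
- `1ic2.pdb`  — Tpm1.1 N-terminal peptide
- `tm1bzip.pdb` — the aTM1bZIP tropomyosin/GCN4 chimera crystal structure

Chain pairing between the structures is searched automatically
(`best_pairing_rmsd()`); the comparisons use backbone atoms of residues
12-74 and alpha carbons of residues 12-35 respectively.
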