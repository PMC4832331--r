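# Reference inputs (not bundled)

This directory is populated by `scripts/fetch_reference_data.R` (network
required), which downloads:

- `ldcI_ldcC_ecoli.fasta` — UniProt P0A9H3 (E. coli LdcI/CadA) and
  P52095 (E. coli LdcC);
- `3N75-assembly1.cif`, `5FKX-assembly1.cif`, `5FKZ-assembly1.cif`,
  `5FL2-assembly1.cif` — RCSB biological assemblies of the decamer
  models (LdcI inactive-pH crystal; LdcI at active pH; LdcC; LdcI-LARA).

They feed the two reference-reproduction tests in
`tests/testthat/test-acceptance.R` (LdcI/LdcC identity-similarity and
the domain RMSD ranges). Reinstall the package after fetching so the
files are visible through `system.file()`.
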