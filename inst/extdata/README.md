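# External reference data (not shipped)

The regression test for the published coxI calibration expects two files
here, which must be assembled by the user from the public archives (they
are third-party records and are not redistributed with the package):

- `reference_dataset.fasta` — the 556-bp coxI alignment of the deposited
  barcode accessions (EMBL FR856638-FR856846 plus GenBank
  GU270553-GU270566), headers formatted as
  `sample_id|species_label|locality_group`.
- `reference_dataset_metadata.tsv` — sample metadata TSV with columns
  `sample_id`, `species_label`, `locality_group` (UNKNOWN species for the
  41 morphologically unidentified samples).

With these present, `tests/testthat/test-acceptance.R` re-runs the full
pipeline (excluding Myotis nattereri from OT calibration) and checks the
reported calibration (OT ~= 4.4%, MCE ~= 0.08%), divergence summaries,
base composition and the 31-entity partition.
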