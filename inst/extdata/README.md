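# Bundled example data

- `ac2_species_panel_synthetic.csv` — a SYNTHETIC stand-in for a deposited
  species response table: solvent-corrected spikes/s responses of ac2
  sensilla of ten drosophilid species to the C1–C6 acid panel, with `NaN`
  for lost recordings. Generated from Gaussian noise around plausible
  per-species tuning curves (seeded); it mimics the file layout and the
  C2-max/C4-max cluster structure of real species panels but is not
  measured data and does not reproduce any published values.
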