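# Waveform file formats

`aepscatter` defines its own documented dialects for auditory evoked
potential (AEP) records. Vendor export schemas for clinical evoked-potential
systems are proprietary and undocumented, so the package owns a minimal,
explicit format pair instead. Both formats round-trip voltages
bit-identically (decimal text with 17 significant digits) and apply no
resampling, filtering or scaling on read.

## XML dialect

Root element `<aep_records>` holding one `<record>` element per waveform.

```xml
<aep_records>
  <record id="p001_abr_l" patient="p001" ear="left" subtype="ABR"
          fs_hz="30000" stimulus_type="click" rate_hz="22"
          intensity_db_nhl="80" highpass_hz="33" lowpass_hz="1500">
    <samples_uv>0.012 -0.034 0.051 ...</samples_uv>
  </record>
</aep_records>
```

* `id` (required): unique record identifier.
* `patient` (optional, defaults to `id`): patient identifier.
* `ear`: `left` or `right` (optional, default `left`).
* `subtype` (required): `ABR` or `AMLR`.
* `fs_hz`, `stimulus_type`, `rate_hz`, `intensity_db_nhl`, `highpass_hz`,
  `lowpass_hz` (optional): acquisition and stimulus metadata. Omitted
  fields are filled from the subtype defaults (ABR: click, 22/s, 80 dB
  nHL, 33–1500 Hz, 30 kHz; AMLR: 2 kHz tone burst, 6.1/s, 70 dB nHL,
  10–1500 Hz, 3 kHz) with a logged notice.
* `<samples_uv>` (required): whitespace-separated voltages in microvolts,
  in acquisition order. Sample `k` (0-based) sits at `k / fs_hz * 1000` ms
  after stimulus onset.

## CSV dialect

Long format, one row per sample:

```
record_id,patient_id,ear,subtype,fs_hz,sample_index,value_uv
p001_abr_l,p001,left,ABR,30000,0,0.012
p001_abr_l,p001,left,ABR,30000,1,-0.034
```

`sample_index` is 0-based and must be gap-free per record. The CSV carries
no stimulus metadata; subtype defaults are applied on read with a logged
notice. Record order in the file is preserved.

## Clinical table

Written by `write_clinical_table()` as plain CSV (one row per patient,
columns `patient_id`, `thi_score`, `laterality` plus the 33 feature
variables) with a JSON sidecar `<name>.csv.schema.json` typing every
feature column as `numeric` or `categorical`. Categorical variables are
integer-coded from 0; level maps are documented in the methods vignette.
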