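# extdata

`phantom_dataset_s2.csv` (not shipped): per-voxel phantom measurements
converted from the published supplementary table (Dataset S2), used by
the acceptance check of measured flow-state ratios. The original file
is third-party data and cannot be redistributed here.

Expected columns, one row per ROI voxel per state:

| column | meaning |
|---|---|
| `state` | `baseline`, `7cms`, `14cms`, `21cms` |
| `cv` | full-band coefficient of variation |
| `sp` | full-band spectral power |
| `background_sp` | spectral power outside the principal peaks |

Place the file here before installing, or point
`options(mregpulse.dataset_s2 = "<path>")` at it.
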