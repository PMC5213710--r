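# Source-data drop-in directory

`reproduce_source_stats()` (and the corresponding acceptance test) looks
here for the original article's per-participant source-data tables,
converted to CSV (xlsx also works when the readxl package is installed).
They are not redistributed with the package.  Expected files:

- `figure2_weights.csv` — stay/switch regression weights: participant id,
  group label, `prob`, and the lagged outcome weights `RM_t-1` .. `RM_t-4`,
  `EM_t-1` .. `EM_t-4` (header aliases such as `RM_1` are accepted).
- `figure2_params.csv` — per-participant model parameters (`gamma`,
  `beta`, `alpha`, `lambda`), optionally suffixed `_ms` / `_os` for the
  scanner / outside-scanner sessions (untagged columns are read as the
  both-sessions fit).
- `figure3_spectroscopy.csv` — spectroscopy measures per participant:
  glutamate, GABA, creatine (raw amplitudes or creatine ratios), tissue
  fractions (grey/white/CSF), optional CRLB columns, group label.
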