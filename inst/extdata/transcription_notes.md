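# Screen-table fixtures: transcription notes

`table1_nada.tsv` and `table2_ispg.tsv` are hand transcriptions of the
published complementation/recovery screens for the NadA and IspG ortholog
sets (47 heterologous orthologs plus the Escherichia coli host row each).

Conventions applied during transcription:

- `N.T.` (not tested) -> `NT`; `+/-` (partial complementation) -> `partial`;
  `?` kept as `?` for unknown host traits.
- The printed tables carry a combined "Complemented/recovered/detected"
  column. It is redundant and is not transcribed; instead its
  "Detection N.T." entries (negative complementation, mass-spectrometry
  detection not attempted) are folded into `ms_detected = detection_NT`,
  while `ms_detected = NT` marks rows whose MS cell reads N.T. but which
  complemented or recovered (detection simply unnecessary).
- `complemented_or_recovered` is transcribed as printed but is regenerated
  from the individual condition columns at load time and checked for
  consistency; the loader refuses a table where the two disagree.
- The phylum column, printed once per group of rows, is filled down.
- Species names are kept verbatim apart from typography: en dashes are
  transcribed as ASCII hyphens (`Dictyoglomus thermophilum H-6-12`), and
  italic markup is dropped.
- `tir_log10` is the RBS-calculator predicted translation-initiation rate
  on a log10 scale; `NT` becomes `NA` on load.
- `is_host_control` flags the E. coli row; `is_suf_donor` (NadA schema only)
  flags the Bacillus subtilis row, the donor of the coexpressed SUF operon.

MD5 checksums of the committed fixtures:

    533f8005c205f8da337c57d86c384e26  table1_nada.tsv
    c36a98a7a3c59a17a08e1e486b63b1fb  table2_ispg.tsv
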