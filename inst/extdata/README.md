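# Bundled fixtures

- `cellmig_cnvs.tsv` — the sixteen rare CNV calls overlapping the
  "regulation of cell migration" gene set (10 case samples, 6 control
  samples), in the `cnv_table` dialect. Marker counts and confidences are
  plausible placeholders (only coordinates, copy numbers and sample ids
  matter to the analyses exercised on this fixture).
- `cellmig_genes_synthetic.bed` — *synthetic* gene models for the fourteen
  genes hit by those calls: intervals are constructed to reproduce the
  gene/CNV containment structure (e.g. one duplication covering both MUC2
  and MUC5AC; one gene body spanning both PTPRK calls), not real genome
  annotation coordinates.
- `cellmig_set.gmt` — the fourteen-gene set in GMT format.
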