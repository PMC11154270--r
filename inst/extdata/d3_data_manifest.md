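# Dispersion reference data manifest

- `d3_c6_reference_synthetic.tsv` — per-element reference coordination
  numbers with homonuclear C6 anchors (hartree*bohr^6). This is a compact
  **synthetic** reference set constructed for this package: anchors follow
  free-atom-limit magnitudes from the dispersion literature and decrease
  with coordination; heteronuclear reference C6 values are geometric means
  of the homonuclear anchors. It covers H, C, N, O, F, P, S, Cl — the
  elements occurring in the motif library.
- `d3_r4r2_synthetic.tsv` — element-wise sqrt(<r^4>/<r^2>) ratios (q) for
  the C8 = 3 C6 sqrt(qA qB) relation; same compact synthetic provenance.
- `d3bj_functional_params.tsv` — per-functional global scalings and
  Becke-Johnson damping constants. Rows marked `fitted` follow the standard
  published BJ-damping fits; rows marked `nominal` are placeholders for
  functionals conventionally used with zero damping, kept explicit and
  swappable here.

All three files are plain TSV with `#` comment headers and can be replaced
by user files of the same schema through the corresponding loader
arguments.
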