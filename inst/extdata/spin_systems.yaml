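# Spin-system parameters for the tracer-enriched metabolites quantified by
# the pipeline. Chemical shifts (ppm, pH ~7) follow standard metabolomics
# reference values (HMDB conventions, DSS = 0 ppm). One-bond 13C-13C scalar
# couplings (Hz) are literature-typical values: ~52-55 Hz for couplings to a
# carboxyl carbon, ~34-37 Hz for aliphatic CH-CH(n) pairs. All values are
# editable; the analysis records which file was used.
- name: lactate
  sites:
    - {index: 1, c13_shift: 185.1, h1_shift: null, n_protons: 0}   # C1 carboxyl
    - {index: 2, c13_shift: 71.2,  h1_shift: 4.10, n_protons: 1}   # C2 CH
    - {index: 3, c13_shift: 22.8,  h1_shift: 1.31, n_protons: 3}   # C3 methyl
  couplings:
    - {i: 1, j: 2, hz: 55.0}
    - {i: 2, j: 3, hz: 37.0}
- name: alanine
  sites:
    - {index: 1, c13_shift: 178.5, h1_shift: null, n_protons: 0}
    - {index: 2, c13_shift: 53.3,  h1_shift: 3.77, n_protons: 1}
    - {index: 3, c13_shift: 19.0,  h1_shift: 1.47, n_protons: 3}
  couplings:
    - {i: 1, j: 2, hz: 54.0}
    - {i: 2, j: 3, hz: 35.0}
- name: acetate
  sites:
    - {index: 1, c13_shift: 184.2, h1_shift: null, n_protons: 0}
    - {index: 2, c13_shift: 26.1,  h1_shift: 1.91, n_protons: 3}
  couplings:
    - {i: 1, j: 2, hz: 52.0}
- name: glutamate
  sites:
    - {index: 1, c13_shift: 177.2, h1_shift: null, n_protons: 0}
    - {index: 2, c13_shift: 57.4,  h1_shift: 3.74, n_protons: 1}
    - {index: 3, c13_shift: 29.7,  h1_shift: 2.06, n_protons: 2}
    - {index: 4, c13_shift: 36.2,  h1_shift: 2.34, n_protons: 2}
    - {index: 5, c13_shift: 183.8, h1_shift: null, n_protons: 0}
  couplings:
    - {i: 1, j: 2, hz: 53.0}
    - {i: 2, j: 3, hz: 35.0}
    - {i: 3, j: 4, hz: 34.0}
    - {i: 4, j: 5, hz: 51.0}
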