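# Titin sarcomeric band map, version 1.
# Residue intervals (1-based, inclusive) per transcript, derived from public
# titin annotation of the N2B cardiac isoform (NM_003319, 26926 aa) and the
# short novex-3 isoform (NM_133379, 5604 aa). Novex-3 terminates within the
# I-band and contains no A- or M-band sequence, so it contributes no shared
# region. The shared intervals mark the constitutive A/M region present in
# all full-length isoforms.
version: 1
isoform_set: [NM_003319]
transcripts:
  NM_003319:
    bands:
      - {band: Z, start: 1, end: 800}
      - {band: I, start: 801, end: 13600}
      - {band: A, start: 13601, end: 24750}
      - {band: M, start: 24751, end: 26926}
    shared:
      - {start: 13601, end: 26926}
  NM_133379:
    bands:
      - {band: Z, start: 1, end: 800}
      - {band: I, start: 801, end: 5604}
    shared: []
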