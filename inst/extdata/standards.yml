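# International reference ratios defining the delta scales.
# Override any entry (or add isotope pairs) and pass the file to
# iso_standards(path) or the CLI --standards flag.
13C/12C:
  element: "C"
  reference_name: VPDB
  reference_ratio: 0.0111802
15N/14N:
  element: "N"
  reference_name: AIR
  reference_ratio: 0.0036765
D/H:
  element: "H"
  reference_name: VSMOW
  reference_ratio: 0.00015576
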