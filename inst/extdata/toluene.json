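{
  "material": "toluene",
  "comment": "ASTM E1840 consensus Raman shift positions for toluene; intensities and widths nominal.",
  "lines": [
    {"center_cm1": 521.7,  "rel_intensity": 0.30, "fwhm_cm1": 7.0, "shape": "lorentzian"},
    {"center_cm1": 786.5,  "rel_intensity": 0.60, "fwhm_cm1": 7.0, "shape": "lorentzian"},
    {"center_cm1": 1003.6, "rel_intensity": 1.00, "fwhm_cm1": 5.0, "shape": "lorentzian"},
    {"center_cm1": 1030.6, "rel_intensity": 0.50, "fwhm_cm1": 6.0, "shape": "lorentzian"},
    {"center_cm1": 1211.4, "rel_intensity": 0.30, "fwhm_cm1": 8.0, "shape": "lorentzian"},
    {"center_cm1": 1605.1, "rel_intensity": 0.30, "fwhm_cm1": 7.0, "shape": "lorentzian"},
    {"center_cm1": 2920.4, "rel_intensity": 0.40, "fwhm_cm1": 12.0, "shape": "lorentzian"},
    {"center_cm1": 3057.1, "rel_intensity": 0.80, "fwhm_cm1": 10.0, "shape": "lorentzian"}
  ]
}
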