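{
  "material": "polystyrene",
  "comment": "ASTM E1840 consensus Raman shift positions for polystyrene. Relative intensities and widths are nominal values for a 785 nm instrument.",
  "lines": [
    {"center_cm1": 620.9,  "rel_intensity": 0.16, "fwhm_cm1": 6.0, "shape": "gaussian"},
    {"center_cm1": 1001.4, "rel_intensity": 1.00, "fwhm_cm1": 4.5, "shape": "gaussian"},
    {"center_cm1": 1031.8, "rel_intensity": 0.27, "fwhm_cm1": 5.0, "shape": "gaussian"},
    {"center_cm1": 1155.3, "rel_intensity": 0.13, "fwhm_cm1": 7.0, "shape": "gaussian"},
    {"center_cm1": 1450.5, "rel_intensity": 0.10, "fwhm_cm1": 9.0, "shape": "gaussian"},
    {"center_cm1": 1583.1, "rel_intensity": 0.12, "fwhm_cm1": 7.0, "shape": "gaussian"},
    {"center_cm1": 1602.3, "rel_intensity": 0.28, "fwhm_cm1": 6.5, "shape": "gaussian"},
    {"center_cm1": 2852.4, "rel_intensity": 0.15, "fwhm_cm1": 10.0, "shape": "gaussian"},
    {"center_cm1": 2904.5, "rel_intensity": 0.20, "fwhm_cm1": 10.0, "shape": "gaussian"},
    {"center_cm1": 3054.3, "rel_intensity": 0.55, "fwhm_cm1": 8.0, "shape": "gaussian"}
  ]
}
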