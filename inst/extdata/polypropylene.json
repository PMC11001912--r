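{
  "material": "polypropylene",
  "comment": "Nominal isotactic polypropylene Raman bands (positions from standard band tables; intensities and widths nominal).",
  "lines": [
    {"center_cm1": 808.9,  "rel_intensity": 0.80, "fwhm_cm1": 7.0, "shape": "gaussian"},
    {"center_cm1": 841.5,  "rel_intensity": 0.60, "fwhm_cm1": 8.0, "shape": "gaussian"},
    {"center_cm1": 972.9,  "rel_intensity": 0.50, "fwhm_cm1": 7.0, "shape": "gaussian"},
    {"center_cm1": 998.3,  "rel_intensity": 0.40, "fwhm_cm1": 7.0, "shape": "gaussian"},
    {"center_cm1": 1151.2, "rel_intensity": 0.30, "fwhm_cm1": 8.0, "shape": "gaussian"},
    {"center_cm1": 1167.7, "rel_intensity": 0.40, "fwhm_cm1": 8.0, "shape": "gaussian"},
    {"center_cm1": 1219.8, "rel_intensity": 0.20, "fwhm_cm1": 8.0, "shape": "gaussian"},
    {"center_cm1": 1328.5, "rel_intensity": 0.40, "fwhm_cm1": 9.0, "shape": "gaussian"},
    {"center_cm1": 1359.4, "rel_intensity": 0.30, "fwhm_cm1": 9.0, "shape": "gaussian"},
    {"center_cm1": 1458.0, "rel_intensity": 1.00, "fwhm_cm1": 10.0, "shape": "gaussian"},
    {"center_cm1": 2839.5, "rel_intensity": 0.90, "fwhm_cm1": 12.0, "shape": "gaussian"},
    {"center_cm1": 2882.0, "rel_intensity": 0.80, "fwhm_cm1": 12.0, "shape": "gaussian"},
    {"center_cm1": 2951.5, "rel_intensity": 0.90, "fwhm_cm1": 14.0, "shape": "gaussian"}
  ]
}
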