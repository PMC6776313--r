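feature,type,color_space,summary,coefficient,canonical_name
Elongation,Morphology,,MAD,-1.51E-01,morph_elongation_mad
Minor axis of the Ellipse Fit,Morphology,,Median,-1.25E+00,morph_ellipse_minor_axis_median
Flatness,Morphology,,MAD,-4.20E-16,morph_flatness_mad
Kurtosis,Intensity,HSV,Median,5.38E-03,int_kurtosis_hsv_median
Skewness,Intensity,H&E,MAD,-2.22E-01,int_skewness_he_mad
Skewness,Intensity,HSV,Median,-2.87E-01,int_skewness_hsv_median
Skewness,Intensity,Lab,MAD,-1.10E-01,int_skewness_lab_mad
Correlation,Texture,HSV,MAD,-2.48E-02,tex_correlation_hsv_mad
Haralick Correlation,Texture,H&E,Median,-2.24E-01,tex_haralick_correlation_he_median
Energy,Texture,Lab,Median,-9.36E-01,tex_energy_lab_median
Energy,Texture,Lab,MAD,-3.74E-01,tex_energy_lab_mad
Inverse difference moment,Texture,H&E,Median,-4.81E-01,tex_inverse_difference_moment_he_median
Inverse difference moment,Texture,H&E,MAD,-4.19E-02,tex_inverse_difference_moment_he_mad
Inverse difference moment,Texture,HSV,Median,1.67E-01,tex_inverse_difference_moment_hsv_median
Inverse difference moment,Texture,HSV,MAD,-1.19E-01,tex_inverse_difference_moment_hsv_mad
Inertia,Texture,H&E,Median,-1.77E-01,tex_inertia_he_median
Inertia,Texture,Lab,Median,-9.72E-02,tex_inertia_lab_median
Entropy,Texture,HSV,Median,8.97E-03,tex_entropy_hsv_median
Low gray-level run emphasis,Texture,H&E,MAD,-7.52E-02,tex_lgre_he_mad
Long run high gray-level emphasis,Texture,HSV,MAD,1.50E-01,tex_lrhge_hsv_mad
Long run low gray-level emphasis,Texture,H&E,MAD,-7.71E-16,tex_lrlge_he_mad
Short run high gray-level emphasis,Texture,HSV,MAD,4.02E-02,tex_srhge_hsv_mad
Short run low gray-level emphasis,Texture,H&E,MAD,-1.28E-15,tex_srlge_he_mad
Gray level non-uniformity,Texture,HSV,Median,-4.26E-01,tex_gln_hsv_median
Gray level non-uniformity,Texture,Lab,MAD,2.45E+00,tex_gln_lab_mad
High gray-level run emphasis,Texture,HSV,MAD,6.21E-03,tex_hgre_hsv_mad
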