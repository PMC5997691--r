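version: '1.0'
panel:
- name: mean
  category: histogram
- name: median
  category: histogram
- name: minimum
  category: histogram
- name: maximum
  category: histogram
- name: range
  category: histogram
- name: sd
  category: histogram
- name: variance
  category: histogram
- name: skewness
  category: histogram
- name: kurtosis
  category: histogram
- name: energy
  category: histogram
- name: entropy
  category: histogram
- name: rms
  category: histogram
- name: iqr
  category: histogram
- name: mad
  category: histogram
- name: upp
  category: histogram
- name: p2_5
  category: histogram
- name: p25
  category: histogram
- name: p75
  category: histogram
- name: p97_5
  category: histogram
- name: mean_outer
  category: outer
- name: median_outer
  category: outer
- name: sd_outer
  category: outer
- name: minimum_outer
  category: outer
- name: maximum_outer
  category: outer
- name: skewness_outer
  category: outer
- name: kurtosis_outer
  category: outer
- name: energy_outer
  category: outer
- name: entropy_outer
  category: outer
- name: mean_delta
  category: delta
- name: median_delta
  category: delta
- name: sd_delta
  category: delta
- name: minimum_delta
  category: delta
- name: maximum_delta
  category: delta
- name: skewness_delta
  category: delta
- name: kurtosis_delta
  category: delta
- name: energy_delta
  category: delta
- name: entropy_delta
  category: delta
- name: volume
  category: shape
- name: surface_area
  category: shape
- name: surface_to_volume
  category: shape
- name: compactness
  category: shape
- name: sphericity
  category: shape
- name: convexity
  category: shape
- name: max_3d_diameter
  category: shape
- name: elongation
  category: shape
- name: density
  category: shape
- name: mass
  category: shape
- name: glcm_autocorrelation
  category: glcm
- name: glcm_contrast
  category: glcm
- name: glcm_correlation
  category: glcm
- name: glcm_dissimilarity
  category: glcm
- name: glcm_energy
  category: glcm
- name: glcm_entropy
  category: glcm
- name: glcm_homogeneity
  category: glcm
- name: glcm_cluster_shade
  category: glcm
- name: glcm_cluster_prominence
  category: glcm
- name: glcm_sum_average
  category: glcm
- name: glcm_variance
  category: glcm
- name: intensity_variability
  category: iszm
- name: size_zone_variability
  category: iszm
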