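seed: 1
voxel_mm: 2.0
levels: 64.0
volumes_ml:
- 0.5
- 0.745947778910305
- 1.112876177722436
- 1.660295025948483
- 2.476986773884197
- 3.695405564738239
- 5.513159146378546
- 8.225057640040221
- 12.270926955994485
- 18.306941415989364
- 27.312044575796687
- 40.746717977629594
- 60.789847546594828
- 90.692103515357005
- 135.303146363968011
- 201.85816301955586
- 301.151296718704145
- 449.286281806551472
- 670.288208016933368
- 999.999999999999773
scanners:
  scanner:
  - S1
  - S2
  - S3
  psf_fwhm_mm:
  - 6.5
  - 7.0
  - 6.0
  postfilter_fwhm_mm:
  - 6.0
  - 6.5
  - 5.0
  voxel_mm:
  - 4.0
  - 4.0
  - 4.0
  acq_time_s:
  - 180.0
  - 180.0
  - 120.0
clinical_acq_time_s: 120.0
acq_times_s:
- 60.0
- 120.0
- 180.0
- 240.0
settings:
  setting:
  - A
  - B
  - C
  - D
  - E
  - F
  psf_fwhm_mm:
  - 6.5
  - 5.5
  - 6.5
  - 5.8
  - 6.5
  - 4.8
  postfilter_fwhm_mm:
  - 5.0
  - 5.0
  - 5.0
  - 5.0
  - 4.0
  - 5.0
  voxel_mm:
  - 4.0
  - 4.0
  - 3.13
  - 4.0
  - 4.0
  - 4.0
n_replicates: 3
noise_scale: 4.7
nonuniformity_amp: 0.05
frame_times_min:
- 0.0
- 4.0
- 8.0
- 12.0
- 16.0
- 20.0
- 24.0
- 28.0
- 32.0
- 36.0
- 40.0
- 44.0
- 48.0
- 52.0
- 56.0
- 60.0
- 64.0
- 68.0
- 72.0
- 76.0
c11_activity: 80.0
f18_activity: 40.0
seg_threshold: 2.5
selection:
  cv_max: 0.1
  cv_cell_fraction: 0.75
  s_min: 0.2
  v_min_ml: 30.0
  slope_tol: 0.05
  r2_min: 0.8
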