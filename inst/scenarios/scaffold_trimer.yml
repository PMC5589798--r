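# Scaffold trimer counting with an mEos2-like tag (150 nm mask, 60 s window).
name: scaffold_trimer
seed: 1
field:
  width_um: 18
  height_um: 18
  density_um2: 3
  subunits_per_complex: 3
  tagged_per_complex: 3
photophysics:
  p_det: 0.48
  mean_detections_per_burst: 19
  tau_bleach_frames: 1200
  noise_detections: 50
counting:
  mask_diameter_nm: 150
stoichiometry:
  fit_n: 3
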