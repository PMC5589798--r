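# Heteromer model comparison: three tagged alpha copies per pentamer;
# candidate copy numbers compared at the calibrated p_det.
name: heteromer
seed: 1
field:
  width_um: 18
  height_um: 18
  density_um2: 3
  subunits_per_complex: 5
  tagged_per_complex: 3
photophysics:
  p_det: 0.44
  mean_detections_per_burst: 16
  tau_bleach_frames: 250
  noise_detections: 50
stoichiometry:
  fit_n: ~
  fixed_p: 0.44
  candidate_ns: [1, 2, 3, 4, 5]
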