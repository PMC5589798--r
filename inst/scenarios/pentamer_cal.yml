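# Homopentamer calibration: tagged pentameric receptors expressed sparsely in
# a cell without endogenous partners; free (N, p_det) fit with n = 5.
name: pentamer_cal
seed: 1
field:
  width_um: 18
  height_um: 18
  density_um2: 3
  subunits_per_complex: 5
  tagged_per_complex: 5
photophysics:
  p_det: 0.44
  mean_detections_per_burst: 16
  tau_bleach_frames: 250
  noise_detections: 50
stoichiometry:
  fit_n: 5
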