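# Synaptic copy-number quantification: dense synaptic ROIs holding 83
# heteromeric complexes each (3 tagged alpha copies -> ~250 tagged subunits),
# quantified via N = x/(n p) and the alpha3:beta2 stoichiometry.
name: synapse_counting
seed: 1
field:
  width_um: 12
  height_um: 12
  density_um2: 0.5
  subunits_per_complex: 5
  tagged_per_complex: 3
  synapse_areas_um2: [0.07, 0.07, 0.07, 0.07, 0.07, 0.05, 0.05, 0.05, 0.1, 0.1]
  complexes_per_synapse: 83
photophysics:
  p_det: 0.44
  mean_detections_per_burst: 16
  tau_bleach_frames: 250
  noise_detections: 50
stoichiometry:
  fit_n: ~
quantification:
  copies_per_complex: 3
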