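# Cytokine-challenge condition: same synapses with fewer complexes each
# (85 -> 61), for condition comparison against synapse_counting.
name: cytokine_reduction
seed: 1
field:
  width_um: 12
  height_um: 12
  density_um2: 0.5
  subunits_per_complex: 5
  tagged_per_complex: 3
  synapse_areas_um2: [0.06, 0.06, 0.06, 0.06, 0.06, 0.05, 0.05, 0.05, 0.08, 0.08]
  complexes_per_synapse: 61
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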