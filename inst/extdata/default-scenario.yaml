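# Default folding-scenario configuration. All numeric defaults of the
# simulation pipeline live here; run_scenario() merges user overrides on top.
scenario: basal_decrease   # basal_decrease | lateral_increase | apical_increase
nx: 10                     # cell columns
ny: 10                     # cell rows (even)
aspect_ratio: 5.0          # columnar height / diameter before folding
stripe_width: 2            # pre-fold stripe width in cell rows
delta_max: 0.8             # terminal |delta| of the tension ramp
n_steps: 40                # uniform ramp steps
replicates: 1              # replicate simulations (seeded packing noise)
perturb_amplitude: 0.01    # replicate perturbation amplitude (length units)
seed: 1
tol: 1.0e-6                # force tolerance of each relaxation
params:
  T_a: 1.0                 # apical surface tension (tension unit)
  T_b: 4.0                 # basal surface tension (4x apical baseline)
  T_l: null                # lateral tension; null = calibrate to aspect ratio
  Lambda_a: 1.0            # apical edge tension (normalized value 1)
  Lambda_b: 4.0            # basal edge tension
  k: 1.0                   # ECM spring constant (normalized value 1)
  K_V: 20000.0             # volume-penalty stiffness
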