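# Default four-arm coronary bifurcation study.
# Units: lengths mm, times s, velocities m/s, density kg/m^3.
geometry:
  lms_diameter: 4.5
  lad_diameter: 3.5
  lcx_diameter: 3.0
  lms_length: 10
  lad_length: 25
  lcx_length: 25
  bifurcation_angle: 80        # degrees between LAD and LCx centerlines
  fillet_radius: 1.0           # junction / carina smoothing radius

plaques:                       # raised-cosine wall bumps
  - branch: lms
    center_s: 5.0              # mid left main stem
    length: 4
    stenosis_fraction: 0.6     # 60% diameter stenosis
    eccentric: false
  - branch: lad
    center_s: 5.5              # proximal LAD, just distal to the ostium
    length: 4
    stenosis_fraction: 0.6
    eccentric: false

waveform:
  source: default              # or "csv" with a csv path below
  harmonics: 8
  peak_inlet_velocity: 0.017   # spatial peak at systole (0.4 s), m/s
  # csv: my_waveform.csv       # columns t_seconds, velocity_m_per_s

solver:
  dt: 0.0125                   # s per timestep
  steps_per_cycle: 80          # dt * steps_per_cycle = 1.0 s cycle
  cycles: 2                    # first cycle discarded as transient
  residual_target: 1.0e-4
  max_inner_iterations: 100
  rho: 1060

mesh:
  h: 0.15                      # element size, mm (h/2 bands at plaques)
  seed: 1

arms:
  - plaque_newtonian
  - plaque_gpl
  - noplaque_newtonian
  - noplaque_gpl

report_times: [0.4, 0.7]       # peak systole, mid-diastole

output:
  dir: coroflow_out
  fields: reporting            # none | reporting | all (VTK volume output)
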