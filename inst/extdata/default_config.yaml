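# Packaged study configuration: the two-phase primed constant infusion.
# Doses are nmol per g body weight (prime) and nmol/g/min (rate); times in
# minutes from the start of the bicarbonate infusion.
mode: simplified
seed: 1
cv_max: 0.10
slope_alpha: 0.05
residual_threshold: 0.05
breath_palmitate_window: [140, 150]
sampling_times_plasma: [0, 160, 170, 180]
sampling_times_breath: [0, 50, 55, 60, 140, 145, 150]
protocols:
  - tracer: "[1-13C]bicarbonate"
    analyte: co2
    label_atom_count: 1
    prime_nmol_per_g: 12.75
    rate_nmol_per_g_min: 0.15
    infusion_start_min: 0
    infusion_end_min: 60
    plateau_start_min: 50
    plateau_end_min: 60
    matrix: breath
  - tracer: "[U-13C16]palmitate"
    analyte: palmitate
    label_atom_count: 16
    prime_nmol_per_g: 0
    rate_nmol_per_g_min: 1.85
    infusion_start_min: 60
    infusion_end_min: 180
    plateau_start_min: 160
    plateau_end_min: 180
    matrix: plasma
  - tracer: "[1,1,2,3,3-d5]glycerol"
    analyte: glycerol
    label_atom_count: 5
    prime_nmol_per_g: 0
    rate_nmol_per_g_min: 2.5
    infusion_start_min: 60
    infusion_end_min: 180
    plateau_start_min: 160
    plateau_end_min: 180
    matrix: plasma
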