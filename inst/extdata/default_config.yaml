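# Default sensor configuration: dye-doped 20 um polystyrene microsphere
# on a fiber tip, immersed in PBS, neutravidin as the analyte.
resonator:
  radius_um: 10
  n_s: 1.59     # polystyrene
  n_m: 1.33     # PBS buffer
  n_L: 1.5      # polyelectrolyte / protein adlayer
molecule:
  M_g_mol: 55000   # neutravidin
  rho_g_cm3: 1.37  # generic protein density
  "n": 1.5         # generic protein refractive index (quoted: bare n is
                   # a YAML 1.1 boolean)
instrument:
  n_pixels: 2048
  wavelength_window_nm: [570.0, 650.0]
simulation:
  dye_peak_nm: 590
  dye_fwhm_nm: 60
  gain_window_nm: [615.0, 625.0]
  q_below: 3000
  q_above: 15000
  threshold_power_uW: 28
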