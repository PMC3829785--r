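# Built-in worked case: 1.5% w/w Manugel GHB alginate / alpha-tocopherol
# shell-core microparticles atomized by a 25 kHz dual-feed ultrasonic nozzle.
fluid:
  density: "1004 kg/m3"
  surface_tension: "0.07 N/m"
  viscosity: "0.13 Pa.s"     # zero-shear
  K: "0.205 Pa.s"            # consistency index, Pa.s^n
  "n": 0.854                 # flow index (quote the key: bare n is YAML boolean)
  concentration: "1.5 %"
ultrasonic:
  frequency: "25 kHz"
  power: "10 W"
  area: "1.38e-3 m2"
  sound_speed: "1497 m/s"
  coupling_density: "1004 kg/m3"
flow:
  core: "1.1 mL/min"
  shell: "4.2 mL/min"
  policy: shell
correlations:
  select: [lang, ramisetty, avvaru, barba]
  base_exponent: 0.33
  viscosity_policy: apparent
  shear_rate: "333 1/s"
particles:
  - {label: shell-core, fresh: "78 um", dried: "41 um"}
  - {label: matrix, fresh: "76 um", dried: "40 um"}
output:
  digits: 4
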