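[
  {
    "name": "bat_effective",
    "eps_real": 29.29,
    "eps_imag": 12.89,
    "frequency_hz": 1.0e10,
    "note": "Homogenized body-averaged permittivity for a bat carcass at X band."
  },
  {
    "name": "vacuum",
    "eps_real": 1.0,
    "eps_imag": 0.0,
    "frequency_hz": null,
    "note": "Free space."
  },
  {
    "name": "skin_dry",
    "eps_real": 31.29,
    "eps_imag": 14.40,
    "frequency_hz": 1.0e10,
    "note": "Dry human skin at 10 GHz, Gabriel/IFAC tissue dielectric parameterization (eps' 31.29, sigma 8.01 S/m -> eps'' = sigma/(omega eps0)); transcribed 2026-09."
  },
  {
    "name": "skin_wet",
    "eps_real": 33.52,
    "eps_imag": 16.88,
    "frequency_hz": 1.0e10,
    "note": "Wet human skin at 10 GHz, Gabriel/IFAC tissue dielectric parameterization (eps' 33.52, sigma 9.39 S/m -> eps'' = sigma/(omega eps0)); transcribed 2026-09."
  }
]
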