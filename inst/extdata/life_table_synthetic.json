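{
  "description": "Synthetic period life table (remaining life expectancy by age), shaped like European population statistics. Constructed so that linear interpolation passes through 49.87 remaining years at age 30 and 45 remaining years at age 35 (mean age at death 80 for the modelled cohort). Not an official table.",
  "age":       [0,    10,   20,   30,    35, 40,   50,   60,   70,   80,  90],
  "remaining": [80.5, 70.8, 60.9, 49.87, 45, 40.3, 31.0, 22.0, 13.8, 6.9, 2.9]
}
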