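# Channel -> Brodmann area map for the 116-channel study montage
# (124-channel amplifier minus the eight excluded channels
#  F8, POz, AF4, AF8, F6, FC3, M1, M2).
# ba_cortex groups the 21 areas into four cortices using standard lobe
# anatomy; the grouping is an editable stand-in (the exact grouping used
# with any given dataset may differ) and can be overridden by pointing
# load_ba_map() at a copy of this file.
channel_ba:
  C4: 1
  CCP4h: 1
  C3: 2
  CP3: 2
  CCP3h: 2
  CPP3h: 2
  Cz: 5
  CP1: 5
  CP2: 5
  C1: 5
  C2: 5
  CCP1h: 5
  CCP2h: 5
  CPP1h: 5
  CPP2h: 5
  FC1: 6
  FC2: 6
  FCz: 6
  FC4: 6
  FCC3h: 6
  FCC4h: 6
  FCC2h: 6
  FCC1h: 6
  Pz: 7
  P1: 7
  P2: 7
  F4: 8
  F3: 8
  Fz: 8
  F1: 8
  F2: 8
  AFF1: 8
  AFF2: 8
  FFC3: 8
  FFC4: 8
  FFC1: 8
  FFC2: 8
  AF3: 9
  AFz: 9
  AFp3h: 10
  AFp4h: 10
  FPz: 10
  FP3: 10
  FP4: 10
  FP1: 10
  FP2: 10
  O1: 18
  O2: 18
  I1: 18
  I2: 18
  OI1h: 18
  OI2h: 18
  POO9h: 18
  POO10h: 18
  PPO2: 19
  PPO1: 19
  POO3h: 19
  POO4h: 19
  PO3: 19
  PO4: 19
  PO7: 19
  PO8: 19
  FT9: 20
  FT10: 20
  PO9: 20
  P9: 20
  FTT9h: 20
  FTT10h: 20
  PPO9h: 20
  TP7: 21
  TP8: 21
  TPP10h: 21
  TTP8h: 21
  TPP7h: 21
  TPP8h: 21
  T8: 21
  TPP9h: 21
  PO10: 37
  P10: 37
  PPO10h: 37
  P7: 37
  P8: 37
  P3: 39
  P4: 39
  P5: 39
  P6: 39
  PPO5h: 39
  PPO6h: 39
  CP5: 40
  CP6: 40
  CP4: 40
  CPP5h: 40
  CPP6h: 40
  C6: 41
  CCP6h: 41
  CCP5h: 42
  TTP7h: 42
  T7: 42
  C5: 42
  FC6: 44
  FC5: 44
  FCC6h: 44
  FFT8h: 45
  FFT7h: 45
  AFF5h: 46
  AFF6h: 46
  AF7: 46
  F5: 46
  FFC5h: 46
  FFC6h: 46
  FCC5h: 46
  FTT7h: 47
  FTT8h: 47
  F7: 47
  FT7: 47
  FT8: 47
ba_cortex:
  1: parietal
  2: parietal
  5: parietal
  6: frontal
  7: parietal
  8: frontal
  9: frontal
  10: frontal
  18: occipital
  19: occipital
  20: temporal
  21: temporal
  37: temporal
  39: parietal
  40: parietal
  41: temporal
  42: temporal
  44: frontal
  45: frontal
  46: frontal
  47: frontal
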