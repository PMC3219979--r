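model:
  s1_progress:
    CS:
      L: 0.00952
      p: 1.05
      se_L: 0.00095
      se_p: 0.091
      corr_Lp: -0.1
    RS:
      L: 0.011137
      p: 0.85
      se_L: 0.00137
      se_p: 0.08
      corr_Lp: -0.15
  s1_death:
    L: 0.00065
    p: 1.0
    se_L: 0.000325
    se_p: 0.32
    corr_Lp: 0.85
  s1_switch:
    L: 0.001525
    p: 1.0
    se_L: 0.00076
    se_p: 0.5
    corr_Lp: 0.7
  s2:
    zero_fraction:
      CS: 0.45
      RS: 0.45
    zero_fraction_se:
      CS: 0.05
      RS: 0.054
    dwell:
      CS:
        L: 0.081216795428
        p: 0.85
        se_L: 0.0135
        se_p: 0.09
        corr_Lp: -0.33
      RS:
        L: 0.081216795428
        p: 0.85
        se_L: 0.013
        se_p: 0.1
        corr_Lp: -0.26
  s3_progress:
    CS:
      L: 0.029
      p: 0.5
      se_L: 0.0058
      se_p: 0.05
      corr_Lp: -0.05
    RS:
      L: 0.04421
      p: 1.4
      se_L: 0.0039
      se_p: 0.147
      corr_Lp: -0.23
  s3_death:
    hourly_prob: 0.0005
    se: 0.00025
  s4:
    zero_fraction:
      CS: 0.55
      RS: 0.55
    zero_fraction_se:
      CS: 0.057
      RS: 0.055
    dwell:
      CS:
        L: 0.108289060571
        p: 0.85
        se_L: 0.017
        se_p: 0.129
        corr_Lp: -0.21
      RS:
        L: 0.108289060571
        p: 0.85
        se_L: 0.021
        se_p: 0.116
        corr_Lp: -0.22
  s5_progress:
    L: 0.018858105266
    p: 1.3
    se_L: 0.00116
    se_p: 0.077
    corr_Lp: -0.37
  s5_death:
    hourly_prob: 0.0003
    se: 0.00013
  s6:
    zero_fraction: 0.35
    zero_fraction_se: 0.038
    dwell:
      L: 0.073680837026
      p: 1.2
      se_L: 0.0066
      se_p: 0.101
      corr_Lp: -0.33
costs:
  sed_before:
    CS: 1.3
    RS: 7.47
  sed_during:
    CS: 0.41
    RS: 3.85
  sed_before_se:
    CS: 0.13
    RS: 0.27
  sed_during_se:
    CS: 0.12
    RS: 0.41
  icu_day_mv: 2106.0
  icu_day_mv_se: 102.0
  icu_day_nomv: 1645.0
  icu_day_nomv_se: 107.0
design:
  n_CS: 109
  n_RS: 96
  mv_censor_hours: 240.0
  followup_hours: 672.0
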