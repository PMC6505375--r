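# Default simulation scenario: a screening cohort of 159 children
# (55 ASD / 50 SLC / 54 TD) annotated by three raters of heterogeneous,
# feature-specific reliability. `separation` controls how far apart the
# class-conditional answer distributions are (0 = no class signal).
n_asd: 55
n_slc: 50
n_td: 54
separation: 0.2
raters:
  expert:
    reliability: 0.95
    missingness: 0.02
  complementary:
    # mean 0.75, arranged so its strong features complement the others
    reliability: [0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95,
                  0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95,
                  0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95, 0.55, 0.95,
                  0.55]
    missingness: 0.02
  near_chance:
    reliability: 0.40
    missingness: 0.02
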