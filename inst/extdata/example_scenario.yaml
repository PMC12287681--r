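# Example synthetic-site scenario: a short, warmer variant of the default
# subalpine conifer configuration. All omitted parameters keep their
# package defaults.
n_years: 5
start_year: 2010
latitude: 46.815
seed: 42
seasonal:
  t_air_mean:
    mean: 5.0
    trend: 0.04
nee:
  sd: 0.6
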