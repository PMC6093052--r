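# Reduced-scale demonstration pipeline: simulated spectra, three candidate
# preprocessing chains, 5-fold cross-validation.
seed: 20180801
synthetic:
  n_samples: 60
  n_points: 500
  wn_min: 4000
  wn_max: 8000
preprocess:
- []
- - method: snv
- - method: msc
- - method: savgol
    window: 11
    polyorder: 2
    deriv: 1
split:
  ratio: 0.8
cv:
  folds: 5
targets:
- tfc
- taa
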