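# Fixture configuration for `cliffopt simulate`: a scaffold library with a
# planted element-at-site activity rule (O -> S worth +2 log units).
n_scaffolds: 60       # paired scaffolds (one O and one S variant each)
n_background: 80      # single-variant scaffolds (non-cliff ligands)
site_elements: [O, S]
effects: {O: 0.0, S: 2.0}
base_range: [5.0, 7.0]
noise_sigma: 0.2
seed: 1
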