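# Example habiq pipeline run: a simulated 3-date series on a 60x60 grid
# evolved under the published 1995-2020 transition structure, assessed with
# the shipped threat and sensitivity tables.
dates: [1995, 2010, 2020]
simulate:
  size: 60
  patch_scale: 4
  transition: fixture
  clustering: 0
model:
  k: 0.5
  z: 2.5
  k_mode: fixed
breaks: [0.2, 0.5, 0.7]
masks:
  north: [1, 20, 1, 60]
  core: [21, 45, 15, 45]
seed: 42
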