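# Example desk-scale run configuration for the scaraug CLI:
#   scaraug run --config example-config.yaml --seed 1 --outdir out/
n_scar: 120
n_control: 120
n_test_per_class: 20
n_rotations_scar: 8
n_rotations_control: 8
aug_factor: 4
gan: pggan
gan_resolution: 16
gan_steps: 150
gan_fade_steps: 50
n_generate: 60
k_sigma: 1
feature_dim: 1000
phantom:
  image_size: 64
  noise_sd: 0.03
classifier:
  attention: CA
  epochs: 10
  batch_size: 32
  learning_rate: 0.001
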