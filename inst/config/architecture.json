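{
  "generator": {
    "kernel": 3,
    "stem_width": 32,
    "stem_convs": 3,
    "encoder_widths": [64, 128, 256, 512],
    "encoder_refine_convs": [2, 0, 0, 0],
    "scales": 5,
    "skip_width": 32,
    "fused_width": 160,
    "conv_bias": true,
    "upsample": "trilinear",
    "final_activation": "tanh",
    "in_channels": {"A": 7, "B": 2, "C": 1}
  },
  "discriminator": {
    "kernel": 4,
    "strides": [2, 2, 2, 1, 1],
    "widths": [96, 192, 420, 840],
    "leaky_slope": 0.2,
    "in_channels": {"A": 8, "B": 3, "C": 2}
  },
  "normalization": {
    "hu_range": [-600, 1000],
    "dose_range_rx_mult": 1.2
  },
  "structure_labels": {
    "background": -600,
    "body": -400,
    "femur_head_r": -200,
    "femur_head_l": 200,
    "rectum": 600,
    "bladder": 800,
    "ptv": 1000
  },
  "training": {
    "epochs": 500,
    "lr0": 0.002,
    "decay_start": 200,
    "adam_beta1": 0.5,
    "adam_beta2": 0.999,
    "batch_size": 4,
    "crop_size": 96,
    "lambda_cgan": 1,
    "lambda_avd": 10,
    "lambda_l1": 100
  }
}
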