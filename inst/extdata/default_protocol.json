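{
  "scheme": "dw_concept",
  "matrix": 64,
  "fov_m": 0.22,
  "tr_s": 0.6,
  "acq_delay_s": 0.0013,
  "adc_dwell_s": 4e-06,
  "n_interleaves": 3,
  "n_fid_points": 819,
  "samples_per_rev": 270,
  "n_circles": 177,
  "gmax_mT_m": 40,
  "smax_mT_m_ms": 200,
  "kernel_width": 3,
  "overgrid": 2,
  "dcf_max_iter": 50,
  "dcf_tol": 0.005,
  "deapodize": true,
  "post_correct": true,
  "noise_sd": 0,
  "seed": 1,
  "phantom": "single_disk",
  "n_replicas": 256
}
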