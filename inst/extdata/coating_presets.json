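{
  "version": "1.0",
  "notes": "Phenomenological coating parameter presets, one set per protocol regime. Values are synthetic: they are constrained only by the qualitative velocity orderings reported for each regime and by the linear/step-out structure of the propulsion law. c: speed slope (um/s per Hz); f_c0: step-out scale (Hz) at beta_ref = 0.5; p: step-out beta exponent; sigma_U: multiplicative speed noise; B_th: static-field selection threshold (mT); g_shape: static-field speed shaping (per mT^2); bump_*: optional velocity bump in 1/beta.",
  "beta_ref": 0.5,
  "regimes": {
    "sweep_1_19": {
      "protocol": {"f_min": 1, "f_max": 19, "f_step": 1, "beta": 0.5},
      "coatings": {
        "avidin":            {"c": 0.30, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin":            {"c": 0.20, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_peg3_amine": {"c": 0.45, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_chitosan":   {"c": 0.31, "f_c0": 150, "p": 0.7, "sigma_U": 0.16, "B_th": 0.1, "g_shape": 0}
      }
    },
    "sweep_5_50": {
      "protocol": {"f_min": 5, "f_max": 50, "f_step": 5, "beta": 0.175},
      "coatings": {
        "avidin":            {"c": 0.25, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin":            {"c": 0.25, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_peg3_amine": {"c": 0.18, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_chitosan":   {"c": 0.45, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0}
      }
    },
    "sweep_10_100": {
      "protocol": {"f_min": 10, "f_max": 100, "f_step": 10, "beta": 0.1},
      "coatings": {
        "avidin":            {"c": 0.24, "f_c0": 150, "p": 0.68, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin":            {"c": 0.30, "f_c0": 150, "p": 0.68, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_peg3_amine": {"c": 0.22, "f_c0": 150, "p": 0.68, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_chitosan":   {"c": 0.40, "f_c0": 150, "p": 0.68, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0}
      }
    },
    "beta_sweep_14Hz": {
      "protocol": {"f": 14, "inv_beta_min": 2, "inv_beta_max": 10},
      "coatings": {
        "avidin":            {"c": 0.30, "f_c0": 60, "p": 2, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin":            {"c": 0.20, "f_c0": 60, "p": 2, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0, "bump_amp": 0.35, "bump_center": 3, "bump_width": 1.0},
        "biotin_peg3_amine": {"c": 0.45, "f_c0": 60, "p": 2, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_chitosan":   {"c": 0.31, "f_c0": 60, "p": 2, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0, "bump_amp": 1.0, "bump_center": 4, "bump_width": 1.2}
      }
    },
    "static_sweep_15Hz": {
      "protocol": {"f": 15, "beta": 0.5, "B_s_min": -2, "B_s_max": 2, "B_s_step": 0.2},
      "coatings": {
        "avidin":            {"c": 0.30, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin":            {"c": 0.20, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0},
        "biotin_peg3_amine": {"c": 0.45, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0.12},
        "biotin_chitosan":   {"c": 0.31, "f_c0": 150, "p": 0.7, "sigma_U": 0.10, "B_th": 0.1, "g_shape": 0.10}
      }
    }
  }
}
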