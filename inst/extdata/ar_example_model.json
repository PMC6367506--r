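{
  "schema_version": "1.0",
  "pathway": "AR_example",
  "prior_active": 0.5,
  "frozen": false,
  "thresholds": {
    "default": 0
  },
  "target_genes": [
    {
      "gene": "KLK3",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "204582_s_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        },
        {
          "id": "204583_x_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "KLK2",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "209854_s_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "TMPRSS2",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "201858_s_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "NKX3-1",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "209706_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "FKBP5",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "204560_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "PMEPA1",
      "direction": "up_regulated",
      "p_up_given_active": 0.9,
      "p_up_given_inactive": 0.1,
      "probesets": [
        {
          "id": "217875_s_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    },
    {
      "gene": "SERPINB5",
      "direction": "down_regulated",
      "p_up_given_active": 0.1,
      "p_up_given_inactive": 0.9,
      "probesets": [
        {
          "id": "204855_at",
          "p_high_given_up": 0.8,
          "p_high_given_down": 0.2,
          "log2_threshold": 7,
          "soft_scale": 1
        }
      ]
    }
  ]
}
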