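{
  "groups": [
    {
      "name": "radial",
      "count": 1,
      "rel_diameter": 1,
      "law": {
        "linear": {
          "E": 7
        }
      },
      "critical_strain": 0.2
    },
    {
      "name": "axial",
      "count": 2,
      "rel_diameter": 0.2,
      "law": {
        "poly": {
          "c1": 0.1,
          "c3": 5
        }
      },
      "critical_strain": 0.5,
      "coupling": {
        "sources": "uf",
        "Cs": 0.999
      }
    },
    {
      "name": "uf",
      "count": 2,
      "rel_diameter": 0.175,
      "law": {
        "linear": {
          "E": 7
        }
      },
      "loops": {
        "count": 200,
        "threshold": {
          "mean": 0.15,
          "pm": 0.145
        },
        "hidden_length": {
          "mean": 0.038,
          "pm": 0.002
        }
      }
    },
    {
      "name": "pc",
      "count": 6,
      "rel_diameter": 0.035,
      "law": {
        "linear": {
          "E": 7
        }
      },
      "loops": {
        "count": 200,
        "threshold": {
          "mean": 0.15,
          "pm": 0.145
        },
        "hidden_length": {
          "mean": 0.038,
          "pm": 0.002
        }
      }
    }
  ],
  "settings": {
    "dx": 0.005,
    "x_max": 50,
    "slack_mode": "reset",
    "post_loop_critical_strain": 0.5,
    "seed": 1
  }
}
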