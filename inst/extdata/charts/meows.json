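{
  "name": "MEOWS",
  "trigger_rule": {
    "red": 1,
    "orange": 2
  },
  "parameters": [
    {
      "name": "temperature",
      "kind": "continuous",
      "unit": "°C",
      "domain": [
        25,
        45
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": 36,
              "upper": 37.4,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "orange",
          "intervals": [
            {
              "lower": 35,
              "upper": 36,
              "lower_closed": true,
              "upper_closed": false
            },
            {
              "lower": 37.4,
              "upper": 38,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": null,
              "upper": 35,
              "lower_closed": false,
              "upper_closed": false
            },
            {
              "lower": 38,
              "upper": null,
              "lower_closed": true,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "spo2",
      "kind": "continuous",
      "unit": "%",
      "domain": [
        0,
        100
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": 95,
              "upper": 100,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": null,
              "upper": 95,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "heart_rate",
      "kind": "continuous",
      "unit": "beats/min",
      "domain": [
        0,
        300
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": 50,
              "upper": 100,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "orange",
          "intervals": [
            {
              "lower": 100,
              "upper": 120,
              "lower_closed": false,
              "upper_closed": true
            },
            {
              "lower": 40,
              "upper": 50,
              "lower_closed": true,
              "upper_closed": false
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": null,
              "upper": 40,
              "lower_closed": false,
              "upper_closed": false
            },
            {
              "lower": 120,
              "upper": null,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "respiratory_rate",
      "kind": "continuous",
      "unit": "breaths/min",
      "domain": [
        0,
        120
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": 10,
              "upper": 20,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "orange",
          "intervals": [
            {
              "lower": 21,
              "upper": 30,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": null,
              "upper": 10,
              "lower_closed": false,
              "upper_closed": false
            },
            {
              "lower": 30,
              "upper": null,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "systolic_bp",
      "kind": "continuous",
      "unit": "mmHg",
      "domain": [
        0,
        350
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": 100,
              "upper": 150,
              "lower_closed": true,
              "upper_closed": false
            }
          ]
        },
        {
          "zone": "orange",
          "intervals": [
            {
              "lower": 90,
              "upper": 100,
              "lower_closed": true,
              "upper_closed": false
            },
            {
              "lower": 150,
              "upper": 160,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": null,
              "upper": 90,
              "lower_closed": false,
              "upper_closed": false
            },
            {
              "lower": 160,
              "upper": null,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "diastolic_bp",
      "kind": "continuous",
      "unit": "mmHg",
      "domain": [
        0,
        250
      ],
      "bands": [
        {
          "zone": "green",
          "intervals": [
            {
              "lower": null,
              "upper": 90,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        },
        {
          "zone": "orange",
          "intervals": [
            {
              "lower": 90,
              "upper": 100,
              "lower_closed": true,
              "upper_closed": true
            }
          ]
        },
        {
          "zone": "red",
          "intervals": [
            {
              "lower": 100,
              "upper": null,
              "lower_closed": false,
              "upper_closed": false
            }
          ]
        }
      ]
    },
    {
      "name": "neural_response",
      "kind": "categorical",
      "unit": "AVPU",
      "domain": [
        "alert",
        "responds_to_voice",
        "responds_to_pain",
        "unresponsive"
      ],
      "bands": [
        {
          "zone": "green",
          "categories": [
            "alert"
          ]
        },
        {
          "zone": "orange",
          "categories": [
            "responds_to_voice"
          ]
        },
        {
          "zone": "red",
          "categories": [
            "responds_to_pain",
            "unresponsive"
          ]
        }
      ]
    },
    {
      "name": "general_condition",
      "kind": "categorical",
      "unit": "appearance",
      "domain": [
        "looks_well",
        "looks_unwell"
      ],
      "bands": [
        {
          "zone": "green",
          "categories": [
            "looks_well"
          ]
        },
        {
          "zone": "orange",
          "categories": [
            "looks_unwell"
          ]
        }
      ]
    },
    {
      "name": "liquor",
      "kind": "categorical",
      "unit": "colour",
      "domain": [
        "clear",
        "meconium_stained",
        "thick_meconium",
        "blood_stained"
      ],
      "bands": [
        {
          "zone": "green",
          "categories": [
            "clear"
          ]
        },
        {
          "zone": "orange",
          "categories": [
            "meconium_stained"
          ]
        },
        {
          "zone": "red",
          "categories": [
            "thick_meconium",
            "blood_stained"
          ]
        }
      ]
    }
  ]
}
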