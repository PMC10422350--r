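{
  "templates": [
    {
      "name": "subject1_1000mL",
      "label": "target",
      "condition": "1000mL",
      "n_samples": null,
      "values": [0.0, 0.0, 0.2421, 0.0, 0.5263, 0.0, 0.2211, 0.0, 0.0]
    },
    {
      "name": "subject1_500mL",
      "label": "target",
      "condition": "500mL",
      "n_samples": null,
      "values": [0.0, 0.0, 0.0, 0.0, 0.7053, 0.0, 0.2842, 0.0, 0.0]
    },
    {
      "name": "subject1_cough",
      "label": "target",
      "condition": "cough",
      "n_samples": null,
      "values": [0.0, 0.0, 0.9053, 0.0, 0.0105, 0.0737, 0.0, 0.0, 0.0]
    },
    {
      "name": "subject2_1000mL",
      "label": "target",
      "condition": "1000mL",
      "n_samples": null,
      "values": [0.0, 0.0211, 0.3474, 0.0, 0.2421, 0.0, 0.1474, 0.2316, 0.0]
    },
    {
      "name": "subject2_500mL",
      "label": "target",
      "condition": "500mL",
      "n_samples": null,
      "values": [0.0, 0.0, 0.0, 0.0, 0.5158, 0.0, 0.4, 0.0737, 0.0]
    },
    {
      "name": "subject1_template",
      "label": "template",
      "condition": "normal",
      "n_samples": null,
      "values": [0.0, 0.0631, 0.0807, 0.0035, 0.5438, 0.0631, 0.2281, 0.007, 0.0]
    },
    {
      "name": "subject2_template",
      "label": "template",
      "condition": "normal",
      "n_samples": null,
      "values": [0.0, 0.0105, 0.4105, 0.0, 0.2211, 0.0, 0.1474, 0.2, 0.0]
    }
  ]
}
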