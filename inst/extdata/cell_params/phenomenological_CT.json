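{
  "model_id": "phenomenological",
  "variant": "CT",
  "description": "Bundle (conduction-tissue) variant of the phenomenological model: slightly faster inward time constant than the RA set.",
  "version": 1,
  "Cm_pF": 100.0,
  "conductances": {
    "tauIn": 0.25,
    "tauOut": 6.0,
    "tauOpen": 120.0,
    "tauClose": 150.0,
    "vGate": 0.13,
    "Vrest": -81.0,
    "Vamp": 113.0
  },
  "initial_state": { "V": -81.0, "hgate": 1.0 }
}
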