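{
  "model_id": "phenomenological",
  "variant": "RA",
  "description": "Two-variable phenomenological excitable model (Mitchell-Schaeffer style) with the activation variable mapped onto membrane potential in mV. Time constants in ms. Used for fast tests and geometry debugging only.",
  "version": 1,
  "Cm_pF": 100.0,
  "conductances": {
    "tauIn": 0.3,
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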