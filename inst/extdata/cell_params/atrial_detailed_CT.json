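{
  "model_id": "atrial_detailed",
  "variant": "CT",
  "description": "Crista-terminalis / conduction-bundle regional variant of the detailed human atrial model: L-type Ca2+ conductance x1.68 and transient-outward conductance x1.35 relative to the RA set, following the published regional-heterogeneity lineage for atrial bundle tissue.",
  "version": 1,
  "Cm_pF": 100.0,
  "conductances": {
    "gNa": 7.8,
    "gK1": 0.09,
    "gto": 0.223020,
    "gKr": 0.029411765,
    "gKs": 0.12941176,
    "gCaL": 0.207900,
    "gKurScale": 1.0,
    "gbNa": 0.0006744375,
    "gbCa": 0.001131,
    "INaKmax": 0.59933874,
    "INaCamax": 1600.0,
    "IpCamax": 0.275
  },
  "initial_state": {
    "V": -81.18, "m": 0.002908, "h": 0.9649, "j": 0.9775,
    "oa": 0.03043, "oi": 0.9992, "ua": 0.004966, "ui": 0.9986,
    "xr": 3.296e-05, "xs": 0.01869, "d": 0.0001367, "f": 0.9996,
    "fca": 0.7755, "u": 0.0, "v": 1.0, "w": 0.9992,
    "Nai": 11.17, "Ki": 139.0, "Cai": 0.0001013, "Caup": 1.488, "Carel": 1.488
  }
}
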