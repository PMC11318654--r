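{
  "format": "aa-cascade-catalogue",
  "version": 1,
  "compartments": [
    {
      "id": "intracellular",
      "volume_l": 1e-12
    },
    {
      "id": "extracellular",
      "volume_l": 1e-09
    }
  ]
}
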