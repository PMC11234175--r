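{
  "events": [
    {
      "time": 0,
      "kind": "add_ligand"
    },
    {
      "time": 4,
      "kind": "add_ligand"
    },
    {
      "time": 4,
      "kind": "calcium_translocation",
      "payload": [
        {
          "species": "PLA2G4A",
          "from": "Cyt",
          "to": "ERMem",
          "fraction": 0.6,
          "k_ret": 0.5
        },
        {
          "species": "PLA2G4A",
          "from": "Cyt",
          "to": "GolgiMem",
          "fraction": 0.5,
          "k_ret": 0.5
        }
      ]
    }
  ]
}
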