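{
  "nodes": [
    {
      "id": "n0",
      "position": {"x": 0, "y": 0},
      "caption": "",
      "labels": ["Species"],
      "properties": {"id": "string", "name": "string", "compartment": "string"},
      "style": {}
    },
    {
      "id": "n1",
      "position": {"x": 200, "y": 0},
      "caption": "",
      "labels": ["Reaction"],
      "properties": {"id": "string", "name": "string", "reversible": "boolean"},
      "style": {}
    },
    {
      "id": "n2",
      "position": {"x": 0, "y": 200},
      "caption": "",
      "labels": ["Compartment"],
      "properties": {"id": "string", "name": "string"},
      "style": {}
    }
  ],
  "relationships": [
    {
      "id": "r0",
      "type": "IN_COMPARTMENT",
      "fromId": "n0",
      "toId": "n2",
      "properties": {},
      "style": {}
    },
    {
      "id": "r1",
      "type": "HAS_PRODUCT",
      "fromId": "n1",
      "toId": "n0",
      "properties": {},
      "style": {}
    },
    {
      "id": "r2",
      "type": "IS_REACTANT",
      "fromId": "n1",
      "toId": "n0",
      "properties": {},
      "style": {}
    }
  ]
}
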