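{
  "nodes": [
    {"id": "n0", "labels": ["Species"],
     "properties": {"id": "string", "name": "string", "compartment": "string"}},
    {"id": "n1", "labels": ["Reaction"],
     "properties": {"id": "string", "name": "string", "reversible": "boolean"}},
    {"id": "n2", "labels": ["Compartment"],
     "properties": {"id": "string", "name": "string"}},
    {"id": "n3", "labels": ["Model"],
     "properties": {"id": "string", "name": "string"}},
    {"id": "n4", "labels": ["Parameter"],
     "properties": {"id": "string", "value": "double"}},
    {"id": "n5", "labels": ["UnitDefinition"],
     "properties": {"id": "string"}},
    {"id": "n6", "labels": ["GeneProduct"],
     "properties": {"id": "string", "label": "string"}}
  ],
  "relationships": [
    {"id": "r0", "type": "IN_COMPARTMENT", "fromId": "n0", "toId": "n2",
     "properties": {}},
    {"id": "r1", "type": "HAS_PRODUCT", "fromId": "n1", "toId": "n0",
     "properties": {}},
    {"id": "r2", "type": "IS_REACTANT", "fromId": "n1", "toId": "n0",
     "properties": {}},
    {"id": "r3", "type": "HAS_LOWERFLUXBOUND", "fromId": "n1", "toId": "n4",
     "properties": {}},
    {"id": "r4", "type": "HAS_UPPERFLUXBOUND", "fromId": "n1", "toId": "n4",
     "properties": {}},
    {"id": "r5", "type": "HAS_PARAMETER", "fromId": "n3", "toId": "n4",
     "properties": {}},
    {"id": "r6", "type": "HAS_UNIT", "fromId": "n4", "toId": "n5",
     "properties": {}},
    {"id": "r7", "type": "IS_IMPLIED", "fromId": "n1", "toId": "n6",
     "properties": {}}
  ]
}
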