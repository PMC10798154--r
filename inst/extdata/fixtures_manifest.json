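{
  "fixtures": [
    {
      "file": "toy1.xml",
      "spec": {
        "n_compartments": 1,
        "n_species": 2,
        "n_reactions": 1,
        "n_reactants": 1,
        "n_products": 1,
        "packages": [],
        "include_idless": false,
        "seed": 1
      },
      "generated_by": "sbmlgraph::generate_model(fixture_spec())",
      "schema": "schema_metabolic.json",
      "ground_truth": [
        {
          "element": "node",
          "name": "Compartment",
          "n": 1
        },
        {
          "element": "node",
          "name": "Reaction",
          "n": 1
        },
        {
          "element": "node",
          "name": "Species",
          "n": 2
        },
        {
          "element": "relationship",
          "name": "HAS_PRODUCT",
          "n": 1
        },
        {
          "element": "relationship",
          "name": "IN_COMPARTMENT",
          "n": 2
        },
        {
          "element": "relationship",
          "name": "IS_REACTANT",
          "n": 1
        }
      ]
    }
  ]
}
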