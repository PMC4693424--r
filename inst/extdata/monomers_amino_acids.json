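[
  {
    "name": "alanine",
    "smiles": "CC(N)C(=O)O"
  },
  {
    "name": "arginine",
    "smiles": "NC(CCCNC(=N)N)C(=O)O"
  },
  {
    "name": "asparagine",
    "smiles": "NC(=O)CC(N)C(=O)O"
  },
  {
    "name": "aspartate",
    "smiles": "OC(=O)CC(N)C(=O)O"
  },
  {
    "name": "cysteine",
    "smiles": "NC(CS)C(=O)O"
  },
  {
    "name": "glutamine",
    "smiles": "NC(=O)CCC(N)C(=O)O"
  },
  {
    "name": "glutamate",
    "smiles": "OC(=O)CCC(N)C(=O)O"
  },
  {
    "name": "glycine",
    "smiles": "NCC(=O)O"
  },
  {
    "name": "histidine",
    "smiles": "NC(Cc1c[nH]cn1)C(=O)O"
  },
  {
    "name": "isoleucine",
    "smiles": "CCC(C)C(N)C(=O)O"
  },
  {
    "name": "leucine",
    "smiles": "CC(C)CC(N)C(=O)O"
  },
  {
    "name": "lysine",
    "smiles": "NCCCCC(N)C(=O)O"
  },
  {
    "name": "methionine",
    "smiles": "CSCCC(N)C(=O)O"
  },
  {
    "name": "phenylalanine",
    "smiles": "NC(Cc1ccccc1)C(=O)O"
  },
  {
    "name": "proline",
    "smiles": "OC(=O)C1CCCN1"
  },
  {
    "name": "serine",
    "smiles": "NC(CO)C(=O)O"
  },
  {
    "name": "threonine",
    "smiles": "CC(O)C(N)C(=O)O"
  },
  {
    "name": "tryptophan",
    "smiles": "NC(Cc1c[nH]c2ccccc12)C(=O)O"
  },
  {
    "name": "tyrosine",
    "smiles": "NC(Cc1ccc(O)cc1)C(=O)O"
  },
  {
    "name": "valine",
    "smiles": "CC(C)C(N)C(=O)O"
  }
]
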