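[
  {
    "name": "peptide bond from NH2",
    "pattern": {
      "atoms": [
        {
          "element": "N",
          "min_h": 1
        }
      ],
      "bonds": []
    },
    "attach": 1,
    "remove_atoms": [],
    "remove_h": [
      {
        "atom": 1,
        "count": 1
      }
    ],
    "standalone": true,
    "priority": 10,
    "exclude": [
      {
        "atoms": [
          {
            "element": "N",
            "min_h": 0
          },
          {
            "element": "C",
            "min_h": 0
          },
          {
            "element": "O",
            "min_h": 0
          }
        ],
        "bonds": [
          {
            "a": 1,
            "b": 2,
            "order": "any"
          },
          {
            "a": 2,
            "b": 3,
            "order": "double"
          }
        ],
        "anchor": 1
      }
    ]
  },
  {
    "name": "peptide bond from C(=O)OH",
    "pattern": {
      "atoms": [
        {
          "element": "C",
          "min_h": 0
        },
        {
          "element": "O",
          "min_h": 0,
          "max_h": 0
        },
        {
          "element": "O",
          "min_h": 1
        }
      ],
      "bonds": [
        {
          "a": 1,
          "b": 2,
          "order": "double"
        },
        {
          "a": 1,
          "b": 3,
          "order": "single"
        }
      ]
    },
    "attach": 1,
    "remove_atoms": [
      3
    ],
    "remove_h": [],
    "standalone": true,
    "priority": 10,
    "exclude": []
  },
  {
    "name": "SH bond",
    "pattern": {
      "atoms": [
        {
          "element": "S",
          "min_h": 1,
          "max_h": 1
        }
      ],
      "bonds": []
    },
    "attach": 1,
    "remove_atoms": [],
    "remove_h": [
      {
        "atom": 1,
        "count": 1
      }
    ],
    "standalone": false,
    "priority": 5,
    "exclude": []
  }
]
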