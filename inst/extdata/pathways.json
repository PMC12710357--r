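{
  "comment": "Curated default B-vitamin (plus lipoic acid) biosynthesis step definitions. Gene symbols follow KEGG module conventions. Each step lists interchangeable gene symbols (any one intact copy satisfies the step). Steps flagged has_known_alternative_enzymes can be catalyzed by enzymes outside the canonical definition (currently only the riboflavin dephosphorylation step); missing such a step never renders a pathway nonfunctional. These definitions are configuration, not ground truth: module boundaries (notably cobalamin) are approximations and are meant to be edited per study.",
  "pathways": [
    {
      "pathway_id": "biotin",
      "steps": [
        {"step_id": "bioC", "genes": ["bioC"], "has_known_alternative_enzymes": false},
        {"step_id": "bioH", "genes": ["bioH"], "has_known_alternative_enzymes": false},
        {"step_id": "bioF", "genes": ["bioF"], "has_known_alternative_enzymes": false},
        {"step_id": "bioA", "genes": ["bioA"], "has_known_alternative_enzymes": false},
        {"step_id": "bioD", "genes": ["bioD"], "has_known_alternative_enzymes": false},
        {"step_id": "bioB", "genes": ["bioB"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "riboflavin",
      "steps": [
        {"step_id": "ribA", "genes": ["ribA"], "has_known_alternative_enzymes": false},
        {"step_id": "ribD", "genes": ["ribD"], "has_known_alternative_enzymes": false},
        {"step_id": "dephosphorylation", "genes": ["yigB", "ybjI"], "has_known_alternative_enzymes": true},
        {"step_id": "ribH", "genes": ["ribH"], "has_known_alternative_enzymes": false},
        {"step_id": "ribE", "genes": ["ribE"], "has_known_alternative_enzymes": false},
        {"step_id": "ribB", "genes": ["ribB"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "folate",
      "steps": [
        {"step_id": "folE", "genes": ["folE"], "has_known_alternative_enzymes": false},
        {"step_id": "folB", "genes": ["folB"], "has_known_alternative_enzymes": false},
        {"step_id": "folK", "genes": ["folK"], "has_known_alternative_enzymes": false},
        {"step_id": "folP", "genes": ["folP"], "has_known_alternative_enzymes": false},
        {"step_id": "folC", "genes": ["folC"], "has_known_alternative_enzymes": false},
        {"step_id": "dihydrofolate_reduction", "genes": ["folA", "folM"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "thiamine",
      "steps": [
        {"step_id": "thiC", "genes": ["thiC"], "has_known_alternative_enzymes": false},
        {"step_id": "thiD", "genes": ["thiD"], "has_known_alternative_enzymes": false},
        {"step_id": "thiG", "genes": ["thiG"], "has_known_alternative_enzymes": false},
        {"step_id": "thiE", "genes": ["thiE"], "has_known_alternative_enzymes": false},
        {"step_id": "thiL", "genes": ["thiL"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "pyridoxal",
      "steps": [
        {"step_id": "pdxA", "genes": ["pdxA"], "has_known_alternative_enzymes": false},
        {"step_id": "pdxB", "genes": ["pdxB"], "has_known_alternative_enzymes": false},
        {"step_id": "serC", "genes": ["serC"], "has_known_alternative_enzymes": false},
        {"step_id": "pdxJ", "genes": ["pdxJ"], "has_known_alternative_enzymes": false},
        {"step_id": "pdxH", "genes": ["pdxH"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "pantothenate",
      "steps": [
        {"step_id": "panB", "genes": ["panB"], "has_known_alternative_enzymes": false},
        {"step_id": "panE", "genes": ["panE"], "has_known_alternative_enzymes": false},
        {"step_id": "panC", "genes": ["panC"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "nicotinate",
      "steps": [
        {"step_id": "nadB", "genes": ["nadB"], "has_known_alternative_enzymes": false},
        {"step_id": "nadA", "genes": ["nadA"], "has_known_alternative_enzymes": false},
        {"step_id": "nadC", "genes": ["nadC"], "has_known_alternative_enzymes": false},
        {"step_id": "nadD", "genes": ["nadD"], "has_known_alternative_enzymes": false},
        {"step_id": "nadE", "genes": ["nadE"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "cobalamin",
      "steps": [
        {"step_id": "cobA", "genes": ["cobA", "btuR"], "has_known_alternative_enzymes": false},
        {"step_id": "cobU", "genes": ["cobU"], "has_known_alternative_enzymes": false},
        {"step_id": "cobS", "genes": ["cobS"], "has_known_alternative_enzymes": false},
        {"step_id": "cobC", "genes": ["cobC"], "has_known_alternative_enzymes": false}
      ]
    },
    {
      "pathway_id": "lipoic_acid",
      "steps": [
        {"step_id": "lipB", "genes": ["lipB"], "has_known_alternative_enzymes": false},
        {"step_id": "lipA", "genes": ["lipA"], "has_known_alternative_enzymes": false}
      ]
    }
  ]
}
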