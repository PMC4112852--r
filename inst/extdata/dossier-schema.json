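{
  "format": "dicescore evidence dossier",
  "version": 1,
  "dossier": {
    "required": ["factor", "phenotype", "items"],
    "optional": ["notes"]
  },
  "factor": {
    "required": ["name"],
    "optional": ["factor_class", "aliases"],
    "factor_class_enum": ["gene", "variant", "exposure", "pathway", "other"]
  },
  "phenotype": {
    "required": ["name"],
    "optional": ["description"]
  },
  "item": {
    "required": ["item_id", "category", "subtype", "source", "result_key"],
    "optional": ["p_value", "significant_override", "effect", "reviewed"],
    "category_enum": ["omic", "informatic", "experimental"],
    "subtype_enum": {
      "omic": ["discovery", "standard_validation", "alternative_validation"],
      "informatic": ["literature", "pathway_db", "expression_db", "other_db"],
      "experimental": ["animal_model", "cell_molecular", "treatment"]
    }
  },
  "effect": {
    "required": ["odds_ratio", "ci_lower", "ci_upper"],
    "optional": ["ci_level", "label"]
  }
}
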