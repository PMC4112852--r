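factor:
  name: MARVELD3
  factor_class: gene
phenotype:
  name: malaria resistance
  description: resistance to severe malaria
items:
  - item_id: marveld3_snp
    category: omic
    subtype: discovery
    p_value: 3.9e-8
    source: >-
      GWAS of severe malaria (2012): SNP rs2334880, in an intergenic region
      near (not in) MARVELD3
    result_key: "gwas2012:rs2334880"
notes: >-
  New-lead dossier with a dearth of corroborating evidence: no validation,
  informatic, or experimental items. The associated SNP is intergenic,
  between MARVELD3 and TAT in head-to-head configuration, so the signal
  may act through a neighbouring factor.
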