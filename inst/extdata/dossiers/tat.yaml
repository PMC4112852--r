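factor:
  name: TAT
  factor_class: gene
  aliases:
    - tyrosine aminotransferase
phenotype:
  name: malaria resistance
  description: resistance to severe malaria
items:
  - item_id: tat_discovery
    category: omic
    subtype: discovery
    p_value: 3.9e-8
    source: >-
      Reattribution of intergenic SNP rs2334880 (between MARVELD3 and TAT,
      head-to-head configuration) to TAT
    result_key: "gwas2012:rs2334880"
  - item_id: tat_literature
    category: informatic
    subtype: literature
    source: >-
      pubmed search 'tyrosine aminotransferase and malaria' identifies a
      paper implicating the enzyme in malaria pathophysiology [ref23]
    result_key: "pubmed:tyrosine aminotransferase and malaria"
notes: >-
  Nearby-factor reattribution of the intergenic signal near MARVELD3: the
  same underlying association credited to TAT, plus one reviewed
  literature hit.
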