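factor:
  name: ATP2B4
  factor_class: gene
  aliases:
    - PMCA4
phenotype:
  name: malaria resistance
  description: resistance to severe malaria
items:
  - item_id: atp2b4_snp1
    category: omic
    subtype: discovery
    p_value: 6.1e-9
    source: "GWAS of severe malaria (2012), SNP 1 in ATP2B4"
    result_key: "gwas2012:atp2b4_snp1"
  - item_id: atp2b4_snp2
    category: omic
    subtype: discovery
    p_value: 1.5e-8
    source: "GWAS of severe malaria (2012), SNP 2 in ATP2B4"
    result_key: "gwas2012:atp2b4_snp2"
  - item_id: atp2b4_snp3
    category: omic
    subtype: discovery
    p_value: 2.1e-8
    source: "GWAS of severe malaria (2012), SNP 3 in ATP2B4"
    result_key: "gwas2012:atp2b4_snp3"
  - item_id: atp2b4_snp4
    category: omic
    subtype: discovery
    p_value: 5.1e-8
    source: "GWAS of severe malaria (2012), SNP 4 in ATP2B4 (just above threshold)"
    result_key: "gwas2012:atp2b4_snp4"
  - item_id: atp2b4_snp5
    category: omic
    subtype: discovery
    p_value: 3.4e-8
    source: "GWAS of severe malaria (2012), SNP 5 in ATP2B4"
    result_key: "gwas2012:atp2b4_snp5"
  - item_id: atp2b4_alt_validation
    category: omic
    subtype: alternative_validation
    significant_override: true
    source: >-
      Synthetic reconstruction: alternative statistical validation of the
      ATP2B4 association (the original implementation detail is in an
      unavailable supplement)
    result_key: "alt:atp2b4_validation"
  - item_id: atp2b4_literature
    category: informatic
    subtype: literature
    source: >-
      Literature on ATP2B4 as the primary erythrocyte calcium pump, with
      calcium homeostasis relevant to intra-erythrocytic Plasmodium
      development
    result_key: "pubmed:atp2b4 and malaria"
  - item_id: atp2b4_experimental
    category: experimental
    subtype: cell_molecular
    source: >-
      Cell/molecular work on erythrocyte calcium handling and parasite
      development supporting a role for the pump
    result_key: "exp:atp2b4_calcium"
notes: >-
  New-lead dossier. The alternative-validation entry is a synthetic
  reconstruction encoding the reported component pattern; the underlying
  supplementary detail is not available. SNP identifiers are positional
  placeholders for the five reported association p-values.
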