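# Chemosensory class gene-order signatures. Tokens: A=CheA, B=CheB, C=CheC,
# D=CheD, K=other kinase gene, M=chemoreceptor (MCP), R=CheR, S=STAS,
# V=CheV, W=CheW, X=CheX, Y=CheY, Z=CheZ, "."=expected hypothetical gene.
# These orders are best-effort transcriptions of published cluster diagrams;
# replace with curated signatures for other lineages as needed.
signatures:
  - class_name: F3
    gene_order: [V, A, W]
    required_components: [CheV, CheA, CheW]
    auxiliary_rules: [cheA_has_rec, aux_cheB_without_rec]
    max_insertions: 1
  - class_name: F7
    gene_order: [A, W, M, B, R]
    required_components: [CheA, CheW, MCP, CheB, CheR]
    max_insertions: 2
  - class_name: F8
    gene_order: [W, A, Y, M, R, B]
    required_components: [CheW, CheA, CheY, MCP, CheR, CheB]
    max_insertions: 2
  - class_name: F9
    gene_order: [M, W, A, B, R, Y]
    required_components: [MCP, CheW, CheA, CheB, CheR, CheY]
    max_insertions: 2
  - class_name: F14
    gene_order: [S, A, W, M, B, R, D]
    required_components: [STAS, CheA, CheW, MCP, CheB, CheR, CheD]
    max_insertions: 2
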