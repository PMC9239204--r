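# Quorum-sensing pathway screen: per pathway, synthase-diagnostic and
# receptor-ligand-binding domain identifiers. Best-effort defaults; QS
# component inventories are curation-dependent, so override freely.
pathways:
  AHL:
    synthase: [PF00765, Autoind_synth]
    receptor: [PF03472, Autoind_bind]
  AI2:
    synthase: [PF02664, LuxS]
    receptor: [LuxP, PF13407]
  CAI1:
    synthase: [CqsA]
    receptor: [CqsS_6TM]
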