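# Domain vocabulary: role token -> accepted identifiers (Pfam accession,
# Pfam name, common aliases). Mirrors default_vocabulary(); edit a copy and
# point run_census() at it to change domain coverage.
HisKA: [PF00512, HisKA, HisKA_2, PF07568]
HATPase: [PF02518, HATPase_c, HATPase, PF13581, HATPase_c_3]
REC: [PF00072, Response_reg, REC]
Hpt: [PF01627, Hpt, HPT]
GGDEF: [PF00990, GGDEF]
EAL: [PF00563, EAL]
HD_GYP: [PF13487, HD-GYP, HD_GYP, HD_5]
sigma70_r2: [PF04542, Sigma70_r2]
sigma70_r4_2: [PF08281, Sigma70_r4_2]
AC: [PF01295, Adenylate_cycl, PF00211, Guanylate_cyc]
CHASE2: [PF05226, CHASE2]
Pkinase: [PF00069, Pkinase]
PP2C: [PF00481, PP2C, PF07228, SpoIIE]
STAS: [PF01740, STAS]
MCPsignal: [PF00015, MCPsignal, MA, MCP_signal]
CheW: [PF01584, CheW]
CheB: [PF01339, CheB_methylest]
CheR: [PF01739, CheR, PF03705, CheR_N]
CheC: [PF04509, CheC]
CheX: [PF13690, CheX]
CheD: [PF03975, CheD]
CheZ: [PF04344, CheZ]
FecR: [PF04773, FecR]
TonB_receptor: [PF00593, TonB_dep_Rec, Plug, PF07715]
TPR: [PF00515, TPR_1, PF07719, TPR_2, PF13176, TPR_7]
CAMP_PDE: [PF00233, PDEase_I, PF02112, PDEase_II]
CRP: [PF00325, Crp, HTH_Crp_2, PF13545]
hth_output: [PF00196, GerE, PF00486, Trans_reg_C, PF02954, HTH_8,
             PF12833, HTH_18, PF00165, HTH_AraC, PF01978, HTH_10,
             PF13384, HTH_23, PF04397, LytTR]
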